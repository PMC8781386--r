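## Clonal collapse and mutation-load filtering.
##
## Sequences with identical V, D (if applicable) and J genes, identical CDR3
## length and >= 95% pairwise nucleotide CDR3 identity are treated as one
## clone and reduced to the least mutated member, minimising amplification
## and sequencing artifacts. Unmutated sequences and sequences with > 5%
## V-region mutations are excluded from the main analysis; the hypermutated
## remainder can be binned for side-by-side processing.

gene_of <- function(call) sub("\\*.*$", "", call)

clonotype_key <- function(records) {
  d <- ifelse(is.na(records$d_call) | !nzchar(records$d_call),
              "", gene_of(records$d_call))
  j <- ifelse(is.na(records$j_call) | !nzchar(records$j_call),
              "", gene_of(records$j_call))
  paste(gene_of(records$v_call), d, j, nchar(records$cdr3), sep = "|")
}

#' Collapse clonally related records to their least mutated member
#'
#' Records sharing V, D (if present) and J gene (allele suffix stripped) and
#' CDR3 length are clustered by CDR3 nucleotide identity (Hamming identity
#' on the equal-length CDR3s, single linkage); each cluster is replaced by
#' its member with the minimal `mutation_count`. Ties are broken by the
#' lexicographically smallest `sequence_id` for determinism.
#'
#' @param records data.frame with `v_call`, `d_call`, `j_call`, `cdr3`,
#'   `mutation_count`, `sequence_id`.
#' @param identity_threshold minimum CDR3 identity fraction for two records
#'   to be joined (default 0.95).
#' @return data.frame of surviving records (one per clone).
#' @export
collapse_clones <- function(records, identity_threshold = 0.95) {
  if (nrow(records) == 0L) return(records)
  keys <- clonotype_key(records)
  keep_idx <- integer(0)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    n <- length(idx)
    if (n == 1L) { keep_idx <- c(keep_idx, idx); next }
    cdr3 <- toupper(records$cdr3[idx])
    len <- nchar(cdr3[[1]])
    # union-find over >= threshold pairs: single linkage
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (len > 0L) {
      chars <- do.call(rbind, strsplit(cdr3, "", fixed = TRUE))
      for (a in seq_len(n - 1L)) {
        for (b in seq.int(a + 1L, n)) {
          ident <- sum(chars[a, ] == chars[b, ]) / len
          if (ident >= identity_threshold) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[rb] <- ra
          }
        }
      }
    } else {
      parent[] <- 1L  # zero-length CDR3s are identical by convention
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      m <- records$mutation_count[members]
      best <- members[m == min(m)]
      if (length(best) > 1L) {
        best <- best[order(records$sequence_id[best])][[1]]
      }
      keep_idx <- c(keep_idx, best)
    }
  }
  out <- records[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition records by V-region mutation load
#'
#' A record is kept iff `0 < m / L <= max_fraction`, where `m` is its
#' mutation count and `L` the ungapped length of its germline V allele.
#' Unmutated records and records above the threshold are returned in
#' separate partitions (the partition is exhaustive).
#'
#' @param records data.frame with `v_call` and `mutation_count`.
#' @param alleles named list of `germline_allele` (see
#'   [read_germline_fasta()]).
#' @param max_fraction maximum mutated fraction retained (default 0.05).
#' @return list with elements `kept`, `excluded_unmutated`,
#'   `excluded_hypermutated` (data.frames).
#' @export
filter_by_mutation_load <- function(records, alleles, max_fraction = 0.05) {
  frac <- mutation_fraction(records, alleles)
  unmut <- records$mutation_count == 0L
  hyper <- !unmut & frac > max_fraction
  kept <- !unmut & !hyper
  list(
    kept = droprows(records, kept),
    excluded_unmutated = droprows(records, unmut),
    excluded_hypermutated = droprows(records, hyper)
  )
}

#' Bin hypermutated records by mutation load
#'
#' Records with `m / L > 0.05` are assigned to left-open/right-closed bins
#' `(0.05, 0.10]`, `(0.10, 0.20]`, `(0.20, 1]`; records at or below 5%
#' belong to the main analysis set and are not binned.
#'
#' @inheritParams filter_by_mutation_load
#' @return named list of data.frames, one per bin.
#' @export
bin_by_mutation_load <- function(records, alleles) {
  frac <- mutation_fraction(records, alleles)
  list(
    "(0.05,0.10]" = droprows(records, frac > 0.05 & frac <= 0.10),
    "(0.10,0.20]" = droprows(records, frac > 0.10 & frac <= 0.20),
    "(0.20,1]"    = droprows(records, frac > 0.20)
  )
}

mutation_fraction <- function(records, alleles) {
  if (nrow(records) == 0L) return(numeric(0))
  L <- vapply(records$v_call, function(v) {
    a <- alleles[[v]]
    if (is.null(a)) stop("unknown allele in v_call: ", v)
    a$length_ungapped
  }, numeric(1))
  records$mutation_count / L
}

droprows <- function(df, keep) {
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
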