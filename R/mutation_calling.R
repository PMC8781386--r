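## Substitution calling: maximal runs of adjacent mutated positions against
## the germline V allele, with 1-nt flanking context. Insertions/deletions
## and ambiguous bases are disregarded: a gap or N column is never mutated
## and splits a run in two. Events are reported in 0-based ungapped germline
## coordinates.

#' Call substitution events for one record
#'
#' Compares the gapped sequence alignment to the germline allele column by
#' column, drops germline '.' gap columns entirely, and groups maximal runs
#' of adjacent mutated ungapped positions into events. Observed `N`, `-` or
#' `.` characters are never counted as mutated and split runs. Flanks are
#' the germline bases adjacent to the run; the sentinel `'-'` marks a
#' sequence boundary and `'N'` marks an adjacent unreadable observed base.
#'
#' @param record one-row data.frame (or list) with `sequence_id` and
#'   `sequence_alignment`.
#' @param allele matching `germline_allele`; its aligned length must equal
#'   the record's alignment length.
#' @param scan_end optional exclusive upper bound (ungapped position) on the
#'   scanned V region, e.g. the position corresponding to IMGT codon 104;
#'   `NULL` scans the whole alignment.
#' @return data.frame of events with columns `sequence_id`, `allele`,
#'   `start`, `k`, `germline`, `observed`, `flank5`, `flank3`.
#' @export
call_substitutions <- function(record, allele, scan_end = NULL) {
  obs <- toupper(record$sequence_alignment[[1]])
  if (nchar(obs) != nchar(allele$sequence)) {
    stop("alignment length mismatch for sequence_id ", record$sequence_id[[1]],
         ": ", nchar(obs), " vs germline ", nchar(allele$sequence))
  }
  oc <- strsplit(obs, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(oc), c(NUCS, "N", ".", "-"))
  if (length(bad) > 0L) {
    stop("invalid alignment character(s) for sequence_id ",
         record$sequence_id[[1]], ": ", paste(bad, collapse = ", "))
  }
  gc <- strsplit(allele$sequence, "", fixed = TRUE)[[1]]
  keep <- gc != "."          # germline gap columns carry no position
  oc <- oc[keep]; gc <- gc[keep]
  L <- length(gc)
  readable <- oc %in% NUCS
  mutated <- readable & oc != gc
  if (!is.null(scan_end)) {
    scan_end <- min(as.integer(scan_end), L)
    if (scan_end < L) mutated[(scan_end + 1L):L] <- FALSE
  }
  events_from_mask(mutated, gc, oc, record$sequence_id[[1]], allele$name)
}

## Group a logical mutation mask into maximal-run events.
events_from_mask <- function(mutated, gc, oc, sequence_id, allele_name) {
  empty <- data.frame(
    sequence_id = character(0), allele = character(0), start = integer(0),
    k = integer(0), germline = character(0), observed = character(0),
    flank5 = character(0), flank3 = character(0), stringsAsFactors = FALSE
  )
  if (!any(mutated)) return(empty)
  r <- rle(mutated)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  L <- length(mutated)
  flank_at <- function(p) {
    if (p < 1L || p > L) return("-")          # boundary sentinel
    if (!(oc[p] %in% NUCS)) return("N")       # unreadable neighbour
    gc[p]
  }
  data.frame(
    sequence_id = sequence_id,
    allele = allele_name,
    start = starts[runs] - 1L,                 # to 0-based
    k = r$lengths[runs],
    germline = vapply(runs, function(i)
      paste(gc[starts[i]:ends[i]], collapse = ""), character(1)),
    observed = vapply(runs, function(i)
      paste(oc[starts[i]:ends[i]], collapse = ""), character(1)),
    flank5 = vapply(runs, function(i) flank_at(starts[i] - 1L), character(1)),
    flank3 = vapply(runs, function(i) flank_at(ends[i] + 1L), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Call substitution events for a whole repertoire
#'
#' @param records data.frame of rearrangement records.
#' @param alleles named list of `germline_allele`.
#' @param scan_end as in [call_substitutions()].
#' @return data.frame of events across all records, sorted by record order
#'   then start.
#' @export
call_substitutions_all <- function(records, alleles, scan_end = NULL) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    a <- alleles[[rec$v_call]]
    if (is.null(a)) stop("unknown allele in v_call: ", rec$v_call)
    call_substitutions(rec, a, scan_end = scan_end)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tabulate run lengths of substitution events
#'
#' @param events events data.frame.
#' @return named integer vector mapping run length `k` to event count
#'   (empty vector for no events). `sum(k * count)` equals the number of
#'   mutated positions.
#' @export
tabulate_run_lengths <- function(events) {
  if (nrow(events) == 0L) return(structure(integer(0), names = character(0)))
  tab <- table(events$k)
  structure(as.integer(tab), names = names(tab))
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Transition/transversion ratio of single nucleotide substitutions
#'
#' Considers only `k = 1` events; transitions are A<->G and C<->T.
#'
#' @param events events data.frame.
#' @return list with `ratio`, `transitions`, `transversions` and a `flag`:
#'   `"ok"`, `"infinite"` (no transversions) or `"undefined"` (no SNS).
#' @export
compute_ts_tv <- function(events) {
  sns <- events[events$k == 1L, , drop = FALSE]
  if (nrow(sns) == 0L) {
    return(list(ratio = NA_real_, transitions = 0L, transversions = 0L,
                flag = "undefined"))
  }
  is_ts <- TRANSITIONS[sns$germline] == sns$observed
  ts <- sum(is_ts); tv <- sum(!is_ts)
  if (tv == 0L) {
    return(list(ratio = Inf, transitions = ts, transversions = 0L,
                flag = "infinite"))
  }
  list(ratio = ts / tv, transitions = ts, transversions = tv, flag = "ok")
}
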