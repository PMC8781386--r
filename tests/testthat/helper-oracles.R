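# Independent brute-force oracles and small fixture builders.

# Brute-force run scanner: marks mutated positions one by one and groups
# maximal runs with an explicit while-loop (independent of the rle-based
# production path). Inputs are plain ungapped strings.
oracle_runs <- function(germline, observed) {
  g <- strsplit(germline, "", fixed = TRUE)[[1]]
  o <- strsplit(observed, "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  mut <- g %in% acgt & o %in% acgt & g != o
  starts <- integer(0); ks <- integer(0)
  i <- 1L
  while (i <= length(mut)) {
    if (mut[i]) {
      j <- i
      while (j < length(mut) && mut[j + 1L]) j <- j + 1L
      starts <- c(starts, i - 1L)   # 0-based
      ks <- c(ks, j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, k = ks)
}

# Brute-force translator using Biostrings::translate (a different code path
# than the GENETIC_CODE lookup used by the package).
oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# Effect of one single-base substitution per the oracle translator.
oracle_sub_effect <- function(codon, pos, base) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  before <- oracle_translate(codon)
  chars[pos] <- base
  after <- oracle_translate(paste(chars, collapse = ""))
  if (after == "*") "nonsense" else if (after == before) "synonymous"
  else "nonsynonymous"
}

# Minimal one-row record for call_substitutions().
make_record <- function(sequence_alignment, sequence_id = "S1",
                        v_call = "X", cdr3 = "AAATTT") {
  data.frame(sequence_id = sequence_id, v_call = v_call, d_call = "D1*01",
             j_call = "J1*01", sequence_alignment = sequence_alignment,
             germline_alignment = NA_character_, cdr3 = cdr3,
             isotype = "IGHM", stringsAsFactors = FALSE)
}

# Events data.frame builder for classification-level tests.
make_events <- function(start, k, germline, observed, allele = "X",
                        sequence_id = "S1") {
  n <- length(start)
  data.frame(sequence_id = rep_len(sequence_id, n),
             allele = rep_len(allele, n), start = start,
             k = k, germline = germline, observed = observed,
             flank5 = rep_len("-", n), flank3 = rep_len("-", n),
             stringsAsFactors = FALSE)
}

# Minimal records table for selection-stage tests.
make_selection_records <- function(ids, cdr3s, mutation_counts,
                                   v_call = "IGHV1-1*01", d_call = "IGHD1-1*01",
                                   j_call = "IGHJ4*01") {
  data.frame(sequence_id = ids, v_call = v_call, d_call = d_call,
             j_call = j_call, sequence_alignment = NA_character_,
             germline_alignment = NA_character_, cdr3 = cdr3s,
             isotype = "IGHM", mutation_count = mutation_counts,
             stringsAsFactors = FALSE)
}

random_dinuc_events <- function(n, seed) {
  set.seed(seed)
  nucs <- c("A", "C", "G", "T")
  ref <- paste0(sample(nucs, n, TRUE), sample(nucs, n, TRUE))
  alt <- vapply(ref, function(r) {
    paste0(sample(setdiff(nucs, substr(r, 1, 1)), 1),
           sample(setdiff(nucs, substr(r, 2, 2)), 1))
  }, character(1), USE.NAMES = FALSE)
  make_events(start = rep(0L, n), k = rep(2L, n), germline = ref,
              observed = alt)
}
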