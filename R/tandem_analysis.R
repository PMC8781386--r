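## Tandem dinucleotide substitution (TDNS) analysis: juxtalocation /
## inversion geometry, codon frame and amino-acid effect, germline context
## containment, AID hotspot motifs, 144-cell dinucleotide substitution
## tables and their COSMIC-style DBS-78 collapse.

#' Classify a tandem dinucleotide substitution by its geometry
#'
#' For a reference dinucleotide `XY` mutated to `X'Y'` (both bases
#' substituted): an *inversion* exchanges both bases (`X' = Y` and
#' `Y' = X`); a *juxtalocation of the 5' base* re-places the germline 5'
#' base at the 3' slot (`Y' = X`, `X' != Y`), i.e. the downstream sequence
#' shifted up one position; a *juxtalocation of the 3' base* is the mirror
#' case (`X' = Y`, `Y' != X`); anything else is *other*. Inversion takes
#' precedence since it satisfies both equalities. For a homodimer reference
#' (`X = Y`) neither equality can legally hold, so the only possible
#' category is `other`.
#'
#' @param germline,observed character vectors of length-2 dinucleotides;
#'   each observed base must differ from its germline counterpart.
#' @return character vector over `{"inversion", "juxtalocation_5p",
#'   "juxtalocation_3p", "other"}`.
#' @export
classify_tdns <- function(germline, observed) {
  if (any(nchar(germline) != 2L) || any(nchar(observed) != 2L)) {
    stop("classify_tdns requires k = 2 events (dinucleotides)")
  }
  X <- substr(germline, 1, 1); Y <- substr(germline, 2, 2)
  Xp <- substr(observed, 1, 1); Yp <- substr(observed, 2, 2)
  if (any(Xp == X) || any(Yp == Y)) {
    stop("both bases must be substituted (X' != X and Y' != Y)")
  }
  ifelse(Xp == Y & Yp == X, "inversion",
    ifelse(Yp == X, "juxtalocation_5p",
      ifelse(Xp == Y, "juxtalocation_3p", "other")))
}

#' Expected TDNS category fractions under a uniform outcome null
#'
#' Enumerates, for every heterodimer reference dinucleotide, the 9 legal
#' double-base outcomes, classifies each with [classify_tdns()], and
#' averages assuming all outcomes equally likely. Yields inversion 1/9,
#' pooled juxtalocation 4/9, other 4/9.
#'
#' @return named numeric vector `c(inversion, juxtalocation, other)`
#'   summing to 1.
#' @export
expected_category_fractions <- function() {
  counts <- c(inversion = 0, juxtalocation = 0, other = 0)
  n <- 0L
  for (X in NUCS) for (Y in setdiff(NUCS, X)) {
    for (Xp in setdiff(NUCS, X)) for (Yp in setdiff(NUCS, Y)) {
      cl <- classify_tdns(paste0(X, Y), paste0(Xp, Yp))
      cl <- if (cl %in% c("juxtalocation_5p", "juxtalocation_3p"))
        "juxtalocation" else cl
      counts[cl] <- counts[cl] + 1
      n <- n + 1L
    }
  }
  counts / n
}

#' Test an observed category proportion against an expected fraction
#'
#' One-sample two-sided z-test on the proportion (normal approximation);
#' used as the stand-in for a t-test on category fractions.
#'
#' @param observed_count events in the category.
#' @param total total events.
#' @param expected_fraction null fraction, strictly inside (0, 1).
#' @return list with `statistic` (z), `p_value`, and the observed
#'   `proportion`.
#' @export
compare_fraction_to_expected <- function(observed_count, total,
                                         expected_fraction) {
  if (total <= 0) stop("total must be positive")
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    stop("expected_fraction must lie strictly inside (0, 1)")
  }
  p_hat <- observed_count / total
  se <- sqrt(expected_fraction * (1 - expected_fraction) / total)
  z <- (p_hat - expected_fraction) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), proportion = p_hat)
}

#' Codon slot of a tandem event
#'
#' Slot 1: the event covers codon bases 1-2; slot 2: bases 2-3; slot 3:
#' base 3 plus base 1 of the downstream codon.
#'
#' @param start 0-based ungapped start position(s) of k = 2 events.
#' @param allele `germline_allele` supplying `frame_offset`.
#' @return integer vector in `1:3`.
#' @export
assign_codon_slot <- function(start, allele) {
  f <- allele$frame_offset
  if (any(start < f)) stop("event upstream of reading frame start")
  ((start - f) %% 3L) + 1L
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(GENETIC_CODE_TABLE[codon])

#' Amino-acid effect of substitution events
#'
#' Translates the codon(s) affected by each `k <= 2` event before and after
#' substitution using the standard genetic code. Effects: `synonymous`,
#' `nonsynonymous`, `nonsense` (any affected codon becomes a stop), and for
#' slot-3 tandems spanning two codons also `double_synonymous` (both codons
#' silent) and `double_replacement` (both amino acids changed; a mixed
#' silent/replacement pair reports `nonsynonymous`). Events that cannot be
#' assessed (upstream of the frame, incomplete trailing codon, k > 2) get
#' `NA` with the reason recorded.
#'
#' @param events events data.frame for a single allele.
#' @param allele matching `germline_allele`.
#' @return data.frame with columns `codon_slot`, `effect`, `skip_reason`,
#'   row-parallel to `events`.
#' @export
classify_effect <- function(events, allele) {
  g <- strsplit(allele$ungapped, "", fixed = TRUE)[[1]]
  f <- allele$frame_offset
  L <- length(g)
  n <- nrow(events)
  slot <- integer(n); eff <- character(n); reason <- character(n)
  codon_at <- function(chars, q) paste(chars[(f + 3L * q + 1L):(f + 3L * q + 3L)],
                                       collapse = "")
  for (i in seq_len(n)) {
    s <- events$start[i]; k <- events$k[i]
    if (k > 2L) { slot[i] <- NA; eff[i] <- NA; reason[i] <- "k_gt_2"; next }
    if (s < f) { slot[i] <- NA; eff[i] <- NA; reason[i] <- "upstream_of_frame"; next }
    slot[i] <- ((s - f) %% 3L) + 1L
    q <- (s - f) %/% 3L
    q_last <- (s + k - 1L - f) %/% 3L     # codon of the 3'-most base
    if (f + 3L * (q_last + 1L) > L) {
      slot[i] <- slot[i]; eff[i] <- NA; reason[i] <- "incomplete_codon"; next
    }
    mut <- g
    obs <- strsplit(events$observed[i], "", fixed = TRUE)[[1]]
    mut[(s + 1L):(s + k)] <- obs
    qs <- q:q_last
    before <- vapply(qs, function(qq) translate_codon(codon_at(g, qq)), character(1))
    after <- vapply(qs, function(qq) translate_codon(codon_at(mut, qq)), character(1))
    reason[i] <- ""
    if (any(after == "*")) { eff[i] <- "nonsense"; next }
    changed <- before != after
    if (length(qs) == 1L) {
      eff[i] <- if (changed) "nonsynonymous" else "synonymous"
    } else {
      eff[i] <- if (!any(changed)) "double_synonymous"
        else if (all(changed)) "double_replacement"
        else "nonsynonymous"
    }
  }
  data.frame(codon_slot = slot, effect = eff, skip_reason = reason,
             stringsAsFactors = FALSE)
}

#' Germline context containment of a tandem outcome
#'
#' Checks whether the observed dinucleotide of a k = 2 event is already
#' present in the germline immediately around the site: at offset -1
#' (positions `start - 1`, `start`) and/or at offset +1 (positions
#' `start + 1`, `start + 2`). Windows extending past the sequence boundary
#' never match.
#'
#' @param events k = 2 events data.frame for a single allele.
#' @param allele matching `germline_allele`.
#' @return character vector over `{"not_present", "pos_minus1", "pos_t2",
#'   "both"}`.
#' @export
germline_context_containment <- function(events, allele) {
  stopifnot(all(events$k == 2L))
  g <- strsplit(allele$ungapped, "", fixed = TRUE)[[1]]
  L <- length(g)
  vapply(seq_len(nrow(events)), function(i) {
    s <- events$start[i]; obs <- events$observed[i]
    m1 <- s >= 1L && paste0(g[s], g[s + 1L]) == obs
    p1 <- s + 3L <= L && paste0(g[s + 2L], g[s + 3L]) == obs
    if (m1 && p1) "both" else if (m1) "pos_minus1" else if (p1) "pos_t2"
    else "not_present"
  }, character(1))
}

## AID hotspot motifs searched on the coding strand. Reverse-complement
## occurrences (template-strand motifs) are searched as their coding-strand
## image: WRCY -> RGYW, WA -> TW, RCG -> CGY. `offset` is the 0-based
## position of the hotspot base (the deaminated C of WRCY/RCG, the A of WA,
## or its complement for the reverse-complement image) within the motif.
AID_MOTIFS <- list(
  list(motif = "WRCY", strand = "fwd", pattern = "WRCY", offset = 2L),
  list(motif = "WRCY", strand = "rc",  pattern = "RGYW", offset = 1L),
  list(motif = "WA",   strand = "fwd", pattern = "WA",   offset = 1L),
  list(motif = "WA",   strand = "rc",  pattern = "TW",   offset = 0L),
  list(motif = "RCG",  strand = "fwd", pattern = "RCG",  offset = 1L),
  list(motif = "RCG",  strand = "rc",  pattern = "CGY",  offset = 1L)
)

#' Annotate AID hotspot motifs at event ends
#'
#' For each of the motifs WRCY, WA and RCG (forward and
#' reverse-complement), a flag is set iff some occurrence in the germline
#' has its hotspot base coinciding with the event's 5'-most (`_5p_`) or
#' 3'-most (`_3p_`) base.
#'
#' @param events events data.frame for a single allele (any k).
#' @param allele matching `germline_allele`.
#' @return logical data.frame with 12 columns named
#'   `<MOTIF>_<5p|3p>_<fwd|rc>`, row-parallel to `events`.
#' @export
annotate_aid_motifs <- function(events, allele) {
  subject <- Biostrings::DNAString(allele$ungapped)
  out <- list()
  for (m in AID_MOTIFS) {
    hits <- Biostrings::matchPattern(m$pattern, subject, fixed = FALSE)
    hot <- Biostrings::start(hits) - 1L + m$offset   # 0-based hotspot bases
    out[[paste0(m$motif, "_5p_", m$strand)]] <- events$start %in% hot
    out[[paste0(m$motif, "_3p_", m$strand)]] <-
      (events$start + events$k - 1L) %in% hot
  }
  as.data.frame(out[order(names(out))], stringsAsFactors = FALSE)
}

#' Build a dinucleotide substitution table from k = 2 events
#'
#' @param events events data.frame; every event must have `k = 2`.
#' @return `dinuc_table` whose total equals the number of events.
#' @export
build_dinuc_table <- function(events) {
  if (nrow(events) > 0L && any(events$k != 2L)) {
    stop("build_dinuc_table requires k = 2 events only")
  }
  tab <- dinuc_table()
  for (i in seq_len(nrow(events))) {
    tab[events$germline[i], events$observed[i]] <-
      tab[events$germline[i], events$observed[i]] + 1
  }
  tab
}

## The 78 canonical COSMIC doublet-base-substitution classes: 10 canonical
## reference doublets; for palindromic references, outcome pairs that are
## mutual reverse complements collapse onto the conventional representative.
DBS78_CLASSES <- c(
  "AC>CA", "AC>CG", "AC>CT", "AC>GA", "AC>GG", "AC>GT", "AC>TA", "AC>TG", "AC>TT",
  "AT>CA", "AT>CC", "AT>CG", "AT>GA", "AT>GC", "AT>TA",
  "CC>AA", "CC>AG", "CC>AT", "CC>GA", "CC>GG", "CC>GT", "CC>TA", "CC>TG", "CC>TT",
  "CG>AT", "CG>GC", "CG>GT", "CG>TA", "CG>TC", "CG>TT",
  "CT>AA", "CT>AC", "CT>AG", "CT>GA", "CT>GC", "CT>GG", "CT>TA", "CT>TC", "CT>TG",
  "GC>AA", "GC>AG", "GC>AT", "GC>CA", "GC>CG", "GC>TA",
  "TA>AT", "TA>CG", "TA>CT", "TA>GC", "TA>GG", "TA>GT",
  "TC>AA", "TC>AG", "TC>AT", "TC>CA", "TC>CG", "TC>CT", "TC>GA", "TC>GG", "TC>GT",
  "TG>AA", "TG>AC", "TG>AT", "TG>CA", "TG>CC", "TG>CT", "TG>GA", "TG>GC", "TG>GT",
  "TT>AA", "TT>AC", "TT>AG", "TT>CA", "TT>CC", "TT>CG", "TT>GA", "TT>GC", "TT>GG"
)

#' The canonical DBS-78 class labels
#' @return character vector of length 78.
#' @export
dbs78_classes <- function() DBS78_CLASSES

revcomp_dinuc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0(comp[substr(x, 2, 2)], comp[substr(x, 1, 1)])
}

dbs78_class_of <- function(ref, alt) {
  lab <- paste0(ref, ">", alt)
  ifelse(lab %in% DBS78_CLASSES, lab,
         paste0(revcomp_dinuc(ref), ">", revcomp_dinuc(alt)))
}

#' Collapse a dinucleotide substitution table to a DBS-78 catalog
#'
#' Each of the 144 legal cells maps to its canonical class: kept as-is when
#' `ref>alt` is one of the 78 canonical labels, otherwise both reference
#' and alternate are reverse-complemented. Total mass is conserved; a table
#' and its strand-wise reverse complement yield the identical catalog.
#'
#' @param table a `dinuc_table`.
#' @return named numeric vector of length 78 over [dbs78_classes()].
#' @export
to_dbs78 <- function(table) {
  stopifnot(inherits(table, "dinuc_table"))
  out <- structure(numeric(78L), names = DBS78_CLASSES)
  for (ref in DINUCS) {
    for (alt in DINUCS) {
      v <- table[ref, alt]
      if (is.na(v) || v == 0) next
      cl <- dbs78_class_of(ref, alt)
      out[cl] <- out[cl] + v
    }
  }
  out
}

#' Cosine similarity of two signature vectors
#'
#' @param a,b numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return `dot(a, b) / (|a| |b|)`, in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}
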