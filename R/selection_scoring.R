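## Mutational resistance scoring.
##
## For every sense codon, the 9 possible single-base substitutions are
## classified as synonymous, non-synonymous or nonsense. Nonsense
## substitutions are disregarded (a BCR with a stop codon is deleted from
## the repertoire), and the chance of a random substitution being
## synonymous is computed from the rest. Weighted by germline codon usage
## this yields a per-position expected synonymous proportion; the observed
## synonymous proportion of SNS minus this expectation is the mutational
## resistance score (higher = more resistant, i.e. more synonymous
## mutations than expected, suggesting purifying selection). Tandem counts
## per position are then regressed on the score with quasi-Poisson
## regression.

#' Synonymity profile of a sense codon
#'
#' Enumerates the 9 single-base substitutions of `codon` against the
#' standard genetic code.
#'
#' @param codon a 3-letter sense codon.
#' @return list with `n_syn`, `n_nonsyn`, `n_nonsense` (summing to 9) and
#'   `p_syn = n_syn / (n_syn + n_nonsyn)`.
#' @export
codon_syn_profile <- function(codon) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  aa <- translate_codon(codon)
  if (is.na(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon has no synonymity profile: ", codon)
  n_syn <- 0L; n_nonsyn <- 0L; n_nonsense <- 0L
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  for (pos in 1:3) {
    for (b in setdiff(NUCS, chars[pos])) {
      mut <- chars; mut[pos] <- b
      aa2 <- translate_codon(paste(mut, collapse = ""))
      if (aa2 == "*") n_nonsense <- n_nonsense + 1L
      else if (aa2 == aa) n_syn <- n_syn + 1L
      else n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(n_syn = n_syn, n_nonsyn = n_nonsyn, n_nonsense = n_nonsense,
       p_syn = if (n_syn + n_nonsyn > 0) n_syn / (n_syn + n_nonsyn) else NA_real_)
}

## Codons of an allele by common (gapped) codon numbering. Codon q covers
## the three aligned columns starting at the column of the frame offset;
## codons containing gap columns or running past the sequence end are NA.
## IMGT-style alignments insert gaps in codon triplets, so shared numbering
## is preserved across alleles.
allele_codons <- function(allele) {
  chars <- strsplit(allele$sequence, "", fixed = TRUE)[[1]]
  g0 <- allele$map_u2g[allele$frame_offset + 1L]   # 0-based gapped column
  n_codons <- (length(chars) - g0) %/% 3L
  vapply(seq_len(n_codons) - 1L, function(q) {
    cols <- g0 + 3L * q + (1:3)
    cd <- chars[cols]
    if (any(cd == ".")) NA_character_ else paste(cd, collapse = "")
  }, character(1))
}

## Map an ungapped event position to its common codon index (0-based);
## NA if upstream of the reading frame.
codon_index_of <- function(allele, start) {
  g0 <- allele$map_u2g[allele$frame_offset + 1L]
  gcol <- allele$map_u2g[start + 1L]
  ifelse(gcol >= g0, (gcol - g0) %/% 3L, NA_integer_)
}

#' Expected synonymous proportion per codon position
#'
#' `E_q` is the usage-weighted mean of `p_syn` over the germline codons
#' observed at position `q` across alleles; weights renormalize over
#' alleles that have a (gap-free) codon at `q`.
#'
#' @param alleles named list of `germline_allele`, codon-aligned.
#' @param usage_weights optional named weights per allele (e.g. repertoire
#'   frequencies); default uniform. Normalised to sum to 1.
#' @return numeric vector of `E_q`, 0-based position `q` in element
#'   `q + 1`; `NA` where no allele has a codon.
#' @export
expected_syn_by_position <- function(alleles, usage_weights = NULL) {
  if (is.null(usage_weights)) {
    usage_weights <- structure(rep(1, length(alleles)), names = names(alleles))
  }
  usage_weights <- usage_weights[names(alleles)]
  usage_weights <- usage_weights / sum(usage_weights)
  codons <- lapply(alleles, allele_codons)
  n_pos <- max(vapply(codons, length, integer(1)))
  E <- rep(NA_real_, n_pos)
  for (q in seq_len(n_pos)) {
    w_tot <- 0; acc <- 0
    for (a in names(alleles)) {
      cd <- if (q <= length(codons[[a]])) codons[[a]][q] else NA_character_
      if (is.na(cd)) next
      prof <- tryCatch(codon_syn_profile(cd), error = function(e) {
        stop("stop codon in germline of ", a, " at codon position ", q - 1L)
      })
      if (is.na(prof$p_syn)) next  # all-nonsense codon (TGG-like with p defined; guard)
      acc <- acc + usage_weights[[a]] * prof$p_syn
      w_tot <- w_tot + usage_weights[[a]]
    }
    if (w_tot > 0) E[q] <- acc / w_tot
  }
  E
}

#' Build the per-position mutational resistance track
#'
#' Observed synonymous/total SNS counts per codon position (nonsense SNS
#' excluded from both, mirroring the expected-side computation), the score
#' `S_q = s_q / n_q - E_q`, and the tandem (k = 2) count per position,
#' attributed to the codon containing the event's 5' base.
#'
#' @param events events data.frame (k = 1 and k = 2 events used).
#' @param alleles named list of `germline_allele`.
#' @param usage_weights as in [expected_syn_by_position()].
#' @return data.frame with columns `position` (0-based codon index),
#'   `expected_syn`, `n_sns`, `n_syn`, `score`, `n_tdns`.
#' @export
build_resistance_track <- function(events, alleles, usage_weights = NULL) {
  E <- expected_syn_by_position(alleles, usage_weights)
  n_pos <- length(E)
  n_sns <- integer(n_pos); n_syn <- integer(n_pos); n_tdns <- integer(n_pos)
  for (aname in unique(events$allele)) {
    allele <- alleles[[aname]]
    if (is.null(allele)) stop("unknown allele in events: ", aname)
    ev <- events[events$allele == aname, , drop = FALSE]
    q <- codon_index_of(allele, ev$start)
    eff <- classify_effect(ev, allele)
    sns <- ev$k == 1L & !is.na(eff$effect) & eff$effect != "nonsense" &
      !is.na(q) & q < n_pos
    for (i in which(sns)) {
      n_sns[q[i] + 1L] <- n_sns[q[i] + 1L] + 1L
      if (eff$effect[i] == "synonymous") n_syn[q[i] + 1L] <- n_syn[q[i] + 1L] + 1L
    }
    tdns <- ev$k == 2L & !is.na(q) & q < n_pos
    for (i in which(tdns)) n_tdns[q[i] + 1L] <- n_tdns[q[i] + 1L] + 1L
  }
  score <- ifelse(n_sns > 0L, n_syn / n_sns - E, NA_real_)
  data.frame(position = seq_len(n_pos) - 1L, expected_syn = E,
             n_sns = n_sns, n_syn = n_syn, score = score, n_tdns = n_tdns)
}

#' Quasi-Poisson regression of tandem counts on resistance scores
#'
#' Log-link Poisson mean `mu_q = exp(a + b * S_q)` fitted by IRLS
#' ([stats::glm()] with the quasi-Poisson family); dispersion `phi` is the
#' Pearson chi-square over residual degrees of freedom, standard errors are
#' scaled by `sqrt(phi)`, and the slope p-value uses the t distribution
#' with `N - 2` df. Positions with undefined score are dropped.
#'
#' @param t non-negative integer counts per position.
#' @param S resistance scores per position (may contain `NA`).
#' @return object of class `quasipoisson_fit`: a list with `intercept`,
#'   `slope`, `se_intercept`, `se_slope`, `dispersion`, `p_value`,
#'   `converged`, `n`.
#' @export
quasipoisson_regression <- function(t, S) {
  stopifnot(length(t) == length(S))
  ok <- !is.na(S) & !is.na(t)
  t <- t[ok]; S <- S[ok]
  if (length(t) < 3L) stop("need at least 3 positions with defined scores")
  if (stats::var(S) == 0) stop("zero variance in scores")
  fit <- stats::glm(t ~ S, family = stats::quasipoisson(link = "log"),
                    control = list(epsilon = 1e-8, maxit = 100))
  sm <- summary(fit)
  structure(
    list(
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      se_intercept = sm$coefficients[1, 2], se_slope = sm$coefficients[2, 2],
      dispersion = sm$dispersion,
      p_value = sm$coefficients[2, 4],
      converged = fit$converged,
      n = length(t)
    ),
    class = "quasipoisson_fit"
  )
}

#' @export
print.quasipoisson_fit <- function(x, ...) {
  cat("<quasipoisson_fit> n =", x$n, "\n")
  cat(sprintf("  intercept %.4f (SE %.4f)\n", x$intercept, x$se_intercept))
  cat(sprintf("  slope     %.4f (SE %.4f), p = %.4g\n",
              x$slope, x$se_slope, x$p_value))
  cat(sprintf("  dispersion %.3f, converged: %s\n", x$dispersion, x$converged))
  invisible(x)
}
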