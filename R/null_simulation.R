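## Monte-Carlo null model for clustered substitutions.
##
## Observed runs of adjacent substitutions may be genuine single-event
## tandems or coincidental clusters of independently generated single
## nucleotide substitutions (SNS). The null model re-mutates each germline
## in silico: every sequence receives as many substitutions as it carries in
## vivo, placed independently at positions drawn from the observed
## per-position SNS frequency profile. Mutation clusters arising in these
## replicates are "false" tandems; their mean is subtracted from the
## observed run counts to estimate the true tandem incidence.

#' Build a per-position SNS profile for one allele
#'
#' The profile is driven by k = 1 events only: bases inside observed
#' clusters never contribute, keeping the null independent of the signal
#' being tested. Frequency `f(p)` is the SNS count at ungapped position `p`
#' divided by the number of records with a readable base there; `g(p, b)`
#' is the empirical distribution of target bases at `p` (undefined where
#' `f(p) = 0`).
#'
#' @param records data.frame of records carrying this allele.
#' @param allele `germline_allele`.
#' @param events events data.frame (any alleles; filtered internally).
#' @return object of class `position_profile`.
#' @export
build_position_profile <- function(records, allele, events) {
  records <- records[records$v_call == allele$name, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records for allele ", allele$name)
  L <- allele$length_ungapped
  gap_cols <- strsplit(allele$sequence, "", fixed = TRUE)[[1]] != "."
  coverage <- integer(L)
  for (s in records$sequence_alignment) {
    oc <- strsplit(toupper(s), "", fixed = TRUE)[[1]][gap_cols]
    coverage <- coverage + (oc %in% NUCS)
  }
  sns <- events[events$allele == allele$name & events$k == 1L &
                  events$sequence_id %in% records$sequence_id, , drop = FALSE]
  counts <- integer(L)
  target_counts <- matrix(0L, 4L, L, dimnames = list(NUCS, NULL))
  for (i in seq_len(nrow(sns))) {
    p <- sns$start[i] + 1L
    counts[p] <- counts[p] + 1L
    target_counts[sns$observed[i], p] <- target_counts[sns$observed[i], p] + 1L
  }
  f <- ifelse(coverage > 0L, counts / coverage, 0)
  structure(
    list(allele_name = allele$name, f = f, coverage = coverage,
         sns_counts = counts, target_counts = target_counts, length = L),
    class = "position_profile"
  )
}

#' Target-base distribution of a profile at one position
#'
#' @param profile a `position_profile`.
#' @param p 0-based ungapped position with at least one observed SNS.
#' @return named probability vector over the observed target bases.
#' @export
profile_target_distribution <- function(profile, p) {
  cnt <- profile$target_counts[, p + 1L]
  tot <- sum(cnt)
  if (tot == 0L) stop("no SNS observed at position ", p)
  cnt[cnt > 0] / tot
}

#' Simulate one null replicate (reference implementation)
#'
#' For each sequence load `m`, samples `m` distinct positions with
#' probability proportional to `f` (without replacement) and counts maximal
#' runs of adjacent positions. This pure-R path is the readable reference
#' for the compiled kernel used by [run_null_simulation()]; both draw from
#' the same sampling distribution. Uses R's RNG (`set.seed()` applies).
#'
#' @param profile a `position_profile`.
#' @param loads integer vector of per-sequence mutation counts; names, if
#'   present, are used in error messages.
#' @return named integer vector mapping run length `k` to cluster count.
#' @export
simulate_replicate <- function(profile, loads) {
  active <- which(profile$f > 0)
  w <- profile$f[active]
  if (length(active) == 0L) stop("profile has no positions with f > 0")
  too_big <- loads > length(active)
  if (any(too_big)) {
    who <- if (!is.null(names(loads))) names(loads)[too_big][1]
    else which(too_big)[1]
    stop("mutation load exceeds available positions for sequence ", who)
  }
  counts <- integer(0)
  for (m in loads) {
    if (m <= 0L) next
    pos <- sort(active[sample.int(length(active), m, prob = w)])
    runs <- rle(cumsum(c(1L, diff(pos) != 1L)))$lengths
    for (k in runs) {
      kk <- as.character(k)
      counts[kk] <- if (is.na(counts[kk])) 1L else counts[kk] + 1L
    }
  }
  counts[order(as.integer(names(counts)))]
}

#' Run the full Monte-Carlo null simulation
#'
#' Profiles are built per allele from SNS; only the `top_alleles` most
#' abundant alleles (by record count) are modelled, and results carry an
#' extrapolation factor (total events / modelled events) for whole-dataset
#' estimates. Each sequence's load is its called substituted-base count
#' (`sum(k)` over its events). Per run length the observed count, simulated
#' mean/sd over replicates, z-score and corrected count
#' (`observed - mean`) are reported. Deterministic given `seed`.
#'
#' @param records data.frame of records.
#' @param alleles named list of `germline_allele`.
#' @param events events data.frame for these records.
#' @param reps number of replicates (default 1000; the reference analysis
#'   scale is 100000).
#' @param seed integer master seed; replicate streams are derived by
#'   counter, independent of execution order.
#' @param top_alleles number of most abundant alleles modelled.
#' @param max_k run lengths `>= max_k` are pooled at `max_k`.
#' @return object of class `null_sim_result`.
#' @export
run_null_simulation <- function(records, alleles, events, reps = 1000L,
                                seed = 1L, top_alleles = 20L, max_k = 10L) {
  stopifnot(reps >= 1L, nrow(records) > 0L)
  usage <- sort(table(records$v_call), decreasing = TRUE)
  modelled <- names(usage)[seq_len(min(top_alleles, length(usage)))]
  mod_records <- records[records$v_call %in% modelled, , drop = FALSE]
  mod_events <- events[events$allele %in% modelled, , drop = FALSE]

  observed <- integer(max_k)
  kk <- pmin(mod_events$k, max_k)
  for (k in kk) observed[k] <- observed[k] + 1L

  total <- matrix(0L, reps, max_k)
  for (ai in seq_along(modelled)) {
    aname <- modelled[ai]
    allele <- alleles[[aname]]
    if (is.null(allele)) stop("unknown allele in v_call: ", aname)
    profile <- build_position_profile(mod_records, allele, mod_events)
    arec <- mod_records[mod_records$v_call == aname, , drop = FALSE]
    loads <- vapply(arec$sequence_id, function(id) {
      sum(mod_events$k[mod_events$sequence_id == id &
                         mod_events$allele == aname])
    }, numeric(1))
    active <- which(profile$f > 0)
    if (length(active) == 0L) next
    if (any(loads > length(active))) {
      stop("mutation load exceeds available positions for sequence ",
           names(loads)[loads > length(active)][1])
    }
    allele_seed <- (as.double(seed) * 1000003 + ai) %% 2147483647
    total <- total + cpp_simulate_runs(profile$f[active], active - 1L,
                                       as.integer(loads), as.integer(reps),
                                       as.integer(max_k), allele_seed)
  }
  mu <- colMeans(total)
  sdev <- apply(total, 2, stats::sd)      # NA when reps == 1
  undefined <- is.na(sdev) | sdev == 0
  z <- ifelse(!undefined, (observed - mu) / sdev, NA_real_)
  structure(
    list(
      replicates = as.integer(reps), seed = as.integer(seed),
      k = seq_len(max_k), observed = observed, sim_mean = mu, sim_sd = sdev,
      z = z, z_undefined = undefined, corrected = observed - mu,
      negative_corrected = (observed - mu) < 0 & observed > 0,
      per_replicate = total,
      modelled_alleles = modelled,
      extrapolation_factor = nrow(events) / max(nrow(mod_events), 1L)
    ),
    class = "null_sim_result"
  )
}

#' @export
print.null_sim_result <- function(x, ...) {
  cat("<null_sim_result>", x$replicates, "replicates, seed", x$seed, "\n")
  df <- data.frame(k = x$k, observed = x$observed,
                   sim_mean = round(x$sim_mean, 3),
                   sim_sd = round(x$sim_sd, 3), z = round(x$z, 2),
                   corrected = round(x$corrected, 3))
  print(df[df$observed > 0 | df$sim_mean > 0, ], row.names = FALSE)
  invisible(x)
}

#' Corrected incidence of tandem and longer substitutions
#'
#' Counting each expected false cluster of length `k` as `k` independent
#' SNS, the adjusted SNS count is `S' = O_1 + sum_{k>=2} k * mu_k`; the
#' corrected event count is `C_k = O_k - mu_k`; the incidence of length-k
#' events is `C_k / (S' + sum_{k>=2} C_k)`, and the cumulative tandem
#' incidence sums `C_k` over all `k >= 2`.
#'
#' @param result a `null_sim_result`.
#' @return list with `incidence` (named by k >= 2), `cumulative_tandem_incidence`,
#'   `adjusted_sns`, `corrected_counts`, `denominator` and
#'   `negative_flag` (any corrected count below zero).
#' @export
corrected_incidence <- function(result) {
  stopifnot(inherits(result, "null_sim_result"))
  ks <- result$k
  tandem <- ks >= 2L
  O1 <- result$observed[ks == 1L]
  adjusted_sns <- O1 + sum(ks[tandem] * result$sim_mean[tandem])
  Ck <- result$corrected[tandem]
  denom <- adjusted_sns + sum(Ck)
  if (denom <= 0) stop("corrected incidence undefined: denominator <= 0")
  incidence <- Ck / denom
  names(incidence) <- ks[tandem]
  list(
    incidence = incidence,
    cumulative_tandem_incidence = sum(Ck) / denom,
    adjusted_sns = adjusted_sns,
    corrected_counts = structure(Ck, names = ks[tandem]),
    denominator = denom,
    negative_flag = any(Ck < 0)
  )
}
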