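## End-to-end orchestration: select -> call -> simulate-null -> classify ->
## score -> report. All randomness flows from a single seed; per-stage
## record counts are logged via message().

#' Run the full tandem-substitution analysis
#'
#' Sequences are clonally collapsed and filtered by mutation load,
#' substitution events are called, observed run counts are corrected with
#' the Monte-Carlo null, k = 2 events are classified
#' (juxtalocation/inversion, codon slot, amino-acid effect, AID motifs,
#' germline context), dinucleotide and DBS-78 tables are built, and the
#' mutational resistance track with its quasi-Poisson fit is computed.
#'
#' @param records rearrangement records data.frame.
#' @param alleles named list of `germline_allele`.
#' @param reps null-simulation replicates.
#' @param seed integer master seed.
#' @param top_alleles alleles modelled in the null simulation.
#' @param scan_end optional scan bound (see [call_substitutions()]).
#' @param dbs_catalog optional DBS-78 signature vector/matrix (see
#'   [read_dbs_catalog()]); cosine similarities are reported per signature.
#' @param identity_threshold CDR3 identity for clonal collapse.
#' @param max_mutation_fraction mutation-load cutoff.
#' @param collapse,filter set `FALSE` to skip the respective stage.
#' @return list of class `tdns_report`.
#' @export
run_full_analysis <- function(records, alleles, reps = 1000L, seed = 1L,
                              top_alleles = 20L, scan_end = NULL,
                              dbs_catalog = NULL, identity_threshold = 0.95,
                              max_mutation_fraction = 0.05,
                              collapse = TRUE, filter = TRUE) {
  counts <- list(input = nrow(records))
  if (collapse) {
    records <- collapse_clones(records, identity_threshold)
    counts$after_collapse <- nrow(records)
    message("collapse: ", counts$input, " -> ", nrow(records), " records")
  }
  if (filter) {
    parts <- filter_by_mutation_load(records, alleles, max_mutation_fraction)
    records <- parts$kept
    counts$after_filter <- nrow(records)
    counts$excluded_unmutated <- nrow(parts$excluded_unmutated)
    counts$excluded_hypermutated <- nrow(parts$excluded_hypermutated)
    message("filter: kept ", nrow(records), " (unmutated ",
            counts$excluded_unmutated, ", hypermutated ",
            counts$excluded_hypermutated, ")")
  }
  if (nrow(records) == 0L) stop("stage 'selection': no records retained")

  events <- call_substitutions_all(records, alleles, scan_end = scan_end)
  counts$events <- nrow(events)
  message("call: ", nrow(events), " events from ", nrow(records), " records")

  run_lengths <- tabulate_run_lengths(events)
  ts_tv <- compute_ts_tv(events)

  nullsim <- run_null_simulation(records, alleles, events, reps = reps,
                                 seed = seed, top_alleles = top_alleles)
  incidence <- corrected_incidence(nullsim)

  tdns <- events[events$k == 2L, , drop = FALSE]
  expected <- expected_category_fractions()
  category_fractions <- NULL; category_tests <- NULL
  if (nrow(tdns) > 0L) {
    cls <- classify_tdns(tdns$germline, tdns$observed)
    pooled <- ifelse(cls %in% c("juxtalocation_5p", "juxtalocation_3p"),
                     "juxtalocation", cls)
    category_fractions <- as.list(table(factor(pooled, names(expected))) /
                                    length(pooled))
    category_tests <- lapply(names(expected), function(cat) {
      tst <- compare_fraction_to_expected(sum(pooled == cat), length(pooled),
                                          expected[[cat]])
      c(list(category = cat, expected = expected[[cat]]), tst)
    })
  }

  per_allele <- function(fn) {
    parts <- lapply(unique(events$allele), function(a) {
      ev <- events[events$allele == a, , drop = FALSE]
      fn(ev, alleles[[a]])
    })
    do.call(rbind, parts)
  }
  effects <- per_allele(classify_effect)
  # row order of `effects` matches the per-allele blocks below
  ev_ordered <- do.call(rbind, lapply(unique(events$allele), function(a)
    events[events$allele == a, , drop = FALSE]))
  tdns_mask <- ev_ordered$k == 2L & !is.na(effects$effect)
  effect_by_slot <- if (any(tdns_mask)) {
    as.data.frame(table(slot = effects$codon_slot[tdns_mask],
                        effect = effects$effect[tdns_mask]))
  } else NULL

  motif_summary <- NULL; containment_summary <- NULL
  if (nrow(tdns) > 0L) {
    motifs <- per_allele(function(ev, a)
      annotate_aid_motifs(ev[ev$k == 2L, , drop = FALSE], a))
    motif_summary <- as.list(colSums(motifs))
    containment <- unlist(lapply(unique(events$allele), function(a) {
      ev <- events[events$allele == a & events$k == 2L, , drop = FALSE]
      if (nrow(ev) == 0L) return(character(0))
      germline_context_containment(ev, alleles[[a]])
    }))
    containment_summary <- as.list(table(factor(containment,
      c("not_present", "pos_minus1", "pos_t2", "both"))))
  }

  usage <- table(records$v_call)
  usage_weights <- structure(as.numeric(usage), names = names(usage))
  track_alleles <- alleles[names(usage)]
  track <- build_resistance_track(events, track_alleles, usage_weights)
  fit <- tryCatch(quasipoisson_regression(track$n_tdns, track$score),
                  error = function(e) NULL)

  dinuc <- build_dinuc_table(tdns)
  dbs <- to_dbs78(dinuc)
  cosines <- NULL
  if (!is.null(dbs_catalog) && sum(dbs) > 0) {
    cat_mat <- if (is.matrix(dbs_catalog)) dbs_catalog
      else matrix(dbs_catalog, ncol = 1,
                  dimnames = list(names(dbs_catalog), "signature"))
    cosines <- lapply(seq_len(ncol(cat_mat)), function(j)
      cosine_similarity(unname(dbs[rownames(cat_mat)]), cat_mat[, j]))
    names(cosines) <- colnames(cat_mat)
  }

  structure(
    list(
      schema_version = "1.0",
      parameters = list(reps = reps, seed = seed, top_alleles = top_alleles,
                        identity_threshold = identity_threshold,
                        max_mutation_fraction = max_mutation_fraction,
                        scan_end = scan_end),
      stage_counts = counts,
      run_lengths = as.list(run_lengths),
      ts_tv = ts_tv,
      null_simulation = list(
        replicates = nullsim$replicates, seed = nullsim$seed, k = nullsim$k,
        observed = nullsim$observed, sim_mean = nullsim$sim_mean,
        sim_sd = nullsim$sim_sd, z = nullsim$z,
        corrected = nullsim$corrected,
        modelled_alleles = nullsim$modelled_alleles,
        extrapolation_factor = nullsim$extrapolation_factor
      ),
      corrected_incidence = incidence,
      tdns_category_fractions = category_fractions,
      tdns_category_tests = category_tests,
      expected_category_fractions = as.list(expected),
      effect_by_slot = effect_by_slot,
      motif_summary = motif_summary,
      containment_summary = containment_summary,
      dinuc_table = unclass(dinuc),
      dbs78 = as.list(dbs),
      dbs_cosines = cosines,
      resistance_track = track,
      quasipoisson_fit = if (!is.null(fit)) unclass(fit) else NULL
    ),
    class = "tdns_report"
  )
}

#' @export
print.tdns_report <- function(x, ...) {
  cat("<tdns_report> schema", x$schema_version, "\n")
  cat("  records:", x$stage_counts$input, "in")
  if (!is.null(x$stage_counts$after_filter)) {
    cat(" ->", x$stage_counts$after_filter, "analysed")
  }
  cat(";", x$stage_counts$events, "events\n")
  ci <- x$corrected_incidence
  cat(sprintf("  corrected cumulative tandem incidence: %.4f\n",
              ci$cumulative_tandem_incidence))
  if (!is.null(x$tdns_category_fractions)) {
    f <- x$tdns_category_fractions
    cat(sprintf("  TDNS categories: inversion %.3f, juxtalocation %.3f, other %.3f\n",
                f$inversion, f$juxtalocation, f$other))
  }
  if (!is.null(x$ts_tv$ratio)) {
    cat(sprintf("  Ts/Tv: %.3f (%s)\n", x$ts_tv$ratio, x$ts_tv$flag))
  }
  invisible(x)
}

#' Run the pipeline on a synthetic repertoire
#'
#' Generates a repertoire from `config` (including optional clonal
#' expansion) and runs [run_full_analysis()] on it.
#'
#' @param config a [synthetic_config()].
#' @param reps null-simulation replicates.
#' @param ... passed to [run_full_analysis()].
#' @return list with `report`, `simulation` (records/truth/alleles) and the
#'   analysed `records`.
#' @export
run_synthetic_analysis <- function(config, reps = 1000L, ...) {
  sim <- simulate_repertoire(config)
  records <- sim$records
  if (config$clonal_factor > 1L) {
    records <- expand_clones(records, config$clonal_factor,
                             seed = config$seed + 2L)
  }
  report <- run_full_analysis(records, sim$alleles, reps = reps,
                              seed = config$seed, ...)
  list(report = report, simulation = sim, records = records)
}
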