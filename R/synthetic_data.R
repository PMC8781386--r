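## Synthetic repertoire generator with known ground truth.
##
## Emulates the statistical structure of clonally collapsed V(D)J
## repertoires under somatic hypermutation: per-sequence mutation loads in
## the oligomutated (0-5%) range, independent SNS with AID hotspot bias, an
## injected true-tandem process with controllable rate theta and a
## juxtalocation-biased outcome model, and regeneration of sequences that
## acquire stop codons (emulating negative selection of nonsense BCR).
## No indels are simulated.

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

#' Generate toy germline V alleles
#'
#' Random in-frame stop-free sequences guaranteed to contain at least one
#' WRCY and one WA hotspot occurrence. Deterministic per seed.
#'
#' @param n number of alleles.
#' @param length nucleotide length, divisible by 3.
#' @param seed integer seed.
#' @param max_retries attempts to satisfy the hotspot constraint.
#' @return named list of `germline_allele` with toy region annotation.
#' @export
generate_toy_alleles <- function(n, length = 300L, seed = 1L,
                                 max_retries = 50L) {
  if (length %% 3L != 0L) stop("length must be divisible by 3")
  set.seed(seed)
  nc <- length %/% 3L
  brk <- function(x) as.integer(round(x * nc))
  regions <- list(FR1 = c(0L, brk(0.25)), CDR1 = c(brk(0.25), brk(0.33)),
                  FR2 = c(brk(0.33), brk(0.50)), CDR2 = c(brk(0.50), brk(0.58)),
                  FR3 = c(brk(0.58), nc))
  out <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      seq <- paste(sample(SENSE_CODONS, nc, replace = TRUE), collapse = "")
      subject <- Biostrings::DNAString(seq)
      has_wrcy <- length(Biostrings::matchPattern("WRCY", subject, fixed = FALSE)) > 0L
      has_wa <- length(Biostrings::matchPattern("WA", subject, fixed = FALSE)) > 0L
      if (has_wrcy && has_wa) { ok <- TRUE; break }
    }
    if (!ok) stop("could not generate allele with hotspot motifs after ",
                  max_retries, " attempts")
    name <- sprintf("TOYV%d-1*01", i)
    out[[name]] <- germline_allele(name, seq, frame_offset = 0L,
                                   regions = regions)
  }
  out
}

#' Configuration for the synthetic repertoire generator
#'
#' Defaults describe the emulated world: a 300-nt V region, per-sequence
#' loads of 1-12 mutation events (so total mutated bases stay in the 0-5%
#' range at small theta), a 3-fold hotspot weight inside WRCY/WA footprints
#' (either strand), transitions weighted 2:1 per alternative over
#' transversions (Ts/Tv near 1), and a juxtalocation-biased tandem outcome
#' model drawing the +/-1-shifted germline dinucleotide with probability
#' 0.8.
#'
#' @param n_sequences number of sequences.
#' @param theta fraction of mutation events that are single-event 2-nt
#'   tandems, in `[0, 1]`.
#' @param alleles optional named list of `germline_allele`; generated when
#'   `NULL`.
#' @param n_alleles,v_length toy allele generation parameters.
#' @param load_events integer support of the per-sequence event-count
#'   distribution (uniform).
#' @param hotspot_multiplier SNS/tandem weight multiplier for positions
#'   inside WRCY or WA occurrences (forward or reverse-complement).
#' @param tandem_model `"juxtalocation"` or `"uniform"` outcome model.
#' @param juxta_prob probability that a juxtalocation-model tandem draws a
#'   shifted germline dinucleotide (when a legal shift exists).
#' @param transition_weight relative weight of the transition target base.
#' @param clonal_factor expansion factor handed to [expand_clones()] by
#'   callers; 1 means no expansion.
#' @param max_retries regeneration bound for sequences acquiring stops.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sequences = 500L, theta = 0, alleles = NULL,
                             n_alleles = 5L, v_length = 300L,
                             load_events = 1:12, hotspot_multiplier = 3,
                             tandem_model = c("juxtalocation", "uniform"),
                             juxta_prob = 0.8, transition_weight = 2,
                             clonal_factor = 1L, max_retries = 50L,
                             seed = 42L) {
  stopifnot(theta >= 0, theta <= 1, all(load_events >= 1L),
            hotspot_multiplier > 0, clonal_factor >= 1L)
  structure(
    list(n_sequences = as.integer(n_sequences), theta = theta,
         alleles = alleles, n_alleles = as.integer(n_alleles),
         v_length = as.integer(v_length), load_events = as.integer(load_events),
         hotspot_multiplier = hotspot_multiplier,
         tandem_model = match.arg(tandem_model), juxta_prob = juxta_prob,
         transition_weight = transition_weight,
         clonal_factor = as.integer(clonal_factor),
         max_retries = as.integer(max_retries), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

## Position weights: hotspot_multiplier inside WRCY/WA footprints searched
## on both strands (as their coding-strand images RGYW/TW), 1 elsewhere.
hotspot_weights <- function(allele, multiplier) {
  subject <- Biostrings::DNAString(allele$ungapped)
  w <- rep(1, allele$length_ungapped)
  for (pat in c("WRCY", "RGYW", "WA", "TW")) {
    hits <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    for (j in seq_along(hits)) {
      w[Biostrings::start(hits)[j]:Biostrings::end(hits)[j]] <- multiplier
    }
  }
  w
}

#' Positions inside AID hotspot footprints
#' @param allele a `germline_allele`.
#' @return 0-based ungapped positions covered by a WRCY or WA occurrence on
#'   either strand.
#' @export
hotspot_positions <- function(allele) {
  which(hotspot_weights(allele, 2) > 1) - 1L
}

draw_sns_target <- function(germ, transition_weight) {
  alts <- setdiff(NUCS, germ)
  wts <- ifelse(alts == TRANSITIONS[germ], transition_weight, 1)
  sample(alts, 1L, prob = wts)
}

draw_tandem_outcome <- function(g, p, config) {
  X <- g[p + 1L]; Y <- g[p + 2L]
  uniform_draw <- function() {
    paste0(sample(setdiff(NUCS, X), 1L), sample(setdiff(NUCS, Y), 1L))
  }
  if (config$tandem_model == "uniform") return(uniform_draw())
  shifts <- character(0)
  if (p >= 1L && g[p] != X && X != Y) shifts <- c(shifts, paste0(g[p], X))
  if (p + 3L <= length(g) && Y != X && g[p + 3L] != Y) {
    shifts <- c(shifts, paste0(Y, g[p + 3L]))
  }
  if (length(shifts) > 0L && stats::runif(1) < config$juxta_prob) {
    sample(shifts, 1L)
  } else {
    uniform_draw()
  }
}

#' Simulate a repertoire with known ground truth
#'
#' Each sequence draws an allele and an event count; each event is, with
#' probability `theta`, a true tandem (adjacent pair, outcome per the
#' configured model), otherwise an SNS at a hotspot-weighted position.
#' Events never overlap (but may be adjacent, so coincidental clusters
#' arise naturally). Sequences whose mutated V region contains a stop codon
#' are regenerated up to `max_retries` times.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (AIRR-style data.frame), `truth`
#'   (ground-truth events with a `type` column: `"sns"` or `"tandem"`),
#'   `alleles` and `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  alleles <- config$alleles
  if (is.null(alleles)) {
    alleles <- generate_toy_alleles(config$n_alleles, config$v_length,
                                    seed = config$seed)
  }
  set.seed(config$seed + 1L)
  weights <- lapply(alleles, hotspot_weights,
                    multiplier = config$hotspot_multiplier)
  allele_names <- names(alleles)
  rec_rows <- vector("list", config$n_sequences)
  truth_rows <- vector("list", config$n_sequences)
  for (i in seq_len(config$n_sequences)) {
    aname <- sample(allele_names, 1L)
    allele <- alleles[[aname]]
    g <- strsplit(allele$ungapped, "", fixed = TRUE)[[1]]
    L <- allele$length_ungapped
    w <- weights[[aname]]
    n_events <- sample(config$load_events, 1L)
    done <- FALSE
    for (try in seq_len(config$max_retries)) {
      used <- logical(L)
      ev_start <- integer(n_events); ev_k <- integer(n_events)
      ev_obs <- character(n_events)
      obs <- g
      feasible <- TRUE
      for (j in seq_len(n_events)) {
        is_tandem <- stats::runif(1) < config$theta
        if (is_tandem) {
          cand <- which(!used[-L] & !used[-1L])   # 1-based start of free pair
          if (length(cand) == 0L) { feasible <- FALSE; break }
          p1 <- if (length(cand) == 1L) cand else
            sample(cand, 1L, prob = w[cand])
          out2 <- draw_tandem_outcome(g, p1 - 1L, config)
          obs[p1] <- substr(out2, 1, 1); obs[p1 + 1L] <- substr(out2, 2, 2)
          used[p1] <- TRUE; used[p1 + 1L] <- TRUE
          ev_start[j] <- p1 - 1L; ev_k[j] <- 2L; ev_obs[j] <- out2
        } else {
          cand <- which(!used)
          if (length(cand) == 0L) { feasible <- FALSE; break }
          p1 <- if (length(cand) == 1L) cand else
            sample(cand, 1L, prob = w[cand])
          obs[p1] <- draw_sns_target(g[p1], config$transition_weight)
          used[p1] <- TRUE
          ev_start[j] <- p1 - 1L; ev_k[j] <- 1L; ev_obs[j] <- obs[p1]
        }
      }
      if (!feasible) {
        stop("load of ", n_events, " events exceeds available positions for ",
             "sequence ", i)
      }
      aa <- Biostrings::GENETIC_CODE[
        substring(paste(obs, collapse = ""),
                  seq(allele$frame_offset + 1L, L - 2L, by = 3L),
                  seq(allele$frame_offset + 3L, L, by = 3L))]
      if (!any(aa == "*", na.rm = TRUE)) { done <- TRUE; break }
    }
    if (!done) {
      stop("could not place ", n_events, " events without a stop codon for ",
           "sequence ", i, " (", config$max_retries, " retries)")
    }
    sid <- sprintf("SYN%05d", i)
    rec_rows[[i]] <- data.frame(
      sequence_id = sid, v_call = aname, d_call = "TOYD1-1*01",
      j_call = "TOYJ1-1*01",
      sequence_alignment = paste(obs, collapse = ""),
      germline_alignment = allele$sequence,
      cdr3 = paste(sample(NUCS, 3L * sample(5:20, 1L), replace = TRUE),
                   collapse = ""),
      isotype = sample(c("IGHM", "IGHG"), 1L),
      mutation_count = sum(ev_k),
      stringsAsFactors = FALSE
    )
    ord <- order(ev_start)
    truth_rows[[i]] <- data.frame(
      sequence_id = sid, v_call = aname, start = ev_start[ord], k = ev_k[ord],
      germline = vapply(ord, function(j)
        paste(g[(ev_start[j] + 1L):(ev_start[j] + ev_k[j])], collapse = ""),
        character(1)),
      observed = ev_obs[ord],
      type = ifelse(ev_k[ord] == 2L, "tandem", "sns"),
      stringsAsFactors = FALSE
    )
  }
  list(records = do.call(rbind, rec_rows), truth = do.call(rbind, truth_rows),
       alleles = alleles, config = config)
}

#' Add clonal duplicates to a repertoire
#'
#' Each record is represented 1 to `factor` times; duplicates receive 1-3
#' extra SNS at previously unmutated positions (so the original is always
#' the least mutated member) and keep their CDR3, exercising
#' [collapse_clones()] as an inverse.
#'
#' @param records records data.frame.
#' @param factor maximum copies per record (`1` = identity).
#' @param seed integer seed.
#' @return records with appended duplicates.
#' @export
expand_clones <- function(records, factor = 1L, seed = 1L) {
  stopifnot(factor >= 1L)
  if (factor == 1L) return(records)
  set.seed(seed)
  dups <- list()
  for (i in seq_len(nrow(records))) {
    n_copies <- sample(seq_len(factor), 1L)
    if (n_copies == 1L) next
    gl <- strsplit(toupper(records$germline_alignment[i]), "", fixed = TRUE)[[1]]
    for (cp in seq_len(n_copies - 1L)) {
      oc <- strsplit(toupper(records$sequence_alignment[i]), "", fixed = TRUE)[[1]]
      free <- which(gl %in% NUCS & oc == gl)
      n_extra <- min(sample(1:3, 1L), length(free))
      pos <- if (length(free) == 1L) free else sample(free, n_extra)
      for (p in pos) oc[p] <- sample(setdiff(NUCS, gl[p]), 1L)
      row <- records[i, , drop = FALSE]
      row$sequence_id <- paste0(row$sequence_id, "_d", cp)
      row$sequence_alignment <- paste(oc, collapse = "")
      row$mutation_count <- row$mutation_count + n_extra
      dups[[length(dups) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(list(records), dups, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
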