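# Fixture: an allele plus records whose SNS sit at chosen 0-based positions
# with chosen target bases; one list entry per record.
profile_fixture <- function(mutations_per_record, len = 30L) {
  germ <- strrep("ATGGCA", len / 6L)   # stop-free filler, position 5 is 'A'
  allele <- germline_allele("V1*01", germ)
  g <- strsplit(germ, "", fixed = TRUE)[[1]]
  recs <- lapply(seq_along(mutations_per_record), function(i) {
    o <- g
    muts <- mutations_per_record[[i]]
    if (length(muts) > 0) o[as.integer(names(muts)) + 1L] <- unname(muts)
    data.frame(sequence_id = sprintf("r%02d", i), v_call = "V1*01",
               d_call = "D", j_call = "J",
               sequence_alignment = paste(o, collapse = ""),
               germline_alignment = germ, cdr3 = "AAATTT", isotype = "IGHM",
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  records$mutation_count <- count_mutations(records$sequence_alignment,
                                            records$germline_alignment)
  list(allele = allele, records = records,
       events = call_substitutions_all(records, list("V1*01" = allele)))
}

test_that("position profile counts SNS frequency and target distribution", {
  # position 5 mutated A->G in 2 of 10 records
  muts <- c(rep(list(c("5" = "G")), 2), rep(list(c()), 8))
  fx <- profile_fixture(muts)
  prof <- build_position_profile(fx$records, fx$allele, fx$events)
  expect_equal(prof$f[6], 0.2)
  expect_equal(sum(prof$f[-6]), 0)
  expect_equal(profile_target_distribution(prof, 5L), c(G = 1))

  # two target bases with counts 3 and 1 -> g = (0.75, 0.25)
  muts2 <- c(rep(list(c("5" = "G")), 3), list(c("5" = "C")),
             rep(list(c()), 6))
  fx2 <- profile_fixture(muts2)
  prof2 <- build_position_profile(fx2$records, fx2$allele, fx2$events)
  expect_equal(profile_target_distribution(prof2, 5L), c(C = 0.25, G = 0.75))

  # no SNS anywhere -> all f = 0; no records -> error
  fx3 <- profile_fixture(rep(list(c()), 4))
  prof3 <- build_position_profile(fx3$records, fx3$allele, fx3$events)
  expect_true(all(prof3$f == 0))
  other <- germline_allele("V9*01", "ATGGCAATG")
  expect_error(build_position_profile(fx3$records, other, fx3$events),
               "V9\\*01")
})

test_that("profile excludes bases inside observed clusters", {
  # one record with a k = 2 run at 9-10 and an SNS at 5
  muts <- list(c("5" = "G", "9" = "A", "10" = "G"), c())
  fx <- profile_fixture(muts)
  prof <- build_position_profile(fx$records, fx$allele, fx$events)
  expect_equal(prof$f[6], 0.5)
  expect_equal(prof$f[10], 0)   # tandem bases carry no SNS weight
  expect_equal(prof$f[11], 0)
})

test_that("simulate_replicate honours loads and adjacency", {
  muts <- c(rep(list(c("5" = "G")), 2), rep(list(c("20" = "T")), 2))
  fx <- profile_fixture(muts)
  prof <- build_position_profile(fx$records, fx$allele, fx$events)

  set.seed(1)
  counts <- simulate_replicate(prof, rep(1L, 50))
  expect_identical(counts, c("1" = 50L))  # single mutations cannot cluster

  # conservation: total simulated bases equal total load
  set.seed(2)
  counts2 <- simulate_replicate(prof, c(2L, 2L, 1L))
  expect_equal(sum(as.integer(names(counts2)) * counts2), 5L)

  # load exceeding the active positions errors naming the sequence
  expect_error(simulate_replicate(prof, c(a = 1L, bad = 5L)), "bad")
})

test_that("two adjacent active positions with m = 2 always form a tandem", {
  muts <- c(rep(list(c("10" = "G")), 2), rep(list(c("11" = "T")), 2))
  fx <- profile_fixture(muts)
  prof <- build_position_profile(fx$records, fx$allele, fx$events)
  set.seed(3)
  counts <- simulate_replicate(prof, rep(2L, 25))
  expect_identical(counts, c("2" = 25L))
})

test_that("three equal positions with m = 2 give false-tandem probability 2/3", {
  # enumeration oracle: of the 3 equiprobable pairs {10,11},{11,12},{10,12},
  # two are adjacent -> P(one k=2 cluster) = 2/3
  muts <- c(list(c("10" = "G")), list(c("11" = "T")), list(c("12" = "G")))
  fx <- profile_fixture(muts)
  prof <- build_position_profile(fx$records, fx$allele, fx$events)
  reps <- 3000L
  set.seed(4)
  tandems <- vapply(seq_len(reps), function(i) {
    cnt <- simulate_replicate(prof, 2L)
    sum(cnt[names(cnt) == "2"])
  }, numeric(1))
  p_hat <- mean(tandems)
  se <- sqrt((2 / 3) * (1 / 3) / reps)
  expect_lt(abs(p_hat - 2 / 3), 3 * se)

  # the compiled kernel draws from the same distribution
  mat <- tandemshm:::cpp_simulate_runs(prof$f[11:13], 10:12, 2L,
                                       reps, 5L, 99)
  p_cpp <- mean(mat[, 2])
  expect_lt(abs(p_cpp - 2 / 3), 3 * se)
  # and is deterministic per seed
  mat2 <- tandemshm:::cpp_simulate_runs(prof$f[11:13], 10:12, 2L,
                                        reps, 5L, 99)
  expect_identical(mat, mat2)
})

test_that("run_null_simulation is deterministic and flags undefined z", {
  sim <- simulate_repertoire(synthetic_config(n_sequences = 40, theta = 0.05,
                                              seed = 21))
  ev <- call_substitutions_all(sim$records, sim$alleles)
  r1 <- run_null_simulation(sim$records, sim$alleles, ev, reps = 50, seed = 5)
  r2 <- run_null_simulation(sim$records, sim$alleles, ev, reps = 50, seed = 5)
  expect_identical(r1, r2)
  r3 <- run_null_simulation(sim$records, sim$alleles, ev, reps = 50, seed = 6)
  expect_false(identical(r1$per_replicate, r3$per_replicate))

  # R = 1: mean equals the single replicate, z undefined
  r4 <- run_null_simulation(sim$records, sim$alleles, ev, reps = 1, seed = 7)
  expect_true(all(r4$z_undefined))
  expect_equal(unname(r4$sim_mean), as.numeric(r4$per_replicate[1, ]))

  # per-sequence loads are matched exactly in every replicate
  expect_true(all(rowSums(r1$per_replicate %*% diag(r1$k)) == sum(ev$k)))
})

test_that("top-allele restriction and extrapolation factor", {
  sim <- simulate_repertoire(synthetic_config(n_sequences = 60, theta = 0,
                                              seed = 31, n_alleles = 4))
  ev <- call_substitutions_all(sim$records, sim$alleles)
  r <- run_null_simulation(sim$records, sim$alleles, ev, reps = 20, seed = 1,
                           top_alleles = 2L)
  expect_length(r$modelled_alleles, 2L)
  n_mod <- sum(ev$allele %in% r$modelled_alleles)
  expect_equal(r$extrapolation_factor, nrow(ev) / n_mod)
  expect_gte(r$extrapolation_factor, 1)
})

fake_result <- function(observed, sim_mean) {
  structure(list(replicates = 1000L, seed = 1L, k = seq_along(observed),
                 observed = observed, sim_mean = sim_mean,
                 sim_sd = rep(1, length(observed)),
                 z = observed - sim_mean, z_undefined = FALSE,
                 corrected = observed - sim_mean),
            class = "null_sim_result")
}

test_that("corrected incidence arithmetic matches the stated formula", {
  # no false tandems: plain 5 / 100
  r1 <- fake_result(c(95, 5), c(0, 0))
  ci1 <- corrected_incidence(r1)
  expect_equal(unname(ci1$incidence["2"]), 0.05)
  expect_equal(ci1$cumulative_tandem_incidence, 0.05)

  # full correction: all observed tandems explained by chance
  r2 <- fake_result(c(90, 10), c(0, 10))
  ci2 <- corrected_incidence(r2)
  expect_equal(unname(ci2$incidence["2"]), 0)
  expect_equal(ci2$adjusted_sns, 110)

  # false tandems re-counted as multiple SNS each
  r3 <- fake_result(c(0, 2), c(0, 1))
  ci3 <- corrected_incidence(r3)
  expect_equal(ci3$adjusted_sns, 2)
  expect_equal(unname(ci3$corrected_counts["2"]), 1)
  expect_equal(unname(ci3$incidence["2"]), 1 / 3)

  # negative corrected counts are flagged, not clipped
  r4 <- fake_result(c(50, 1), c(0, 3))
  ci4 <- corrected_incidence(r4)
  expect_true(ci4$negative_flag)
  expect_equal(unname(ci4$corrected_counts["2"]), -2)
})
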