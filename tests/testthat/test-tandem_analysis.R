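test_that("tandem classification matches the paper's examples and contracts", {
  expect_identical(classify_tdns("AG", "GA"), "inversion")
  expect_identical(classify_tdns("AG", "CA"), "juxtalocation_5p")
  expect_identical(classify_tdns("AG", "GC"), "juxtalocation_3p")
  expect_identical(classify_tdns("AC", "GT"), "other")
  expect_error(classify_tdns("AGT", "GAC"), "k = 2")
  expect_error(classify_tdns("AG", "AC"), "substituted")
})

test_that("brute-force enumeration gives 12/48/48 over heterodimer pairs", {
  nucs <- c("A", "C", "G", "T")
  cls <- character(0)
  n_homo <- 0L
  for (X in nucs) for (Y in nucs) {
    for (Xp in setdiff(nucs, X)) for (Yp in setdiff(nucs, Y)) {
      got <- classify_tdns(paste0(X, Y), paste0(Xp, Yp))
      if (X == Y) {
        expect_identical(got, "other")  # homodimers can only be 'other'
        n_homo <- n_homo + 1L
      } else {
        cls <- c(cls, got)
      }
    }
  }
  expect_identical(n_homo, 36L)            # 4 homodimer refs x 9 outcomes
  expect_length(cls, 108L)
  counts <- table(cls)
  expect_identical(as.integer(counts[["inversion"]]), 12L)
  expect_identical(as.integer(counts[["juxtalocation_5p"]] +
                                counts[["juxtalocation_3p"]]), 48L)
  expect_identical(as.integer(counts[["other"]]), 48L)

  expected <- expected_category_fractions()
  expect_equal(sum(expected), 1)
  expect_equal(unname(expected["inversion"]), 1 / 9)
  expect_equal(unname(expected["juxtalocation"]), 4 / 9)
  expect_equal(unname(expected["other"]), 4 / 9)
})

test_that("proportion test behaves at its anchors", {
  t0 <- compare_fraction_to_expected(100, 900, 1 / 9)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  t1 <- compare_fraction_to_expected(900, 900, 1 / 9)
  expect_lt(t1$p_value, 1e-6)
  expect_error(compare_fraction_to_expected(1, 0, 0.5), "total")
  expect_error(compare_fraction_to_expected(1, 10, 1), "expected_fraction")
})

test_that("codon slot assignment follows the reading frame", {
  allele <- germline_allele("X", "ATGGGAACC")
  expect_identical(assign_codon_slot(c(0L, 1L, 2L, 3L), allele),
                   c(1L, 2L, 3L, 1L))
  shifted <- germline_allele("Y", "ATGGGAACC", frame_offset = 1L)
  expect_identical(assign_codon_slot(1L, shifted), 1L)
  expect_error(assign_codon_slot(0L, shifted), "upstream")
})

test_that("effect calls match hand-worked codon cases", {
  # k = 1 control: CTG -> CTA, both leucine
  a <- germline_allele("X", "CTGGGA")
  eff <- classify_effect(make_events(2L, 1L, "G", "A"), a)
  expect_identical(eff$effect, "synonymous")
  expect_identical(eff$codon_slot, 3L)

  # slot-2 tandem turning TGG into TAA is nonsense
  a2 <- germline_allele("X", "TGGGCA")
  eff2 <- classify_effect(make_events(1L, 2L, "GG", "AA"), a2)
  expect_identical(eff2$codon_slot, 2L)
  expect_identical(eff2$effect, "nonsense")

  # slot-3 tandem CTG|GGA -> CTA|AGA: Leu silent + Gly->Arg replacement
  a3 <- germline_allele("X", "CTGGGA")
  eff3 <- classify_effect(make_events(2L, 2L, "GG", "AA"), a3)
  expect_identical(eff3$codon_slot, 3L)
  expect_identical(eff3$effect, "nonsynonymous")

  # slot-3 with both codons silent: CTG|AGA -> CTA|CGA (Leu, Arg->Arg)
  a4 <- germline_allele("X", "CTGAGA")
  eff4 <- classify_effect(make_events(2L, 2L, "GA", "AC"), a4)
  expect_identical(eff4$effect, "double_synonymous")

  # slot-3 with both amino acids changed: ATG|GGA -> ATA|CGA (Met->Ile, Gly->Arg)
  a5 <- germline_allele("X", "ATGGGA")
  eff5 <- classify_effect(make_events(2L, 2L, "GG", "AC"), a5)
  expect_identical(eff5$effect, "double_replacement")

  # incomplete trailing codon is skipped with a reason
  a6 <- germline_allele("X", "CTGGG")
  eff6 <- classify_effect(make_events(2L, 2L, "GG", "AA"), a6)
  expect_true(is.na(eff6$effect))
  expect_identical(eff6$skip_reason, "incomplete_codon")
})

test_that("k = 1 effects agree with the brute-force translator over all sense codons", {
  nucs <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (codon in codons) {
    chars <- strsplit(codon, "", fixed = TRUE)[[1]]
    allele <- germline_allele("X", paste0(codon, "GGA"))
    for (pos in 1:3) {
      for (b in setdiff(nucs, chars[pos])) {
        got <- classify_effect(make_events(pos - 1L, 1L, chars[pos], b),
                               allele)$effect
        expect_identical(got, oracle_sub_effect(codon, pos, b),
                         info = paste(codon, pos, b))
      }
    }
  }
})

test_that("germline context containment matches direct string comparison", {
  # T[CT]C: both the -1 and +1 windows read "TC"
  a <- germline_allele("X", "TCTC")
  expect_identical(
    germline_context_containment(make_events(1L, 2L, "CT", "TC"), a), "both")
  # A[AG]T: neither window matches "GA"
  a2 <- germline_allele("X", "AAGT")
  expect_identical(
    germline_context_containment(make_events(1L, 2L, "AG", "GA"), a2),
    "not_present")
  # event at the sequence start: -1 window can never match
  a3 <- germline_allele("X", "AGAGT")
  expect_identical(
    germline_context_containment(make_events(0L, 2L, "AG", "CT"), a3),
    "not_present")
  a4 <- germline_allele("X", "ACGTA")
  expect_identical(
    germline_context_containment(make_events(0L, 2L, "AC", "CG"), a4),
    "pos_t2")  # +1 window (positions 1, 2) reads "CG" = observed
})

test_that("AID motif annotation anchors on the hotspot base", {
  # "TACTG": WRCY occurrence TACT with its C at position 2 = event 5' base
  a <- germline_allele("X", "TACTG")
  fl <- annotate_aid_motifs(make_events(2L, 2L, "CT", "TC"), a)
  expect_true(fl$WRCY_5p_fwd)
  expect_false(fl$WRCY_3p_fwd)

  # "GTAAC": WA with A at position 2 = the SNS position
  a2 <- germline_allele("X", "GTAAC")
  fl2 <- annotate_aid_motifs(make_events(2L, 1L, "A", "G"), a2)
  expect_true(fl2$WA_5p_fwd)
  expect_true(fl2$WA_3p_fwd)  # k = 1: both ends are the same base

  # reverse-complement image: RGYW has its hotspot G at offset 1
  # "AGTA" matches RGYW (R=A, G, Y=T, W=A), hotspot at position 1
  a3 <- germline_allele("X", "CAGTA")
  fl3 <- annotate_aid_motifs(make_events(2L, 1L, "G", "A"), a3)
  expect_true(fl3$WRCY_5p_rc)

  # no IUPAC occurrence in range -> all flags false
  a4 <- germline_allele("X", "GGGGGG")
  fl4 <- annotate_aid_motifs(make_events(2L, 2L, "GG", "AA"), a4)
  expect_false(any(unlist(fl4)))
})

test_that("dinucleotide table construction and contracts", {
  tab <- build_dinuc_table(make_events(0L, 2L, "AG", "GA"))
  expect_equal(tab["AG", "GA"], 1)
  expect_equal(sum(tab, na.rm = TRUE), 1)
  tab2 <- build_dinuc_table(make_events(c(0L, 5L), c(2L, 2L),
                                        c("AG", "AG"), c("GA", "GA")))
  expect_equal(tab2["AG", "GA"], 2)
  expect_error(build_dinuc_table(make_events(0L, 1L, "A", "G")), "k = 2")
  empty <- build_dinuc_table(make_events(integer(0), integer(0),
                                         character(0), character(0)))
  expect_equal(sum(empty, na.rm = TRUE), 0)
})

test_that("DBS-78 collapse conserves mass and is reverse-complement invariant", {
  expect_length(dbs78_classes(), 78L)
  # worked examples
  ev <- make_events(c(0L, 3L), c(2L, 2L), c("GA", "AC"), c("TT", "GT"))
  cat78 <- to_dbs78(build_dinuc_table(ev))
  expect_equal(unname(cat78["TC>AA"]), 1)  # GA>TT maps via reverse complement
  expect_equal(unname(cat78["AC>GT"]), 1)  # AC is canonical, kept as-is
  expect_equal(sum(cat78), 2)

  # conservation and rc-invariance on random tables
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (seed in 1:5) {
    ev <- random_dinuc_events(40, seed)
    tab <- build_dinuc_table(ev)
    cat1 <- to_dbs78(tab)
    expect_equal(sum(cat1), 40)
    ev_rc <- ev
    ev_rc$germline <- vapply(ev$germline, rc, character(1), USE.NAMES = FALSE)
    ev_rc$observed <- vapply(ev$observed, rc, character(1), USE.NAMES = FALSE)
    cat2 <- to_dbs78(build_dinuc_table(ev_rc))
    expect_equal(cat1, cat2)
  }
})

test_that("cosine similarity has its closed-form anchors", {
  a <- c(1, 1, rep(0, 76)); b <- c(1, 0, rep(0, 76))
  expect_equal(cosine_similarity(a, a), 1.0)
  expect_equal(cosine_similarity(a, b), 1 / sqrt(2))
  expect_equal(cosine_similarity(b, c(0, 1, rep(0, 76))), 0)
  expect_error(cosine_similarity(a, rep(0, 78)), "zero")
  # symmetry and scale invariance
  set.seed(5)
  x <- runif(78); y <- runif(78)
  expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
  expect_equal(cosine_similarity(x, y), cosine_similarity(3.7 * x, y))
})
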