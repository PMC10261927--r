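test_that("composition percentages use the miRNA-mapped denominator", {
  ref <- toy_ref()
  prof <- profile_from_counts(c("TGAGG", "TGCGG", "TGAGGT", "CCCCCCCC"),
                              c(75, 10, 15, 50), ref)
  comp <- composition_table(list(prof))
  per <- comp$per_sample
  expect_equal(per[["canonical"]], 75)
  expect_equal(per[["NucVar"]], 10)
  expect_equal(per[["NTA-U"]], 15)
  # unassigned reads are excluded from the denominator entirely
  expect_equal(sum(per[, setdiff(ISOMIR_CLASSES, "unassigned")]), 100)
})

test_that("identical samples give sd 0; empty samples are excluded", {
  ref <- toy_ref()
  p1 <- profile_from_counts(c("TGAGG", "TGAGGT"), c(8, 2), ref, "s1")
  p2 <- profile_from_counts(c("TGAGG", "TGAGGT"), c(8, 2), ref, "s2")
  comp <- composition_table(list(p1, p2), groups = c("g", "g"))
  expect_true(all(comp$group_summary$sd_pct == 0))
  expect_equal(comp$group_summary$mean_pct[
    comp$group_summary$klass == "canonical"], 80)

  p3 <- profile_from_counts("CCCCCCCC", 5, ref, "s3")
  expect_warning(comp2 <- composition_table(list(p1, p3)), "zero")
  expect_equal(nrow(comp2$per_sample), 1L)
})

test_that("class percentages always sum to 100 over mapped classes", {
  cfg <- sim_config(n_mirnas = 6, depth = 2000, seed = 21)
  ref <- generate_reference(cfg)
  sim <- simulate_sample(ref, cfg, "cells")
  prof <- classify_sample(sim$truth$insert, ref)
  comp <- composition_table(list(prof))
  expect_equal(sum(comp$per_sample[, setdiff(ISOMIR_CLASSES, "unassigned")]),
               100, tolerance = 1e-9)
})

test_that("the NucVar spectrum reports reference>read substitution classes", {
  ref <- toy_ref()
  # TGAGG with internal A->C at position 3 plus 99 canonical reads
  prof <- profile_from_counts(c("TGCGG", "TGAGG"), c(1, 99), ref)
  spec <- nucvar_spectrum(prof)
  expect_equal(unname(spec["A>C"]), 1)
  expect_equal(sum(spec), 1)

  prof0 <- profile_from_counts("TGAGG", 10, ref)
  expect_true(all(nucvar_spectrum(prof0) == 0))
})

test_that("a simulated editing-like spectrum recovers the T>C and A>G ranks", {
  cfg <- sim_config(n_mirnas = 10, depth = 3e4, seed = 31,
                    class_probs = c(canonical = 0.7, NucVar = 0.3))
  ref <- generate_reference(cfg)
  sim <- simulate_sample(ref, cfg, "cells")
  prof <- classify_sample(sim$truth$insert, ref)
  spec <- nucvar_spectrum(prof)
  expect_equal(names(which.max(spec)), "T>C")
  expect_true(spec["A>G"] > max(spec[setdiff(names(spec), c("T>C", "A>G"))]))
})

test_that("uridylation percentages are per-miRNA read fractions", {
  ref <- toy_ref()
  prof <- profile_from_counts(c("TGAGG", "TGAGGT"), c(32, 8), ref)
  ut <- uridylation_table(prof)
  expect_equal(ut$pct_NTA_U, 20)
  expect_equal(ut$total_count, 40)
  expect_false(ut$low_coverage)

  # min_reads flags, zero-read miRNAs are simply absent
  prof2 <- profile_from_counts("TGAGG", 3, ref)
  ut2 <- uridylation_table(prof2, min_reads = 10)
  expect_true(ut2$low_coverage)
  expect_equal(nrow(ut2), 1L)
})

test_that("per-miRNA tail probabilities are recovered within binomial error", {
  cfg <- sim_config(n_mirnas = 4, depth = 4000, seed = 41,
                    abundance_sdlog = 0, arm_u_multiplier = 1,
                    class_probs = c(canonical = 0.8, "NTA-U" = 0.2))
  ref <- generate_reference(cfg)
  sim <- simulate_sample(ref, cfg, "cells")
  prof <- classify_sample(sim$truth$insert, ref)
  ut <- uridylation_table(prof)
  # ~1000 reads per miRNA; 3 binomial sd of p=.2 is ~3.8 points
  expect_true(all(abs(ut$pct_NTA_U - 20) < 3 * 100 * sqrt(0.2 * 0.8 / 800)))
})

test_that("arm uridylation contrasts 3p against 5p arms", {
  cfg <- sim_config(n_mirnas = 8, depth = 2e4, seed = 51,
                    abundance_sdlog = 0, arm_u_multiplier = 10,
                    class_probs = c(canonical = 0.85, "NTA-U" = 0.11,
                                    lv3pT = 0.04))
  ref <- generate_reference(cfg)
  sim <- simulate_sample(ref, cfg, "cells")
  prof <- classify_sample(sim$truth$insert, ref)
  arm <- arm_uridylation(list(prof), ref)
  p3 <- arm$mean_pct_NTA_U[arm$arm == "3p"]
  p5 <- arm$mean_pct_NTA_U[arm$arm == "5p"]
  expect_true(p3 / p5 > 4)   # configured 10x enrichment, sampling error aside
  expect_true(p3 / p5 < 25)
})

test_that("arm uridylation handles one-sided and symmetric cases", {
  cfg <- sim_config(n_mirnas = 4, seed = 61)
  ref <- generate_reference(cfg)
  e5 <- ref$entries$mirna_id[ref$entries$arm == "5p"][1]
  e3 <- ref$entries$mirna_id[ref$entries$arm == "3p"][1]
  m5 <- ref$entries$mature_seq[ref$entries$mirna_id == e5]
  m3 <- ref$entries$mature_seq[ref$entries$mirna_id == e3]
  # NTA-U only on the 3p arm
  prof <- profile_from_counts(c(m5, m3, paste0(m3, "T")), c(10, 8, 2), ref)
  arm <- arm_uridylation(list(prof), ref)
  expect_equal(arm$mean_pct_NTA_U[arm$arm == "5p"], 0)
  expect_equal(arm$mean_pct_NTA_U[arm$arm == "3p"], 20)
  # equal uridylation on both arms gives equal percentages
  prof2 <- profile_from_counts(c(m5, paste0(m5, "T"), m3, paste0(m3, "T")),
                               c(9, 1, 9, 1), ref)
  arm2 <- arm_uridylation(list(prof2), ref)
  expect_equal(arm2$mean_pct_NTA_U[arm2$arm == "5p"],
               arm2$mean_pct_NTA_U[arm2$arm == "3p"])
})

test_that("group comparison runs Welch tests with BH correction", {
  a <- data.frame(x = c(10, 12, 11), y = c(5, 5, 5))
  b <- data.frame(x = c(2, 3, 2), y = c(5, 5, 5))
  res <- compare_group_fractions(a, b)
  expect_true(res$p[res$klass == "x"] < 0.01)
  expect_true(res$significant[res$klass == "x"])
  expect_equal(res$t[res$klass == "y"], 0)
  expect_equal(res$p[res$klass == "y"], 1)
  expect_false(res$significant[res$klass == "y"])
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(compare_group_fractions(a[1, , drop = FALSE], b), "fewer than 2")
})

test_that("the coefficient of variation matches hand arithmetic and scales", {
  expect_equal(cov_equality(c(5, 5, 5)), 0)
  expect_equal(cov_equality(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  x <- c(3, 9, 1, 14, 6)
  expect_equal(cov_equality(x), cov_equality(1000 * x))
  expect_error(cov_equality(c(0, 0)), "positive")
  expect_error(cov_equality(3))
})
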