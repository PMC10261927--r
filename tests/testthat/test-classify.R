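# Toy reference: hairpin CCTGAGGAAG, mature TGAGG at [2,7); the templated
# downstream bases are "AAG".

test_that("the hierarchical schema labels the canonical toy cases", {
  ref <- toy_ref()
  p <- classify_params()

  r <- classify_read("TGAGG", ref, p)
  expect_equal(r$klass, "canonical")
  expect_equal(c(r$shift5, r$shift3), c(0L, 0L))
  expect_equal(r$weight, 1)

  # trailing T does not match the downstream template "A": a uridyl tail
  r <- classify_read("TGAGGT", ref, p)
  expect_equal(r$klass, "NTA-U")
  expect_equal(r$tail, "T")
  expect_equal(c(r$shift5, r$shift3), c(0L, 0L))

  # trailing A matches the template: a templated 3' extension, not NTA
  r <- classify_read("TGAGGA", ref, p)
  expect_equal(r$klass, "lv3pE")
  expect_equal(r$shift3, 1L)
  expect_equal(r$tail, "")

  # one internal substitution with canonical ends
  r <- classify_read("TGCGG", ref, p)
  expect_equal(r$klass, "NucVar")
  expect_equal(r$subst_pos, 3L)
  expect_equal(c(r$subst_from, r$subst_to), c("A", "C"))

  # 5' trimmed by one
  r <- classify_read("GAGG", ref, p)
  expect_equal(r$klass, "lv5pT")
  expect_equal(r$shift5, -1L)

  # 5' deviation plus a non-templated tail leaves the NTA class: mv
  r <- classify_read("GAGGTT", ref, p)
  expect_equal(r$klass, "mv")
})

test_that("uridylation of a trimmed species is still NTA, and configurable", {
  ref <- toy_ref()
  # TGAG + G is templated-ambiguous; use an unambiguous trimmed+tailed read
  r <- classify_read("TGAGT", ref, classify_params())
  expect_equal(r$klass, "NTA-U")
  expect_equal(r$shift3, -1L)
  expect_equal(r$tail, "T")
  r2 <- classify_read("TGAGT", ref, classify_params(nta_on_shifted_3p = FALSE))
  expect_equal(r2$klass, "mv")
})

test_that("reads with no valid decomposition are unassigned, not forced", {
  ref <- toy_ref()
  expect_equal(classify_read("CCCCCCCC", ref)$klass, "unassigned")
  # two internal mismatches exceed the NucVar budget
  expect_equal(classify_read("TCACG", ref)$klass, "unassigned")
})

test_that("classification is deterministic and tails break ties lexicographically", {
  ref <- small_ref()
  reads <- vapply(1:20, function(i) {
    set.seed(i + 100)
    paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  }, character(1))
  reads <- c(reads, ref$entries$mature_seq)
  a <- lapply(reads, classify_read, ref = ref)
  b <- lapply(reads, classify_read, ref = ref)
  expect_identical(a, b)
})

test_that("multi-mapped reads get equal fractional weights that sum to one", {
  # the same mature embedded in two hairpins under two ids
  ref <- build_reference(
    c(a = "TGAGGTAGTAGGTTGTATAGTT", b = "TGAGGTAGTAGGTTGTATAGTT"),
    c(hp1 = "CCTGAGGTAGTAGGTTGTATAGTTGC", hp2 = "AATGAGGTAGTAGGTTGTATAGTTCG"))
  r <- classify_read("TGAGGTAGTAGGTTGTATAGTT", ref)
  expect_equal(nrow(r), 2L)
  expect_equal(r$mirna_id, c("a", "b"))   # lexicographic order
  expect_equal(r$weight, c(0.5, 0.5))
  expect_equal(sum(r$weight), 1)
})

test_that("classify_read agrees with the brute-force oracle", {
  for (seed in 1:150) {
    inst <- random_instance(seed)
    got <- classify_read(inst$read, inst$ref)
    want <- oracle_classify(inst$read, inst$ref)
    expect_equal(got$klass, want$klass, info = paste("seed", seed))
    expect_equal(got$mirna_id, want$mirna_id, info = paste("seed", seed))
    expect_equal(got$shift5, want$shift5, info = paste("seed", seed))
    expect_equal(got$shift3, want$shift3, info = paste("seed", seed))
    expect_equal(got$tail, want$tail, info = paste("seed", seed))
    expect_equal(got$weight, want$weight, info = paste("seed", seed))
  }
})

test_that("classify_sample accumulates weighted counts and conserves totals", {
  ref <- toy_ref()
  prof <- profile_from_counts("TGAGG", 10, ref)
  expect_equal(prof$mapped_total, 10)
  expect_equal(unname(prof$class_totals["canonical"]), 10)
  expect_equal(unname(100 * prof$class_totals["canonical"] /
                        prof$mapped_total), 100)

  reads <- c("TGAGG", "TGAGGT", "TGAGGA", "TGCGG", "GAGG", "GAGGTT",
             "CCCCCCCC")
  prof <- profile_from_counts(reads, rep(1, 7), ref)
  expect_equal(prof$mapped_total, 6)
  expect_equal(prof$unassigned_total, 1)
  got <- prof$class_totals[prof$class_totals > 0]
  expect_equal(got[sort(names(got))],
               c(canonical = 1, "lv3pE" = 1, "lv5pT" = 1, mv = 1,
                 "NTA-U" = 1, NucVar = 1)[sort(names(got))])
})

test_that("hierarchy exclusivity: each read contributes to exactly one class", {
  ref <- small_ref()
  cfg <- sim_config(n_mirnas = 4, depth = 500, seed = 5)
  sim <- simulate_sample(generate_reference(cfg), cfg, "cells")
  prof <- classify_sample(sim$truth$insert, ref = generate_reference(cfg))
  # weighted class totals add up to the mapped total
  expect_equal(sum(prof$class_totals), prof$mapped_total)
  # per-read weights sum to 1 within each assignable read
  calls <- prof$calls[prof$calls$klass != "unassigned", ]
  w <- tapply(calls$weight, calls$read_seq, sum)
  expect_true(all(abs(w - 1) < 1e-9))
})

test_that("min_count filters rare collapsed reads before classification", {
  ref <- toy_ref()
  prof <- profile_from_counts(c("TGAGG", "TGAGGT"), c(5, 1), ref,
                              params = classify_params(min_count = 2))
  expect_equal(prof$mapped_total, 5)
  expect_false("NTA-U" %in% prof$calls$klass)
})
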