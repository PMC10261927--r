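LET7 <- "TGAGGTAGTAGGTTGTATAGTT"

test_that("seed sites of the three canonical types are found", {
  # reverse complement of seed 2-8 (GAGGTAG) is CTACCTC; +A makes an 8mer
  s <- seed_sites(LET7, "GGGCTACCTCAGGG")
  expect_equal(s$site_type, "8mer")
  expect_equal(c(s$start, s$end), c(3, 11))

  s <- seed_sites(LET7, "GGGCTACCTCGGGG")   # no A opposite position 1
  expect_equal(s$site_type, "7mer-m8")
  expect_equal(c(s$start, s$end), c(3, 10))

  s <- seed_sites(LET7, "GGGTACCTCAGGG")    # no m8 pair, A1 present
  expect_equal(s$site_type, "7mer-A1")
  expect_equal(c(s$start, s$end), c(3, 10))

  expect_equal(nrow(seed_sites(LET7, "AAAAAAAAAAAA")), 0L)
})

test_that("seed sites at the UTR boundary are reported", {
  s <- seed_sites(LET7, "GGGCTACCTC")       # m8 match ends at the last base
  expect_equal(s$site_type, "7mer-m8")
  expect_equal(s$end, 10)
  s2 <- seed_sites(LET7, "CTACCTCA")        # 8mer is the whole UTR
  expect_equal(s2$site_type, "8mer")
})

test_that("tail-U windows pair antiparallel with bounded G:U wobbles", {
  # toy query window AGTTT (3' end of ...AGTT + U, window 5)
  s <- tumr_sites("AGTT", "GGAAACTGG", max_wobbles = 3, window_len = 5)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end, s$wobbles), c(2, 7, 0))

  s <- tumr_sites("AGTT", "GGAAGCTGG", max_wobbles = 3, window_len = 5)
  expect_equal(c(s$start, s$end, s$wobbles), c(2, 7, 1))  # query T : site G

  # the same window is rejected when wobbles are disallowed
  expect_equal(nrow(tumr_sites("AGTT", "GGAAGCTGG", max_wobbles = 0,
                               window_len = 5)), 0L)
})

test_that("max_wobbles = 0 reduces to exact reverse-complement search", {
  set.seed(17)
  q_mature <- "TGAGGTA"          # query window = GAGGTAT with the added U
  for (i in 1:100) {
    utr <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    got <- tumr_sites(q_mature, utr, max_wobbles = 0, window_len = 8)
    expect_equal(got$start, oracle_revcomp_scan(paste0(q_mature, "T"), utr))
  }
})

test_that("every reported site re-verifies pair by pair", {
  set.seed(23)
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  query <- substr(paste0(mature, "T"), nchar(mature) + 2 - 8, nchar(mature) + 1)
  for (i in 1:50) {
    utr <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                        prob = c(.35, .15, .15, .35)), collapse = "")
    s <- tumr_sites(mature, utr, max_wobbles = 3, window_len = 8)
    for (j in seq_len(nrow(s)))
      expect_true(oracle_verify_site(query, utr, s$start[j], s$end[j], 3))
  }
})

test_that("the conservation filter keeps genes seen in enough species", {
  mk <- function(genes) data.frame(utr_id = genes,
                                   species_id = rep("x", length(genes)),
                                   start = rep(0L, length(genes)),
                                   end = rep(8L, length(genes)),
                                   site_type = rep("TUMR", length(genes)),
                                   wobbles = rep(0L, length(genes)))
  sites <- c(lapply(1:15, function(i) mk(c("g1", "g2"))),
             lapply(16:23, function(i) mk("g1")))
  res <- conservation_filter(sites, min_species = 15, n_species = 23)
  expect_true(res$kept[res$utr_id == "g1"])     # 23 of 23
  expect_true(res$kept[res$utr_id == "g2"])     # exactly 15 of 23
  expect_equal(res$conserved_in[res$utr_id == "g1"], 23L)

  # 14 of 23 is below the threshold
  sites14 <- c(lapply(1:14, function(i) mk("g3")),
               lapply(15:23, function(i) mk(character(0))))
  res14 <- conservation_filter(sites14, 15, 23)
  expect_false(res14$kept[res14$utr_id == "g3"])

  # a single species suffices when min_species is 1
  expect_true(conservation_filter(sites14, 1, 23)$kept[1])
  expect_error(conservation_filter(sites14, 24, 23), "exceeds")
  expect_error(conservation_filter(sites14[1:5], 3, 23), "expected")
})

test_that("raising min_species never adds targets (monotonicity)", {
  set.seed(31)
  sites <- lapply(1:23, function(i) {
    genes <- sample(sprintf("g%02d", 1:12), sample(1:8, 1))
    data.frame(utr_id = genes, species_id = paste0("sp", i), start = 0L,
               end = 8L, site_type = "TUMR", wobbles = 0L)
  })
  kept_prev <- NULL
  for (ms in 1:23) {
    res <- conservation_filter(sites, ms, 23)
    kept <- res$utr_id[res$kept]
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("targetome comparison partitions gene sets exactly", {
  expect_equal(targetome_compare(c("a", "b"), c("a", "b"))$n_overlap, 2)
  expect_equal(targetome_compare(c("a", "b"), c("c"))$n_overlap, 0)
  res <- targetome_compare(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(res$n_unique_canonical, 1)
  expect_equal(res$n_unique_tumr, 1)
  expect_equal(res$n_overlap, 2)
  expect_equal(res$overlap, c("b", "c"))
})

test_that("multi-species UTR FASTA round-trips and drives target prediction", {
  # build a 3-species toy set where gene A has a TUMR site in all species
  # and gene B a canonical 8mer in all species
  mature <- LET7
  q <- substr(paste0(mature, "T"), nchar(mature) - 6, nchar(mature) + 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  site <- paste(rev(comp[strsplit(q, "")[[1]]]), collapse = "")
  seed8 <- "CTACCTCA"
  lines <- character(0)
  for (sp in c("hsa", "mmu", "rno")) {
    lines <- c(lines,
               paste0(">A|", sp), paste0("GGGG", site, "GGGG"),
               paste0(">B|", sp), paste0("TTTT", seed8, "TTTT"))
  }
  fa <- tempfile(fileext = ".fa")
  writeLines(lines, fa)
  utrs <- read_utr_fasta(fa)
  expect_equal(nrow(utrs), 6L)
  expect_equal(sort(unique(utrs$species_id)), c("hsa", "mmu", "rno"))

  res <- predict_targets(mature, utrs, min_species = 3, n_species = 3)
  expect_true("A" %in% res$tumr$utr_id[res$tumr$kept])
  expect_true("B" %in% res$canonical$utr_id[res$canonical$kept])
  expect_false("B" %in% res$tumr$utr_id[res$tumr$kept])
})
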