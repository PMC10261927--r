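#' Simulation configuration
#'
#' Defines the conditions under which synthetic small RNA libraries are
#' generated.  Two regimes are supported by [simulate_sample()]:
#' \describe{
#'   \item{pool}{an equimolar pool of chemically synthesized canonical
#'     miRNAs: no biological isomiRs, only low-rate uniform oligosynthesis
#'     substitutions and rare terminal truncations.}
#'   \item{cells}{a cellular sample: molecules drawn from
#'     \code{class_probs}, with non-templated uridyl/adenyl tails, an
#'     internal substitution spectrum enriched for the RNA-editing-like
#'     T>C and A>G changes, and 3' length variants dominating.}
#' }
#' Both regimes share the library-construction layer: a per-sequence
#' log-normal ligation (capture) efficiency, geometric PCR duplication, and
#' random-nucleotide UMIs attached per the protocol lengths.
#'
#' @param n_mirnas number of mature miRNAs (two arms per hairpin).
#' @param hairpin_len hairpin length in nt.
#' @param mature_len_range inclusive range of mature lengths.
#' @param class_probs named probabilities over isomiR classes generated in
#'   cells mode; must sum to 1.
#' @param tail_len_probs probabilities of tail lengths 1..3 for NTA classes.
#' @param subst_spectrum named weights over the 12 substitution classes
#'   ("A>C", ..., "T>G") used for NucVar molecules; T>C and A>G enriched by
#'   default.
#' @param synthesis_error_rate per-base substitution probability in pool
#'   mode (oligosynthesis errors, uniform over the 12 classes).
#' @param pool_trunc5_rate,pool_trunc3_rate per-molecule probability of a 1-2
#'   nt terminal truncation in pool mode.
#' @param ligation_bias_sd log-scale sd of the per-sequence capture
#'   efficiency; 0 emulates randomized-adapter (bias-free) protocols,
#'   values near 1 emulate fixed-adapter ligation bias.
#' @param pcr_dup_mean mean PCR duplicates per captured molecule
#'   (geometric; 1 = no duplication).
#' @param umi5_len,umi3_len UMI lengths attached to each molecule (5N
#'   protocol: both 5).
#' @param adapter3 3' adapter sequence appended to each read.
#' @param depth target total read count (post-PCR).
#' @param abundance_sdlog log-scale sd of per-miRNA abundances.
#' @param arm_u_multiplier fold-enrichment of NTA-U probability on 3p-arm
#'   miRNAs relative to 5p (uridylation predominantly affects 3p arms).
#' @param seed integer seed; every randomized step derives from it.
#' @return a list of class \code{SimConfig}.
#' @export
sim_config <- function(n_mirnas = 20L,
                       hairpin_len = 60L,
                       mature_len_range = c(20L, 23L),
                       class_probs = c(canonical = 0.45, lv3pT = 0.25,
                                       "NTA-U" = 0.10, "NTA-A" = 0.10,
                                       NucVar = 0.05, lv3pE = 0.05),
                       tail_len_probs = c(0.7, 0.2, 0.1),
                       subst_spectrum = default_subst_spectrum(),
                       synthesis_error_rate = 0.003,
                       pool_trunc5_rate = 0.01,
                       pool_trunc3_rate = 0.02,
                       ligation_bias_sd = 0,
                       pcr_dup_mean = 1,
                       umi5_len = 5L, umi3_len = 5L,
                       adapter3 = "AGATCGGAAGAGCACACGTCT",
                       depth = 5e4,
                       abundance_sdlog = 1,
                       arm_u_multiplier = 5,
                       seed = 1L) {
  stopifnot(n_mirnas >= 1,
            abs(sum(class_probs) - 1) < 1e-8,
            all(class_probs >= 0), all(tail_len_probs >= 0),
            all(names(class_probs) %in% setdiff(ISOMIR_CLASSES, "unassigned")),
            max(mature_len_range) <= hairpin_len,
            synthesis_error_rate >= 0, synthesis_error_rate < 1,
            pcr_dup_mean >= 1, depth >= 1)
  structure(as.list(environment()), class = "SimConfig")
}

#' Default NucVar substitution spectrum (cells mode)
#'
#' T>C and A>G dominate, reflecting APOBEC- and ADAR-like editing; the ten
#' remaining classes share the rest uniformly.
#' @return named numeric over the 12 substitution classes, summing to 1.
#' @export
default_subst_spectrum <- function() {
  cls <- subst_class_names()
  w <- stats::setNames(rep(0.045, 12), cls)
  w["T>C"] <- 0.30; w["A>G"] <- 0.25
  w / sum(w)
}

#' The 12 substitution class names ("A>C", ..., "T>G")
#' @export
subst_class_names <- function() {
  b <- c("A", "C", "G", "T")
  unlist(lapply(b, function(x) paste0(x, ">", setdiff(b, x))))
}

#' Generate a random miRNA reference
#'
#' Builds random hairpins with a 5p and a 3p mature arm embedded (the last
#' hairpin carries a single 5p arm when \code{n_mirnas} is odd).  The two
#' hairpin bases immediately downstream of each mature end are drawn from
#' \{C, G\}, so that the uridyl and adenyl tails generated in cells mode are
#' never accidentally templated.  Each mature sequence is checked to occur
#' exactly once across all hairpins (resampling otherwise), which keeps
#' classification of simulated reads unambiguous.
#'
#' @param cfg a [sim_config()].
#' @return a \code{ReferenceSet} with ids \code{sim-mir-<i>-5p/-3p}.
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (max(cfg$mature_len_range) > cfg$hairpin_len - 10)
    stop("mature length incompatible with hairpin length")
  set.seed(cfg$seed)
  n_hp <- ceiling(cfg$n_mirnas / 2)
  hairpins <- character(0); matures <- character(0)
  for (i in seq_len(n_hp)) {
    for (try in 1:100) {
      hp <- paste(sample(c("A", "C", "G", "T"), cfg$hairpin_len, TRUE),
                  collapse = "")
      L5 <- sample(cfg$mature_len_range[1]:cfg$mature_len_range[2], 1)
      L3 <- sample(cfg$mature_len_range[1]:cfg$mature_len_range[2], 1)
      s5 <- 4L; e5 <- s5 + L5                  # 0-based half-open
      e3 <- cfg$hairpin_len - 4L; s3 <- e3 - L3
      both <- (i * 2 <= cfg$n_mirnas)
      if (both && e5 + 2 > s3) next            # arms must not touch
      # force a C/G dinucleotide downstream of each mature end
      substr(hp, e5 + 1, e5 + 2) <- paste(sample(c("C", "G"), 2, TRUE), collapse = "")
      if (both)
        substr(hp, e3 + 1, e3 + 2) <- paste(sample(c("C", "G"), 2, TRUE), collapse = "")
      m5 <- substr(hp, s5 + 1, e5); m3 <- substr(hp, s3 + 1, e3)
      cand_m <- if (both) c(m5, m3) else m5
      all_hp <- c(hairpins, hp)
      ok <- all(vapply(cand_m, function(m)
        sum(vapply(all_hp, function(h) count_occurrences(m, h), integer(1))) == 1L,
        logical(1))) && !any(cand_m %in% matures)
      if (!ok) next
      hairpins[sprintf("sim-mir-%d", i)] <- hp
      matures[sprintf("sim-mir-%d-5p", i)] <- m5
      if (both) matures[sprintf("sim-mir-%d-3p", i)] <- m3
      break
    }
  }
  if (length(matures) < cfg$n_mirnas)
    stop("could not generate a repeat-free reference; relax the configuration")
  build_reference(matures, hairpins)
}

count_occurrences <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Simulate a small RNA library with per-read ground truth
#'
#' Generates molecules according to the regime (see [sim_config()]), applies
#' the library-construction layer (ligation bias, PCR duplication, UMIs,
#' 3' adapter) and returns the reads together with an exact truth table.
#' Every read is labelled with the isomiR class the molecule actually
#' realizes; truth proportions are therefore exact by construction.
#'
#' In cells mode, per-miRNA class probabilities are derived from the global
#' \code{class_probs} by scaling the NTA-U probability with the arm
#' multiplier (3p up, 5p down) such that the abundance-weighted mean equals
#' the global value; the difference is absorbed by the canonical class.
#'
#' @param ref a \code{ReferenceSet} (normally from [generate_reference()]).
#' @param cfg a [sim_config()].
#' @param mode \code{"pool"} or \code{"cells"}.
#' @param fastq_path optional path; when given, reads are written as FASTQ.
#' @return a list of class \code{SimSample}:
#'   \item{reads}{character vector of full reads (UMI5 + insert + UMI3 +
#'     adapter)}
#'   \item{truth}{data.frame, one row per read: read_id, molecule_id,
#'     mirna_id, klass, shift5, shift3, tail, subst, insert, umi}
#'   \item{n_molecules}{captured (pre-PCR) molecule count}
#'   \item{class_props}{realized molecule-level class proportions}
#' @export
simulate_sample <- function(ref, cfg, mode = c("cells", "pool"),
                            fastq_path = NULL) {
  stopifnot(inherits(ref, "ReferenceSet"), inherits(cfg, "SimConfig"))
  mode <- match.arg(mode)
  set.seed(cfg$seed + 1L)
  ent <- ref$entries
  n_mol <- max(1L, round(cfg$depth / cfg$pcr_dup_mean))

  # per-miRNA abundances
  ab <- stats::rlnorm(nrow(ent), 0, cfg$abundance_sdlog)
  ab <- ab / sum(ab)

  # per-molecule miRNA and class
  mirna_idx <- sample.int(nrow(ent), n_mol, TRUE, prob = ab)
  if (mode == "pool") {
    klass_intent <- rep("canonical", n_mol)
  } else {
    pmat <- per_mirna_class_probs(cfg, ent$arm, ab)
    klass_intent <- character(n_mol)
    for (i in seq_len(nrow(ent))) {
      sel <- mirna_idx == i
      if (!any(sel)) next
      klass_intent[sel] <- sample(colnames(pmat), sum(sel), TRUE, prob = pmat[i, ])
    }
  }

  mol <- realize_molecules(ref, cfg, mode, mirna_idx, klass_intent)

  # ligation bias: capture probability proportional to a per-sequence
  # log-normal efficiency
  if (cfg$ligation_bias_sd > 0) {
    useq <- unique(mol$insert)
    eff <- stats::setNames(stats::rlnorm(length(useq), 0, cfg$ligation_bias_sd), useq)
    keepers <- sample.int(nrow(mol), nrow(mol), TRUE, prob = eff[mol$insert])
    mol <- mol[keepers, , drop = FALSE]
  }
  mol$molecule_id <- seq_len(nrow(mol))

  # UMIs per molecule
  umi_n <- cfg$umi5_len + cfg$umi3_len
  mol$umi <- if (umi_n > 0) random_seqs(nrow(mol), umi_n) else ""

  # PCR duplication: geometric on {1, 2, ...} with mean pcr_dup_mean
  dup <- if (cfg$pcr_dup_mean > 1)
    1L + stats::rgeom(nrow(mol), 1 / cfg$pcr_dup_mean) else rep(1L, nrow(mol))
  idx <- rep(seq_len(nrow(mol)), dup)
  truth <- mol[idx, , drop = FALSE]
  truth$read_id <- sprintf("read%d", seq_len(nrow(truth)))
  rownames(truth) <- NULL

  u5 <- substr(truth$umi, 1, cfg$umi5_len)
  u3 <- substr(truth$umi, cfg$umi5_len + 1, umi_n)
  reads <- paste0(u5, truth$insert, u3, cfg$adapter3)

  out <- structure(list(
    reads = reads,
    truth = truth[, c("read_id", "molecule_id", "mirna_id", "klass", "shift5",
                      "shift3", "tail", "subst", "insert", "umi")],
    n_molecules = nrow(mol),
    class_props = prop.table(table(factor(mol$klass, levels = ISOMIR_CLASSES)))),
    class = "SimSample")
  if (!is.null(fastq_path)) write_sim_fastq(out, fastq_path)
  out
}

# per-miRNA class probability matrix: NTA-U scaled by arm, canonical absorbs
per_mirna_class_probs <- function(cfg, arms, ab) {
  classes <- names(cfg$class_probs)
  pmat <- matrix(rep(cfg$class_probs, each = length(arms)),
                 nrow = length(arms), dimnames = list(NULL, classes))
  if ("NTA-U" %in% classes && cfg$arm_u_multiplier != 1) {
    w <- ifelse(arms == "3p", cfg$arm_u_multiplier, 1)
    w <- w / sum(ab * w)                 # abundance-weighted mean of w == 1
    if (!"canonical" %in% classes)
      stop("arm-specific uridylation requires a canonical class to absorb the difference")
    pu <- cfg$class_probs[["NTA-U"]] * w
    # cap so the canonical class can always absorb the difference; when the
    # cap binds the realized overall NTA-U rate falls slightly below nominal
    pu <- pmin(pu, cfg$class_probs[["NTA-U"]] + cfg$class_probs[["canonical"]] - 0.01)
    pmat[, "NTA-U"] <- pu
    pmat[, "canonical"] <- pmat[, "canonical"] + cfg$class_probs[["NTA-U"]] - pu
  }
  pmat
}

# turn (miRNA, intended class) pairs into concrete molecules with exact labels
realize_molecules <- function(ref, cfg, mode, mirna_idx, klass_intent) {
  ent <- ref$entries
  n <- length(mirna_idx)
  insert <- character(n); klass <- klass_intent
  shift5 <- integer(n); shift3 <- integer(n)
  tail <- character(n); subst <- character(n)
  tailp <- cfg$tail_len_probs / sum(cfg$tail_len_probs)
  spec <- cfg$subst_spectrum / sum(cfg$subst_spectrum)

  down <- vapply(seq_len(nrow(ent)), function(i)
    downstream_template(ref, ent$mirna_id[i], 4L), character(1))
  up <- vapply(seq_len(nrow(ent)), function(i) {
    e <- ent[i, ]
    if (e$start == 0) "" else
      substr(ref$hairpins[[e$hairpin_id]], max(1, e$start - 3), e$start)
  }, character(1))

  for (j in seq_len(n)) {
    i <- mirna_idx[j]
    m <- ent$mature_seq[i]
    L <- nchar(m)
    k <- klass_intent[j]
    if (mode == "pool") {
      res <- realize_pool_molecule(m, cfg)
      insert[j] <- res$seq; klass[j] <- res$klass
      shift5[j] <- res$shift5; shift3[j] <- res$shift3; subst[j] <- res$subst
      next
    }
    switch(k,
      canonical = { insert[j] <- m },
      NucVar = {
        res <- draw_internal_subst(m, spec)
        insert[j] <- res$seq; subst[j] <- res$subst
        if (res$seq == m) klass[j] <- "canonical"   # no eligible position
      },
      "NTA-U" = , "NTA-A" = , "NTA-C" = , "NTA-G" = {
        base <- chartr("U", "T", sub("NTA-", "", k))
        tl <- sample.int(length(tailp), 1, prob = tailp)
        if (substr(down[i], 1, 1) == base) {
          # tail would be templated for this miRNA; realized class changes
          insert[j] <- m; klass[j] <- "canonical"
        } else {
          insert[j] <- paste0(m, strrep(base, tl)); tail[j] <- strrep(base, tl)
        }
      },
      "NTA-mixed" = {
        b1 <- sample(setdiff(c("A", "C", "G", "T"), substr(down[i], 1, 1)), 1)
        b2 <- sample(setdiff(c("A", "C", "G", "T"), b1), 1)
        insert[j] <- paste0(m, b1, b2); tail[j] <- paste0(b1, b2)
      },
      lv3pT = {
        tl <- sample(1:2, 1, prob = c(0.75, 0.25))
        insert[j] <- substr(m, 1, L - tl); shift3[j] <- -tl
      },
      lv3pE = {
        el <- sample(1:2, 1, prob = c(0.8, 0.2))
        el <- min(el, nchar(down[i]))
        if (el == 0) { insert[j] <- m; klass[j] <- "canonical" }
        else { insert[j] <- paste0(m, substr(down[i], 1, el)); shift3[j] <- el }
      },
      lv5pT = {
        tl <- sample(1:2, 1, prob = c(0.75, 0.25))
        insert[j] <- substr(m, tl + 1, L); shift5[j] <- -tl
      },
      lv5pE = {
        el <- min(sample(1:2, 1, prob = c(0.8, 0.2)), nchar(up[i]))
        if (el == 0) { insert[j] <- m; klass[j] <- "canonical" }
        else {
          insert[j] <- paste0(substr(up[i], nchar(up[i]) - el + 1, nchar(up[i])), m)
          shift5[j] <- el
        }
      },
      mv = {
        # 5' trim by one plus a non-templated tail base
        b <- sample(setdiff(c("A", "C", "G", "T"),
                            substr(down[i], 1, 1)), 1)
        insert[j] <- paste0(substr(m, 2, L), b)
        shift5[j] <- -1L; shift3[j] <- 0L; tail[j] <- b
      },
      stop("unknown class in class_probs: ", k)
    )
  }
  data.frame(mirna_id = ent$mirna_id[mirna_idx], klass = klass,
             shift5 = shift5, shift3 = shift3, tail = tail, subst = subst,
             insert = insert, stringsAsFactors = FALSE)
}

# pool-mode molecule: optional terminal truncation, then per-base
# oligosynthesis substitutions; the realized label reflects what was made
realize_pool_molecule <- function(m, cfg) {
  L <- nchar(m)
  s5 <- 0L; s3 <- 0L
  if (stats::runif(1) < cfg$pool_trunc5_rate) { s5 <- -sample(1:2, 1); m <- substr(m, -s5 + 1, L) }
  L <- nchar(m)
  if (stats::runif(1) < cfg$pool_trunc3_rate) { s3 <- -sample(1:2, 1); m <- substr(m, 1, L + s3) }
  v <- strsplit(m, "")[[1]]
  hit <- which(stats::runif(length(v)) < cfg$synthesis_error_rate)
  subst <- ""
  for (p in hit) {
    newb <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    subst <- paste0(subst, if (nzchar(subst)) ";" else "",
                    v[p], ">", newb, "@", p)
    v[p] <- newb
  }
  seq <- paste(v, collapse = "")
  klass <-
    if (!length(hit) && s5 == 0 && s3 == 0) "canonical"
    else if (length(hit) == 1 && s5 == 0 && s3 == 0 &&
             hit > 1 && hit < length(v)) "NucVar"
    else if (!length(hit) && s5 < 0 && s3 == 0) "lv5pT"
    else if (!length(hit) && s5 == 0 && s3 < 0) "lv3pT"
    else if (!length(hit)) "mv"
    else "unassigned"   # multi-error molecules have no clean single label
  list(seq = seq, klass = klass, shift5 = s5, shift3 = s3, subst = subst)
}

# one internal substitution drawn from the spectrum, restricted to classes
# whose from-base occurs strictly inside the mature
draw_internal_subst <- function(m, spec) {
  v <- strsplit(m, "")[[1]]
  L <- length(v)
  internal <- 2:(L - 1)
  for (try in 1:20) {
    cls <- sample(names(spec), 1, prob = spec)
    fromb <- substr(cls, 1, 1); tob <- substr(cls, 3, 3)
    pos <- internal[v[internal] == fromb]
    if (!length(pos)) next
    p <- if (length(pos) == 1) pos else sample(pos, 1)
    v[p] <- tob
    return(list(seq = paste(v, collapse = ""),
                subst = paste0(fromb, ">", tob, "@", p)))
  }
  list(seq = m, subst = "")
}

random_seqs <- function(n, len) {
  if (len == 0) return(rep("", n))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Write a simulated sample as FASTQ
#'
#' @param sim a \code{SimSample}.
#' @param path output FASTQ path.
#' @return invisibly, the path.
#' @export
write_sim_fastq <- function(sim, path) {
  x <- Biostrings::BStringSet(stats::setNames(sim$reads, sim$truth$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(sim$reads))))
  invisible(path)
}

#' Realized class proportions of a simulated sample
#'
#' @param sim a \code{SimSample}.
#' @param level \code{"molecule"} (pre-PCR, the biological truth) or
#'   \code{"read"} (post-PCR).
#' @return named proportions over isomiR classes.
#' @export
truth_class_props <- function(sim, level = c("molecule", "read")) {
  level <- match.arg(level)
  tr <- sim$truth
  if (level == "molecule") tr <- tr[!duplicated(tr$molecule_id), ]
  prop.table(table(factor(tr$klass, levels = ISOMIR_CLASSES)))
}
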