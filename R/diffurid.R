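#' Differential uridylation between WT and TUT4/7-DKO samples
#'
#' Compares per-miRNA uridylation percentages (fraction of a miRNA's reads
#' carrying an NTA-U tail) between two groups of samples.  miRNAs below
#' \code{min_reads} total count in any sample are excluded.  A two-sided
#' t-test (Welch by default) is applied per miRNA and corrected across
#' miRNAs by Benjamini-Hochberg; a miRNA is called differentially
#' uridylated when q < alpha and the WT/DKO fold change is at least
#' \code{fc_min}.
#'
#' The fold change is the ratio of group mean percentages, with a floor of
#' 0.1 percentage points on the denominator to avoid division blow-ups when
#' uridylation is absent in the knockout; floored results are flagged.
#'
#' @param wt,dko lists of per-sample uridylation tables (from
#'   [uridylation_table()]), one element per sample.
#' @param fc_min minimum WT/DKO fold change (default 1.5).
#' @param alpha FDR level (default 0.05).
#' @param min_reads per-sample per-miRNA count threshold (default 10).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return data.frame: mirna_id, mean_pct_wt, mean_pct_dko, fc, p, q,
#'   significant, fc_floored.
#' @export
diff_uridylation <- function(wt, dko, fc_min = 1.5, alpha = 0.05,
                             min_reads = 10, var_equal = FALSE) {
  if (length(wt) < 2) stop("WT group has fewer than 2 samples")
  if (length(dko) < 2) stop("DKO group has fewer than 2 samples")
  get_ok <- function(tabs) {
    ids <- Reduce(intersect, lapply(tabs, function(t)
      t$mirna_id[t$total_count >= min_reads]))
    ids
  }
  shared <- intersect(get_ok(wt), get_ok(dko))
  if (!length(shared)) stop("no shared miRNAs between groups after filtering")
  pct_mat <- function(tabs, ids) {
    vapply(tabs, function(t) t$pct_NTA_U[match(ids, t$mirna_id)],
           numeric(length(ids)))
  }
  a <- pct_mat(wt, shared); b <- pct_mat(dko, shared)
  if (length(shared) == 1) { a <- matrix(a, nrow = 1); b <- matrix(b, nrow = 1) }
  res <- do.call(rbind, lapply(seq_along(shared), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = var_equal)$p.value
    }
    denom <- max(mean(y), 0.1)
    data.frame(mirna_id = shared[i], mean_pct_wt = mean(x),
               mean_pct_dko = mean(y), fc = mean(x) / denom, p = p,
               fc_floored = mean(y) < 0.1, stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha & res$fc >= fc_min
  res[order(res$q, res$mirna_id),
      c("mirna_id", "mean_pct_wt", "mean_pct_dko", "fc", "p", "q",
        "significant", "fc_floored")]
}

#' Intersection of significant miRNA sets across studies
#'
#' @param sets named list of character vectors (one per study) of
#'   differentially uridylated miRNA ids.
#' @return a list with \item{observed}{size of the intersection over all
#'   studies} \item{common}{the intersected ids} \item{membership}{logical
#'   matrix (miRNA x study) supporting upset-style bar output}
#' @export
intersect_studies <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 studies")
  if (any(!vapply(sets, length, integer(1))))
    { }  # empty sets are allowed; the intersection is then empty
  if (is.null(names(sets))) names(sets) <- paste0("study", seq_along(sets))
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(universe, names(sets)))
  else rownames(membership) <- universe
  common <- if (length(universe)) universe[rowSums(membership) == length(sets)]
            else character(0)
  list(observed = length(common), common = common, membership = membership)
}

#' Closed-form expected intersection under independent random sets
#'
#' If each study draws its observed number of miRNAs uniformly at random
#' (without replacement within the study) from a universe of size N, each
#' element lies in study i's set with probability s_i/N independently
#' across studies, so by linearity the expected size of the full
#' intersection is \eqn{E = N \prod_i (s_i / N)}.
#'
#' @param set_sizes integer vector of per-study set sizes.
#' @param universe_size N, size of the common universe.
#' @return the expected intersection size.
#' @export
expected_overlap <- function(set_sizes, universe_size) {
  stopifnot(universe_size >= 1, all(set_sizes >= 0),
            all(set_sizes <= universe_size))
  universe_size * prod(set_sizes / universe_size)
}

#' Randomization test for cross-study intersection
#'
#' Repeatedly draws, for each study, the same number of miRNAs uniformly
#' without replacement from the universe, intersects the draws, and
#' summarises the empirical null distribution of the intersection size.
#' The Z score is the number of null standard deviations separating the
#' observed intersection from the null mean; the O/E ratio is reported
#' alongside.
#'
#' @param sets named list of character vectors of significant miRNA ids.
#' @param universe character vector of miRNA ids to draw from; by default
#'   the union of all sets (miRNAs differentially uridylated in at least
#'   one study).
#' @param n_iter number of randomizations (default 1000).
#' @param seed integer seed (stored in the result).
#' @return an object of class \code{IntersectionResult}: observed, expected,
#'   sd, z, oe_ratio, n_iter, seed, degenerate, null_sizes.
#' @export
randomization_z <- function(sets, universe = NULL, n_iter = 1000L,
                            seed = 1L) {
  obs <- intersect_studies(sets)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  if (!all(unlist(sets) %in% universe))
    stop("every study set must be a subset of the universe")
  N <- length(universe)
  sizes <- vapply(sets, length, integer(1))
  set.seed(seed)
  null_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    draws <- lapply(sizes, function(s) sample(universe, s))
    null_sizes[it] <- length(Reduce(intersect, draws))
  }
  expected <- mean(null_sizes)
  s <- stats::sd(null_sizes)
  degenerate <- is.na(s) || s == 0
  structure(list(observed = obs$observed,
                 expected = expected,
                 sd = s,
                 z = if (degenerate) NA_real_ else (obs$observed - expected) / s,
                 oe_ratio = if (expected > 0) obs$observed / expected else NA_real_,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 degenerate = degenerate, null_sizes = null_sizes),
            class = "IntersectionResult")
}

#' @export
print.IntersectionResult <- function(x, ...) {
  cat("Cross-study intersection: observed", x$observed,
      "| expected", signif(x$expected, 4), "+/-", signif(x$sd, 4), "\n")
  if (x$degenerate) cat("  degenerate null (sd = 0); Z undefined\n")
  else cat("  Z =", signif(x$z, 4), " O/E =", signif(x$oe_ratio, 4),
           " (", x$n_iter, "randomizations, seed", x$seed, ")\n")
  invisible(x)
}
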