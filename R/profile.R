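#' Per-sample isomiR class composition, with group summaries
#'
#' Converts class totals of each profile into percentages of the
#' miRNA-mapped total (unassigned reads are excluded from the denominator)
#' and summarises per group as the mean of per-sample percentages with the
#' sample (n-1) standard deviation.
#'
#' @param profiles a list of \code{SampleProfile} objects.
#' @param groups optional character vector (recycled names accepted) giving
#'   one group label per profile; defaults to a single group.
#' @return a list with \item{per_sample}{data.frame, one row per sample,
#'   columns sample_id, group and one percentage column per class}
#'   \item{group_summary}{data.frame group x class with mean and sd}
#'   Samples with zero mapped reads are excluded with a warning.
#' @export
composition_table <- function(profiles, groups = NULL) {
  if (inherits(profiles, "SampleProfile")) profiles <- list(profiles)
  if (is.null(groups)) groups <- rep("all", length(profiles))
  stopifnot(length(groups) == length(profiles))
  ok <- vapply(profiles, function(p) p$mapped_total > 0, logical(1))
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " sample(s) with zero miRNA-mapped reads")
    profiles <- profiles[ok]; groups <- groups[ok]
  }
  classes <- setdiff(ISOMIR_CLASSES, "unassigned")
  per <- do.call(rbind, lapply(profiles, function(p) {
    pct <- 100 * p$class_totals[classes] / p$mapped_total
    as.data.frame(c(list(sample_id = p$sample_id), as.list(pct)),
                  check.names = FALSE)
  }))
  per$group <- groups
  per <- per[, c("sample_id", "group", classes)]
  summ <- do.call(rbind, lapply(unique(groups), function(g) {
    sub <- per[per$group == g, classes, drop = FALSE]
    data.frame(group = g, klass = classes,
               mean_pct = vapply(sub, mean, numeric(1)),
               sd_pct = vapply(sub, stats::sd, numeric(1)),
               row.names = NULL)
  }))
  summ$sd_pct[is.na(summ$sd_pct)] <- 0   # single-sample groups
  list(per_sample = per, group_summary = summ)
}

#' NucVar substitution spectrum of a sample
#'
#' Percentage of miRNA-mapped reads in each of the 12 substitution classes
#' (reference base > read base), taken from the substitution recorded on
#' each NucVar call.
#'
#' @param profile a \code{SampleProfile}.
#' @return named numeric of length 12 ("A>C" ... "T>G"); sums to the total
#'   NucVar percentage of the sample.
#' @export
nucvar_spectrum <- function(profile) {
  stopifnot(inherits(profile, "SampleProfile"))
  cls <- subst_class_names()
  out <- stats::setNames(numeric(12), cls)
  nv <- profile$calls[profile$calls$klass == "NucVar", , drop = FALSE]
  if (nrow(nv) > 0) {
    key <- paste0(nv$subst_from, ">", nv$subst_to)
    agg <- tapply(nv$weighted_count, key, sum)
    out[names(agg)] <- agg
  }
  100 * out / profile$mapped_total
}

#' Per-miRNA non-templated addition percentages
#'
#' For every miRNA with at least one mapped read, the percentage of its
#' reads carrying each NTA tail class, plus its total weighted count.
#' miRNAs below \code{min_reads} are flagged low-coverage (and typically
#' excluded from downstream differential testing).
#'
#' @param profile a \code{SampleProfile}.
#' @param min_reads minimum per-miRNA total for full confidence (default 10).
#' @return data.frame: mirna_id, pct_NTA_U/A/C/G, total_count, low_coverage.
#' @export
uridylation_table <- function(profile, min_reads = 10) {
  stopifnot(inherits(profile, "SampleProfile"))
  calls <- profile$calls[profile$calls$klass != "unassigned", , drop = FALSE]
  if (nrow(calls) == 0)
    return(data.frame(mirna_id = character(0), pct_NTA_U = numeric(0),
                      pct_NTA_A = numeric(0), pct_NTA_C = numeric(0),
                      pct_NTA_G = numeric(0), total_count = numeric(0),
                      low_coverage = logical(0)))
  tot <- tapply(calls$weighted_count, calls$mirna_id, sum)
  pct_of <- function(kl) {
    sub <- calls[calls$klass == kl, , drop = FALSE]
    x <- stats::setNames(numeric(length(tot)), names(tot))
    if (nrow(sub)) {
      agg <- tapply(sub$weighted_count, sub$mirna_id, sum)
      x[names(agg)] <- agg
    }
    100 * x / as.numeric(tot)
  }
  out <- data.frame(mirna_id = names(tot),
                    pct_NTA_U = pct_of("NTA-U"), pct_NTA_A = pct_of("NTA-A"),
                    pct_NTA_C = pct_of("NTA-C"), pct_NTA_G = pct_of("NTA-G"),
                    total_count = as.numeric(tot), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$low_coverage <- out$total_count < min_reads
  out[order(out$mirna_id), ]
}

#' Read-weighted uridylation percentage per hairpin arm
#'
#' Aggregates NTA-U reads over all miRNAs of each arm (5p/3p) within each
#' sample, then averages per group: uridylation by TUT4/7 acts
#' predominantly on 3p-arm miRNAs, and this table exposes that contrast.
#'
#' @param profiles list of \code{SampleProfile}.
#' @param ref the \code{ReferenceSet} carrying arm annotation.
#' @param groups optional group label per profile.
#' @return data.frame: group, arm, mean_pct_NTA_U, sd_pct, n_samples.
#' @export
arm_uridylation <- function(profiles, ref, groups = NULL) {
  if (inherits(profiles, "SampleProfile")) profiles <- list(profiles)
  stopifnot(inherits(ref, "ReferenceSet"))
  if (is.null(groups)) groups <- rep("all", length(profiles))
  arm_of <- stats::setNames(ref$entries$arm, ref$entries$mirna_id)
  per <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    calls <- profiles[[i]]$calls
    calls <- calls[calls$klass != "unassigned", , drop = FALSE]
    calls$arm <- arm_of[calls$mirna_id]
    do.call(rbind, lapply(c("5p", "3p"), function(a) {
      sub <- calls[calls$arm == a, , drop = FALSE]
      tot <- sum(sub$weighted_count)
      u <- sum(sub$weighted_count[sub$klass == "NTA-U"])
      data.frame(group = groups[i], arm = a,
                 pct = if (tot > 0) 100 * u / tot else NA_real_)
    }))
  }))
  out <- do.call(rbind, lapply(split(per, list(per$group, per$arm), drop = TRUE),
    function(d) data.frame(group = d$group[1], arm = d$arm[1],
                           mean_pct_NTA_U = mean(d$pct, na.rm = TRUE),
                           sd_pct = stats::sd(d$pct[!is.na(d$pct)]),
                           n_samples = sum(!is.na(d$pct)))))
  out$sd_pct[is.na(out$sd_pct)] <- 0
  rownames(out) <- NULL
  out[order(out$group, out$arm), ]
}

#' Compare per-class percentages between two sample groups
#'
#' Two-sided Welch (unequal-variance) t-test per class, with
#' Benjamini-Hochberg correction across the tested classes; classes with
#' q < alpha are flagged.  A pooled-variance test can be requested instead.
#'
#' @param groupA,groupB data.frames (or matrices) of per-sample percentages
#'   with one column per class and one row per sample, e.g. the class
#'   columns of \code{composition_table()$per_sample}.
#' @param alpha significance level on the adjusted p-value.
#' @param var_equal use a pooled-variance t-test instead of Welch.
#' @return data.frame: klass, mean_A, mean_B, t, p, q, significant.
#' @export
compare_group_fractions <- function(groupA, groupB, alpha = 0.05,
                                    var_equal = FALSE) {
  groupA <- as.data.frame(groupA); groupB <- as.data.frame(groupB)
  if (nrow(groupA) < 2) stop("group A has fewer than 2 samples")
  if (nrow(groupB) < 2) stop("group B has fewer than 2 samples")
  classes <- intersect(names(groupA), names(groupB))
  res <- do.call(rbind, lapply(classes, function(k) {
    a <- groupA[[k]]; b <- groupB[[k]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    data.frame(klass = k, mean_A = mean(a), mean_B = mean(b),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  res
}

#' Coefficient of variation of per-species counts
#'
#' CoV = sample standard deviation (n-1 denominator) / mean.  Used as an
#' equality-of-capture metric over an equimolar spike-in set: a perfectly
#' unbiased protocol gives CoV 0; ligation bias inflates it.
#'
#' @param counts numeric vector of per-species counts (length >= 2).
#' @return the coefficient of variation (scale-invariant).
#' @export
cov_equality <- function(counts) {
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m <= 0) stop("mean of counts must be positive")
  stats::sd(counts) / m
}
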