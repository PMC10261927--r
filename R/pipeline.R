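#' Assemble a pipeline run configuration
#'
#' Collects every input path and parameter of an end-to-end run.  The
#' sample sheet is a TSV with columns \code{sample}, \code{fastq},
#' \code{group} (e.g. WT/DKO), \code{study}, and optionally per-sample
#' protocol columns \code{adapter3}, \code{umi5_len}, \code{umi3_len}.
#'
#' @param mature_fasta,hairpin_fasta reference FASTA paths.
#' @param sample_sheet path to the sample sheet TSV.
#' @param out_dir output directory (created if absent).
#' @param protocol default [protocol_spec()] applied where the sheet has no
#'   per-sample protocol columns.
#' @param classify [classify_params()].
#' @param dedup collapse PCR duplicates by UMI where UMIs are present.
#' @param fc_min,alpha,min_reads,n_iter differential-uridylation and
#'   randomization parameters.
#' @param utr_fasta optional multi-species 3'-UTR FASTA for target search.
#' @param target_mirna mature miRNA id to run target prediction for
#'   (required when \code{utr_fasta} is given).
#' @param n_utr_species,min_utr_species conservation-filter settings.
#' @param seed integer seed for the randomization test.
#' @return a list of class \code{RunConfig}; paths are checked to exist.
#' @export
run_config <- function(mature_fasta, hairpin_fasta, sample_sheet, out_dir,
                       protocol = protocol_spec(), classify = classify_params(),
                       dedup = TRUE, fc_min = 1.5, alpha = 0.05,
                       min_reads = 10, n_iter = 1000L, utr_fasta = NULL,
                       target_mirna = NULL, n_utr_species = 23L,
                       min_utr_species = 15L, seed = 1L) {
  for (p in c(mature_fasta, hairpin_fasta, sample_sheet, utr_fasta))
    if (!file.exists(p)) stop("config error: missing input file: ", p)
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  need <- c("sample", "fastq", "group")
  if (!all(need %in% names(sheet)))
    stop("config error: sample sheet must have columns ",
         paste(need, collapse = ", "))
  if (!"study" %in% names(sheet)) sheet$study <- "study1"
  for (p in sheet$fastq)
    if (!file.exists(p)) stop("config error: missing FASTQ: ", p)
  if (!is.null(utr_fasta) && is.null(target_mirna))
    stop("config error: target_mirna required when utr_fasta is given")
  structure(list(mature_fasta = mature_fasta, hairpin_fasta = hairpin_fasta,
                 sheet = sheet, out_dir = out_dir, protocol = protocol,
                 classify = classify, dedup = dedup, fc_min = fc_min,
                 alpha = alpha, min_reads = min_reads,
                 n_iter = as.integer(n_iter), utr_fasta = utr_fasta,
                 target_mirna = target_mirna,
                 n_utr_species = as.integer(n_utr_species),
                 min_utr_species = as.integer(min_utr_species),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full isomiR pipeline
#'
#' Executes preprocess -> classify -> profile for every sample in the
#' sheet; when both a WT and a DKO group are present, runs differential
#' uridylation per study and, with two or more studies, the cross-study
#' intersection with its randomization Z score; when a UTR set is supplied,
#' runs canonical and tail-U target prediction for the configured miRNA.
#' All tables are written as TSV (intersection and manifest as JSON) into
#' \code{out_dir}.  Identical config and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory results (profiles,
#'   composition, uridylation, diffurid, intersection, targets, manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- load_reference(config$mature_fasta, config$hairpin_fasta)
  sheet <- config$sheet

  profiles <- vector("list", nrow(sheet))
  accounting <- list()
  for (i in seq_len(nrow(sheet))) {
    sm <- sheet$sample[i]
    spec <- config$protocol
    if (all(c("adapter3", "umi5_len", "umi3_len") %in% names(sheet)))
      spec <- protocol_spec(sheet$adapter3[i], sheet$umi5_len[i],
                            sheet$umi3_len[i], spec$min_insert, spec$max_insert)
    step <- function(what, expr) tryCatch(expr, error = function(e)
      stop("stage ", what, " failed for sample ", sm, ": ",
           conditionMessage(e), call. = FALSE))
    trimmed <- step("preprocess", extract_and_trim(sheet$fastq[i], spec))
    collapsed <- step("preprocess",
                      collapse_reads(trimmed$pairs,
                                     dedup = config$dedup &&
                                       (spec$umi5_len + spec$umi3_len) > 0))
    profiles[[i]] <- step("classify",
                          classify_sample(collapsed, ref, config$classify,
                                          sample_id = sm))
    accounting[[sm]] <- as.list(trimmed$stats)
    write_calls(profiles[[i]], file.path(config$out_dir,
                                         paste0(sm, ".calls.tsv")))
  }

  comp <- composition_table(profiles, groups = sheet$group)
  write_tsv_out <- function(d, f) utils::write.table(
    d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_tsv_out(comp$per_sample, "composition_per_sample.tsv")
  write_tsv_out(comp$group_summary, "composition_group_summary.tsv")

  spectra <- do.call(rbind, lapply(profiles, function(p)
    as.data.frame(c(list(sample_id = p$sample_id),
                    as.list(nucvar_spectrum(p))), check.names = FALSE)))
  write_tsv_out(spectra, "nucvar_spectrum.tsv")

  urid <- lapply(profiles, uridylation_table, min_reads = config$min_reads)
  names(urid) <- sheet$sample
  urid_all <- do.call(rbind, lapply(seq_along(urid), function(i)
    data.frame(sample_id = sheet$sample[i], urid[[i]])))
  write_tsv_out(urid_all, "uridylation_per_mirna.tsv")
  arm <- arm_uridylation(profiles, ref, groups = sheet$group)
  write_tsv_out(arm, "arm_uridylation.tsv")

  diffres <- NULL; inter <- NULL
  has_both <- all(c("WT", "DKO") %in% sheet$group)
  if (has_both) {
    studies <- unique(sheet$study)
    diffres <- list()
    for (st in studies) {
      wt_i <- which(sheet$study == st & sheet$group == "WT")
      dko_i <- which(sheet$study == st & sheet$group == "DKO")
      if (length(wt_i) < 2 || length(dko_i) < 2) next
      diffres[[st]] <- diff_uridylation(urid[wt_i], urid[dko_i],
                                        fc_min = config$fc_min,
                                        alpha = config$alpha,
                                        min_reads = config$min_reads)
      write_tsv_out(diffres[[st]], paste0("diff_uridylation_", st, ".tsv"))
    }
    if (length(diffres) >= 2) {
      sets <- lapply(diffres, function(d) d$mirna_id[d$significant])
      inter <- randomization_z(sets, n_iter = config$n_iter,
                               seed = config$seed)
      jsonlite::write_json(
        inter[c("observed", "expected", "sd", "z", "oe_ratio", "n_iter",
                "seed", "degenerate")],
        file.path(config$out_dir, "intersection.json"), auto_unbox = TRUE,
        digits = NA)
      memb <- intersect_studies(sets)$membership
      utils::write.table(data.frame(mirna_id = rownames(memb), memb),
                         file.path(config$out_dir, "intersection_membership.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    message("diffurid stage skipped: sample sheet lacks a WT/DKO pair")
  }

  targets <- NULL
  if (!is.null(config$utr_fasta)) {
    utrs <- read_utr_fasta(config$utr_fasta)
    idx <- match(config$target_mirna, ref$entries$mirna_id)
    if (is.na(idx)) stop("stage tumr failed: unknown target_mirna ",
                         config$target_mirna)
    targets <- predict_targets(ref$entries$mature_seq[idx], utrs,
                               min_species = config$min_utr_species,
                               n_species = config$n_utr_species)
    write_tsv_out(targets$canonical, "targets_canonical_conservation.tsv")
    write_tsv_out(targets$tumr, "targets_tumr_conservation.tsv")
    jsonlite::write_json(targets$compare[c("n_unique_canonical",
                                           "n_unique_tumr", "n_overlap")],
                         file.path(config$out_dir, "targetome_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("isomirtools")),
    n_samples = nrow(sheet), groups = as.list(table(sheet$group)),
    seed = config$seed,
    params = list(fc_min = config$fc_min, alpha = config$alpha,
                  min_reads = config$min_reads, n_iter = config$n_iter,
                  classify = unclass(config$classify)),
    read_accounting = accounting)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(profiles = profiles, composition = comp,
                 uridylation = urid, arm_uridylation = arm,
                 diff_uridylation = diffres, intersection = inter,
                 targets = targets, manifest = manifest))
}
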