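#' Classification parameters
#'
#' Bundles the tunable limits of the hierarchical isomiR classifier.
#'
#' @param max_5p_shift maximum 5' end offset considered (trim or templated
#'   extension), in nucleotides.
#' @param max_3p_shift maximum 3' end offset (templated portion).
#' @param max_tail maximum non-templated 3' tail length.  Terminal
#'   nucleotidyl transferases add up to about three bases, hence the default.
#' @param max_internal_mismatch maximum internal substitutions tolerated
#'   within the templated span; 1 matches the single-mismatch definition of
#'   the NucVar class.
#' @param min_count minimum collapsed-read count for a read to be classified
#'   in [classify_sample()].
#' @param nta_on_shifted_3p if \code{TRUE} (default) a non-templated tail on
#'   a 3'-shifted (e.g. trimmed-then-uridylated) read is still called NTA;
#'   if \code{FALSE} such reads fall through to \code{mv}.
#' @return a list of class \code{ClassifyParams}.
#' @export
classify_params <- function(max_5p_shift = 5L, max_3p_shift = 5L,
                            max_tail = 3L, max_internal_mismatch = 1L,
                            min_count = 1L, nta_on_shifted_3p = TRUE) {
  stopifnot(max_5p_shift >= 0, max_3p_shift >= 0, max_tail >= 0,
            max_internal_mismatch >= 0, min_count >= 1)
  structure(list(max_5p_shift = as.integer(max_5p_shift),
                 max_3p_shift = as.integer(max_3p_shift),
                 max_tail = as.integer(max_tail),
                 max_internal_mismatch = as.integer(max_internal_mismatch),
                 min_count = as.integer(min_count),
                 nta_on_shifted_3p = isTRUE(nta_on_shifted_3p)),
            class = "ClassifyParams")
}

#' All isomiR class labels, in hierarchy order
#' @export
ISOMIR_CLASSES <- c("canonical", "NucVar", "NTA-A", "NTA-U", "NTA-C", "NTA-G",
                    "NTA-mixed", "lv5pT", "lv5pE", "lv3pT", "lv3pE", "mv",
                    "unassigned")

# class label for one valid candidate, per the hierarchical schema:
# (1) canonical; (2) NucVar; (3) NTA if the 5' end is canonical and a
# non-templated tail is present; (4) single-end templated length variants;
# (5) mv for everything else (both ends deviate, or 5' deviation plus tail).
assign_class <- function(shift5, shift3, tail, mm, nta_on_shifted_3p = TRUE) {
  if (mm > 0) return("NucVar")
  if (shift5 == 0 && shift3 == 0 && tail == "") return("canonical")
  if (nchar(tail) > 0 && shift5 == 0 && (shift3 == 0 || nta_on_shifted_3p)) {
    bases <- unique(strsplit(tail, "")[[1]])
    if (length(bases) == 1L)
      return(switch(bases, A = "NTA-A", T = "NTA-U", C = "NTA-C", G = "NTA-G"))
    return("NTA-mixed")
  }
  if (tail == "") {
    if (shift5 != 0 && shift3 == 0) return(if (shift5 < 0) "lv5pT" else "lv5pE")
    if (shift5 == 0 && shift3 != 0) return(if (shift3 < 0) "lv3pT" else "lv3pE")
  }
  "mv"
}

#' Classify a single read against a reference
#'
#' Aligns the read to every mature miRNA in the reference at all 5' offsets
#' within \code{params$max_5p_shift}, extends along the hairpin to find the
#' maximal templated 3' match, and treats any residual suffix (up to
#' \code{max_tail} bases) as a non-templated tail.  Trailing bases that match
#' the hairpin downstream of the mature end are always consumed as templated
#' extension before a tail is called, because non-templated additions are by
#' definition absent from the template.  Among the valid decompositions the
#' one with the fewest total edits (mismatches + |shift5| + |shift3| + tail
#' length) wins per miRNA; miRNAs tied at the global minimum are all reported
#' with fractional weight 1/k.
#'
#' @param insert_seq the read (insert) sequence, DNA or RNA alphabet.
#' @param ref a \code{ReferenceSet}.
#' @param params a \code{ClassifyParams}.
#' @return a data.frame with one row per assigned miRNA (or a single
#'   \code{unassigned} row): columns \code{mirna_id}, \code{klass},
#'   \code{shift5}, \code{shift3}, \code{tail}, \code{subst_pos} (1-based
#'   within the read), \code{subst_from}, \code{subst_to}, \code{edits},
#'   \code{weight}.  Weights of an assignable read sum to 1.
#' @export
classify_read <- function(insert_seq, ref, params = classify_params()) {
  stopifnot(inherits(ref, "ReferenceSet"))
  insert_seq <- toupper(chartr("Uu", "Tt", insert_seq))
  ent <- ref$entries
  cand <- classify_candidates_cpp(insert_seq,
                                  unname(ref$hairpins[ent$hairpin_id]),
                                  ent$start, ent$end,
                                  params$max_5p_shift, params$max_3p_shift,
                                  params$max_tail, params$max_internal_mismatch)
  unassigned <- data.frame(mirna_id = NA_character_, klass = "unassigned",
                           shift5 = NA_integer_, shift3 = NA_integer_,
                           tail = "", subst_pos = NA_integer_,
                           subst_from = "", subst_to = "",
                           edits = NA_integer_, weight = 1,
                           stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(unassigned)
  # best candidate per entry: fewest edits, ties broken deterministically
  o <- order(cand$entry, cand$edits, abs(cand$shift5), abs(cand$shift3),
             cand$tail_len)
  cand <- cand[o, ]
  best <- cand[!duplicated(cand$entry), ]
  keep <- best[best$edits == min(best$edits), ]
  keep$mirna_id <- ent$mirna_id[keep$entry]
  keep <- keep[order(keep$mirna_id), ]
  k <- nrow(keep)
  data.frame(mirna_id = keep$mirna_id,
             klass = vapply(seq_len(k), function(i)
               assign_class(keep$shift5[i], keep$shift3[i], keep$tail[i],
                            keep$mm[i], params$nta_on_shifted_3p),
               character(1)),
             shift5 = keep$shift5, shift3 = keep$shift3, tail = keep$tail,
             subst_pos = keep$subst_pos, subst_from = keep$subst_from,
             subst_to = keep$subst_to, edits = keep$edits,
             weight = rep(1 / k, k), stringsAsFactors = FALSE)
}

#' Classify a collapsed sample into a per-sample isomiR profile
#'
#' Runs [classify_read()] over a collection of collapsed reads and
#' accumulates weighted counts per (miRNA, variant) and per class.
#' Unassigned reads are tallied separately and excluded from the
#' miRNA-mapped total, which is the denominator of all class percentages.
#'
#' @param reads a data.frame of collapsed reads with columns \code{insert}
#'   and \code{count} (as produced by [collapse_reads()]), or a character
#'   vector of sequences (counts then taken as 1 each, with identical
#'   sequences pooled).
#' @param ref a \code{ReferenceSet}.
#' @param params a \code{ClassifyParams}.
#' @param sample_id identifier stored in the profile.
#' @return an object of class \code{SampleProfile}: a list with
#'   \item{sample_id}{identifier}
#'   \item{calls}{data.frame of per-read calls (read_seq, count, mirna_id,
#'     klass, shift5, shift3, tail, subst_pos/from/to, weight)}
#'   \item{class_totals}{named numeric of weighted counts per class}
#'   \item{mapped_total}{weighted miRNA-mapped total (unassigned excluded)}
#'   \item{unassigned_total}{count of unassigned reads}
#' @export
classify_sample <- function(reads, ref, params = classify_params(),
                            sample_id = "sample") {
  stopifnot(inherits(ref, "ReferenceSet"))
  if (nrow(ref$entries) == 0L) stop("empty reference")
  if (is.character(reads)) {
    tab <- table(reads)
    reads <- data.frame(insert = names(tab), count = as.numeric(tab),
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(reads) > 0, all(c("insert", "count") %in% names(reads)))
  reads <- reads[reads$count >= params$min_count, , drop = FALSE]
  calls <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    cl <- classify_read(reads$insert[i], ref, params)
    cl$read_seq <- reads$insert[i]
    cl$count <- reads$count[i]
    calls[[i]] <- cl
  }
  calls <- do.call(rbind, calls)
  calls$weighted_count <- calls$count * calls$weight
  mapped <- calls[calls$klass != "unassigned", , drop = FALSE]
  class_totals <- vapply(setdiff(ISOMIR_CLASSES, "unassigned"), function(k)
    sum(mapped$weighted_count[mapped$klass == k]), numeric(1))
  structure(list(sample_id = sample_id, calls = calls,
                 class_totals = class_totals,
                 mapped_total = sum(class_totals),
                 unassigned_total = sum(calls$count[calls$klass == "unassigned"])),
            class = "SampleProfile")
}

#' @export
print.SampleProfile <- function(x, ...) {
  cat("SampleProfile", shQuote(x$sample_id), "-", nrow(x$calls), "calls,",
      round(x$mapped_total, 1), "miRNA-mapped (",
      x$unassigned_total, "unassigned )\n")
  pct <- 100 * x$class_totals / x$mapped_total
  print(round(pct[pct > 0], 2))
  invisible(x)
}

#' Write per-sample isomiR calls to TSV
#'
#' @param profile a \code{SampleProfile}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_calls <- function(profile, path) {
  cols <- c("read_seq", "count", "mirna_id", "klass", "shift5", "shift3",
            "tail", "subst_pos", "subst_from", "subst_to", "weight")
  utils::write.table(profile$calls[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
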