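#' Library-protocol layout specification
#'
#' Describes the adapter/UMI layout of a small RNA library.  Fixed-adapter
#' protocols use \code{umi5_len = umi3_len = 0}; randomized-adapter (4N/5N)
#' protocols carry 4 or 5 random bases on each adapter which, after adapter
#' trimming, flank the insert and together form a unique molecular
#' identifier.
#'
#' @param adapter3 3' adapter sequence to locate and trim; \code{""} means
#'   the reads are already adapter-trimmed.
#' @param umi5_len,umi3_len number of random bases flanking the insert on
#'   each side (0-8).
#' @param min_insert,max_insert insert length bounds after trimming; reads
#'   outside are discarded.
#' @return a list of class \code{ProtocolSpec}.
#' @export
protocol_spec <- function(adapter3 = "AGATCGGAAGAGCACACGTCT",
                          umi5_len = 0L, umi3_len = 0L,
                          min_insert = 16L, max_insert = 28L) {
  stopifnot(umi5_len >= 0, umi5_len <= 8, umi3_len >= 0, umi3_len <= 8,
            min_insert <= max_insert)
  structure(list(adapter3 = toupper(adapter3),
                 umi5_len = as.integer(umi5_len),
                 umi3_len = as.integer(umi3_len),
                 min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert)),
            class = "ProtocolSpec")
}

#' Locate and trim the 3' adapter, strip UMIs
#'
#' For each read the 3' adapter is located by the longest-prefix rule: the
#' leftmost read position from which the read suffix matches a prefix of the
#' adapter with at most one mismatch and an overlap of at least 8 bases (or
#' the full remaining read, if shorter than 8 would end the read).  The
#' retained portion is then split into \code{umi5 | insert | umi3}; the two
#' UMIs are concatenated into \code{umi_key}.  Reads without an adapter hit,
#' or whose insert falls outside the protocol's length bounds, are discarded
#' and counted by reason.
#'
#' @param reads a FASTQ/FASTA path (gz-transparent) or a character vector of
#'   read sequences.
#' @param spec a [protocol_spec()].
#' @param min_overlap minimum adapter overlap (default 8).
#' @param max_mismatch maximum mismatches in the adapter match (default 1).
#' @return a list with \item{pairs}{data.frame (insert, umi_key) of kept
#'   reads} \item{stats}{named counts: total, kept, no_adapter, too_short,
#'   too_long}
#' @export
extract_and_trim <- function(reads, spec, min_overlap = 8L, max_mismatch = 1L) {
  stopifnot(inherits(spec, "ProtocolSpec"))
  if (length(reads) == 1L && file.exists(reads)) reads <- read_reads_file(reads)
  reads <- toupper(reads)
  n <- length(reads)
  if (nzchar(spec$adapter3)) {
    pos <- adapter_pos_cpp(reads, spec$adapter3, as.integer(min_overlap),
                           as.integer(max_mismatch))
    no_adapter <- is.na(pos)
    trimmed <- substr(reads, 1L, ifelse(no_adapter, 0L, pos - 1L))
  } else {
    no_adapter <- rep(FALSE, n)
    trimmed <- reads
  }
  ins_len <- nchar(trimmed) - spec$umi5_len - spec$umi3_len
  too_short <- !no_adapter & ins_len < spec$min_insert
  too_long <- !no_adapter & ins_len > spec$max_insert
  keep <- !(no_adapter | too_short | too_long)
  inserts <- substr(trimmed[keep], spec$umi5_len + 1L,
                    spec$umi5_len + ins_len[keep])
  umis <- paste0(substr(trimmed[keep], 1L, spec$umi5_len),
                 substr(trimmed[keep], spec$umi5_len + ins_len[keep] + 1L,
                        nchar(trimmed[keep])))
  list(pairs = data.frame(insert = inserts, umi_key = umis,
                          stringsAsFactors = FALSE),
       stats = c(total = n, kept = sum(keep), no_adapter = sum(no_adapter),
                 too_short = sum(too_short), too_long = sum(too_long)))
}

# leftmost position j such that read[j..] matches adapter[1..overlap] with
# <= max_mismatch mismatches and overlap >= min_overlap (a read suffix
# shorter than min_overlap never qualifies); NA if no hit
find_adapter <- function(read, adapter, min_overlap = 8L, max_mismatch = 1L) {
  n <- nchar(read); a <- nchar(adapter)
  rv <- strsplit(read, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  last <- n - min_overlap + 1L
  if (last < 1L) return(NA_integer_)
  for (j in seq_len(last)) {
    overlap <- min(n - j + 1L, a)
    if (sum(rv[j:(j + overlap - 1L)] != av[1:overlap]) <= max_mismatch)
      return(j)
  }
  NA_integer_
}

#' Collapse (insert, UMI) pairs into unique reads with counts
#'
#' With \code{dedup = TRUE}, identical (insert, UMI) pairs are counted once,
#' so the count per insert is the number of distinct UMI pairs -- an estimate
#' of pre-amplification molecule numbers.  With \code{dedup = FALSE}, raw
#' read counts per insert are reported.  \code{umi_distinct} always carries
#' the distinct-UMI count.
#'
#' @param pairs data.frame with columns \code{insert}, \code{umi_key} (from
#'   [extract_and_trim()]).
#' @param dedup collapse PCR duplicates by UMI?
#' @return a data.frame (insert, count, umi_distinct) sorted by decreasing
#'   count then insert.
#' @export
collapse_reads <- function(pairs, dedup = TRUE) {
  stopifnot(all(c("insert", "umi_key") %in% names(pairs)))
  dt <- data.table::as.data.table(pairs)
  agg <- dt[, list(raw = .N,
                   umi_distinct = data.table::uniqueN(umi_key)),
            by = "insert"]
  agg[, "count" := if (dedup) agg$umi_distinct else agg$raw]
  out <- as.data.frame(agg[order(-count, insert),
                           c("insert", "count", "umi_distinct"), with = FALSE])
  out
}

#' Write collapsed reads as FASTA plus TSV
#'
#' FASTA headers follow the \code{seq{i}-{count}} convention used by
#' collapsed-read small RNA tools.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param fasta_path,tsv_path output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_collapsed <- function(collapsed, fasta_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(fasta_path)) {
    ids <- sprintf("seq%d-%d", seq_len(nrow(collapsed)), collapsed$count)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(collapsed$insert, ids)), fasta_path)
    written <- c(written, fasta_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(collapsed, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

# reads a FASTQ or FASTA file into a character vector of sequences
read_reads_file <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- tryCatch(Biostrings::readBStringSet(path, format = fmt),
                error = function(e) stop("malformed ", fmt, " file ", path,
                                         ": ", conditionMessage(e)))
  as.character(x)
}
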