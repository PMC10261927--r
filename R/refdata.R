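#' Load a mature/hairpin miRNA reference
#'
#' Reads a miRBase-style pair of FASTA files (mature miRNAs and hairpin
#' precursors), locates every mature sequence inside its hairpin and returns a
#' validated reference set.  All sequences are stored in DNA space (U is
#' converted to T); coordinates are 0-based half-open.
#'
#' Matures are matched to hairpins by exact substring search.  Hairpins whose
#' identifier shares a stem with the mature identifier (the mature id minus a
#' trailing \code{-5p}/\code{-3p}) are searched first; if the mature is not
#' found there, all hairpins are searched.  Alternatively an explicit
#' coordinates table (columns \code{mirna_id}, \code{hairpin_id},
#' \code{start}, \code{end}) can be supplied and is then taken as
#' authoritative.  If a mature occurs at several positions within a hairpin
#' the leftmost occurrence is used and a warning is emitted.
#'
#' The arm (5p/3p) is taken from an id suffix \code{-5p}/\code{-3p} when
#' present, otherwise inferred from the position of the mature midpoint
#' relative to the hairpin midpoint.
#'
#' @param mature_fasta path to the mature miRNA FASTA file.
#' @param hairpin_fasta path to the hairpin FASTA file.
#' @param coords optional data.frame with columns \code{mirna_id},
#'   \code{hairpin_id}, \code{start}, \code{end} (0-based half-open) that
#'   overrides substring search.
#' @return an object of class \code{ReferenceSet}: a list with
#'   \item{entries}{data.frame with columns \code{mirna_id},
#'     \code{mature_seq}, \code{hairpin_id}, \code{start}, \code{end},
#'     \code{arm}} \item{hairpins}{named character vector of hairpin
#'     sequences} \item{n_dropped}{number of matures that could not be located
#'     in any hairpin (these are reported via a warning and dropped)}
#' @export
load_reference <- function(mature_fasta, hairpin_fasta, coords = NULL) {
  mat <- read_fasta_dna(mature_fasta)
  hp  <- read_fasta_dna(hairpin_fasta)
  if (length(mat) == 0L) stop("empty mature reference: ", mature_fasta)
  if (length(hp) == 0L) stop("empty hairpin reference: ", hairpin_fasta)
  if (anyDuplicated(names(mat)))
    stop("duplicate mirna_id in mature FASTA: ",
         paste(unique(names(mat)[duplicated(names(mat))]), collapse = ", "))
  if (anyDuplicated(names(hp)))
    stop("duplicate hairpin_id in hairpin FASTA")
  build_reference(mat, hp, coords = coords)
}

#' Build a ReferenceSet from in-memory sequences
#'
#' Workhorse behind [load_reference()]; also used by the synthetic generator
#' and by tests to construct references without touching the file system.
#'
#' @param matures named character vector of mature sequences (DNA or RNA
#'   alphabet; U is converted to T).
#' @param hairpins named character vector of hairpin sequences.
#' @inheritParams load_reference
#' @return a \code{ReferenceSet}; see [load_reference()].
#' @export
build_reference <- function(matures, hairpins, coords = NULL) {
  matures  <- toupper(chartr("Uu", "Tt", matures))
  hairpins <- toupper(chartr("Uu", "Tt", hairpins))
  ids <- names(matures)
  if (is.null(ids) || any(!nzchar(ids))) stop("mature sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate mirna_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))

  rows <- vector("list", length(ids))
  dropped <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]; seq <- matures[[i]]
    if (!is.null(coords) && id %in% coords$mirna_id) {
      cr <- coords[match(id, coords$mirna_id), ]
      hpid <- as.character(cr$hairpin_id)
      if (!hpid %in% names(hairpins)) stop("coordinates refer to unknown hairpin: ", hpid)
      st <- as.integer(cr$start); en <- as.integer(cr$end)
      if (substr(hairpins[[hpid]], st + 1L, en) != seq)
        stop("coordinates table disagrees with sequences for ", id)
      rows[[i]] <- data.frame(mirna_id = id, mature_seq = seq, hairpin_id = hpid,
                              start = st, end = en, stringsAsFactors = FALSE)
      next
    }
    hit <- locate_mature(id, seq, hairpins)
    if (is.null(hit)) { dropped <- c(dropped, id); next }
    rows[[i]] <- hit
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning(length(dropped), " mature sequence(s) not found in any hairpin and dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(rows)) stop("no mature sequence could be located in a hairpin")
  entries <- do.call(rbind, rows)
  entries$arm <- infer_arm(entries$mirna_id, entries$start, entries$end,
                           nchar(hairpins[entries$hairpin_id]))
  rownames(entries) <- NULL
  structure(list(entries = entries, hairpins = hairpins,
                 n_dropped = length(dropped)),
            class = "ReferenceSet")
}

# leftmost exact occurrence; hairpins sharing the id stem are preferred
locate_mature <- function(id, seq, hairpins) {
  stem <- sub("-[35]p$", "", id)
  pref <- names(hairpins)[startsWith(names(hairpins), stem) |
                          startsWith(stem, names(hairpins))]
  for (cand in unique(c(pref, names(hairpins)))) {
    hits <- gregexpr(seq, hairpins[[cand]], fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    if (length(hits) > 1L)
      warning("mature ", id, " occurs ", length(hits), " times in hairpin ",
              cand, "; using leftmost occurrence")
    st <- hits[1] - 1L
    return(data.frame(mirna_id = id, mature_seq = seq, hairpin_id = cand,
                      start = st, end = st + nchar(seq), stringsAsFactors = FALSE))
  }
  NULL
}

infer_arm <- function(ids, start, end, hairpin_len) {
  arm <- ifelse(grepl("-5p$", ids), "5p", ifelse(grepl("-3p$", ids), "3p", NA))
  mid <- (start + end) / 2
  arm[is.na(arm)] <- ifelse(mid[is.na(arm)] < hairpin_len[is.na(arm)] / 2, "5p", "3p")
  arm
}

#' Templated hairpin sequence downstream of a mature miRNA
#'
#' Returns up to \code{n} hairpin nucleotides immediately 3' of the mature
#' end -- the template against which candidate 3' extensions are checked when
#' deciding whether a trailing read base is templated or a non-templated
#' addition.  Near the hairpin boundary fewer than \code{n} bases may be
#' available.
#'
#' @param ref a \code{ReferenceSet}.
#' @param mirna_id mature miRNA identifier.
#' @param n maximum number of downstream bases (>= 0).
#' @return a character string of length between 0 and \code{n}.
#' @export
downstream_template <- function(ref, mirna_id, n) {
  stopifnot(inherits(ref, "ReferenceSet"), n >= 0)
  i <- match(mirna_id, ref$entries$mirna_id)
  if (is.na(i)) stop("unknown mirna_id: ", mirna_id)
  e <- ref$entries[i, ]
  hp <- ref$hairpins[[e$hairpin_id]]
  if (n == 0 || e$end >= nchar(hp)) return("")
  substr(hp, e$end + 1L, min(e$end + n, nchar(hp)))
}

#' Write a ReferenceSet back to FASTA
#'
#' Writes the mature and hairpin sequences of a reference to two FASTA files,
#' such that [load_reference()] on the result reproduces identical entries.
#'
#' @param ref a \code{ReferenceSet}.
#' @param mature_fasta,hairpin_fasta output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, mature_fasta, hairpin_fasta) {
  stopifnot(inherits(ref, "ReferenceSet"))
  mat <- Biostrings::DNAStringSet(stats::setNames(ref$entries$mature_seq,
                                                  ref$entries$mirna_id))
  hp <- Biostrings::DNAStringSet(ref$hairpins)
  Biostrings::writeXStringSet(mat, mature_fasta)
  Biostrings::writeXStringSet(hp, hairpin_fasta)
  invisible(c(mature_fasta, hairpin_fasta))
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", nrow(x$entries), "mature miRNAs in",
      length(x$hairpins), "hairpins\n")
  cat("  arms:", sum(x$entries$arm == "5p"), "5p /",
      sum(x$entries$arm == "3p"), "3p\n")
  if (x$n_dropped > 0) cat("  dropped at load:", x$n_dropped, "\n")
  invisible(x)
}

read_fasta_dna <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  x <- Biostrings::readBStringSet(path)
  out <- toupper(chartr("Uu", "Tt", as.character(x)))
  # headers may carry descriptions after the id
  names(out) <- vapply(strsplit(names(x), "[ \t]"), `[`, character(1), 1L)
  out
}
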