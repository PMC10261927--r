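#' Canonical seed target sites (8mer, 7mer-m8, 7mer-A1)
#'
#' Scans a 3'-UTR for the three standard seed-match site types of a miRNA.
#' The seed is miRNA positions 2-8 (1-based, 5' to 3').  On the UTR
#' (5' to 3'): a 7mer-m8 site is the reverse complement of positions 2-8;
#' a 7mer-A1 site is the reverse complement of positions 2-7 followed by an
#' A (opposite miRNA position 1, regardless of the miRNA base there); an
#' 8mer site is both at once.  Each UTR locus is reported once with its
#' strongest type.  Coordinates are 0-based half-open.
#'
#' @param mirna_seq mature miRNA sequence (DNA or RNA alphabet), length >= 8.
#' @param utr_seq 3'-UTR sequence.
#' @param utr_id,species_id identifiers copied into the output.
#' @return data.frame: utr_id, species_id, start, end, site_type, wobbles
#'   (always 0 for seed sites).
#' @export
seed_sites <- function(mirna_seq, utr_seq, utr_id = "utr", species_id = "sp") {
  mirna_seq <- dna(mirna_seq); utr_seq <- dna(utr_seq)
  stopifnot(nchar(mirna_seq) >= 8)
  s78 <- revcomp(substr(mirna_seq, 2, 8))   # 7 nt, complement of m8 first
  s67 <- revcomp(substr(mirna_seq, 2, 7))   # 6 nt
  n <- nchar(utr_seq)
  sites <- list()
  for (i in find_all(s78, utr_seq)) {       # 1-based starts
    has_a1 <- i + 7 <= n && substr(utr_seq, i + 7, i + 7) == "A"
    sites[[length(sites) + 1]] <- data.frame(
      start = i - 1L, end = i - 1L + (if (has_a1) 8L else 7L),
      site_type = if (has_a1) "8mer" else "7mer-m8")
  }
  for (j in find_all(s67, utr_seq)) {
    if (j + 6 > n || substr(utr_seq, j + 6, j + 6) != "A") next
    # exclude loci already covered by an m8 match one base upstream
    if (j > 1 && substr(utr_seq, j - 1, j - 1) == substr(s78, 1, 1)) next
    sites[[length(sites) + 1]] <- data.frame(start = j - 1L, end = j + 6L,
                                             site_type = "7mer-A1")
  }
  if (!length(sites))
    return(data.frame(utr_id = character(0), species_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), wobbles = integer(0)))
  out <- do.call(rbind, sites)
  out <- data.frame(utr_id = utr_id, species_id = species_id, out,
                    wobbles = 0L, stringsAsFactors = FALSE)
  out[order(out$start), ]
}

#' Tail-U (TUMR) target sites with bounded G:U wobble pairing
#'
#' The query is the 3'-terminal \code{window_len} bases of the
#' mono-uridylated miRNA (mature sequence plus one U).  A UTR window of the
#' same length is a site when every antiparallel base pair is either
#' Watson-Crick or a G:U wobble (query G opposite site T, or query T
#' opposite site G), with at most \code{max_wobbles} wobbles.  With
#' \code{max_wobbles = 0} this reduces to an exact reverse-complement
#' search.
#'
#' @param mature_seq mature miRNA sequence (the U tail is appended
#'   internally).
#' @param utr_seq 3'-UTR sequence.
#' @param max_wobbles maximum number of G:U pairs per site (default 3).
#' @param window_len length of the 3'-terminal pairing window (default 8).
#' @param utr_id,species_id identifiers copied into the output.
#' @return data.frame: utr_id, species_id, start, end (0-based half-open),
#'   site_type = "TUMR", wobbles.
#' @export
tumr_sites <- function(mature_seq, utr_seq, max_wobbles = 3L,
                       window_len = 8L, utr_id = "utr", species_id = "sp") {
  mature_seq <- dna(mature_seq); utr_seq <- dna(utr_seq)
  uridylated <- paste0(mature_seq, "T")
  stopifnot(window_len <= nchar(uridylated), window_len >= 1)
  query <- substr(uridylated, nchar(uridylated) - window_len + 1,
                  nchar(uridylated))
  qv <- strsplit(query, "")[[1]]
  uv <- strsplit(utr_seq, "")[[1]]
  n <- length(uv)
  rows <- list()
  if (n >= window_len) for (i in seq_len(n - window_len + 1)) {
    w <- 0L; ok <- TRUE
    for (k in seq_len(window_len)) {
      qb <- qv[k]; sb <- uv[i + window_len - k]   # antiparallel partner
      if (is_wc(qb, sb)) next
      if (is_wobble(qb, sb)) { w <- w + 1L; if (w > max_wobbles) { ok <- FALSE; break } }
      else { ok <- FALSE; break }
    }
    if (ok) rows[[length(rows) + 1]] <- data.frame(start = i - 1L,
                                                   end = i - 1L + window_len,
                                                   wobbles = w)
  }
  if (!length(rows))
    return(data.frame(utr_id = character(0), species_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), wobbles = integer(0)))
  out <- do.call(rbind, rows)
  data.frame(utr_id = utr_id, species_id = species_id,
             start = out$start, end = out$end, site_type = "TUMR",
             wobbles = out$wobbles, stringsAsFactors = FALSE)
}

is_wc <- function(q, s) (q == "A" && s == "T") || (q == "T" && s == "A") ||
                        (q == "C" && s == "G") || (q == "G" && s == "C")
# G:U wobble in DNA space: query G pairs site T (site U), query T (query U)
# pairs site G
is_wobble <- function(q, s) (q == "G" && s == "T") || (q == "T" && s == "G")

#' Multi-species conservation filter for target sites
#'
#' A target UTR (gene) is retained when a qualifying site exists in at
#' least \code{min_species} of the \code{n_species} species analysed.
#'
#' @param sites_by_species named list (one element per species) of site
#'   data.frames as returned by [seed_sites()]/[tumr_sites()]; orthology is
#'   taken from shared \code{utr_id} values across species.
#' @param min_species minimum number of species with a site (default 15).
#' @param n_species declared number of species (default 23); the input must
#'   have exactly this many elements.
#' @return data.frame: utr_id, conserved_in, kept -- one row per gene seen
#'   in any species, ordered by decreasing conservation.
#' @export
conservation_filter <- function(sites_by_species, min_species = 15L,
                                n_species = 23L) {
  if (min_species > n_species) stop("min_species exceeds n_species")
  if (length(sites_by_species) != n_species)
    stop("expected sites for ", n_species, " species, got ",
         length(sites_by_species))
  per_species_genes <- lapply(sites_by_species, function(d) unique(d$utr_id))
  genes <- sort(unique(unlist(per_species_genes)))
  conserved_in <- vapply(genes, function(g)
    sum(vapply(per_species_genes, function(s) g %in% s, logical(1))),
    integer(1))
  out <- data.frame(utr_id = genes, conserved_in = conserved_in,
                    kept = conserved_in >= min_species, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$conserved_in, out$utr_id), ]
}

#' Compare canonical and TUMR targetomes
#'
#' @param canonical_targets,tumr_targets character vectors of gene ids.
#' @return a list with the three parts of the set partition and their sizes:
#'   unique_canonical, unique_tumr, overlap, n_unique_canonical,
#'   n_unique_tumr, n_overlap.
#' @export
targetome_compare <- function(canonical_targets, tumr_targets) {
  canonical_targets <- unique(canonical_targets)
  tumr_targets <- unique(tumr_targets)
  ov <- intersect(canonical_targets, tumr_targets)
  uc <- setdiff(canonical_targets, tumr_targets)
  ut <- setdiff(tumr_targets, canonical_targets)
  list(unique_canonical = sort(uc), unique_tumr = sort(ut),
       overlap = sort(ov), n_unique_canonical = length(uc),
       n_unique_tumr = length(ut), n_overlap = length(ov))
}

#' Read a multi-species 3'-UTR FASTA
#'
#' Headers are expected as \code{gene|species}; orthologous UTRs share the
#' gene identifier across species.
#'
#' @param path FASTA path.
#' @return data.frame: utr_id (gene), species_id, seq.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- vapply(strsplit(names(x), "[ \t]"), `[`, character(1), 1L)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 2))
    stop("UTR FASTA headers must look like 'gene|species'")
  data.frame(utr_id = vapply(parts, `[`, character(1), 1L),
             species_id = vapply(parts, `[`, character(1), 2L),
             seq = toupper(chartr("Uu", "Tt", as.character(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full target search for one miRNA over a multi-species UTR set
#'
#' Runs [seed_sites()] (canonical) and [tumr_sites()] (tail-U) over every
#' UTR, applies the conservation filter to each targetome, and reports the
#' conserved gene lists and their overlap.
#'
#' @param mature_seq mature miRNA sequence.
#' @param utrs data.frame from [read_utr_fasta()].
#' @param min_species,n_species conservation thresholds.
#' @param max_wobbles,window_len TUMR scan parameters.
#' @return a list: canonical (conservation table), tumr (conservation
#'   table), compare (from [targetome_compare()] on the kept genes).
#' @export
predict_targets <- function(mature_seq, utrs, min_species = 15L,
                            n_species = 23L, max_wobbles = 3L,
                            window_len = 8L) {
  species <- sort(unique(utrs$species_id))
  if (length(species) != n_species)
    stop("UTR set contains ", length(species), " species, expected ", n_species)
  by_sp <- function(scan) {
    stats::setNames(lapply(species, function(sp) {
      sub <- utrs[utrs$species_id == sp, , drop = FALSE]
      hits <- lapply(seq_len(nrow(sub)), function(i)
        scan(sub$seq[i], sub$utr_id[i], sp))
      do.call(rbind, hits)
    }), species)
  }
  can <- by_sp(function(s, g, sp) seed_sites(mature_seq, s, g, sp))
  tum <- by_sp(function(s, g, sp)
    tumr_sites(mature_seq, s, max_wobbles, window_len, g, sp))
  can_f <- conservation_filter(can, min_species, n_species)
  tum_f <- conservation_filter(tum, min_species, n_species)
  list(canonical = can_f, tumr = tum_f,
       compare = targetome_compare(can_f$utr_id[can_f$kept],
                                   tum_f$utr_id[tum_f$kept]))
}

dna <- function(x) toupper(chartr("Uu", "Tt", x))
revcomp <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))
find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}
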