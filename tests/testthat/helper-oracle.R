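# Independent brute-force oracles used to validate the fast implementations.
# These are written against the documented decomposition rules directly,
# with plain substring operations, and share no code with the package
# internals they check.

# Enumerate every (entry, shift5, tail-length) decomposition of a read and
# return the same call table classify_read() would produce.
oracle_classify <- function(read, ref, params = classify_params()) {
  ent <- ref$entries
  cands <- list()
  for (e in seq_len(nrow(ent))) {
    H <- ref$hairpins[[ent$hairpin_id[e]]]
    hv <- strsplit(H, "")[[1]]
    rv <- strsplit(read, "")[[1]]
    n <- length(rv); st <- ent$start[e]; en <- ent$end[e]
    for (shift5 in -params$max_5p_shift:params$max_5p_shift) {
      p <- st - shift5                      # 0-based read start on hairpin
      if (p < 0 || p >= length(hv)) next
      for (t in 0:min(params$max_tail, n - 1)) {
        span <- n - t
        if (p + span > length(hv)) next
        # tails must be maximal: templated explanations win
        if (t > 0 && p + span < length(hv) && rv[span + 1] == hv[p + span + 1]) next
        shift3 <- (p + span) - en
        if (abs(shift3) > params$max_3p_shift) next
        mism <- which(rv[1:span] != hv[(p + 1):(p + span)])
        if (length(mism) > params$max_internal_mismatch) next
        if (length(mism) > 0) {
          if (shift5 != 0 || shift3 != 0 || t != 0) next
          if (any(mism == 1) || any(mism == n)) next
        }
        cands[[length(cands) + 1]] <- data.frame(
          entry = e, shift5 = shift5, shift3 = shift3,
          tail = paste(rv[seq_len(t) + span], collapse = ""), tail_len = t,
          mm = length(mism),
          subst_pos = if (length(mism)) mism else NA_integer_,
          subst_from = if (length(mism)) hv[p + mism] else "",
          subst_to = if (length(mism)) rv[mism] else "",
          edits = length(mism) + abs(shift5) + abs(shift3) + t,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands))
    return(data.frame(mirna_id = NA_character_, klass = "unassigned",
                      shift5 = NA_integer_, shift3 = NA_integer_, tail = "",
                      weight = 1, stringsAsFactors = FALSE))
  cand <- do.call(rbind, cands)
  cand <- cand[order(cand$entry, cand$edits, abs(cand$shift5),
                     abs(cand$shift3), cand$tail_len), ]
  best <- cand[!duplicated(cand$entry), ]
  keep <- best[best$edits == min(best$edits), ]
  keep$mirna_id <- ent$mirna_id[keep$entry]
  keep <- keep[order(keep$mirna_id), ]
  keep$klass <- mapply(oracle_class, keep$shift5, keep$shift3, keep$tail,
                       keep$mm, MoreArgs = list(nta3 = params$nta_on_shifted_3p))
  keep$weight <- 1 / nrow(keep)
  rownames(keep) <- NULL
  keep
}

# hierarchical labels, restated independently
oracle_class <- function(s5, s3, tail, mm, nta3 = TRUE) {
  if (mm > 0) return("NucVar")
  if (s5 == 0 && s3 == 0 && tail == "") return("canonical")
  if (tail != "" && s5 == 0 && (s3 == 0 || nta3)) {
    u <- unique(strsplit(tail, "")[[1]])
    if (length(u) > 1) return("NTA-mixed")
    return(c(A = "NTA-A", T = "NTA-U", C = "NTA-C", G = "NTA-G")[[u]])
  }
  if (tail == "" && s5 != 0 && s3 == 0) return(if (s5 < 0) "lv5pT" else "lv5pE")
  if (tail == "" && s5 == 0 && s3 != 0) return(if (s3 < 0) "lv3pT" else "lv3pE")
  "mv"
}

# naive exact reverse-complement scan, the max_wobbles = 0 oracle
oracle_revcomp_scan <- function(query, utr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(query, "")[[1]]]), collapse = "")
  hits <- gregexpr(rc, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L   # 0-based
}

# verify one reported pairing window base by base
oracle_verify_site <- function(query, utr, start, end, max_wobbles) {
  qv <- strsplit(query, "")[[1]]
  wv <- strsplit(substr(utr, start + 1, end), "")[[1]]
  if (length(qv) != length(wv)) return(FALSE)
  w <- 0
  for (k in seq_along(qv)) {
    sb <- wv[length(wv) - k + 1]
    pair <- paste0(qv[k], sb)
    if (pair %in% c("AT", "TA", "CG", "GC")) next
    if (pair %in% c("GT", "TG")) { w <- w + 1; next }
    return(FALSE)
  }
  w <= max_wobbles
}

# Benjamini-Hochberg step-up, restated from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n); out[o] <- q
  out
}

# random read/reference instance generator for the equivalence sweep
random_instance <- function(seed) {
  set.seed(seed)
  cfg <- sim_config(n_mirnas = sample(1:3, 1), hairpin_len = sample(56:60, 1),
                    seed = seed)
  ref <- generate_reference(cfg)
  ent <- ref$entries[sample.int(nrow(ref$entries), 1), ]
  m <- ent$mature_seq
  kind <- sample(c("canonical", "perturb", "random"), 1,
                 prob = c(0.2, 0.6, 0.2))
  read <- switch(kind,
    canonical = m,
    random = paste(sample(c("A", "C", "G", "T"), sample(16:28, 1), TRUE),
                   collapse = ""),
    perturb = {
      x <- m
      for (op in sample(c("trim5", "trim3", "ext", "tail", "sub"),
                        sample(1:2, 1))) {
        L <- nchar(x)
        x <- switch(op,
          trim5 = substr(x, sample(1:3, 1) + 1, L),
          trim3 = substr(x, 1, L - sample(1:3, 1)),
          ext = paste0(x, substr(downstream_template(ref, ent$mirna_id, 3),
                                 1, sample(1:2, 1))),
          tail = paste0(x, strrep(sample(c("A", "C", "G", "T"), 1),
                                  sample(1:3, 1))),
          sub = {
            p <- sample(seq_len(L), 1)
            v <- strsplit(x, "")[[1]]
            v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
            paste(v, collapse = "")
          })
      }
      x
    })
  list(ref = ref, read = read)
}
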