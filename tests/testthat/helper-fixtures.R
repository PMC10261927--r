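# Tiny references and samples built in code, shared across test files.

toy_ref <- function() {
  build_reference(c("toy-mir" = "TGAGG"), c("toy-hp" = "CCTGAGGAAG"))
}

# two hairpins, four arms, C/G downstream context; big enough for
# realistic classification but small enough to read by eye
small_ref <- function(seed = 11) {
  generate_reference(sim_config(n_mirnas = 4L, seed = seed))
}

# a profile built from explicit (sequence, count) pairs
profile_from_counts <- function(seqs, counts, ref, sample_id = "s1",
                                params = classify_params()) {
  classify_sample(data.frame(insert = seqs, count = counts,
                             stringsAsFactors = FALSE),
                  ref, params, sample_id = sample_id)
}

# uridylation tables with prescribed per-miRNA NTA-U percentages; counts
# large so nothing is filtered
fake_urid_table <- function(pcts, total = 100) {
  data.frame(mirna_id = names(pcts), pct_NTA_U = as.numeric(pcts),
             pct_NTA_A = 0, pct_NTA_C = 0, pct_NTA_G = 0,
             total_count = total, low_coverage = FALSE,
             stringsAsFactors = FALSE)
}
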