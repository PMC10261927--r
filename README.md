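# isomirtools

Small RNA sequencing reads rarely match their annotated mature miRNA
exactly: ends shift, internal bases vary, and terminal nucleotidyl
transferases (notably TUT4/7) append non-templated uridines or adenines.
Distinguishing these biological isomiRs from library-preparation and
synthesis artifacts is essential before drawing conclusions about miRNA
modification or targeting. `isomirtools` provides, for analysts of bulk or
single-cell small RNA-seq data:

- a **template-aware hierarchical isomiR classifier**: every read is
  decomposed against each mature miRNA and its hairpin; 3' bases matching
  the hairpin downstream of the mature end are consumed as *templated*
  extension before any non-templated addition (NTA) is called, and the
  minimal-edit decomposition assigns exactly one class per read:
  `canonical` → `NucVar` (one internal substitution, canonical ends) →
  `NTA-A/U/C/G/mixed` (non-templated 3' tail, canonical 5' end) →
  `lv5pT/lv5pE/lv3pT/lv3pE` (single-end trimmed/templated-extended length
  variants) → `mv` (both ends deviate);
- **adapter and UMI handling** for fixed- and randomized-adapter (4N/5N)
  library layouts, with UMI-based PCR-duplicate collapsing;
- **profiling**: per-sample class composition, the 12-class internal
  substitution (NucVar) spectrum, per-miRNA and per-arm (5p/3p)
  uridylation percentages, Welch *t* group comparisons with
  Benjamini-Hochberg correction, and a coefficient-of-variation metric for
  equimolar spike-in capture equality;
- **differential uridylation** between wild-type and TUT4/7 double-knockout
  samples (per-miRNA *t*-test, BH correction, fold-change filter, default
  ≥ 1.5x) and a **cross-study randomization test**: the observed
  intersection of significant miRNA sets across studies is compared with
  draws of the same set sizes from the miRNA universe, giving
  *Z* = (observed − E)/sd and an O/E ratio, where the closed form
  E = N·Π(sᵢ/N) serves as an analytic check;
- **tail-U target prediction (TUMR)**: canonical seed sites (8mer,
  7mer-m8, 7mer-A1) and tail-U sites in which the 3'-terminal window of the
  mono-uridylated miRNA pairs a 3'-UTR window allowing up to 3 G:U wobbles,
  with a ≥ 15-of-23-species conservation filter and targetome overlap
  reporting;
- a fully **seeded synthetic-data generator** that emulates both an
  isomiR-free synthetic miRNA pool (oligosynthesis substitutions only) and
  cell-like samples (NTA tails, editing-enriched T>C / A>G substitutions,
  abundant 3' length variants), plus ligation bias, PCR duplication and 5N
  UMIs — with exact per-read ground truth, so every stage of the pipeline
  is testable without external data.

## Worked example

Simulate a cell-like 5N library, trim/collapse it, classify, and profile:

```r
library(isomirtools)

cfg <- sim_config(n_mirnas = 10, depth = 20000, seed = 42)
ref <- generate_reference(cfg)
ref
#> ReferenceSet: 10 mature miRNAs in 5 hairpins
#>   arms: 5 5p / 5 3p

sim <- simulate_sample(ref, cfg, "cells")
spec <- protocol_spec(cfg$adapter3, cfg$umi5_len, cfg$umi3_len)
collapsed <- collapse_reads(extract_and_trim(sim$reads, spec)$pairs, dedup = TRUE)
prof <- classify_sample(collapsed, ref, sample_id = "cells_wt_1")
prof
#> SampleProfile 'cells_wt_1' - 435 calls, 19995 miRNA-mapped ( 0 unassigned )
#> canonical    NucVar     NTA-A     NTA-U     lv3pT     lv3pE
#>     45.42      4.68      9.82     10.04     24.96      5.08
```

The recovered composition sits within sampling error of the generator's
class probabilities (45% canonical, 25% lv3pT, 10% NTA-U, 10% NTA-A, 5%
NucVar, 5% lv3pE). Uridylation is strongly 3p-arm biased, as configured:

```r
arm_uridylation(list(prof), ref)
#>   group arm mean_pct_NTA_U sd_pct n_samples
#> 1   all  3p          17.18      0         1
#> 2   all  5p           3.46      0         1
```

A cross-study intersection with its randomization null:

```r
sets <- list(study1 = sprintf("mir%02d", 1:25),
             study2 = sprintf("mir%02d", c(1:20, 30:39)),
             study3 = sprintf("mir%02d", c(1:18, 40:52)))
randomization_z(sets, n_iter = 1000, seed = 1)
#> Cross-study intersection: observed 18 | expected 10.15 +/- 1.902
#>   Z = 4.125  O/E = 1.773  ( 1000 randomizations, seed 1 )
```

End-to-end runs (trim → classify → profile → differential uridylation →
intersection → target prediction) are driven by `run_config()` /
`run_pipeline()`, or from a shell via the wrapper in
`inst/scripts/run_pipeline.R`; outputs are TSV/JSON report tables plus a
run manifest.

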