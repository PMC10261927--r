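---
title: "Template-aware isomiR classification and uridylation analysis"
author: "isomirtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-aware isomiR classification and uridylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirtools)
```

## The problem

Mature miRNAs observed by small RNA sequencing deviate from their
annotated (canonical) sequences in reproducible ways: shifted 5' or 3'
ends from variable Drosha/Dicer cleavage or exonucleolytic trimming,
internal single-nucleotide changes from RNA editing (ADAR-type A>G,
APOBEC-type T>C in cDNA space), and non-templated 3' additions (NTAs) laid
down by terminal nucleotidyl transferases — chiefly uridylation by TUT4/7
and adenylation. Library preparation adds its own artifacts: ligation bias
from fixed-sequence adapters, PCR duplication, and apparent variants from
synthesis errors in reference oligo pools. This package classifies reads
into isomiR classes in a way that separates these signals, quantifies
uridylation and its loss in TUT4/7 double-knockout (DKO) cells, and
propagates the added uridine into target-site prediction.

## The classification model

Each read is aligned against every mature miRNA in the reference. A
*decomposition* places the read's 5' end at hairpin position
`start − shift5` and splits the read into a *templated span*, matched
base-by-base against the hairpin, followed by a *tail* of up to
`max_tail` (default 3) trailing bases. The decomposition is valid when:

- `|shift5| ≤ 5` and `|shift3| ≤ 5` (defaults), where
  `shift3 = (alignment end) − (mature end)`; negative shifts are trims,
  positive shifts templated extensions;
- the tail is *maximal*: its first base differs from the hairpin base at
  its own position (or the hairpin is exhausted). Trailing bases that
  match the template are always consumed as templated extension first,
  because non-templated additions are by definition absent from the
  template;
- mismatches within the templated span number at most one, and a mismatch
  forces `shift5 = shift3 = 0` and an empty tail, at an internal read
  position (not the first or last base).

Classes are assigned per decomposition in strict hierarchical order:
canonical (exact match), NucVar (one internal substitution), NTA-A/U/C/G
(homopolymer non-templated tail with canonical 5' end; mixed-base tails
are NTA-mixed and excluded from the four single-base percentages),
lv5pT/lv5pE/lv3pT/lv3pE (a single deviating end, templated), and mv
(both ends deviate, or a 5' deviation combined with a tail). Three
consequences of these rules are worth spelling out:

- a read whose 3'-terminal base differs from the mature sequence is not a
  NucVar; its minimal decomposition is a 1-nt tail on a 1-nt-trimmed body,
  i.e. NTA of a trimmed species. This is deliberate
  (`nta_on_shifted_3p = TRUE`): uridylation of trimmed miRNAs is
  biologically expected. Setting the flag to `FALSE` reroutes such reads
  to mv.
- a read whose 5'-terminal base differs has no valid decomposition (the
  schema has no 5'-tail class) and is `unassigned` rather than
  force-fitted.
- among valid decompositions the fewest total edits
  (mismatches + |shift5| + |shift3| + tail length) wins per miRNA;
  within-miRNA ties prefer smaller |shift5|, then |shift3|, then shorter
  tails. Reads tied across miRNAs at the global minimum are fractionally
  weighted 1/k, so weighted totals are conserved.

The candidate enumeration is implemented in C++; a brute-force R
enumeration of all decompositions, written independently against the rules
above, is used in the tests and acceptance sweep to verify exact
agreement on randomized instances.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_5p_shift`, `max_3p_shift` | 5 nt | largest end offset considered |
| `max_tail` | 3 nt | longest non-templated tail (transferases add up to ~3) |
| `max_internal_mismatch` | 1 | the NucVar budget |
| `min_count` | 1 | collapsed-read count threshold |
| `min_reads` (profiling) | 10 | per-miRNA coverage below which uridylation percentages are flagged |
| `fc_min` (differential) | 1.5 | minimum WT/DKO uridylation fold change |
| `alpha` | 0.05 | BH-adjusted significance level |
| `n_iter` | 1000 | randomization draws for the intersection Z |
| `max_wobbles`, `window_len` (TUMR) | 3, 8 nt | G:U budget and pairing window |

Percent denominators are miRNA-mapped reads only; unassigned reads never
enter a percentage. Group tables are means of per-sample percentages with
n−1 standard deviations, and the coefficient of variation likewise uses
the n−1 standard deviation. Welch's unequal-variance *t*-test is the
default wherever groups are compared (`var_equal = TRUE` switches to the
pooled test).

## Differential uridylation and the intersection test

Per miRNA, the uridylation percentage (NTA-U reads / all reads of that
miRNA) is compared between WT and DKO samples by a two-sided *t*-test;
p-values are BH-corrected across miRNAs and a call requires q < 0.05 and a
fold change of at least `fc_min`, computed as the ratio of group means
with the denominator floored at 0.1 percentage points (floored results are
flagged). Whether a consensus across studies exceeds chance is assessed by
randomization: each study's significant-set size is redrawn uniformly
without replacement from the universe (by default the union of all
studies' significant miRNAs; a broader all-detected universe can be
supplied), the draws are intersected, and Z = (observed − mean)/sd over
`n_iter` draws. The empirical mean is checked against the exact
closed-form E = N·Π(sᵢ/N), which holds by linearity of expectation since
each element enters study *i*'s random set with probability sᵢ/N. A null
with zero variance (e.g. every set equal to the universe) is flagged
degenerate rather than reported as a Z.

## Tail-U (TUMR) target search

Canonical sites use the three standard seed-match types defined on the
UTR: 7mer-m8 (reverse complement of miRNA positions 2-8), 7mer-A1
(reverse complement of positions 2-7 followed by an A opposite position
1), and 8mer (both). No context scoring or 3'-supplementary pairing is
attempted. The TUMR query is the 3'-terminal `window_len` (default 8)
bases of the mono-uridylated sequence (mature + U); a UTR window is a site
when every antiparallel pair is Watson-Crick or a G:U wobble (query G with
site U, query U with site G) with at most `max_wobbles` wobbles. The
window parameterization is an operationalization — the original pairing
geometry lives in an unpublished script — so the window length is exposed
as a parameter rather than hard-coded. With `max_wobbles = 0` the scan
provably reduces to exact reverse-complement search, which the tests
exploit as an oracle. Orthology across species is taken from shared gene
identifiers in `gene|species` FASTA headers, never computed; a gene is a
conserved target when a qualifying site appears in at least 15 of the 23
declared species.

## What the generator emulates — and what it does not

`simulate_sample()` produces two regimes with exact per-read truth.
*Pool* mode emulates an equimolar pool of chemically synthesized canonical
miRNAs: no biological isomiRs, only uniform per-base oligosynthesis
substitutions (default 0.003/base) and rare 1-2 nt terminal truncations
(1%/2% per molecule at the 5'/3' end). The substitution default is chosen
so that the structural false-NTA floor — a 3'-terminal synthesis error is
indistinguishable from a 1-nt tail, so the classifier's false-NTA rate on
pool data approximately equals the per-base rate — stays well below half a
percent while still yielding a NucVar fraction of the same order
(~5%) as real synthetic pools. *Cells* mode draws molecules from
configurable class probabilities (defaults: canonical 0.45, lv3pT 0.25,
NTA-U 0.10, NTA-A 0.10, NucVar 0.05, lv3pE 0.05), with tail lengths 1-3
at probabilities 0.7/0.2/0.1, a NucVar spectrum enriched for T>C (0.30)
and A>G (0.25), and NTA-U concentrated 5-fold on 3p-arm miRNAs (the
canonical class absorbs the per-miRNA difference, so the global NTA-U rate
is preserved). Both regimes share per-miRNA log-normal abundances
(sdlog 1), an optional per-sequence log-normal ligation efficiency
(sd 0 by default, emulating randomized adapters; ~1 emulates fixed-adapter
bias), geometric PCR duplication (mean 1 = off), and 5N+5N UMIs plus the
3' adapter on every read.

Two generator properties keep the truth labels exact and are *not*
properties of real data: the two hairpin bases downstream of each mature
end are drawn from {C, G}, so uridyl/adenyl tails are never accidentally
templated, and each mature sequence occurs exactly once across all
hairpins. Real genomes offer no such guarantees — templated-U junctions
and multi-mapping make some real reads genuinely ambiguous — so passing
recovery tests here demonstrates correctness of the machinery, not that
every real read is classifiable. The generator also ignores
quality-score-dependent sequencer errors and protocol chemistry beyond UMI
lengths and a scalar bias parameter.

## Numerical and degenerate-input choices

Ties in classification are broken deterministically (see above), and
candidate miRNAs are ordered lexicographically before weighting, so
identical inputs give byte-identical outputs. Reads failing every
decomposition are values (`unassigned`), not errors. Samples with zero
mapped reads are excluded from composition tables with a warning; a
single-sample group reports sd 0. Fold-change denominators are floored as
described; t-tests between two exactly constant groups return p = 1 (equal
means) or p = 0 (unequal) rather than erroring. UMI deduplication performs
no 1-mismatch UMI clustering — sequencing errors in UMIs slightly inflate
molecule counts; with 10 random bases the collision-driven undercount is
negligible at the depths used here. All simulations, randomizations and
pipeline runs are governed by explicit integer seeds.

## Problem sizes used in validation

The test and acceptance suites run entirely on generated data: 1,000
random read/reference instances (hairpins 56-60 nt) for the
classifier-oracle sweep; three seeds at depth 5×10⁴ with 20 miRNAs for
composition recovery (each class recovered within ±1.5 percentage
points); depth 5×10⁴ pool runs for the false-NTA bound (< 0.5% of mapped
reads); five set-size configurations at 2,000 draws for the randomization
null plus a planted-overlap instance (N = 300, sets ≈ 50, 18 planted) that
must give Z > 10; 1,000 random UTRs for the wobble-free TUMR scan; and a
3x-duplicated library of 2×10⁴ molecules for UMI recovery within ±2%.
These sizes were chosen so that sampling error sits comfortably inside
each tolerance.

## Known limitations

The classifier is reference-bounded: reads from unannotated loci are
unassigned, and no genome-wide alignment is attempted. NucVar is defined
as exactly one internal substitution; doubly-substituted reads are
unassigned rather than fuzzily matched. No RPM or cross-library
normalization is performed — composition is inherently compositional, and
comparisons are made on percentages. The differential test treats
per-sample percentages as approximately normal, which is adequate at the
read depths profiled here but not for very low-coverage miRNAs (hence
`min_reads`). Ligation bias is studied, not corrected. TUMR sites are
sequence matches; no repression efficacy is implied.
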