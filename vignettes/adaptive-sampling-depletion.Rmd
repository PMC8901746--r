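---
title: "Models and methods: adaptive-sampling depletion analysis with poresift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: adaptive-sampling depletion analysis with poresift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poresift)
```

## The measurement model

Nanopore adaptive sampling evaluates each molecule while it is being
sequenced and logs one of three decisions per read: `unblock` (eject the
molecule — the read ends truncated, typically within 400–800 bp),
`stop_receiving` (accept; sequence to completion) and `no_decision` (keep
evaluating). `poresift` treats the decision log as the authoritative record
of this process and derives a read's category from its **last** log record
in file order: the log is time-ordered and the final decision supersedes
earlier interval re-evaluations. Reads present in the FASTQ but absent from
the log were sequenced but never decided; they are classed `no_decision`
with a logged count. Runs without a log are `control` runs. These two rules
are package decisions — decision-log semantics are not formally documented
— and both are surfaced (warning + attributes) rather than silent.

Three derived quantities carry the analysis:

* **rejected percentage** `100 · rejected / total` — how aggressively the
  run depleted;
* **category content** — human / bacterial / other / unclassified
  percentages with each category's own read count as denominator. The
  `kept` row (accepted ∪ no-decision) is the material an analyst actually
  works with after depletion;
* **microbial bases** — bases of kept-category reads whose lineage is
  microbial. "Microbial" defaults to superkingdom ∈ {Bacteria, Archaea};
  a flag widens it to "classified, non-human" because usage of the word in
  the field is ambiguous between the two. Control runs count all reads as
  kept.

## Taxonomic bookkeeping

Per-read classifications arrive as centrifuge/kraken2/plain TSV. Multi-hit
reads are resolved by best score; **tied** best hits across different
taxids are demoted to taxid 0 (unclassified) and counted, rather than
inventing a lowest-common-ancestor the classifier did not report. Human
detection is keyed on the lineage (species *Homo sapiens*), never a
hard-coded taxid, so the miniature synthetic taxonomy behaves like a real
one. Lookups are total: unknown taxids resolve to an explicit "unresolved"
sentinel and are reported separately from taxid-0 "unclassified".

## Abundance tables and their denominators

Genus/species tables apply a **minimum of 30 reads per taxon** (the
conventional guard against over-interpreting uncertain assignments; the
dropped mass is recorded) and sort by count with alphabetical tie-breaks.
The denominator is an explicit policy, not a convention: proportions
relative to *all* reads including rejected (used when comparing a depletion
run against its control, since rejection changes the denominator
asymmetrically) or relative to the selected categories' reads. The filter
applies per run at the tabulated rank, not jointly across a pair.

## Concordance statistics

Control/depletion pairs are compared over the union of taxa that passed
the 30-read filter in *either* member (absent-in-one counts are zero):

* **fold deviations** `proportion_b / proportion_a` per taxon, stratified
  by `max(count)` into `[30,100)`, `[100,500)`, `[500,1000)`, `[1000,∞)`;
  taxa with zero control proportion are reported separately, never
  divided. Low strata are expected to be noisier — that expectation is the
  point of the stratification.
* **Bray–Curtis** `Σ|p−q| / Σ(p+q)` on relative abundances renormalized
  to sum 1 over the pair's union. The taxon universe and the
  renormalization are package decisions (the statistic's name alone does
  not fix them); zero-count taxa stay in, because BC is used here as a
  whole-composition distance. An empty side yields BC = 1 (disjoint), two
  empty sides NA.
* **Spearman** on average ranks over *pairwise cases* — taxa observed in
  both members. Fewer than two such cases make rank correlation undefined:
  the sample is excluded with a reason rather than returning a number.
  P-values use exact full-permutation enumeration up to 8 cases (an
  8! = 40 320 enumeration is cheap and reproducible) and the t
  approximation above; results with < 10 cases carry a
  `few_pairwise_cases` flag. No multiple-testing correction is applied.

## Mock-community representation

Bases sequenced per organism are the summed block lengths of **primary**
PAF alignments, one per read. Summed per-position depth and summed aligned
block lengths agree up to clipping and overlap effects; the block-length
proxy is deterministic from the PAF alone and is recorded in every report
(`bases_metric` attribute). Expected composition and Gram-group membership
are config inputs, not hard-coded.

## The synthetic generator: a stated world

The generator emulates the statistical structure the analysis assumes, not
sequencing physics. Its defaults are the conditions the modelled
experiments state; where nothing is stated, a value was chosen once as
realistic and is listed here.

* **Read lengths**: log-normal with median 2500 bp (PCR-based rapid-kit
  libraries produce ~2.5 kb fragments). `sdlog = 0.55` is not stated
  anywhere; it gives the right-skewed spread (IQR roughly 1.7–3.6 kb)
  typical of such libraries.
* **bp-to-decision**: bounded (min, max, median) distributions realized as
  a scaled Beta with shape1 = 2 and shape2 solved from the median via the
  `(a−1/3)/(a+b−2/3)` approximation. Rejections: 400–800 bp, median 600.
  Acceptance decisions: ~4000 bp under depletion, 400–800 bp under
  enrichment. Rejected reads are emitted truncated at the draw; accepted
  bp-at-decision is clamped to the read length.
* **Decision models**: either direct category frequencies with
  per-category composition (used by the named presets, because the
  modelled experiments report exactly those frequencies) or per-class
  probabilities P(reject | class), P(accept | class) (used for mechanistic
  scenarios).
* **Named presets**: control 87.93 % host; depletion P(rejected) = 0.8101,
  kept-fraction human 34.73 %, rejected-fraction human 99.8 %, kept reads
  split accepted : no-decision = 0.04 : 0.96 (the accepted verdict is
  rare); enrichment P(rejected) = 0.9593, kept human 8.29 %, rejected
  fraction containing 5.48 % *Gardnerella*, 2.41 % *Lactobacillus*, 2.20 %
  other microbial reads. The genus split of the non-human mass
  (*Lactobacillus*-dominated, with *Gardnerella*, *Ureaplasma*,
  *Prevotella* and a yeast) is illustrative scenery and never a numeric
  target.
* **cohort15**: 15 paired runs whose per-sample parameters are
  deterministic, not sampled: `value_i = m + s·z_i` with `z_i` the 15
  symmetric normal quantiles at `p = (i−0.5)/15`, clipped to the valid
  range, then the non-clipped values shifted (iterating if the shift clips
  anew) so the mean equals `m` exactly. Parameter pairs: control human
  (97.59, 7.63), rejected % (92.05, 7.42), rejected-fraction human
  (99.80, 0.09), read-count fold (1.70, 0.27). The fold is encoded as the
  paired run's read count `round(n · fold_i)` — the sources report the
  abstract-level fold as 1.70 and the body-level as 1.71 (± 0.27 both);
  the preset uses 1.70 and this discrepancy is simply noted. Both members
  of a pair share the sample's genus composition (a per-sample Dirichlet
  draw, concentration 8 × the default split). Kept-fraction human
  percentages (accepted 1.23 %, no-decision 25.06 %) and the
  accepted share 0.041 come from the cohort-level figures and are scenery.
* **Pore-time mode**: an optional mechanistic mode draws reads against a
  pore-seconds budget (`duration × channels`), each read costing capture
  overhead + length/speed (+ unblock overhead when rejected); defaults
  450 bp/s, 1 s capture, 0.5 s unblock — plausible figures, stated
  nowhere, so this mode backs only the *qualitative* property that
  rejection raises yield. The 1.70-fold cohort yield is deliberately a
  per-sample parameter, not emergent from overhead constants that would
  have had to be invented.
* Read ids carry no truth information; truth lives only in the sidecar
  table, so no parser can accidentally exploit it. All randomness flows
  from one explicit seed (Mersenne-Twister, state restored on exit);
  written runs include a manifest with preset, seed and file checksums.

**What a green test does not establish**: sequences are random nucleotides
(no genome content, no error model), classification on synthetic runs is
by construction (optionally corrupted at configurable rates), per-sample
cohort parameters are a declared quantile construction rather than an
inference of any real cohort, and basecalling, alignment and classification
engines are out of scope — their output formats are consumed, not
reproduced.

## Numerical and testing choices

* Percentages are reported to 2 decimals; cohort dispersion is the sample
  SD (n−1) — the "±" convention in the field is rarely defined, so it is
  defined here.
* Per-category means in cohort summaries exclude samples whose category
  holds fewer than `min_category_reads = 100` reads (the default
  reproduces the conventional exclusion of accepted fractions with only a
  handful of reads); excluded sample ids are listed, never silently
  dropped.
* Statistical recovery tests use 3-binomial-SD envelopes at the stated n.
  Where several taxa are checked simultaneously, the envelope is
  Bonferroni-adjusted and paired with a pooled chi-square goodness-of-fit
  (α = 0.001), and the check averages replicate runs — this targets
  generator *bias* with controlled false-positive rate instead of gating
  on a single seed's tail behaviour.
* Degenerate inputs are errors, not guesses: empty runs, zero fold-change
  denominators, conflicting lineage rows, malformed FASTQ records (with
  byte offsets), unrecognized decision strings (with row numbers).

## Known limitations

* The `no_decision` category conflates "evaluated, never decided" with
  "absent from the log"; both are counted, but a run with a pathological
  log (many unmatched records) deserves manual inspection of the logged
  counts.
* Bray–Curtis on very sparse pairs (0–2 retained taxa) is reported but
  nearly meaningless; the pairwise-case flag and exclusion rule exist for
  exactly this regime.
* The pore-time model is a budget model, not a channel-level simulation:
  it reallocates time, it does not model pore death, mux scans or refuels.
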