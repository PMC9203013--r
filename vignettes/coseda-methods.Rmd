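---
title: "Methods: differential co-sedimentation analysis with coseda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-sedimentation analysis with coseda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coseda)
```

## The experimental design the package models

A microtubule co-sedimentation experiment asks which proteins in a lysate
associate with microtubules, and how that association changes under a
perturbation. A soluble extract is split into two aliquots; one receives a
14-3-3 inhibitor (the R18 peptide, which occupies the phospho-docking
groove of 14-3-3 dimers) and the other an equal volume of vehicle.
Microtubules are polymerised with a stabilising drug and pelleted through a
sucrose cushion, and the pellets are quantified by label-free LC-MS/MS.
Each biological replicate therefore yields a *pair* of measurements per
protein: a control intensity and an inhibitor-treated ("sample")
intensity, on the same extract. `coseda` takes such paired protein-groups
tables from the search software onward; spectra, database search and LFQ
normalisation are upstream of its scope.

## The differential model

For gene $g$ and replicate pair $j$, write $c_{gj}$ and $s_{gj}$ for the
control and sample intensities. An intensity of 0 means *not detected* —
it is never treated as a measured value and never imputed. The estimator
in `cosed_diff()` is deliberately the field's plain workhorse:

* **Pre-filtering.** Decoy (reverse-database), contaminant and
  identified-only-by-site groups are removed; groups supported by a single
  peptide are removed; where several accessions map to one gene the
  highest-scored record is kept (`collapse_accessions()`).
* **Zero handling.** A pair contributes to gene $g$ only if both arms were
  detected. Genes whose every detected pair has exactly one zero arm get
  no ratio at all; they are removed from testing and listed as the *zero
  set* (candidates for on/off behaviour, summarised separately).
* **Effect size.** Over the usable pairs,
  $\log_2 R_g = \overline{\log_2 s_{gj}} - \overline{\log_2 c_{gj}}$.
* **Test.** With at least `min_pairs = 2` usable pairs, a two-tailed
  one-sample $t$ on the per-pair differences $d_{gj} = \log_2 s_{gj} -
  \log_2 c_{gj}$ (default, *paired*), or a two-tailed two-sample Student
  $t$ on the two arms (*unpaired* mode). Both modes are exposed because
  the two descriptions of the source analysis disagree; paired is the
  default because the deposited result table's p-value column is paired,
  and because pairing matches the split-extract design. If all $d_{gj}$
  are identical the statistic is undefined; the gene is flagged
  `degenerate` and classified `unchanged` rather than given an artificial
  p-value.
* **Classification.** `increased` iff $2^{\log_2 R_g} > 1.5$ *and*
  $p < 0.05$; `decreased` iff $2^{\log_2 R_g} < 1/1.5 \approx 0.6667$ and
  $p < 0.05$; strict inequalities on both, exactly as the thresholds are
  printed. No multiple-testing correction enters the classification — the
  raw-p threshold is part of the procedure being reproduced — but BH
  q-values are emitted in an extra column for users who want them.

Replicate-pair QC (`replicate_qc()`) summarises each pair's log2
distributions and the least-squares line of sample against control; a pair
is flagged when its median deviates from the cross-pair median by more
than 2 log2 units (a conventional "order of magnitude-ish" cut on the
log scale) or its slope leaves $[0.5, 2]$. Flagging is advisory: the
analyst decides which pairs to drop, mirroring the way 6 of 8 replicates
were retained in the source design.

## Motif annotation and sequence-context statistics

Candidate 14-3-3 binding phospho-sites come from an external predictor
whose per-site ANN, PSSM and SVM scores plus consensus are imported
(`import_predictions()`); a site passes only when all four exceed their
thresholds (consensus 0.9; ANN 0.55; PSSM 0.80; SVM 0.25) *strictly*,
reading "above" literally. Where predictor output is unavailable,
`scan_consensus()` is an explicitly simple stand-in: it reports every S/T
with a basic residue at $-3$ or $-4$ and a proline at $+2$ — the mode-I
arrangement — and makes no claim to the predictor's accuracy.

Each site carries a 13-residue window (positions $-6..+6$, phospho-site at
0). The width is fixed at 13 because the published count table places the
phospho-site at position 7 of 13. Overhangs beyond the protein termini are
padded and excluded from denominators. `annotate_aurora_context()` marks
windows whose $-2$ residue is S/T inside an R/K-x-S/T arrangement — the
configuration in which Aurora B can phosphorylate the residue two
positions N-terminal to the 14-3-3 site (as on Borealin S161/S163).

Two statistics sit on top:

* **Directional enrichment** (`directional_enrichment()`): all quantified
  genes are split by has-a-passing-site, and within each partition the
  up/down split (by the *sign* of the log ratio, not the volcano classes —
  the published 375+225+448+456 sums to all 1,504 quantifiable proteins,
  which identifies the intended denominator) is tested against 50:50 with
  a two-sided exact binomial test. The source does not name its test; the
  exact binomial is validated against the one printed p-value it allows
  (448/456 gives 0.8159, printing as 0.82).
* **Positional composition** (`positional_composition()` /
  `composition_significance()`): genes are ranked by log ratio and cut
  into 5 near-equal bins (ties broken by gene name; remainders go to the
  top bins so sizes differ by at most one), the top 20% / middle 60% /
  bottom 20% site windows are pooled, and each (position, residue) cell is
  compared between the top group and the rest with a two-sided Fisher
  exact test, flagged at raw $p < 0.01$. Every passing site contributes
  one window (the source is silent on per-protein deduplication; counting
  every site keeps the counts interpretable as site-level frequencies).
  No correction is applied by default, matching the raw threshold; a BH
  option exists.

## Network edge enrichment

`edge_enrichment()` counts physical-interaction edges with both endpoints
in a candidate set and compares the count with a permutation null: uniform
same-size subsets of a background proteome. The background defaults to the
quantifiable proteins, the sampling frame from which candidate sets arise,
not the whole proteome. The empirical p-value uses the add-one convention
$(1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$, standard permutation
practice that avoids zero p-values. This deliberately replaces the
external database's analytic expected-edge model, whose published
expectation and p-value are version-dependent and out of scope.

## Densitometry and phenotype statistics

Band and spindle signals are quantified by the two-box rule: an inner box
S (mostly signal) and a larger box L (signal plus surrounding background)
give
$$\mathrm{signal} = I_S - N_S\,\frac{I_L - I_S}{N_L - N_S},$$
the inner total minus the inner area times the mean per-pixel intensity of
the surrounding ring. The formula is exact whenever the background is
constant per pixel — a property the tests verify across random geometries
— and linear in $(I_S, I_L)$ at fixed geometry. Negative outputs are
possible for dim boxes in bright surroundings and are returned as-is with
a warning rather than clipped. Degenerate geometry ($N_L = N_S$ or
$N_S = 0$) is an error.

Group comparisons of per-oocyte intensities use the two-sided Wilcoxon
rank-sum test (exact for small untied samples; mid-ranks with normal
approximation under ties, on which the source is silent) and report the
percent change of *medians*, $100\,(m_A - m_B)/m_A$, because the figure
legends mark medians. Bi- vs mono-orientation counts are compared with the
two-sided Fisher exact test.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` generates the world the analysis assumes: a
log-normal baseline per protein (log2 $\mathcal N(25, 2)$, an LFQ-like
scale), a shared per-pair effect plus independent per-measurement noise
(each $\mathcal N(0, 0.7)$ log2 units, i.e. a replicate log-ratio SD near
1 — chosen to match the character of the study's volcano, where only
47 of 1,504 proteins pass $p<0.05$ although many exceed the fold-change
cut), multiplicative spikes on the sample arm (defaults: 47 up and 20 down
at fold change 4 among 3,564 proteins, the published classification
counts), and zero-inflated missingness. Intensities are formed as
$2^{\text{log2 draw}}$, so zeros arise *only* from the missingness
mechanism, matching the "0 = not detected" convention. Missingness is
missing-completely-at-random by default at rate 0.52 per cell —
calibrated once so that the expected fraction of proteins quantifiable in
$\ge 2$ of 6 pairs is $\approx 42\%$, the published quantifiable fraction
— with an optional intensity-dependent mode in which low-abundance
proteins are proportionally more likely to drop out at the same average
rate.

Sequences are drawn from a 18-letter alphabet that excludes S and T except
inside planted motifs, so that a consensus-scanner hit identifies a
planted site exactly; motif presence is Bernoulli at 0.6 for spiked-up
proteins and 0.35 otherwise (giving roughly the published 600-of-1,504
with-site fraction). One global seed drives the run, with per-replicate
sub-streams derived deterministically from it, so identical configurations
are byte-identical.

The generator does **not** emulate: peptide- or spectrum-level structure
(razor-peptide assignment, shared peptides), intensity-dependent variance,
correlated missingness between arms, batch drift across pairs, or a
motif-effect association among *non-spiked* proteins. Consequently,
passing tests demonstrate the pipeline's statistical behaviour under its
own assumptions, not the biological claims of any particular dataset; in
particular the generator's null proteins carry no motif-direction signal,
so a default-condition run shows directional enrichment only through its
spiked minority.

### A note on power under the calibrated missingness

The 42% calibration has a hard statistical consequence worth stating
plainly. Under per-cell MCAR at 0.52, a pair is doubly detected with
probability $0.48^2 \approx 0.23$, so genes passing the $\ge 2$-pair
filter carry almost exclusively 2 or 3 usable pairs. A paired $t$ on two
differences needs $|t| > 12.7$, on three $|t| > 4.30$; at a replicate
log-ratio SD near 1 this yields per-gene power of roughly 0.1 (2 pairs)
and 0.4 (3 pairs) even for a fourfold spike. The pipeline therefore
recovers only a minority (~20-30%) of quantifiable spiked proteins under
these study-like conditions — a property of the design, not a defect of
the estimator, and consistent with the modest published hit counts. In
the intensity-dependent missingness mode the quantifiable set concentrates
at high replicate support and recovery rises accordingly. The test suite
asserts recovery honestly under the default conditions rather than under
conditions chosen to flatter the method.

## Numerical and design choices

* Fold-change thresholds are compared on the natural scale with strict
  inequalities (`> 1.5`, `< 0.6667`), so boundary values classify as
  `unchanged`.
* Dialects of protein-groups tables (MaxQuant TSV vs supplementary-style
  sheet with `logSAM`/`logCON` columns) are selected by an explicit flag
  and never sniffed; silent mis-parsing of intensity columns is the
  dominant failure mode for such tables. Replicate labels are exposed
  verbatim (the source numbers its kept replicates 1, 2, 5, 6, 7, 8).
* Bin assignment, collapsing and volcano ordering all break ties
  deterministically (by gene name or lead accession), so reruns are
  byte-identical.
* The zero set is listed, not summarised: how those proteins were
  "analysed separately" in the source is unstated, and the package does
  not invent a statistic for them.
* Edge tables accept scores on either the 0-1 or the 0-999 export scale
  (rescaled once, before the 0.400 cutoff); reversed duplicates and
  self-loops are removed.
* Exact tests (`binom.test`, `fisher.test`, `wilcox.test`, `t.test`) come
  from base R; the suite cross-checks each against an independent
  full-enumeration oracle at small margins rather than re-implementing
  them.

## Problem sizes used by the test suite

Simulation-backed tests run at 40-2,000 proteins with 6 replicate pairs:
2,000 for distributional checks (null uniformity, type-I error,
enrichment recovery), 600-1,500 for power and recovery, and tens to
hundreds for structural checks. The permutation null uses 200-2,000
draws in tests. These sizes make every distributional assertion stable
under its fixed seed while keeping a full run of the suite inexpensive.

## Known limitations

* The consensus scanner is a coarse stand-in for the published predictor;
  its hits should not be interpreted as high-confidence 14-3-3 sites on
  real sequences.
* The unpaired mode uses the equal-variance Student form; with strongly
  unbalanced detection between arms a Welch variant could be argued, but
  the source's wording ("Student's T-test") fixes the choice.
* Percent changes are computed on medians; means can differ appreciably
  on skewed intensity distributions.
* `reproduce_supplementary()` requires the study's supplementary tables,
  which are not redistributable with the package; without them the
  reproduction path is exercised only by the synthetic generator.
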