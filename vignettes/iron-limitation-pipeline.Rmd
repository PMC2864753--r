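---
title: "Methods: integrative transcriptome-proteome analysis of iron limitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative transcriptome-proteome analysis of iron limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrolimit)
library(dplyr)
```

# The experimental design being modelled

ferrolimit implements the analysis used to characterize how *Ca.*
Pelagibacter ubique — the most abundant heterotroph in the oceans, with
one of the smallest free-living genomes — responds to iron limitation
imposed by a siderophore. The design it assumes throughout:

* **Transcriptome**: six batch cultures (3 iron-limited, 3 iron-replete
  biological replicates) sampled on days 17, 18 and 28, one microarray
  chip per culture per day — 18 chips in total.
* **Proteome**: pooled cell pellets per treatment on days 18 and 28
  (4 samples), each run in 3 LC-MS technical replicates, quantified
  label-free against an accurate-mass-and-time (AMT) tag library.

The central biological phenomenon is *decoupling*: under iron stress the
global proteome is strongly suppressed while the transcriptome is not
proportionally remodelled, and a single periplasmic iron(III)-binding
transporter subunit (the *sfuC* marker) is strongly induced on **both**
platforms. The pipeline's job is to measure each of those statements.

# Differential transcripts

Fluorescence is first normalized across chips by global-median scaling:
each chip is rescaled so its median gene fluorescence equals the median
of per-chip medians. The method behind the original study's cross-chip
normalization is not recorded, so the choice here favours robustness and
idempotence, and the step is an explicit verb (`normalize_chips()`) that
can be replaced. One consequence worth knowing: when a condition
asymmetrically up-regulates a few percent of genes, the affected chips'
medians shift slightly (on the default synthetic study, a measured
~0.01 log10 attenuation of the largest planted fold), a generic property
of global scaling rather than a defect of this implementation.

Per gene and day, `differential_transcripts()` reports

* `ratio` — mean of the three iron-limited replicate fluorescences over
  the mean of the three iron-replete replicates;
* `p_value` — two-tailed Student (pooled-variance) two-sample t-test on
  the biological replicates, n = 3 per arm.

Degenerate inputs follow documented conventions: zero variance in both
arms yields p = 1 for equal means and p = 0 otherwise (the t statistic
is infinite). No multiple-testing correction is applied — the original
tables report raw p-values (up to 0.091 among listed rows), and the
package reproduces that convention rather than "improving" on it.
`filter_upregulated()` keeps `ratio >= 1.5`, the inclusive reading of
"at least 50 percent more abundant" (the published list includes
borderline 1.52–1.54 entries).

# The radial layout

`radial_layout()` is a modified radial-coordinate (RadViz) construction.
Chips are collapsed to one sample per treatment × day (six samples);
`S[i, g]` is the log10 of gene *g*'s mean fluorescence in sample *i*,
with fluorescence floored at the smallest positive value in the matrix
before logging. Anchors sit on the unit circle; the study arrangement
places iron-limited samples left, iron-replete right, exponential
growth (day 17) at the bottom and stationary phase (day 28) at the top.

The published account describes genes "attracted" to the samples where
they are most abundant; the exact coordinate formulas are not printed.
The construction used here is the standard convex-weight barycenter:
weights `w[i] = S[i, g] - min_j S[j, g]`, normalized to sum to one
(uniform when all signals are equal), and position
`P[g] = sum_i w[i] * DA[i]`. It satisfies every stated property — pairwise
attraction, centroid neutrality for uninformative genes, a gene elevated
in exactly one sample landing on that sample's anchor — and is isolated
in `gene_position()` so an alternative (e.g. force-directed springs)
could be swapped in. The per-gene minimum baseline makes position
respond to *relative*, not absolute, expression. Point size is the
largest pairwise log10 difference (max − min), invariant to global
rescaling.

Cluster labels are operationalized (the published clusters were drawn by
eye): genes within 0.1 circumradius of the anchor centroid are
`unassigned` (a centroid gene carries no condition preference); all
others take the cluster of the nearest anchor, exact ties unassigned.

# AMT-tag protein quantitation

The stage order is fixed, and each step only removes records (only the
normalization alters values):

1. **Match** (`match_features()`): feature ↔ tag iff within ±6 ppm in
   mass *and* ±0.001 NET (both inclusive). 0.001 is the absolute-NET
   reading of the stated ±0.1% elution window. Ambiguities resolve by
   smallest combined normalized distance, then closest mass, then
   smallest `peptide_id` — a deterministic rule the original account
   leaves unstated.
2. **Presence filter**: a (peptide, sample) group needs observations in
   ≥ 2 of 3 technical replicates; absence is row absence, never zero.
3. **MA normalization** (`ma_normalize()`): per sample, each technical
   replicate is regressed against a reference replicate (replicate 1 by
   default; no reference is named in the original description) in
   minus-versus-average space, `m = log10 A_i − log10 A_ref`,
   `a = (log10 A_i + log10 A_ref)/2`; the fitted `m*(a)` is subtracted,
   `x' = log10 A_i − m*(a)`; the reference is passed through unchanged.
   Peptides without a reference partner are corrected at `a ≈ log10 A_i`.
4. **Variability filter**: drop (peptide, sample) groups whose linear-scale
   (`10^x'`) standard deviation exceeds the mean — "measurement value"
   is read as the abundance itself, not its log.
5. **F-score filter**: per protein, drop the lowest `floor(k/3)` of the
   `k` distinct peptides by maximum PeptideProphet F-score; floor never
   removes more than necessary and keeps the rule deterministic; ties at
   the cut drop the lexicographically larger peptide id.
6. **Peptide ratios**: replicate abundances (linear `10^x'`) are averaged
   per sample; the sample-1/sample-2 quotient is log10-transformed. The
   one-tailed Student t-test runs on the `x'` (log-scale) values — the
   natural scale for the normalized quantities, flagged as the one
   genuinely ambiguous reading — in the direction of the protein mean,
   computed from a provisional equal-weight rollup (the published
   opposite-direction rule presupposes a protein direction known before
   peptide testing). Peptides opposing that direction get p = 1.
7. **Rollup** (`protein_rollup()`): proteins need ≥ 3 passing peptides;
   `log10_ratio` is the mean member log ratio; significance combines the
   member p-values by Fisher's method, χ² = −2Σln p on 2k degrees of
   freedom, with p floored at 1e−300 before the logarithm.

An optional global linear NET recalibration (match once, fit tag-NET on
feature-NET, rematch) is available via `quantify_proteins(recalibrate =
TRUE)` but off by default: inputs are assumed already aligned in both
dimensions.

# Integration

`build_pairs()` inner-joins the two platforms on locus (only genes
measured on both can enter the comparison) and keeps loci with
`min(mrna_p, protein_p) <= 0.05`. `r_squared()` is the squared Pearson
correlation of the log ratios. `proteome_summary()` counts detected and
significantly-down proteins and reports the mean percent change,
arithmetic on the linear scale by default (the headline "average
decrease" convention is not uniquely determined, so a geometric option
exists). `marker_report()` tabulates the marker gene per day and flags
it "coupled" where both folds are ≥ 1.5; `coupled_loci()` adds the
p ≤ 0.05 requirement on both platforms for the uniqueness check. Which
four comparisons produced the published R² values is given only in an
unreproduced legend, so comparisons here are explicit arguments; the
default pipeline runs limited-vs-replete at each proteomic day.

# The synthetic study and what it does (not) show

`simulation_config()` defaults *are* the study conditions: 2,000 genes,
250 tagged proteins, 18 chips, 4 proteomic samples × 3 technical
replicates, multiplicative lognormal noise of 0.1 on the log10 scale for
both platforms (matching the analysis's exclusive use of log10 ratios),
global proteome suppression 0.59 (iron-limited abundances × 0.41),
marker mRNA fold 16 and marker protein fold 27, 90% per-replicate
detection, 1 ppm / 2×10⁻⁴ NET measurement jitter well inside the
matching windows, and 5% decoy features rejection-sampled > 10 ppm from
every tag. Four planted programs mirror the observed clusters:
exponential (day 17, both treatments), stationary (day 28, iron-replete
only — the iron-limited cultures are growth-arrested rather than
classically stationary), early iron stress (limited, day 18) and late
iron stress (limited, day 28), 50 genes each at fold 4 except the
16-fold marker. Decoupling is planted by drawing per-(protein, day)
folds around the suppression level (lognormal, sd 0.15 on log10)
independently of the mRNA programs; only the marker is coupled. The
marker protein fold is a single knob applied on both days; the original
study's smaller day-18 induction is not separately emulated.

Detection dropout is Bernoulli per (peptide, replicate), which is what
exercises the 2-of-3 presence rule; peptide counts are 3 + Poisson(4)
per protein so the 3-peptide rollup threshold is reachable but not
guaranteed after filtering.

`parameter_recovery()` repeats the full pipeline over seeded replicates
(the validation suite and the acceptance script use 50, about 2.5
minutes on one core) and checks that recovered log folds are unbiased
within three standard errors, that the marker is the unique coupled
locus in ≥ 90% of seeds, and that the decoupled R² stays below 0.1 in
≥ 95% of seeds.

What passing does **not** show: the generator plants no chip-level batch
effects, probe biases, chimeric or contaminant features, retention-time
drift beyond Gaussian jitter, or correlated peptide noise within a
protein. Real microarray and LC-MS data violate all of these; the tests
demonstrate correctness of the estimators under the stated model, not
robustness to unmodelled artifacts.

# Numerical choices

* Inclusive boundaries everywhere a threshold is stated as "at least"
  (fold ≥ 1.5, |Δmass| ≤ window, |ΔNET| ≤ 0.001).
* Zero-variance t-tests: p = 1 (equal means) / p = 0 (unequal), two- and
  one-tailed alike; p = 0 is floored at 1e−300 before Fisher's logarithm.
* Matching tie-breaks: normalized Euclidean distance, then |Δmass|, then
  lexicographic peptide id; at most one record per (peptide, sample,
  replicate), keeping the closest feature.
* log of zero fluorescence: floored at the smallest positive matrix
  value (configurable `eps`).
* TSV readers use base R's correctly-rounded double parser so a
  write-then-read round trip is bit-exact and reruns are checksum-stable.
* All randomness flows from one integer seed; the proteome stage derives
  its stream from `seed + 1`.

# Worked example

```{r pipeline, eval = FALSE}
manifest <- run_pipeline(pipeline_config(), out_dir = "ferrolimit_demo")
manifest
```

The manifest lists every stage output with row counts and md5 checksums;
rerunning with the same seed reproduces the checksums exactly. See the
README for the numbers this produces and what they mean.
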