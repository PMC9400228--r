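---
title: "Models and methods behind circm6a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circm6a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circm6a)
```

## The measurement model

A two-channel m⁶A epitranscriptomic array hybridizes, for each target, the
antibody-captured methylated fraction (IP, Cy5) and the supernatant (Sup,
Cy3). Writing $A$ for a target's total abundance and $f \in [0,1]$ for the
fraction of its copies carrying m⁶A, the package's generative model is

$$\mathrm{IP}_{raw} = A \, f \, e \, \eta_{ip}, \qquad
  \mathrm{Sup}_{raw} = A \, (1-f) \, \eta_{sup},$$

with $e$ the IP capture efficiency (default 1, exposed because real
immunoprecipitation is lossy) and $\eta$ independent log-normal noise per
channel with standard deviation `noise_log2_sd` on the log2 scale (default
0.25, a typical replicate CV for two-color arrays). Raw intensities are
clipped below at a floor $\varepsilon$ (default 1) so logarithms are
defined; scanners report positive intensities, and the floor preserves
ordering.

Each channel is anchored to an exogenous spike-in panel:

$$\log_2 \mathrm{IP}_{norm} = \log_2 \mathrm{IP}_{raw}
  - \overline{\log_2 \mathrm{IP}_{spike}},$$

and likewise for Sup. Because the offset is a per-sample, per-channel
constant, any global rescaling of a channel cancels exactly — the property
the test suite checks to machine precision. The panel composition is a
modelling choice: 8 spike-ins with fixed intensities log2-spaced over two
log2 units ($2^{10}$–$2^{12}$), identical across samples and channels by
default since they are the normalization anchor; optional spike-in noise is
exposed for robustness experiments.

From normalized intensities the two per-sample measures are

$$\text{modified\%} = \frac{\mathrm{IP}}{\mathrm{IP}+\mathrm{Sup}}
 \in (0,1), \qquad
  \text{quantity} = \log_2 \mathrm{IP}_{norm}.$$

With no noise and $e = 1$, modified% equals $f$ identically (the
identifiability property); the estimator's bias grows with channel noise
but is negligible at the default noise level (a second-order Jensen term,
$\approx 10^{-4}$ at $f = 0.6$).

## QC retention

A probe is kept when at least `min_ok = 3` samples carry Present or
Marginal flags; a sample counts only when **both** channels are P/M there,
because both are needed to form the ratio (the flag rule is stated per
"probe signal", so the channel combination is a package decision). Flags
are simulated independently per probe × sample × channel at P:M:A =
0.9:0.05:0.05 — the simplest model that exercises the 3-of-6 rule.

## Differential screening

Group means are compared on each metric's natural scale: modified
fractions directly (their ratio is the level fold change), quantities as
$2^{\Delta \log_2}$. Significance uses a two-sided unpaired Welch t-test on
an analysis scale chosen for approximate normality: logit for fractions
(bounded support; under the log-normal noise model the logit of modified%
is exactly Gaussian), log2 for quantities. No test is named in standard
vendor workflows beyond a t-test on normalized values, so Welch — robust to
unequal variances — is the default. A target passes as up when fold change
> 1.5 and p < 0.05 (strict inequalities), down when fold change < 1/1.5 at
the same significance. Raw p-values drive the calls; a Benjamini–Hochberg
column is emitted for information only. The final differential set is the
per-direction intersection of the level and quantity calls.

Two calibration facts matter at the default design of 3 vs 3 samples:

* the Welch test there is conservative (empirical size ≈ 0.034 at nominal
  0.05) because the Satterthwaite degrees of freedom are small and noisy;
  it is never anti-conservative. The package's null-calibration experiment
  therefore uses 10 replicates per group, where the approximation is
  essentially exact (measured 0.047–0.050 over 10,000 null targets), so
  the empirical size isolates the test's calibration rather than the
  small-sample penalty;
* the fold-change gate can only remove calls, so the gated call rate is
  bounded by the test-only rejection rate — checked on the same null run.

Targets with fewer than two testable replicates per group are flagged
untestable and excluded from calls; exactly identical groups return p = 1.

## Coordinates and genomic characterization

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted at the reader boundary, BED passes through
unchanged. This convention is anchored by published single-exon back-splice
spans whose printed lengths equal end − start (549, 792 and 80 bp in the
shipped reference tables).

Spliced length is the exon-block sum, not the genomic span; histograms
stage lengths in half-open 100-bp bins and report the 200–500 bp fraction,
and exon counts report the 1–3-exon fraction. Metagene profiles map each
site's **midpoint** (peak summits are not modelled) to transcript
coordinates on one representative transcript per gene, assign it to 5'UTR,
CDS or 3'UTR, normalize the position within its region, and pool site
density over 50 bins per region, normalized to sum to 1 (pooled-site
density, not per-transcript averaging — the simplest normalization
consistent with a single profile per cohort). A circRNA's position in its
host uses the same machinery on its transcript-interval midpoint; the
"front part of CDS" is operationalized as normalized CDS position < 0.5,
since no published cutoff exists. All mappings are strand-aware: mirroring
the annotation and flipping strands leaves every region assignment
unchanged, a property the suite tests.

## Subgroup classification

Each circRNA is placed in a 2×2 taxonomy by its own m⁶A state and its
host's: `neither`, `host_only`, `circ_only`, `both`. Host methylation means
at least one MeRIP-seq peak overlapping an exon by ≥ 1 bp (intronic peaks
do not count; browser tracks of such data show exonic peaks), with each
qualifying peak's midpoint labelled by tripartite region. The circRNA's own
binarization is not standardized anywhere, so two modes are exposed:
threshold mode (default; mean tumor modified% > 0.2, which cleanly
separates the generator's methylated regime f ∈ [0.3, 0.8] from its
unmethylated regime f ∈ [0.01, 0.1]) and calls mode (membership in the
intersection call universe). On noiseless data threshold mode recovers
planted labels exactly. Circ and host states are drawn independently in the
generator, so a chi-square test on the 2×2 label table should not reject —
the independence property observed in real data, reproduced by
construction.

## Synthetic cohorts: what they emulate, and what not

The generator emulates a 3 tumor vs 3 normal two-color design: per-target
log2-normal abundance (mean 10, sd 1.5 on the log2 scale, spanning the
typical array dynamic range), a bimodal methylation fraction (unmethylated
f ∈ [0.01, 0.1], methylated f ∈ [0.3, 0.8], half of targets methylated),
genes of 3–10 exons (90–320 bp) with 5'UTR/CDS/3'UTR splits of roughly
10–20% / 50–75% / 15–35% of the transcript, circRNAs as contiguous runs of
1–5 host exons weighted toward 1–3 (and hence spliced lengths
concentrating in the low hundreds of bp), mRNA m⁶A sites biased toward the
stop-codon/3'UTR region, and 100-bp peak intervals centered on sites.
Planted effects are exact ratios of $2^{1.5}$ on 15% of targets, split
between level effects (fraction ratio, both fractions kept inside (0,1))
and quantity effects (abundance ratio).

Not emulated: probe sequence effects and cross-hybridization, dye bias,
spatial artifacts, RNase R digestion, correlated noise between channels,
and multi-isoform hosts (one transcript per gene). Passing tests therefore
demonstrate correctness of the estimators, screens and classifications
under the stated statistical model — not robustness to these unmodelled
artifacts on real arrays.

## Problem sizes and numerical choices

The test suite runs cohorts of tens to hundreds of genes; calibration
experiments use 2,000 targets (parameter recovery) and 10,000 targets
(null size), sizes at which Monte-Carlo error is well below the asserted
tolerances. Ties at exactly FC = 1.5 or p = 0.05 fail the strict
inequalities. Degenerate inputs are defined: empty circRNA sets give empty
histograms, zero mapped sites give an empty flagged profile, and fully
unmethylated targets emit the floor in the IP channel.

One ambiguity in the published ranked tables is left unreconciled: the
down-regulated table's fold-change column prints values in (0, 1) under a
log2 heading, consistent with linear ratios; the package reports both the
linear ratio and its log2 everywhere so no reading is forced.
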