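---
title: "Poisson partition statistics and duplication calling for duplex ddPCR"
author: "dropletCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson partition statistics and duplication calling for duplex ddPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletCNV)
```

## The measurement problem

Droplet digital PCR (ddPCR) partitions a PCR reaction into roughly 15,000
droplets of about 1 nL, amplifies to end point, and reads each droplet as
positive (contains at least one template molecule) or negative. Because
molecules land in droplets essentially independently, the number of
templates per droplet is Poisson with mean $\lambda$, a droplet is negative
with probability $e^{-\lambda}$, and the positive count in a well of $n$
accepted droplets is $Binomial(n,\, 1 - e^{-\lambda})$.

This makes absolute quantification a counting problem. The maximum
likelihood estimate is

$$\hat\lambda = -\ln\!\left(\frac{n_{neg}}{n_{tot}}\right), \qquad
  \hat c = \frac{\hat\lambda}{V}\ \text{copies}/\mu l,$$

with $V$ the droplet volume in $\mu$l. `dropletCNV` applies this to a
duplex FGFR1 assay: a FAM-labelled target amplicon inside the
tyrosine-kinase domain (exon 16, covered by the internal tandem
duplication) and a HEX-labelled reference amplicon outside it (exon 8).
The diploid-normalized copy number is

$$CNV = 2\,\frac{c_{target}}{c_{reference}},$$

so a normal locus reads 2 and a monoallelic duplication carried by a
fraction $f$ of cells reads $CNV = 2 + f$: cells average $2 + f$ target
copies against 2 reference copies. Inverting this mixture model
(`tumorFraction()`) turns a CNV into an estimate of the duplicated-cell
fraction; the calling cutoff CNV $> 2.25$ corresponds to a
target/reference ratio of 1.125, i.e. a duplication present in 25% of the
analyzed cells.

## Confidence intervals

The variance of $\hat\lambda$ follows from the binomial variance of the
negative fraction $\hat p_{neg}$ by the delta method:

$$\widehat{var}(\hat\lambda) = \frac{1 - \hat p_{neg}}{n\,\hat p_{neg}},$$

and the package constructs the 95% interval on the log scale,
$\hat\lambda \exp(\pm z_{0.975}\sqrt{\widehat{var}}/\hat\lambda)$, which
keeps both bounds strictly positive and is symmetric in log space. The
interval construction used by the instrument vendor's software is not
published; the log-scale delta interval is the standard textbook choice
for digital PCR and the test suite validates it against a parametric
bootstrap and verifies ~95% empirical coverage at the study's typical
operating point (15,000 droplets, 50 copies/$\mu$l), where its exact
coverage is 95.1%.

For the CNV two propagation methods are implemented (`computeCnv()`):

* `log_delta` (default): independent channels on the log-ratio scale,
  $var(\ln CNV) = var(\ln\hat\lambda_t) + var(\ln\hat\lambda_r)$, bounds
  $CNV\exp(\mp z\sqrt{var})$.
* `bound_ratio`: the conservative ratio of opposite per-channel CI bounds,
  $CNV_{min} = 2\,c_t^{low}/c_r^{high}$ and
  $CNV_{max} = 2\,c_t^{high}/c_r^{low}$. Always at least as wide; kept as
  a configuration switch because published CNVmin/CNVmax error bars could
  have been produced either way.

Degenerate wells are flagged rather than fatal: a well with no positive
droplets carries the exact one-sided bound $[0, -\ln(\alpha)/n]$ on
$\lambda$ (the largest $\lambda$ that still produces zero positives with
probability $\alpha$), and an all-positive (saturated) well carries
$[-\ln(1-\alpha^{1/n}), \infty)$. Both can be rescued by merging further
wells before estimation; only `estimateLambda()` itself refuses a
saturated well, because no point estimate exists.

## Well merging

FFPE material is fragmented and often dilute. When one well leaves the
interval too wide, replicate wells of the same sample and channel are
pooled by summing accepted and positive droplet counts (`mergeWells()`),
which is exactly equivalent to one well with the combined droplet count.
Merging $k$ equal wells shrinks interval widths by about $1/\sqrt{k}$; the
test suite verifies the factor-2 shrinkage from quadrupling droplets.

## The calling rule

`classify()` maps a CNV estimate and the two channel concentrations to a
call:

1. **Conclusiveness.** Each channel must reach 5 copies/$\mu$l
   (`minConc`). Below that the sample is `inconclusive` with a
   `low_target_conc`/`low_reference_conc` flag. The floor is applied to
   both channels: the published rule states it for the target, but a ratio
   against an unmeasurable reference is equally meaningless.
2. **Dual threshold.** `duplicated` requires CNV $> 2.25$ *and*
   CNVmin $> 2$, both strict. When the two cutoffs disagree the sample is
   `inconclusive` with a `borderline` flag — never `non_duplicated` —
   mirroring how borderline clinical samples are sent back for more
   material.
3. **Low-CNV flags.** At adequate concentration, CNVmax $< 2$ flags
   `possible_deletion` and CNVmax $< 1.5$ additionally flags
   `low_cnv_artefact` (low CNVmax values have been shown by RNA-seq to be
   artefacts rather than fusions). With inadequate DNA a low CNV is not
   interpreted at all. Status remains `non_duplicated` in both cases.

The dual threshold is deliberately conservative. At a single
15,000-droplet well and 50 copies/$\mu$l the false-duplicated rate of the
rule on a diploid sample is about 1.5% (the CNV cutoff is then only ~2.2
standard errors above 2); merging four wells drops it to effectively zero,
which is why the pipeline and the acceptance checks operate on merged
wells for borderline material.

## The synthetic-data generator

No per-well droplet counts are publicly available for the study cohort, so
`simulateWell()`, `simulateSample()` and `simulateCohort()` generate
droplet data with known ground truth:

* **Partitioning noise**: pure binomial thinning,
  $n_{pos} \sim Binomial(n, 1 - e^{-cV})$ — the same ideal-Poisson
  assumption the quantification makes. Droplet-volume variation, rain
  (intermediate fluorescence) and PCR-efficiency kinetics are *not*
  modelled, so passing tests demonstrate statistical correctness of the
  estimator chain, not robustness to instrument-level artefacts.
* **Accepted droplets** per well are drawn log-uniformly over
  7,177–47,840, the observed per-assay range; only the range and median of
  the real distribution are known, so no finer distributional claim is
  made.
* **The duplex mixture**: target concentration
  $= c_{ref}\,(2+f)/2 \cdot degradation \cdot imbalance$. The shared
  `degradation` factor models FFPE fragmentation; it cancels in the CNV
  ratio but pushes samples below the 5 copies/$\mu$l floor, reproducing
  the inconclusive low-DNA cases. The target-only `channelImbalance`
  exists solely to exercise the deletion/artefact flags.
* **Cohort defaults** emulate the 36-sample study: 12 DNT, 2 PTO, 3 PDA,
  14 GG, 5 PA, duplication confined to DNT at prevalence 5/12
  (deterministic rounding, randomized assignment). Duplicated samples draw
  $f$ uniformly from 0.75–1, the clonal band where observed duplicated
  CNVs cluster (2.75–3); non-duplicated samples have $f = 0$ and their
  CNVs concentrate in 1.75–2.25. Reference concentrations are drawn
  log-uniformly over 2–200 copies/$\mu$l, spanning sub-threshold FFPE
  extractions to well-preserved material.

```{r cohort}
coh <- simulateCohort(seed = 1)
calls <- callSamples(coh$wells)
table(truth = coh$truth$expected_call, called = calls$status)
```

## Cohort analysis

`loadCohort()` ships a transcription of the study's 36-patient table.
`summarizeCohort()` reproduces its arithmetic — 5/12 duplicated DNTs
(41.7%), 13 BRAF V600E carriers, one FGFR1 missense carrier (G539R, itself
a duplicated DNT), zero overlap between BRAF V600E and FGFR1 alterations,
and a MAPK-altered fraction of 8/12 (66.7%) in DNT under the union
definition BRAF V600E ∪ duplication ∪ missense (silent changes such as
L548L are parsed but never counted as alterations).

`associationTest()` relates diagnosis to duplication status with Fisher's
exact test (DNT vs rest, 2×2) or a chi-square test (5×2). Inconclusive
calls are excluded by default (n = 35) or counted as negative
(`as_negative`); the published p-value's exact table variant is not
recoverable, so the function exposes all variants rather than asserting
one, and no multiple-testing correction is applied (two unadjusted tests
were reported).

```{r assoc}
associationTest(loadCohort())$p.value
```

## Numerical choices and problem sizes

* All computation is double precision; CSV output serializes doubles at 6
  significant digits so a fixed seed and configuration reproduce identical
  bytes.
* Cutoffs are strict inequalities; a sample exactly at a cutoff is not
  duplicated.
* Property-style checks in the test suite use 300–2,000 replicates (2,000
  wells for CI coverage, 500 replicates per setting for
  fraction-recovery and interval-shrinkage checks), sizes at which the
  binomial noise of the checked rates is well inside the asserted bands.
* `alpha = 1` collapses intervals onto the point estimate; `alpha` is
  shared by both channels and checked for equality before CNV
  propagation.

## Limitations

* Counts are taken as the reader software exports them; droplet gating and
  amplitude thresholding are out of scope.
* Only the two-channel duplex design is supported.
* The tumor-fraction model assumes a single monoallelic duplication; it
  reports `clamp(CNV - 2, 0, 1)` and does not deconvolve multi-allelic or
  subclonal mixtures.
* The synthetic generator's fidelity claims are limited to what the
  printed summaries constrain (droplet-count range, cohort composition,
  prevalence, concentration spread).
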