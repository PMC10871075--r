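---
title: "Genomic-wave correction and CNV screening: models and design choices"
author: "wavecnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-wave correction and CNV screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavecnv)
```

## The problem

SNP-array CNV calling reads copy number from the log R ratio (LRR), the
normalized log2 probe-intensity ratio that sits near 0 at two copies, drops
toward −0.66 under a heterozygous deletion and rises toward +0.4 under a
duplication. Overlaid on this signal is the *genomic wave*: a smooth,
chromosome-scale baseline drift that recurs across samples in a handful of
shared patterns, with a sample-specific strength. Waves of ±0.2–0.3 LRR are
comparable to the copy-number shifts themselves, so segmentation over raw
LRR fragments or misses real events and hallucinates others.

`wavecnv` implements a reference-based correction. The premise is that a
large cohort run on the same platform contains only a few distinct wave
shapes, so a new sample's wave can be estimated from the cohort rather than
from the sample itself (as GC-covariate regression would do).

## The model

**Reference fitting** (`wave_reference()`). Autosomes are tiled into 1 Mb
bins and each cohort sample is summarized by its per-bin mean LRR. Bins with
no markers in some sample, or whose across-sample standard deviation is at
or below 0.05, are dropped: a bin that looks the same in everyone carries no
wave information. The number of wave patterns `k` is chosen by the elbow of
the within-cluster distance curve — k-means is fitted for k = 2..20 and the
curve of summed point-to-centroid Euclidean distances (unsquared) is scanned
for the k maximizing the discrete second difference
`score(k−1) − 2·score(k) + score(k+1)`, the left edge padded with the k = 1
score and ties broken to the smallest k. The cohort is then clustered at
that k and, per cluster and per marker, the LRR mean `m_i` and standard
deviation `s_i` (n−1 divisor) across member samples are frozen. The model
never updates after fitting.

**Correction** (`correct_sample()`, or `predict(model, sample)`). A test
sample's bin features are computed on the model's informative bins and the
sample is assigned to the wave cluster holding the majority of its 5 nearest
reference samples (Euclidean; vote ties break to the nearest centroid, then
the smaller index). Its LRR is Z-scored per marker against the cluster's
frozen statistics, `z_i = (x_i − m_i)/s_i`, which cancels the cluster's wave
because the wave is part of `m_i`. Finally the Z-scores are mapped back to
the sample's own scale:

```
mlrr_i = (z_i − mean(z)) * sd(x)/sd(z) + mean(x)
```

so the corrected signal (the *modified LRR*, mLRR) has exactly the raw
signal's mean and SD and drops into any downstream caller unchanged.

**Segmentation** (`call_cnvs()`). A five-state HMM over copy numbers 0–4
decodes the (corrected) LRR by Viterbi. Transitions decay with inter-marker
distance `d`: `a(s→t | d) = ρ(d)·1[s=t] + (1−ρ(d))·prior[t]` with
`ρ(d) = exp(−d/D)`, so dense markers inherit their neighbour's state while
distant ones relax to the prior; chromosome boundaries reset to the prior.
Emissions are per-state Gaussians in LRR and, optionally, a genotype-mixture
BAF term with binomial weights in the marker's population B-allele
frequency. Calls are maximal non-diploid runs; their confidence is the
summed log-likelihood advantage of the called state over the diploid state.

**Screening** (`run_screen_pipeline()`). Per sample: QC (genotype call rate
≥ 0.98, autosomal LRR SD ≤ 0.2, both inclusive), correction, calling,
merging of same-direction calls separated by less than 200 kb, optional
union with an external caller's calls (union semantics, to reduce false
negatives; overlapping same-direction calls collapse with confidence = max
because the two confidence scales are not commensurable), strict filtering
(> 10 SNPs, > 50 kb, confidence > 50), and matching against a disorder
region database. A disorder is *detected* when direction (and expected copy
number, when the database gives one) match and the detected fraction — the
union of call∩region lengths over the region length — reaches the
configured threshold (default: any positive overlap).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 1e6 | bp | wave features; waves vary on multi-Mb scales, 1 Mb resolves them with stable bin means (~50 markers/bin at production density) |
| bin SD cutoff | 0.05 | LRR | exclusive bound; flat bins carry no wave signal |
| `k_min..k_max` | 2..20 | clusters | elbow search range |
| `nstart` | 10 | restarts | each restart kmeans++-seeded; see below |
| `sd_floor` | 1e-4 | LRR | keeps `z_i` finite when a cluster is constant at a marker |
| `knn_k` | 5 | neighbours | small odd count; majority is stable once clusters are coherent |
| HMM means/SDs | (−3, −0.66, 0, 0.40, 0.68) / (1, 0.28, 0.16, 0.21, 0.19) | LRR | canonical SNP-array per-copy-number values; fully configurable |
| `prior` | CN2 = 0.995 | — | CNVs are rare; remainder split evenly |
| `decay_distance` | 1e5 | bp | state memory ~ typical CNV marker spacing |
| `max_gap` | 2e5 | bp | strict merge bound for adjacent same-direction calls |
| filters | 10 / 5e4 / 50 | SNPs, bp, LLR | strict bounds; calls at the boundary are removed |

## Numerical choices

* One SD convention package-wide: the n−1 divisor.
* k-means restarts are kmeans++-seeded. With uniform random seeding, Lloyd's
  algorithm at k = 6 on 300 cohort samples converged, for roughly one seed
  in four, to a solution merging two planted wave patterns into one cluster
  and splitting another in two — the elbow still reported 6, but the merged
  cluster's per-marker SDs were inflated several-fold, silently attenuating
  Z-scores (and therefore CNV contrast) for every sample assigned to it.
  Distance-proportional seeding removes this failure mode at no measurable
  cost.
* The selection curve uses unsquared distances; the best restart is chosen
  by the same score, so the reported curve is consistent with the fit.
* Degenerate rescale: if `sd(z) < 1e-12` (a sample exactly matching its
  cluster means), mLRR collapses to `mean(x)` and the scale is recorded
  as 0.
* Missing values: unparseable numeric fields read as missing, never as
  errors; missing LRR yields missing z and mLRR; fully missing observations
  contribute log-likelihood 0 to every HMM state, so no-call markers are
  transparent to decoding.
* Moment matching for the rescale uses autosomal markers only (clusters are
  fitted on autosomes); the affine map is applied genome-wide.
* Ties in Viterbi break toward the diploid state, then the smaller copy
  number; vote ties in k-NN break by nearest centroid, then smaller index.
  Both rules make every code path deterministic.
* Coordinates are 1-based inclusive throughout; BED export is the only
  0-based half-open surface. Lengths are `end − start + 1`.

## The synthetic cohort

`simulate_cohort()` is the package's test bed and defines the study
conditions. Each of 6 wave archetypes is, per chromosome, a sum of 3
sinusoids with 3–20 Mb periods, rescaled so the peak |wave| equals
`wave_amplitude` (0.2 LRR by default) and redrawn until all pairwise
correlations are below 0.5. A sample is
`lrr = state_shift + s·wave + noise` with a per-sample amplitude factor
`s ~ N(1, 0.1)` and Gaussian marker noise (SD 0.15 by default; the
validation cohorts scale this to 0.05, matching low-noise production
arrays). BAF is drawn from the genotype mixture of the local copy number
with a cohort-level population B-allele frequency per marker, so
`compute_pfb()` recovery is testable. The genome is scaled to 22 chromosomes
of 10 Mb with 500 markers each (11,000 markers) so that a full
fit–correct–call–screen cycle over hundreds of samples runs in seconds to
minutes; validation uses reference cohorts of 50–100 samples per archetype
and test sets of 50–100 samples.

What the generator does *not* emulate: GC-tracking probe bias (the wave is
painted directly rather than arising from sequence composition), platform
batch effects, mosaicism, sex-chromosome dosage, and genotyping-error
structure. Passing tests therefore show that the estimator recovers the
model it assumes under realistic dimensions and noise — not that real-array
waves are exactly low-order sinusoids.

## Design decisions that were genuinely open

* **Bin-exclusion SD** is read as the across-sample SD of per-bin means: a
  bin is useful exactly when samples disagree in it. The within-sample
  reading would drop bins by local marker noise instead, which does not
  match the stated purpose of the rule.
* **The Z-score subscript is per marker** (mean/SD across cluster members at
  each marker). This is the only reading that cancels marker-wise waves; a
  per-bin reading would leave intra-bin structure untouched.
* **The rescale is per sample, global.** Per-chromosome rescaling would
  re-introduce chromosome-scale offsets through the local SD of z.
* **Reference members re-corrected use the frozen model including
  themselves** — no leave-one-out refitting. Simpler contract; with ≥ 50
  members per cluster the self-contribution is negligible.
* **Merging is direction-restricted** (a deletion never merges into a
  duplication) and the merged call takes the longer constituent's copy
  number and the summed confidence (log-likelihoods add over disjoint
  markers).
* **Pipeline order**: merge within caller, then union across callers, then
  filter. Filtering last means two sub-threshold fragments that merge into
  one adequate call survive.

## Known limitations

* The sample-specific wave amplitude is not modelled: correction removes the
  cluster's *mean* wave, leaving a residual `(s−1)·wave` for a sample with
  amplitude factor `s`. With amplitude jitter of SD 0.1 this residual is
  small relative to copy-number shifts (detection is unaffected in the
  validation runs) but it dominates the per-bin flatness of corrected
  CNV-free samples: roughly the top third of samples by |s−1| retain per-bin
  wave residuals above ~30% of their raw value. A per-sample amplitude
  regression against the cluster wave would remove it, at the cost of
  departing from the plain Z-score estimator this package implements.
* Because mLRR is rescaled to the raw signal's SD — which includes the wave
  variance — corrected signal carries proportionally inflated marker noise
  when the wave is large relative to noise. Downstream emission SDs are
  configurable for that regime.
* The elbow rule needs a curve that actually bends: on cohorts with one
  dominant pattern plus stragglers the second difference can be nearly flat
  and the selected k unstable; the curve is returned so this is visible.
* The HMM has no copy-neutral LOH state and no family-based calling; its
  confidence scale is its own (summed log-likelihood ratio) and is not
  comparable to external callers' scales, which is why the cross-caller
  union takes the maximum rather than the sum.
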