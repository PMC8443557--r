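---
title: "Methods: quantifying synaptic development across age, from currents to transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptic development across age, from currents to transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptodev)
```

# Scope and data model

`synaptodev` implements the quantitative analysis chain used to
characterize cortical synaptic development in a prenatal-exposure primate
model across three early postnatal ages (0M = birth, 3M = infancy,
6M = puberty), with an unexposed group (UE) and an exposed group (VPA):

1. **Miniature synaptic currents** — detection of mEPSCs/mIPSCs in
   voltage-clamp traces, per-cell frequency and amplitude,
   excitation/inhibition (E/I) ratios, long-term depression (LTD)
   magnitude, paired-pulse ratios.
2. **Spine morphometry** — head diameters from Gaussian fits of intensity
   profiles, volumes from a spheroid closed form, optical-density (OD)
   calibration, densities, and distribution comparisons.
3. **Vocalization** — call-type ratios and repertoire Shannon entropy.
4. **Transcriptomics** — per-age differential expression on a log2 matrix,
   DEG selection, probe collapse, and k-means clustering of logFC
   trajectories with AIC model selection.
5. **Integration** — a trajectory distance linking gene clusters to
   physiological phenotypes, and cross-species logFC concordance.

Every stage has a seeded synthetic-data generator that plants ground
truth, so the full pipeline is testable without any external download.
The common currency across stages is the **logFC trajectory**: the base-2
log ratio of the exposed-group value over the unexposed-group value,
ordered over the three ages — applied identically to gene expression and
to physiological parameters.

# Miniature-event detection

## Model of the recording

`gen_mini_trace()` simulates a voltage-clamp recording as a homogeneous
Poisson train of synaptic events convolved with a difference-of-
exponentials kernel (default rise 0.5 ms, decay 5 ms) in additive white
Gaussian noise, sampled at 10 kHz. The kernel is normalized so that its
peak equals the drawn amplitude, because the detection thresholds are
amplitude-based. Amplitudes are Gamma-distributed with a stated mean and
CV (default 15 pA, CV 0.3) — a positive-support distribution matching the
mean/CV parameterization; no published distributional parameters exist
for these currents in the marmoset cortex, so the defaults are documented
placeholders. Overlapping events sum linearly, so detector behavior under
overlap is a measured property rather than an assumption.

## Threshold conventions

Detection follows the field's two-threshold scheme: an **amplitude
threshold** in units of the baseline SD and an **area threshold** in units
of SD x ms, keyed by age and condition — 3 / 4.5 (0M mEPSC), 3 / 9
(0M mIPSC), 2 / 3 (3M and 6M mEPSC), 2 / 6 (3M and 6M mIPSC) — exposed in
`detection_params()`.

Two conventions deserve emphasis:

* **Baseline SD is measured on the raw trace.** A 50 ms window slides in
  10 ms steps and the minimum-SD window is taken as the event-free
  baseline, automating the manual choice of a quiet segment. Measuring on
  the raw trace makes the SD commensurate with the recorded noise
  amplitude. Detection itself runs on the 4–1000 Hz band-passed trace,
  whose in-band noise is never larger, so SD-unit thresholds act
  conservatively. (Measuring the SD on the filtered trace would shrink
  white-noise SD by roughly sqrt of the band fraction and turn a nominal
  2-SD threshold into ~1.5 effective noise SDs, at which band-limited
  Gaussian noise alone triggers several false events per second.)
* **The filter is a zero-phase 2nd-order Butterworth band-pass (4–1000
  Hz)** applied forward–backward, preserving event timing. The input mean
  is removed and ends are padded with one low-cut period of reflected data
  so start-up transients never leak into the output.

## Candidate definition and monotonicity

Candidates are local maxima of the rectified filtered trace that exceed
the amplitude threshold **and** whose topographic prominence also reaches
the amplitude threshold: a peak riding on a larger event's decay is not a
separate event unless the trace dips by at least the threshold between
them. Candidates closer than 2 ms keep the larger peak. Event boundaries
extend to the crossings of half the amplitude threshold around the peak
(sub-threshold hysteresis stabilizes area integration), and acceptance
requires the trapezoidal area between the boundaries, in SD x ms, to reach
the area threshold.

This design was chosen over the more obvious "contiguous supra-threshold
region" candidate because region-based definitions are not monotone: a
region containing two peaks can split into two accepted events when the
threshold is *raised*. With prominence-gated local maxima every criterion
tightens as either threshold rises, so the accepted-event count is
provably non-increasing in both thresholds — a property the test suite
checks on simulated traces, together with detection precision and recall
(both at least 0.9 at a planted mean peak of 8 noise SDs, 1 Hz, 60 s), the
false-positive rate on pure noise (at most 0.2/s at the 3M mEPSC
defaults; measured rate is essentially zero), and recovery of planted
event frequencies within 10% across 0.2–2 Hz.

Whether the original analysis measured amplitudes on the filtered or raw
trace is not documented; this package standardizes on the filtered trace.

## Derived physiology

`summarize_cells()` reports frequency (count/duration) and mean amplitude;
`ei_ratio()` forms per-cell mEPSC/mIPSC frequency ratios (miniature mode)
or peak EPSC (−65 mV) over peak IPSC (0 mV) amplitude ratios (evoked
mode). Amplitude, rather than charge, is used for evoked ratios to match
the miniature analysis; the source methods do not state which was used.
Zero-denominator ratios are flagged `NA` and excluded listwise from group
statistics. `ltd_magnitude()` renormalizes a field-EPSP series to the mean
of the (−10, 0] min baseline and returns the mean over [30, 40] min after
low-frequency stimulation; the result is invariant to uniform rescaling
and renormalization is idempotent. Group comparisons use Welch's t-test
per age with Holm–Sidak step-down adjustment across the age family
(`group_compare()`).

# Spine morphometry

Head diameters come from least-squares Gaussian fits
(`fit_profile_diameter()`), taking 2 sigma as the diameter — the
convention validated against electron microscopy for heads above 0.4 um.
The fit includes a constant offset: real profiles sit on nonzero
background staining, and the offset term costs nothing on clean data
(noiseless profiles are recovered to machine precision). Volume is the
spheroid closed form pi d_t^2 d_a / 6. OD calibration
(`calibrate_od()`) is a through-origin fit of volume against optical
density over reference spines — proportionality is the model, so no
intercept — and requires at least three references. References must have
diameter over 0.4 um and volume under 0.4 um^3; with two diameters per
spine the criterion is applied to the smaller (both axes resolvable).
Spine density is reported per um of dendritic segment (25–50 um from the
soma at 0M, 50–75 um at 3M/6M in the reference design); the per-um unit
choice is ours and is stated here because the source leaves it implicit.
Distribution comparisons use the two-sample Kolmogorov–Smirnov test,
exact when the smaller sample has at most 10 observations.

# Vocalization

Calls annotated with the seven-label vocabulary (ekk/cough, phee, trill,
tsik, twitter, phee-trill/trill-phee, other) are first merged into bouts:
consecutive calls with gaps of at most `max_gap_s` form one bout. The
default gap is 0.05 s — the convention is "no silent gap", and a small
tolerance absorbs annotation jitter. A bout mixing phee and trill takes
the compound phee-trill/trill-phee label, mirroring the annotation
vocabulary's compound category; otherwise the modal syllable wins, ties
to the first. Repertoire entropy is `-sum(r_i log2 r_i)` over call-type
ratios with 0 log 0 = 0, bounded by log2(7) bits. Whether the original
entropy was computed on raw calls or bouts is unstated; this package
computes on bouts by default and exposes `merge = FALSE`. Entropy is
computed per session and averaged per animal (`animal_entropy()`), the
granularity at which groups are compared.

# Transcriptomics

## Differential expression

The pipeline starts from a normalized log2 expression matrix (probe- or
gene-keyed) plus sample metadata (age, group, area); array normalization
is upstream of this package. Cortical areas are treated as exchangeable
replicates within each (age x group) cell, matching the reference
design's sample accounting. A gene is **expressed** if its mean log2
value across all samples exceeds 5 (strict); the mean rule is our
documented choice where the source is ambiguous between per-sample and
aggregate readings. Per age, Welch's t-test (two-sided) compares groups
per expressed gene and logFC is the difference of group means on the
log2 scale. Benjamini–Hochberg adjustment runs across all expressed,
non-degenerate genes **within each age** — per-age adjusted p-values are
what the downstream DEG rule consumes, and pooling ages would couple the
families. Zero-variance genes with equal means get p = 1; zero-variance
genes with unequal means have an undefined Welch statistic and are
flagged and excluded from the BH family with a logged count. A gene is a
**DEG** iff |logFC| > 0.4 and adjusted p < 0.05 at some age (both
strict). Multi-probe genes keep the probe with the smallest adjusted p
(minimum across ages; ties by raw p, then probe ID).

## Trajectory clustering and AIC

DEG logFC triples are clustered by k-means (k-means++ seeding, 50
restarts, fixed seed, best of restarts by within-cluster sum of squares)
for each k in 1..8, and k is selected by minimizing

    AIC(k) = RSS(k) + 2 * k * d,    d = 3 ages,

the standard k-means AIC in which each extra centroid (d parameters, 2d
penalty) must buy its keep in residual reduction; ties go to the smaller
k. We deliberately do not use the log-likelihood variant
`n d ln(RSS/(n d)) + 2 k d`: with hundreds of well-separated
trajectories, splitting one Gaussian cluster in half reduces the log term
by tens of units against a fixed penalty of 2d = 6, so that variant
over-selects k essentially always, and it is undefined at RSS = 0 where
noiseless data should make the selection trivial. The absolute-scale form
satisfies both requirements: on noiseless planted data AIC is strictly
increasing beyond the planted k, and on the default synthetic study the
modal selected k across 20 replicates equals the planted 3.

Cluster labels are deterministic: clusters are renumbered by ascending
centroid logFC at 0M, so cluster 1 is the most strongly downregulated at
birth (the synaptogenesis-like trajectory), and relabeling is invariant
to the clustering seed once the solution has converged.

## Enrichment

Overlap between DEG sets (e.g., up at 3M vs up at 6M) and gene-set
enrichment of clusters (e.g., ASD-associated or critical-period
catalogues) use the one-sided Fisher exact test against the universe of
expressed genes, reported as raw p-values — no correction across
enrichment tests, matching the reference analysis; the in-cluster and
universe ratios are returned for the standard baseline comparison.

# Integration

`trajectory_distance()` is the mean absolute difference between two logFC
triples — a metric, property-tested on random triples. The
cluster-by-phenotype `distance_matrix()` appends a "3r" row, the negation
of cluster 3's centroid, exposing phenotypes that track cluster 3 with
inverted sign; "3r" against a phenotype equals cluster 3 against the
negated phenotype by the symmetry of |.|.

Cross-species comparison restricts to genes with adjusted p below 0.1 **in
both** datasets (the stricter reading of "modulated genes"; a flag
switches to either-dataset filtering) and reports Spearman's rho with
average ranks and a two-sided p, exact for small tie-free samples.
Module-level concordance counts per-gene logFC sign agreements within
each co-expression module and tests the agreement fraction against 0.5
with a one-sided exact binomial test; genes with zero logFC are excluded
with a logged count. Per-gene sign agreement is the most direct reading
of "concordance of modulations tested by the binomial test"; the source
does not define the unit, so this choice is flagged here. External
symbols are harmonized through a two-column homolog map with
deterministic first-target resolution of one-to-many mappings.

# Synthetic-data generators as study conditions

Generator defaults encode the study design rather than convenient test
settings:

* **Expression**: 5000 genes, 10% DEGs split 40/30/30 across three
  clusters with planted logFC trajectories (−0.8, −0.2, −0.1),
  (−0.1, −0.7, −0.3), (0.1, 0.7, 0.3) — signs and timing mirroring the
  three observed cluster archetypes (early down; infancy down; infancy
  up) at magnitudes that clear the DEG threshold at realistic power —
  baseline N(7, 1.5^2), noise SD 0.3, and 8 samples per (age x group)
  cell, the scale of the reference arrays.
* **Traces**: 10 kHz, 60 s, 1 Hz events, 15 pA mean amplitude (CV 0.3),
  2 pA noise.
* **Calls**: i.i.d. categorical draws; a phee-dominated distribution
  reproduces the low-entropy phenotype.
* **Cross-species tables**: per-module sign concordance probabilities,
  e.g. 0.9 vs 0.5 to represent concordant and null modules.

All randomness flows from one master seed through labeled sub-streams
(`derive_seed()`), so adding a generator never perturbs existing
streams, and every generator is a pure function of its configuration.

What the generators deliberately do **not** emulate: probe-level array
artifacts and normalization residue, non-Poisson event clustering and
series-resistance effects in recordings, acoustic structure of calls
(labels are drawn, not classified), and LTD induction dynamics (LTD
series enter as normalized amplitude time courses). Passing tests
therefore demonstrate correctness of the estimators under the stated
generative models, not robustness to every artifact of real data.

# Numerical choices and degenerate inputs

* Planted-DEG recall is assessed among planted DEGs whose baseline clears
  the expression filter: DEGs are planted uniformly over genes, so ~9%
  fall below the log2 > 5 floor and are outside the analyzable universe
  by construction.
* Problem sizes used by the test suite: 20 replicate expression studies
  of 5000 genes for cluster-number and FDR/recall checks; 20 x 60 s
  traces per event-rate condition; exhaustive enumeration oracles up to
  n = 12 (Fisher, binomial), n = 8 (KS), n = 7 (Spearman).
* Exact-test fallbacks: KS switches to the asymptotic p when both samples
  exceed 10; Spearman uses the asymptotic p in the presence of ties.
* k-means candidates above the number of distinct trajectories are
  skipped; with a single distinct trajectory the selection degenerates to
  k = 1, as it should.
* Undefined ratios (zero denominators), empty call sessions, and
  insufficient cross-species gene sets are flagged (`NA` /
  `insufficient`) rather than silently dropped, and exclusions are
  counted in messages.
* Pipeline outputs are plain TSV (UTF-8, '.' decimal) written
  deterministically; the manifest records an MD5 per output, and a rerun
  with the same configuration and seed is byte-identical.

# Known limitations

* The detector is a threshold detector; template matching or
  deconvolution would outperform it at low SNR, but the point here is a
  faithful, characterized implementation of the two-threshold scheme.
* Kinetic properties of events (rise/decay fits) are out of scope, as are
  acquisition-side exclusions (series-resistance gates).
* The 2-sigma diameter convention is taken as given; its microscopy
  validation cannot be reproduced here.
* Group-level statistical power depends on per-animal raw data that are
  not part of the package; the package reproduces the estimators and
  their behavior under planted truth, not specific published group
  p-values.
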