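# synaptodev

Quantitative analysis of cortical synaptic development in a
prenatal-exposure primate model of autism spectrum disorder, across three
early postnatal ages (birth, infancy, puberty) and two groups (unexposed
`UE`, exposed `VPA`). The package is aimed at researchers who need a
tested, reproducible implementation of this analysis chain — from raw
voltage-clamp traces and imaging profiles to differential-expression
trajectories — together with seeded synthetic-data generators that plant
ground truth for every stage, so each estimator can be validated without
any external dataset.

## What it computes

**Miniature synaptic currents.** Events are detected on the band-passed
(4–1000 Hz, zero-phase Butterworth) trace with the field's two-threshold
scheme: a peak must exceed `a` baseline SDs in amplitude (and in
topographic prominence), and its integrated area between half-threshold
crossings must exceed `b` SD·ms, with `(a, b)` keyed by age and condition
— (3, 4.5) and (3, 9) for mEPSCs/mIPSCs at birth, (2, 3) and (2, 6)
afterwards. The baseline SD comes from the minimum-SD 50 ms window of the
raw trace. Downstream summaries: per-cell frequency and amplitude, E/I
ratios (mEPSC/mIPSC frequency, or evoked EPSC/IPSC peak amplitude), LTD
magnitude (baseline-normalized field EPSP over post-induction minutes
30–40), paired-pulse ratios, and Welch + Holm–Sidak group comparisons.

**Spine morphometry.** Head diameters are 2σ of Gaussian profile fits;
volume is the spheroid form πd²ₜd_a/6; optical density is calibrated to
volume by a through-origin fit on reference spines (diameter > 0.4 µm,
volume < 0.4 µm³); distributions are compared with the two-sample KS test.

**Vocalization.** Calls merge into bouts (compound phee-trill labeling),
and the repertoire entropy is −Σᵢ rᵢ log₂ rᵢ over call-type ratios.

**Transcriptomics.** From a log2 expression matrix: expressed genes
(mean log2 > 5), per-age Welch tests with Benjamini–Hochberg adjustment,
DEGs (|logFC| > 0.4 and p_adj < 0.05 at either age), probe collapse by
lowest p_adj, and k-means clustering of logFC trajectories over
k ∈ 1..8 with the cluster number selected by AIC = RSS + 2kd.

**Integration.** Gene clusters link to physiological phenotypes through
the trajectory distance Σₜ|logFC_syn(t) − logFC_gene(t)|/3 (including the
reversed-cluster-3 column "3r"), and model-vs-external comparisons use
Spearman correlation on genes with p_adj < 0.1 in both datasets plus
per-module sign-concordance binomial tests.

All logFC values are base-2 logs of the exposed/unexposed ratio, for
phenotypes and genes alike, which is what makes the integration step a
single distance in one space.

## Worked example

```r
library(synaptodev)

## simulate a 60 s mEPSC recording with planted events, then detect them
cfg <- sim_config(seed = 42, duration_s = 60, event_rate_hz = 1,
                  amp_mean_pa = 16, noise_sd_pa = 2)
rec <- gen_mini_trace(cfg)
events <- detect_minis(rec$trace, detection_params("3M", "mEPSC"))
summarize_cells(events, condition = "mEPSC", age = "3M", group = "VPA")
#>   frequency_hz mean_amplitude_pa n_events condition age group
#> 1    0.9666667          15.60692       58     mEPSC  3M   VPA
nrow(rec$truth)   # planted events
#> [1] 58

## synthetic expression study -> DEGs -> trajectory clusters
study <- gen_expression(expr_sim_config(seed = 42))
degs <- deg_analysis(study$matrix, study$metadata)
sum(degs$is_deg)
#> [1] 379
traj <- as.matrix(degs[degs$is_deg, grep("^logFC_", names(degs))])
cm <- cluster_trajectories(traj, seed = 42)
cm
#> <cluster_model> k = 3 selected by AIC over k in {1, 2, 3, 4, 5, 6, 7, 8}
#>   logFC_0M logFC_3M logFC_6M
#> 1   -0.826   -0.163   -0.092
#> 2   -0.083   -0.716   -0.274
#> 3    0.098    0.728    0.264

## link clusters to phenotype logFC trajectories
pheno <- rbind(spine_density = c(-0.75, -0.25, 0.1),
               ei_ratio      = c(-0.05, -0.6, -0.2))
round(distance_matrix(cm$centroids, pheno), 3)
#>    spine_density ei_ratio
#> 1          0.118    0.440
#> 2          0.502    0.074
#> 3          0.663    0.647
#> 3r         0.498    0.080
```

The detector recovered 58 events at 0.97 Hz against 58 planted (a 1 Hz
Poisson train realizes 58 here); the expression study recovers three
trajectory clusters whose centroids match the planted effects
(−0.8, −0.2, −0.1), (−0.1, −0.7, −0.3), (0.1, 0.7, 0.3); and the distance
matrix identifies cluster 1 as closest to the spine-density-like
phenotype and cluster 2 (with reversed cluster 3, "3r") as closest to the
E/I-ratio-like phenotype — the structure the integration step is designed
to expose.

A phee-dominated call distribution gives a correspondingly low repertoire
entropy:

```r
call_entropy(c(0.79, 0.05, 0.06, 0.02, 0.05, 0.02, 0.01))
#> [1] 1.236581    # bits; uniform over 7 types would be 2.807
```

The end-to-end pipeline (simulate → detect → fit → summarize → DEGs →
integrate) runs from one call and writes per-stage TSVs plus a hashed
manifest; identical config and seed give byte-identical outputs:

```r
run_pipeline(list(seed = 1, out_dir = "runs/demo"))
```

A thin command-line wrapper is in `inst/scripts/run-pipeline.R`.

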