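# avihrf

Event-related fMRI analysis for awake pigeons: species-specific
hemodynamic response function (HRF) estimation, Go/NoGo task GLMs with
permutation cluster inference, preprocessing and QC statistics, and
signal-detection-theory scoring of mandibulation behaviour — plus a
synthetic-session generator that emulates the whole scanning protocol so
the pipeline runs, and is tested, without any scanner data.

## Who this is for

Researchers doing task fMRI in birds (or any species whose hemodynamics
differ from the human default), and anyone who needs a desk-scale,
fully testable event-related analysis chain: the statistics here are the
standard neuroimaging toolkit (double-gamma HRF, voxelwise OLS, z > 3.1
cluster-extent FWE at p < 0.05), implemented so every stage can be
validated against a generator with known ground truth.

## The model

The BOLD response to a stimulus of duration *d* is a boxcar convolved
with a difference of two gamma densities:

    y(t) = [Π(t,0) − Π(t,d)] ⊗ A ( g(t; α₁, β₁) − c · g(t; α₂, β₂) )

with `g(t; α, β) = t^(α−1) β^α e^(−βt) / Γ(α)`. The package ships two
canonical parameter sets: the human default (α₁ = 6, α₂ = 16,
β₁ = β₂ = 1, c = 1/6) and the awake-pigeon best fit
(α₁ = 7.71, α₂ = 11.48, β₁ = 1.74, β₂ = 0.74, c = 0.25), estimated from
entopallium responses to 2-s colour stimuli. `fit_hrf()` re-estimates
all six parameters from a trial-averaged percent-signal-change curve by
bounded multi-start nonlinear least squares with linearized 95% CIs.

## Worked example

Characterize the pigeon HRF from five simulated runs (run 1 localizes
the responsive region with the human canonical HRF; runs 2–5 are
trial-averaged and fitted):

```r
library(avihrf)

canonical_hrf("pigeon")
#> HRF parameters: alpha1 = 7.71, alpha2 = 11.48, beta1 = 1.74 1/s,
#>   beta2 = 0.74 1/s, c = 0.25, A = 1

hdr_features(hrf_response(canonical_hrf("pigeon"), stim_duration = 2))
#> HDR features: H = 0.492 %, T = 4.94 s, W = 3.76 s

res <- run_pipeline("hrf", out_dir = tempfile(), seed = 42, n_runs = 5)
res$fit
#> Double-gamma HRF fit
#>   A         1.170  [1.097, 1.243]
#>   alpha1    8.020  [6.503, 9.536]
#>   alpha2   14.565  [5.361, 23.769]
#>   beta1     1.826  [1.453, 2.199]
#>   beta2     0.920  [0.322, 1.519]
#>   c         0.350  [0.260, 0.440]
#>   RSS 0.001944 over 16 points
```

Reading this: the modelled response to a 2 s stimulus peaks (`T`) about
4.9 s after onset — earlier than the ~5–6 s human response — with height
`H` in percent signal change and width `W` the full-width at
half-maximum of the continuous curve. The fit recovers the generating
pigeon parameters within its confidence intervals from one noisy
five-run experiment (α₁ = 8.02 against a generating 7.71, and so on);
the response-lobe parameters α₁ and β₁ are well determined while the
undershoot parameters are, as always with 30 s epochs, much less so.

A full task session — BOLD, events, motion, piezo log — can be
simulated, written to standard formats and analyzed from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "avihrf", package = "avihrf"))')
Rscript $CLI simulate --out session --seed 3
Rscript $CLI glm --bold session/bold.nii.gz --events session/events.tsv \
    --piezo session/piezo.csv --motion session/motion.par --out glm_out
Rscript $CLI behavior --events session/events.tsv --piezo session/piezo.csv \
    --out beh_out
#> SDT summary: hit rate 0.889, FA rate 0.083, d' = 2.540
#>   counts: Hit 64, Miss 8, CR 66, FA 6
```

The GLM step writes z maps (NIfTI), a cluster table (CSV: id, size,
peak z, peak coordinate) and the design matrix for audit; `behavior`
writes per-trial outcomes (Hit/Miss/CR/FA, reaction times) and the
session SDT summary.

## Package layout

- `R/hrf-core.R` — double-gamma model, canonical parameter sets, HDR
  features
- `R/synthetic-*.R` — session designs, BOLD/motion/piezo generators
- `R/preprocess-qc.R` — smoothing, scaling, high-pass, percent signal
  change, tSNR, MAD
- `R/hrf-fit.R` — localizer GLM, ROI selection, HDR averaging,
  nonlinear HRF fit, recovery experiment
- `R/glm-task.R` — design matrix, voxelwise OLS, contrasts, cluster
  permutation inference, group level
- `R/behavior.R` — mandibulation detection, trial classification, d′
- `R/io.R` — NIfTI/TSV/CSV/YAML readers and writers, end-to-end
  pipelines
- `vignettes/avihrf-methods.Rmd` — the methods vignette: model,
  assumptions, design decisions, limitations
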