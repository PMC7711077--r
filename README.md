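# migroup

Multi-subject modeling of time-frequency brain dynamics in two-class
motor-imagery (MI) EEG.

Imagining a left- or right-hand movement desynchronizes the sensorimotor
mu (~8-12 Hz) and beta (~16-28 Hz) rhythms over the contralateral
hemisphere. Individual subjects express this to very different degrees, so
claims about *common* neural dynamics require group-level statistics, not
single-subject maps. `migroup` implements the full chain for researchers
working with multi-subject MI cohorts:

* **Subject-level dynamics** on a shared time-frequency grid by three
  extractors:
  * filter-bank **CSP** — spatial filters maximizing the Rayleigh quotient
    `J(w) = w'Σ_l w / w'(Σ_l + Σ_l')w` per (band, window) cell, with
    log-variance features, pattern dynamics and cross-validated accuracy
    time-courses;
  * **wPLI** functional connectivity — the trial-ensemble weighted phase
    lag index `|E{|Im S| sgn Im S}| / E{|Im S|}` on complex Morlet
    coefficients, insensitive to zero-lag (volume-conduction) coupling,
    marginalized to per-channel node strength;
  * **ERD/S** maps — relative band-power change
    `ζ = (ξ − ξ̄)/ξ̄` against a pre-cue reference, with BCa-bootstrap
    significance masking.
* **Group inference** — per-subject Mann-Whitney channel-relevance
  thresholding, Storey-type positive-FDR correction pooled across
  subjects, support-aware aggregation, BCI-literacy clustering of subjects
  (Mahalanobis-trimmed accuracy predictor), and Gaussian-kernel similarity
  of group models under worst-subject desegregation.
* **A synthetic cohort generator** with planted ERD depths, phase-lagged
  coupling, 1/f background and per-subject effect-size jitter — every
  stage is testable offline with known ground truth.
* I/O: a plain-text trial container, a minimal GDF 2.x reader for
  competition-style recordings, topographic map export, and a
  `run_pipeline()` runner with a thin CLI (`inst/scripts/migroup.R`).

## Worked example

Generate a small synthetic cohort with a planted right-hand ERD at C3
(depth −0.5 in the 8-12 Hz band during the MI interval 2.6-4.6 s), extract
ERD/S dynamics, and build the group model:

```r
library(migroup)

strip <- c("C5","C3","C1","Cz","C2","C4","C6","CP3","CPz","CP4")
sp <- synth_spec(n_subjects = 5, n_trials_per_class = 20, n_channels = 10,
                 sample_rate = 128, montage = montage_bci2a(strip),
                 erd_plants = list(erd_plant("C3", c(8, 12), c(2.6, 4.6),
                                             -0.5, label = "right")),
                 subject_jitter = 0.2, seed = 42)
co  <- generate_cohort(sp)
fb  <- build_filterbank(8, 12, 4, 2)          # single mu band
dyns  <- lapply(co$subjects, erds_dynamics, fb = fb)
masks <- lapply(dyns, channel_relevance, interval = c(2.6, 4.6), alpha = 0.05)

p    <- do.call(rbind, lapply(masks, function(m) as.numeric(m$p)))
corr <- pfdr_correct(as.numeric(p), q = 0.05)
sum(corr$mask)
#> [1] 5        # exactly one channel per subject survives correction

qm <- matrix(corr$mask, nrow = 5)
gd <- group_aggregate(dyns, lapply(1:5, function(i) matrix(qm[i, ], nrow = 10)))
gd
#> <group_dynamics:erds> 5 subjects; 1/10 cells supported (>= 0.5 of cohort)

sel <- which(gd$positions >= 2.6 & gd$positions <= 4.6)
sort(rowMeans(gd$theta_group[, 1, sel, "right"], na.rm = TRUE), decreasing = TRUE)[1]
#>    C3
#> 0.922
```

The five discoveries are the planted channel in each subject; the group
model supports only the (C3, mu) cell and its activation peaks in the MI
interval. The subject-level relative power change recovers the planted
depth (`mean(dyns[[1]]$zeta["C3", 1, sel, "right"])` ≈ −0.49 against the
planted −0.5; the 1% shortfall is the in-band noise floor at the
generator's 20 dB SNR).

The same analysis runs end-to-end from a JSON configuration:

```sh
Rscript inst/scripts/migroup.R run --config cfg.json --out runs/demo
Rscript inst/scripts/migroup.R report --out runs/demo
```

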