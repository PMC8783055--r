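# fretpath

Kinetic analysis of single-molecule FRET (smFRET) trajectories of bacterial
RNA polymerase (RNAP)–promoter open-complex formation.

## The problem

When RNAP binds a promoter it first forms a closed complex (RP_C), then
melts the DNA around the transcription start site to form the
transcription-competent open complex (RP_O). With a donor/acceptor dye pair
flanking the transcription bubble (positions −15/+15), these conformations
produce distinct apparent FRET efficiencies

    E* = I_DA / (I_DA + I_DD)          (proximity ratio, uncorrected)

of roughly 0.20 (closed), 0.32 (a transient intermediate, RP_i) and 0.45
(open). Time-resolved E* trajectories recorded at 20 ms frames therefore
encode the opening pathway of each single molecule: whether the bubble
opened in one step (RP_C → RP_O) or via the intermediate
(RP_C → RP_i → RP_O), and whether the resulting open complex holds the
bubble open ("static") or keeps sampling a partially closed state
("dynamic", RP_O ↔ RP_ISO, E* ≈ 0.27/0.46).

`fretpath` implements the full analysis chain needed to resolve that
branched pathway, plus the simulation machinery needed to calibrate it:

* **Trajectory simulation** — Markov state paths with frame-wise geometric
  dwells (`p = 1 − exp(−Δt/τ)`), per-state Gaussian E* noise, optional
  intensity-channel rendering, ground truth retained.
* **HMM segmentation** — 1–3-state Gaussian-emission hidden Markov models
  (Rcpp Baum–Welch + Viterbi), with a left-to-right "chain" topology for
  bubble-opening mechanism models and an Allan-pinned fixed-variance mode.
* **Allan-deviation transition filter** — a decoded transition is accepted
  only if its E*-level step exceeds `multiplier ×` the trace's Allan
  deviation (multiplier 3 for post-formation dynamics, 2 for the first
  bubble opening).
* **Classification** — static vs dynamic (> 2 accepted transitions),
  mechanism selection (2- vs 3-state by likelihood + AIC + a mechanistic
  staircase check + an accepted middle-state dwell).
* **Kinetics** — censoring-aware dwell extraction, mono-/bi-exponential
  histogram fits (`y = A·exp(−t/τ)`) with a bi-exponential rejection rule,
  percentile-bootstrap lifetime CIs, exact (Clopper–Pearson) binomial CIs,
  two-sample t-tests on replicate fractions.
* **E\* histograms** — Gaussian component fits
  `y = Σ A/(w√(π/2))·exp(−2(E*−Ec)²/w²)` (area `A`, width `w = 2σ`,
  centre `Ec`).
* **Detection-efficiency calibration** — simulation-based efficiency of
  intermediate detection by true dwell length, false-positive rates,
  missed-event histogram correction, and the expected detection fraction
  under an exponential dwell model.

## Worked example

Simulate 25 dynamic open complexes (RP_ISO ↔ RP_O, E* 0.279/0.462, noise
SD 0.06, lifetimes 0.085 s / 0.56 s, 4–7 s trajectories) and run the
post-formation dynamics pipeline:

```r
library(fretpath)
ds <- simulate_dynamic_dataset(25, length_range = c(200, 350), seed = 7)
report <- run_pipeline(list(trajectories = lapply(ds, `[[`, "trajectory"),
                            analysis = "dynamics", seed = 7))
print(report)
#> fretpath run report: 25 trajectories
#>            metric successes trials fraction     ci_lo     ci_hi
#>  dynamic_fraction        24     25     0.96 0.7964831 0.9989878
#>   static_fraction         1     25     0.04 0.0010122 0.2035169
#>   state   n       tau     tau_se amplitude amplitude_se
#>  state1 174 0.1011634 0.00778734  44.49655     2.951582
#>  state2 180 0.5748244 0.04420234  32.48827     1.833888
```

24/25 complexes are recognised as dynamic. The fitted lifetimes recover the
simulation ground truth: `state2` (open bubble) 0.57 ± 0.04 s vs the true
0.56 s; `state1` (the transient RP_ISO excursion) fits at 0.10 s vs the
true 0.085 s — biased upward because sub-frame dwells go undetected, which
is exactly what the detection-efficiency correction
(`estimate_efficiency()` + `correct_dwell_hist()`) quantifies.

The pieces compose explicitly if you want to look inside one molecule:

```r
x <- ds[[1]]$trajectory$e_star
fit <- fit_hmm(x, k = 2, seed = 1)
print(fit)
#> 2-state Gaussian HMM: logL = 378.08, AIC = -742.16 (converged in 25 iter)
#>   means: 0.2861, 0.4618
#>   SDs:   0.0661, 0.0580
f <- filter_transitions(viterbi(fit, x), x, multiplier = 3,
                        allan = allan_deviation(x, m = 2, robust = TRUE))
classify_dynamics(f)
#> [1] "dynamic"
exact_binomial_ci(107, 147)   # the static-fraction arithmetic
#> 107/147 = 72.8% (exact 95% CI: 64.8-79.8%)
```

A command-line interface wraps the same steps:

```sh
Rscript -e 'fretpath::fretpath_cli()' simulate --preset dynamic-rpo --n 10 --out sim/
Rscript -e 'fretpath::fretpath_cli()' analyze  --input sim/ --seed 1
Rscript -e 'fretpath::fretpath_cli()' calibrate --preset paper-conservative --n 100
```

## Notes

The methods vignette (`vignettes/fretpath-methods.Rmd`) documents the
model, every tunable threshold, what the simulator does and does not
emulate, and known limitations — including the one deliberate gap: the
maximum-likelihood mechanism selector calls a spurious intermediate in ~7%
of two-state traces, several-fold more than the variational-evidence-based
reference analysis it stands in for; `select_mechanism(evidence = "bic")`
is the conservative alternative.
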