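# compgrowth

Analysis pipeline for **size-dependent compensatory growth** in
proliferating mammalian cells, from per-cell feature tables of fixed-cell
high-content imaging (integrated DNA, FUCCI/Geminin, total-protein dye,
K48-polyubiquitin immunostain) and nuclear-area time-lapse tracks. It is
aimed at quantitative cell biologists asking how protein synthesis and
degradation scale with cell size.

The core measurement is the K48-polyUb clearance rate,

> ΔK48-polyUb = K48-polyUb(+CFZ, 30 min) − K48-polyUb(−CFZ),

the excess polyubiquitinated protein accumulated during a 30-minute
proteasome blockade, estimated from every cross pair of blocked and
vehicle replicate wells. The scientific question is whether this flux
scales *superlinearly* with cell size — fold changes in ΔK48-polyUb
exceeding fold changes in size (excess ratio = fold ΔK48 / fold size > 1)
— which is the signature of compensatory degradation in overgrown cells,
alongside:

* automatic cell-cycle staging from the DNA and log-Geminin
  distributions (2N/4N density cuts, Geminin baseline cut);
* a continuous cell-cycle axis ℓ from the density ridge of the
  DNA × log-Geminin distribution, with nearest-point projection and
  (ℓ, size) summaries;
* nascent vs long-lived decomposition of the flux by translation
  blockade, and CHX-chase size-loss slopes for small vs large cells;
* growth-rate and cycle-length inference from bulk time courses
  (τ = ln2/α from exponential count fits; ν = (1/N) dM/dt) and from
  smoothed nuclear-area track derivatives.

Because the estimators need known truth to be validated, the package
includes a first-class agent-based simulator (sizer-gated G1 exit, timer
S/G2+M, mass dynamics dM/dt = [s − d₀(M/M_target)^β]·M, an explicit
K48-pool, perturbation arms for CDK2/CDK4-6/mTOR/proteasome inhibition)
that generates snapshot populations, tracks and bulk curves with
ground-truth sidecars.

## Worked example

```r
library(compgrowth)

cfg  <- sim_config(seed = 1)                       # RPE1-like defaults
ctrl <- simulate_experiment(cfg, "control")        # paired ±CFZ wells
cdk  <- simulate_experiment(cfg, "CDK2i")          # CDK2-inhibited arm

d_ctrl <- delta_k48(ctrl[ctrl$cfz_flag, ], ctrl[!ctrl$cfz_flag, ])
d_cdk  <- delta_k48(cdk[cdk$cfz_flag, ],  cdk[!cdk$cfz_flag, ])
scaling_analysis(d_ctrl, d_cdk, n_boot = 1000, seed = 1)
```

```
Flux/size scaling: fold delta-K48 = 1.331, fold size = 1.011, excess ratio = 1.316 (P[<=1] = 0.000, 1000 resamples)
```

The CDK2-inhibited cells clear ~33% more K48-polyUb while their median
size is ~1% larger: a strongly superlinear flux/size relationship (the
wells-bootstrap probability of proportionality is < 0.001). Running the
same comparison on the CDK4/6-inhibition arm gives fold changes of 1.18
(flux) vs 1.23 (size) — an excess ratio of 0.96, i.e. proportional
scaling: a larger size *target* alone does not trigger compensatory
degradation.

The full narrative analysis lives in `analysis/01_simulate.R` …
`analysis/04_growth.R`; each script states what it finds and writes its
tables under `results/`. For example `04_growth.R` prints, for the same
seed family:

```
control: alpha = 0.0293 /h, tau = 23.7 h
CDK2i:   alpha = 0.0262 /h, tau = 26.5 h
growth_slow / null0 rate ratio: 0.790 (planted 0.79)
G1 extension: 3.52 h (95% CI 2.66-4.39), p = 4.3e-14
```

— the planted −21% growth-rate multiplier and the ~+32% G1 extension of
the CDK2i arm are recovered from the track pipeline.

## Layout

```
R/                     estimators and simulator (every analysis step)
analysis/01..04_*.R    narrative workflow: simulate, stage/project,
                       turnover, growth
scripts/acceptance.R   end-to-end recovery statistics (JSON out)
tests/testthat/        unit, property and acceptance tests
vignettes/             methods vignette: model, algorithms, choices
```
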