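---
title: "Methods: size-dependent compensatory growth from high-content imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-dependent compensatory growth from high-content imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compgrowth)
```

## The problem

Proliferating mammalian cells keep their size distribution remarkably
stable. Two mechanisms contribute: a *size checkpoint* that delays
cell-cycle progression (chiefly G1 exit) in small cells, and a
*compensatory growth slowdown* in cells that have overgrown. This package
implements the quantitative analysis pipeline for the second mechanism as
measured by fixed-cell high-content imaging (integrated DAPI for DNA
content, a Geminin-degron FUCCI reporter for cycle position, an
amine-reactive succinimidyl-ester dye, "SE", for total protein mass,
K48-linked polyubiquitin immunostaining for proteasome-targeted protein)
and by nuclear-area time-lapse tracking.

The central measurement is the **K48-polyUb clearance rate**
(delta-K48-polyUb): wells are fixed with or without a 30-minute proteasome
blockade (carfilzomib, CFZ); the excess K48-polyUb accumulated in blocked
wells estimates the amount of polyubiquitinated protein that would have
been degraded in those 30 minutes. The scientific question is how this
flux scales with cell size: proportional scaling means a constant per-mass
degradation rate, *superlinear* scaling (flux per unit mass rising with
size) is the signature of compensatory degradation.

Because the original imaging data exist only as per-figure source files,
the package pairs every estimator with a generative simulator
(`sim_config()`, `simulate_snapshot()`, `simulate_tracks()`,
`simulate_bulk()`) whose ground truth is known exactly; all statistical
claims in the test suite are recovery statements against that truth.

## The generative model

Each cell carries a mass $M$ (arbitrary units; the quantity the SE stain
integrates), a cycle phase in $\{$G1, G1/S, S, G2+M$\}$, a K48-polyUb pool
$U$, and a Geminin reporter level. Mass follows

$$\frac{dM}{dt} = \left[ s - d_0 \left(\frac{M}{M_\mathrm{target}}\right)^{\beta} \right] M,$$

integrated by forward Euler at $\Delta t = 0.05$ h. The synthesis term
$sM$ encodes size-proportional protein synthesis (ribosome content scales
with size); the degradation term is proportional to mass when $\beta = 0$
and superlinear when $\beta > 0$ — the compensation exponent is the
simulator's handle on compensatory degradation. The simulator places
$\beta$ on the degradation rate constant; the alternative (compensation
acting on ubiquitination supply) would be observationally equivalent for
every readout in this package and is not separately modeled.

Phase structure:

* **G1 exit is sizer-gated**: hazard
  $\lambda(M) = k \cdot \max(0, M/M_\mathrm{target} - \theta)$ with
  $k = 2.7\,\mathrm{h^{-1}}$ and $\theta = 0.85$. Small newborns must
  grow before the hazard engages — "smaller cells spend longer in G1".
* **G1/S, S and G2+M are Gamma timers** (means 1.5, 7 and 3.5 h; CVs
  0.2, 0.15, 0.15). DNA content ramps linearly from 2N to 4N through S;
  Geminin sits at a baseline through G1 and accumulates linearly from the
  G1/S commitment.
* **Division** halves mass with a daughter-fraction CV of 5%; the engine
  follows one random daughter (population statistics are
  lineage-sampled), except for bulk time courses where both daughters are
  kept so counts grow.

With the defaults the control population self-organizes to a ~10.5 h G1
before the Geminin rise and a ~22.7 h cycle — an RPE1-like epithelial
line. Mass balance then forces the net growth rate to
$\ln 2 / \tau \approx 0.03\,\mathrm{h^{-1}}$, which the defaults
($s = 0.055$, $d_0 = 0.025$, $\beta = 0.3$) satisfy at
$M \approx M_\mathrm{target}$.

The K48 pool obeys $dU/dt = W - k_U U$ with ubiquitination flux
$W = d_0 (M/M_\mathrm{target})^{\beta} M$ and clearance constant
$k_U = 2\,\mathrm{h^{-1}}$ (pool half-life ~20 min). Under CFZ the
clearance stops and the pool accumulates at $W$, so a 30-minute blockade
plants an excess of $W \times 0.5$ h — the quantity the
delta-K48 estimator is built to recover. A planted fraction (40%) of $W$
draws from nascent proteins and disappears under translation blockade
(CHX); CHX also zeroes synthesis and pauses cycle progression (no cyclin
synthesis, no progression), which is what makes the CHX chase a clean
degradation assay.

Readouts add multiplicative lognormal noise: CV 3% for integrated DNA
(DNA histograms from imaging cytometry are tight; this is what makes
2N/4N gating workable in practice) and CV 8% for all stains and
immunostains. The nuclear-area proxy used by the track simulator is
$\mathrm{area} = 100\,M^{2/3}$ (an area is a two-dimensional section of a
volume-like mass; the estimators tested are insensitive to the exact
exponent) with 5% per-frame noise at 15-minute frames.

### Perturbation arms

Arms are parameter overlays on the control model
(`default_perturbations()`):

| arm | mechanism | intent |
|---|---|---|
| `CDK2i` | G1-exit set point x1.07, $\beta = 0.8$, degradation activation x1.13, G1/S flux x1.4, onset ramp 8-24 h | CDK2 inhibition: longer G1 (+~32%), compensatory degradation with delayed onset, G1/S hyperactivity |
| `CDK4/6i` | whole size target x1.35 | larger adopted target; flux scales proportionally with the new size |
| `mTORi` | synthesis x0.8, $\beta = 0.8$ confined before G1/S | translation inhibition; size compensation concentrated pre-G1/S |
| `growth_slow` | net mass flux x0.79, $\beta = 0$ | planted -21% growth rate for recovery tests |
| `null0` | $\beta = 0$ | exactly proportional degradation (null for scaling tests) |
| `G1S_hyper` | G1/S flux x1.4 | planted G1/S degradation excess |
| `barasertib`, `JNJ` | G2+M / S timer x1.5 | mitotic and S-phase delay arms |
| `bortezomib` | clearance off, dark MV151 | proteasome inhibition control |

The `CDK2i` arm distinguishes the *sizer set point* (raised: cells commit
to S at a larger size, which is the checkpoint effect of CDK2 inhibition)
from the *degradation reference size* (unchanged: cells now sit above the
size their degradation machinery regards as the target, so compensation
engages). The CDK4/6 arm moves both together, which is why its flux/size
scaling stays proportional — reproducing the control contrast between the
two drugs. The three CDK2i numbers (1.07, 1.13, 1.4) were calibrated once
against the arm's declared phenotype — mean G1 duration ~32% longer than
control, clearance flux ~30% above control at a near-unchanged mean size
— and are part of the study conditions, not free parameters. The
activated components ramp in linearly between 8 and 24 h of treatment,
reflecting that compensation follows the gradual build-up of excess mass
rather than the immediate drug effect; snapshots at 24 h see the fully
developed state.

### What the simulator does not emulate

No pixel-level image formation, no segmentation errors beyond the noise
CVs, no spatial or density effects, no mechanistic p38/CDK signaling. Two
structural simplifications matter when interpreting test results. First,
fixed-cell populations are *lineage-sampled* (one daughter followed), so
phase occupancies are duration-weighted, and finite populations keep
slowly decaying cohort waves — phase fractions fluctuate a few percent
between snapshots, as they do between real wells seeded from a common
stock. Second, the sizer-gated G1 exit erases birth-size memory at the
G1/S transition: post-G1/S contrasts classified by *birth* size are null
by construction in this generator, and the corresponding comparisons are
therefore exercised on constructed track fixtures rather than simulator
output. Passing tests demonstrate estimator correctness under these
conditions; they do not certify behavior under, e.g., strong
density-dependence or segmentation artifacts.

## Staging

`detect_thresholds()` finds the DNA cuts in two passes. A
Silverman-bandwidth KDE locates the two dominant modes and checks
bimodality (unimodal input is refused). The density is then re-estimated
with a bandwidth of 1/40 of the 2N-4N mode gap — Silverman's rule, tuned
for unimodal smoothness, is far too wide to resolve a sharp 2N peak
sitting on an S-phase ramp. On the refined density each cut is the
smaller (resp. larger) of the global inter-mode valley (tie-break:
closest to the mode midpoint) and the *flank-reflection boundary*: the
mode's uncontaminated outer flank is mirrored across the component center
as an estimate of the pure component density, and the cut is placed where
that estimate falls to half of the total — the Bayes crossing against
whatever fills the inter-mode region. Two refinements keep this stable:
the component centers are re-estimated from multi-point flank geometry
(the raw mode position is dragged by S-phase contamination), with the 4N
center pinned at exactly twice the 2N center (DNA doubling — the prior
every DNA-histogram model shares); and the reflection residual must clear
three times the KDE's local sampling error, so that clean well-separated
modes (where tiny center errors would otherwise manufacture a spurious
boundary) fall back to the valley. The construction is fully
scale-equivariant.

The Geminin cut applies the same machinery to log intensity; when the
accumulating mode is not separable the cut falls back to the baseline
mode plus three one-sided MADs, and with no usable signal at all the cut
is marked unavailable and early G1 / G1-S are merged. `assign_stage()`
applies the DNA rule first and lets Geminin split only the 2N class; M is
not separated from G2.

At default noise the calls agree with simulator truth on ~91-92% of cells;
the residual disagreement is dominated by genuinely ambiguous early- and
late-S cells whose DNA content is within noise of 2N or 4N — the oracle
(best fixed cuts with known labels) reaches ~92% on the same data.

## The continuous cycle axis

`fit_ridge()` estimates a 2-D KDE of (DNA, log Geminin) on z-scored
channels (Silverman bandwidth per channel, 200x200 grid) and traces the
density ridge exploiting the one monotone feature of the system: the
Geminin reporter only accumulates along cycle progression. From the
global density mode the tracer walks the log-Geminin axis row by row in
both directions, taking each row's conditional density mode within a
continuity window (8% of the grid) around the previous position. Rows
below a data-driven density floor (2nd percentile of per-cell density)
are bridged — the G1 baseline blob and the rising-Geminin arm are
separated by a genuine low-density gap, because a linear accumulation
spreads thin at the bottom of a log axis — and trailing sub-floor rows
are trimmed so the endpoints stay anchored in the early-G1 mode and the
4N/high-Geminin region. Three passes of local averaging (principal-curve
style) smooth the polyline; arc length normalized to [0,1] defines
$\ell$. Degenerate inputs are rejected post hoc: if the median
perpendicular distance of the data to the curve exceeds twice the
bandwidth there is no simple ridge (rotationally symmetric blobs), and if
more than 30% of cells sit beyond six bandwidths the ridge is
disconnected from part of the data and a larger bandwidth is suggested.

$\ell$ is arc length, not wall-clock time: it orders cycle positions but
does not measure phase durations. Projection (`project_cells()`) is
nearest-point on the polyline in the standardized units used for the fit
(the channels have arbitrary, unequal scales; z-scoring is this
package's choice and is flagged for sensitivity analysis); ties resolve
to the smaller $\ell$. `ell_size_heatmap()` bins cells on $(\ell,
\log \mathrm{size})$ and reports the joint frequency plus a per-bin
feature mean (optionally per unit size), masking bins with fewer than 20
cells.

## Turnover statistics

`delta_k48()` pairs every blocked well with every vehicle well of the
same condition and fixation time. Within wells the default summary is the
median (robust to segmentation outliers); across the cross pairs the
central estimate is the mean, which is algebraically the difference of
arm means. Cells within a well are not independent, so the CI treats the
well as the replication unit: the t interval over pair values uses a
conservative effective sample size (min wells per arm, minus one) — cross
pairs must not masquerade as independent replicates. Identical arms give
zero with a CI spanning zero; a constant staining background cancels
exactly (location equivariance).

`scaling_analysis()` forms fold changes of clearance and of median size
against control and their ratio (the excess ratio; 1 = proportional
scaling). Significance of superlinearity comes from resampling wells
within each of the four well sets — with nine wells per arm and skewed
ratios, a bootstrap is more trustworthy than a delta-method normal
approximation. `g1s_deviation()` fits clearance against median size over
G1, S and G2+M and reports the G1/S residual; its CI is residual
&plusmn; t x bootstrap SE (percentile intervals under-cover at nine
wells).

`chx_decomposition()` splits clearance into CHX-sensitive (nascent) and
CHX-insensitive (long-lived) shares. One caveat is intrinsic to the
assay, not the estimator: during the hours of translation blockade the
treated cells stop growing while the reference cells continue, so in a
growing population the measured CHX-sensitive share folds in a
growth-divergence component of a few percentage points. The planted-share
recovery test therefore runs in a quiescent configuration (synthesis
balancing degradation, checkpoint off) where the decomposition is exact;
on growing populations the reported share should be read with that
caveat.

`chx_chase_slopes()` tracks the median size of the smaller-20% and
larger-20% classes (recomputed per timepoint, per stage) as a fraction of
the class median at time zero, with least-squares slopes over the chase.
Because CHX arrests the cycle in the simulator, the chase isolates
degradation; the large-faster contrast is clearest in G1, where the
relative size spread is widest.

## Growth inference

Cycle length comes from an unweighted least-squares fit of log counts
against time (count noise is multiplicative), $\tau = \ln 2 / \alpha$
identically, CI from the regression SE. The per-cell bulk growth rate is
$\nu_t = (1/N_t)\, dM_t/dt$ with $M_t$ = mean size x count and central
differences (one-sided at the ends).

Track rates smooth the area series with a 5-frame moving average (~75
min; the window is a package choice — sensitivity across windows 3/5/9 is
a tested property, with rate changes under 2%) and differentiate
centrally; the first and last six frames of each cycle are excluded
(nuclear envelope breakdown and reformation), and too-short tracks are
excluded with a logged reason. Rate *ratios* between conditions are
computed on specific rates (derivative over area) so the arbitrary area
scale cancels; comparisons stay on the nuclear-area proxy throughout and
are never converted to mass. Phase durations use Welch's t-test
(unequal variances between arms is the safe default). Aligned growth
curves shift tracks so the chosen anchor (birth or G1/S) sits at zero,
snap to the common frame grid, and mask grid points with fewer than ten
tracks.

## Numerical choices and scales

Euler at $\Delta t = 0.05$ h (first-order convergence is a tested
property); KDE grids 200x200 (pseudo-time is stable under grid doubling
for 95% of cells within 0.02); all seeds flow from a single integer in
`sim_config()`, and identical seed + configuration reproduces output
tables byte for byte. The test suite and the acceptance script run at
desk scale: snapshot experiments of 9+9 wells x 60-300 cells, 100-200
replicate simulations per statistical claim, 100 tracks per arm, a
40,000-point fixture for the ridge-recovery check — sizes chosen so each
claim has the replication it needs while the whole suite remains a
few-minute run.

## Known limitations

* The compensation exponent acts on the degradation rate constant; the
  ubiquitination-supply alternative is observationally equivalent here
  but could be distinguished with linkage-resolved or pulse-labeled data.
* The G1/S class follows the Geminin-high definition strictly; late-G1
  Geminin-low large cells stay in G1.
* Population snapshots are lineage-sampled and carry cohort waves;
  bulk mean-size trajectories inherit a few percent of wobble, so
  transient size dynamics (e.g. the early rise under CDK2 inhibition)
  are visible but not sharply testable at desk scale.
* The sizer fully erases birth-size memory by G1/S; real checkpoints are
  partial, so birth-size-classified post-G1/S contrasts in real data will
  sit between this generator's null and the no-checkpoint extreme.
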