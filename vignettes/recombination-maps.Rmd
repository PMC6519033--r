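---
title: "Estimating variable recombination maps with rhomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating variable recombination maps with rhomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Meiotic recombination in many species is concentrated in narrow (1–2 kb)
hotspots separated by long cold regions. Given a sample of phased
haplotypes, `rhomap` estimates the population recombination rate
$\rho = 4N_e r$ per base pair as a piecewise-constant function along the
sequence, and calls hotspots against the inferred background rate. The
estimator is designed to be fast, to work for small samples (down to ~10
haplotypes), and to be *parsimonious*: the number of rate changes it
reports is controlled by an explicit type-I error level.

## The two-stage model

**Stage 1 — per-segment regression.** The sequence is cut into short
segments (1 kb by default). For each segment a vector of summary
statistics is computed from the biallelic segregating sites:

| statistic | meaning |
|---|---|
| `haps` | distinct haplotypes / (n · L) |
| `wath` | Watterson's $\hat\theta$ per bp, $S/(a_n L)$ |
| `apwd`, `vapw` | mean and variance over haplotype pairs of per-bp Hamming distance |
| `hahe` | mean per-site heterozygosity (with $n/(n-1)$ factor) |
| `nss` | fraction of adjacent site pairs compatible under the four-gamete test |
| `maxchi` | max 2×2 $\chi^2$ of mismatch counts left/right of any split, over haplotype pairs |
| `tajd` | Tajima's D (demography-aware models only) |

A Box–Cox transform $t(\rho) = (\rho^\lambda - 1)/\lambda$ stabilises the
response variance, and an additive model
$t(\rho_i) = f_1(z_{i1}) + \dots + f_q(z_{iq})$ with cubic regression
splines $f_j$ (fitted by `mgcv::gam` with GCV smoothing) is trained on
coalescent simulations of constant-rate segments: sample sizes
$\{10, 16, 20\}$, lengths $\{1, 2, 3\}$ kb, 111 values of $\rho$
equidistant in $[0, 0.1]$, $\theta = 0.01$ — 999 scenarios per replicate,
two replicates by default. $\lambda$ is chosen by profile maximum
likelihood over a grid (0.05–1 in steps of 0.05) on the training data and
then frozen; $\rho = 0$ rows cannot enter the transform and are excluded
from fitting (predictions may still return 0 through flooring).
For portability each fitted smooth is distilled onto a dense
interpolation grid spanning the training range of its predictor; all
predictions are evaluated through these tables, which makes the
JSON-serialised model file (`save_rho_model`/`load_rho_model`)
reproduce predictions exactly. Predictors outside the training hull are
clamped to it with a warning.

**Stage 2 — segmentation.** The per-segment back-transformed rates form a
noisy, approximately Gaussian track. A simultaneous multiscale
change-point estimator returns the piecewise-constant fit with the
*fewest* jumps such that on every interval inside a constant block the
local likelihood-ratio statistic stays below a critical value calibrated
by Monte-Carlo so that $P(\text{too many jumps}) \le \alpha$
(default $\alpha = 0.05$). The noise scale is estimated robustly (MAD of
first differences / $\sqrt 2$) unless supplied. Among minimal-jump fits
the maximum-likelihood one is returned, ties broken towards leftmost
change points; block means are clamped into the multiscale confidence
interval, which is also reported as a band.

## The bias correction

The raw regression estimates are *attenuated*: 1 kb segments carry little
linkage information at small $\rho$, so the fit regresses towards the
training mean — low rates are overestimated on average, high rates
underestimated. A correction that conditions on the estimate (a direct
quantile regression of truth on estimate) cannot undo attenuation: under
the training prior the conditional quantile of the truth given a raw
estimate of 0.02 is itself far above a true background of 0.001.

`rhomap` therefore uses a classical **inverse calibration**: on an
independent calibration replicate it fits, for each quantile label $q$,
the $(1-q)$-quantile curve of the transformed *estimate given the truth*
(a smooth monotone curve: check-loss IRLS on a cubic spline basis,
isotonised, stored as a table; a linear variant is available) and
*inverts* it at application time. By the usual quantile/confidence-bound
duality, inverting the upper $(1-q)$ curve yields a lower $q$-bound for
the true rate given the estimate, so smaller labels give more
conservative (smaller) rates. Empirically the background specificity PCB
is maximal at $q = 0.25$ and decreases through $q = 0.5$ while hotspot
sensitivity PCH moves the other way; $q = 0.35$ is the default
compromise. The calibration is fitted on 1 kb calibration segments by
default so that the curve's spread matches the noise level of the
segments the pipeline actually scores.

Because the inverted curve is steep at the low end, applying it to every
noisy segment estimate amplifies noise. The pipeline therefore segments
the **raw** rate track first and applies the calibration to the fitted
block means, which average away most of the segment-level noise
(`correction_stage = "block"`, the default; `"segment"` applies the
correction per segment before segmentation, matching the order one would
use with a gentler correction).

## Hotspot calls and evaluation

The background rate is estimated as the mean of all per-segment estimates
strictly below their median — deliberately downward-biased — and hotspots
are maximal runs of map blocks exceeding `factor` (default 5) times that
background. `evaluate_map()` computes: RMSE of the per-bp rate on a
1,000-point equidistant grid; WRMSE over estimated blocks weighted by
block length; PCH, the proportion of true hotspots intersecting a
detected hotspot region; PCB, the analogue for background; and
AP = (PCH + PCB)/2.

## Synthetic data and what it does (not) show

All training and evaluation data come from the built-in coalescent
generator (msprime through a bundled Python helper; haploid samples with
reference size 0.5 so that engine rates equal $\rho$ and $\theta$
per bp directly). Three designs are provided:

* constant-rate grids (`constant_rate_grid()`, the 999-scenario design);
* single-hotspot "simple" maps and the 30 kb two-hotspot map
  (`table2_truth_map()`: hotspots at 10 and 20 kb, 1 kb long,
  intensities 20 and 35);
* the 1 Mb "natural" maps (`natural_hotspot_map()`): 15 hotspots with
  centres at $L\,i/16$, intensities equidistant between 8- and 40-fold,
  lengths alternating 1 and 2 kb — 31 true blocks. The "evenly
  distributed" placement and the intensity/length assignment are fixed
  conventions chosen once, since only the ranges are prescribed.

The bottleneck-growth demography has relative sizes
$\eta = 100 / 0.1 / 1$ on epochs $(-0.5, 0]$, $(-0.58, -0.5]$,
$(-\infty, -0.58]$ in coalescent units of $2N_e$ generations, with the
ancestral epoch as the reference size defining $\rho$ and $\theta$.
Demography-aware training reruns the identical pipeline on data simulated
under this history, adds Tajima's D as a covariate, and reuses the
neutral model's $\lambda$.

Passing tests on these designs show that the estimator recovers the rates
it was trained for under the coalescent with the stated demography. They
do not demonstrate robustness to gene conversion, missing data,
genotyping error, variable mutation rate along the sequence, or
demographies other than the one trained on; a misspecified $\theta$
(data diversity 2x away from the training value) measurably degrades
accuracy.

## Numerical choices and problem sizes

* Multiscale threshold: penalty $\sqrt{2\log(en/\ell)}$ per interval of
  length $\ell$; all-interval system; Monte-Carlo calibration (1,000
  replicates by default, cached per configuration, seeded).
* Dynamic program: $O(n^2)$ over block start/end pairs with incremental
  feasibility bounds; exact, and cross-checked against exhaustive
  enumeration on short sequences.
* Spline smooths: `bs = "cr"` with up to 10 knots per predictor, GCV;
  distilled to 400-point tables (interpolation error far below the
  estimator's noise floor).
* Quantile IRLS: Schlossmacher-style reweighting with
  $\varepsilon = 10^{-8}\,\mathrm{sd}(y)$ guard, checked against exact
  small-n enumeration.
* Degenerate inputs: monomorphic segments are flagged and imputed from
  the nearest informative neighbours (one-sided at the ends); an
  all-sparse sequence is an error; all-equal tracks return one block.
* Default study sizes keep a full train-and-evaluate cycle at a few
  minutes on one core: two training replicates of the 999-scenario grid,
  one calibration replicate, 10 replicates per background rate in the
  two-hotspot study, 20 replicates of the 1 Mb natural design in the
  test suite.

## Known limitations

* Training covers $\rho \in (0, 0.1]$ per bp; rates above the grid (very
  intense hotspots on a high background) saturate and are reported near
  the grid ceiling even after calibration.
* Detection power at the default $\alpha = 0.05$: hotspots below roughly
  8–15× a low background produce raw-scale contrasts under the
  calibrated multiscale detection limit and are absorbed into the
  background block. On the 1 Mb 15-hotspot evaluation design the median
  estimated block count is ~22 of the true 31 — parsimony is preferred
  over sensitivity to weak hotspots.
* The inverse calibration trades a small upward bias at high rates for
  calibrated backgrounds; with the default conservative quantile, weak
  hotspots (< ~8-fold) on noisy backgrounds are often absorbed into the
  background block — parsimony is preferred over sensitivity.
* Term-wise significance of individual predictors is not guaranteed on
  retraining (GCV may shrink a redundant smooth); the fitted p-values
  are stored in the model object for inspection.
* The coalescent engine is external: the package requires a Python with
  msprime on the PATH at training/simulation time (estimation from files
  with a saved model needs no Python).
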