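---
title: "Feedback-mediated HSC culture kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-mediated HSC culture kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscdyn)
```

## The biological system

`hscdyn` models a liquid culture of murine hematopoietic stem and progenitor
cells: 5000 freshly sorted LSK cells seeded in a 300 µL well with 100 ng/mL
stem cell factor (SCF) and a 10 mM nutrient stock, cultured for 9 days with
full media exchanges at a fixed frequency. Cells are tracked as bulk
compartments along the differentiation hierarchy, in two resolutions:

* **3-state**: LSK → CMP → Terminal;
* **5-state**: LT-HSC → ST-HSC → MPP → CMP → Terminal.

Terminal collects every cell outside the progenitor gates. The culture
environment feeds back on the kinetics through four pooled classes of
cell-secreted biomolecules — differentiation stimulators and inhibitors
(DiffS, DiffI) and proliferation stimulators and inhibitors (ProS, ProI) —
acting only through the two ratios

$$R_d = \frac{\mathrm{DiffS}}{\mathrm{DiffI}}, \qquad
  R_p = \frac{\mathrm{ProS}}{\mathrm{ProI}}.$$

## Rate laws

Each compartment $i$ obeys a balance of proliferation, differentiation in
and out, and apoptosis. The kernels are:

* self-renewal (modified Monod): $f_i = f_{i,\max} / (1 + R_d + s_i [\mathrm{SCF}])$,
  always $\le f_{i,\max} \le 1$;
* proliferation (3-state): $PR_i = PR_{i,\max}\,(1 - e^{-[\mathrm{SCF}] R_p / \hat s})$ —
  zero without SCF or proliferation stimulators, saturating at $PR_{i,\max}$;
* quiescence: $q = q_{\max} e^{-R_d}$ on the stem compartments — quiescence
  collapses as differentiation stimulation rises;
* jump: $j = j_{\max} e^{-T_d/\hat t}$ with $T_d = c_3 \cdot \#\mathrm{Terminal}$,
  the fraction of differentiation flux that bypasses CMP directly into
  Terminal, under negative feedback from Terminal abundance ($c_3$ is the
  Terminal DiffS secretion rate);
* apoptosis: $DR_i = DR_{i,\max} / (1 + d_i [\mathrm{GC}])$ — maximal when the
  nutrient stock is exhausted;
* secretion (3-state): $c = m\,e^{-[\mathrm{pool}]/\hat c}$ per cell and day,
  a product-feedback law that damps secretion as the pool accumulates.

The 5-state variant differs in exactly four respects: proliferation rates
are constants, secretion rates are constants, jumps originate from ST-HSC
and MPP (each with its own $j_{\max}$, sharing the $T_d$ feedback), and
quiescence applies to LT-HSC, ST-HSC and MPP.

### Flow wiring

The kernels define fractions and rates but not by themselves the flux
algebra; the package wires them as follows. Within the active (non-quiescent)
fraction $(1-q)$ of a compartment, the self-renewing fraction $f$
proliferates in place at rate $PR$, and the complement $(1-f)$
differentiates out at the per-transition rate constants $DR_{i \to j}$; for
jump-bearing states the differentiation flux splits $(1-j)$ stepwise versus
$j$ direct-to-Terminal, each path with its own rate constant. Apoptosis is
environmental (nutrient-driven) and applies to the whole compartment,
quiescent cells included — quiescence shields cells from proliferation and
differentiation decisions but not from a depleted medium. This wiring makes
pure inter-state transfer exactly conservative: with proliferation, death
and quiescence disabled, the total cell number is an invariant of the RHS,
which the test suite asserts on randomized draws.

### Units and nondimensionalization

Pools are tracked as amounts (ng) in the well; kernel feedbacks use
concentration = amount / 0.3 mL (the volume is constant, so the two
representations are equivalent). SCF is tracked as a concentration, with
per-cell consumption `K_SCF_consumption` (ng/cell/day) converted through the
300 µL volume; the nutrient is tracked directly as mM with
`K_GC_consumption` (mM/cell/day, volume folded in). The exponentials
$e^{-[\mathrm{pool}]}$, $e^{-[\mathrm{SCF}]R_p}$ and $e^{-T_d}$ take
dimensional arguments; the package divides each by a reference scale
($\hat c$, $\hat s$, $\hat t$), defaulting to $\hat c = 5$ ng/mL and
$\hat s = \hat t = 1$, absorbed into the calibrated parameter set. This
changes no model expressiveness, only makes the units coherent.

### Degenerate inputs and numerical choices

* **Zero pools.** At $t = 0$ (and right after every media exchange) all four
  pools are zero; the ratio convention is: zero stimulator → ratio 0; zero
  inhibitor with positive stimulator → inhibitor floored at $\varepsilon =
  10^{-9}$ ng. The empty-culture ratio is therefore 0, not 0/0.
* **Stock exhaustion.** Consumption of SCF and nutrient is multiplied by a
  smooth depletion switch $x/(x + 0.01)$ rather than an abrupt cutoff at
  zero. The switch acts only in the last 0.01 unit of stock (10⁻⁴ of the SCF
  input, 10⁻³ of the nutrient input), keeps both stocks non-negative, and
  keeps the right-hand side Lipschitz — an abrupt cutoff provokes step-size
  collapse in the adaptive solver exactly at the exhaustion boundary.
* **Integration.** `deSolve::lsoda` (adaptive, stiff-capable) at `rtol =
  1e-8`, `atol = 1e-4` cells, dense output every 0.05 days plus all exchange
  and sampling times. Media exchange is applied as an instantaneous solver
  event — SCF and nutrient reset to their inputs, pools to zero — which is
  exact for a constant-volume full exchange; trajectories report the
  post-exchange (right-continuous) state at event rows. Tiny solver
  negatives are rounded up to zero on output. Halving the tolerances moves
  day-9 counts by well under 0.1% (asserted in the tests).
* **Off-grid sampling** uses monotone cubic (Fritsch–Carlson) interpolation:
  exact at grid points, no overshoot between them.

## Calibrated default parameters

The package ships one calibrated parameter set per variant
(`default_params()`, stored as YAML under `inst/params/`). They are
calibration artifacts of this package — chosen so the simulated culture
reproduces the system's characteristic population scales and shapes:
Terminal expanding to a peak near $6 \times 10^5$ cells by day 9 under
2-day exchange, LSK cycling in the $10^2$–$2 \times 10^3$ band with a
biphasic minimum near day 4, a transient CMP spike before day 1 with CMP
staying below ~300 cells throughout, reduced expansion of every compartment
when media are never exchanged, and (5-state) a declining LT-HSC pool, a
biphasic ST-HSC pool carrying most progenitor activity, and a Terminal
compartment least sensitive to parameter perturbation. The 5-state split of
the 5000 seeded cells defaults to 10% / 60% / 30% LT-HSC / ST-HSC / MPP,
reflecting ST dominance within the gate. All of these properties are
recomputed, not assumed, by the test suite.

Two design questions were genuinely open and resolved as follows. The
Terminal feedback signal $T_d$ is the instantaneous product
$c_3 \cdot \#\mathrm{Terminal}$ rather than the accumulated DiffS pool: the
jump should respond to the present size of the mature compartment, and the
pool reading would make the jump collapse between exchanges for reasons
unrelated to Terminal abundance. Quiescence does not gate apoptosis, since
death in this model is an environmental (nutrient) effect rather than a
biological activity.

## Calibration to observed counts

Counts span four orders of magnitude across compartments, so the loss is a
sum of squared log-residuals, $\sum [\log(\mathrm{model}+\delta) -
\log(\mathrm{obs}+\delta)]^2$ with $\delta = 1$ cell and equal state
weights (optionally inverse relative-SEM weights). Fitting
(`fit_params()`) runs bounded Levenberg–Marquardt in log10 parameter space
with seeded Latin-hypercube multi-start; a handful of sampling times cannot
identify the full 30+-dimensional parameter set, so fits of more than 10
parameters are refused unless forced — the intended workflow is a
sensitivity-guided subset with everything else frozen at defaults. The
parameter-recovery tests fit 5 parameters perturbed ±30% from truth on
noise-free and 5%-noise synthetic data (10 seeds for the noisy study).

## Local sensitivity analysis

`sensitivity_matrix()` computes, for every perturbable parameter and state,
$$S = \big\langle (\Delta O / O) / (\Delta P / P) \big\rangle_{t},$$
the time-averaged relative output change per relative parameter change,
with a one-sided +1% perturbation by default (central differences
available). $\Delta P / P$ is the constant perturbation fraction, so the
denominator average is trivial. The average is over the measurement times
{0.5, 1, 2, 4, 7, 9} days; per-time values are signed and the signed mean
is reported (an absolute-mean option exists), with $|S| > 1$ flagged as
high impact. Times where the baseline count is zero leave the quotient
undefined and are excluded with a warning rather than treated as infinite.
Zero-valued parameters are not perturbable (1% of zero is zero); the
reference scales are structural and likewise excluded.

## The synthetic-data generator

`generate_observations()` emulates the flow-cytometry readout of the
culture: subset counts at days 0.5, 1, 2, 4, 7 and 9 (merging the original
and follow-up sampling designs), three replicates per point with lognormal
multiplicative noise at CV 0.15, reported as replicate mean ± SEM. The
lognormal multiplier has unit mean, so replicate means are unbiased; the
noise CV default is an engineering choice, since only SEM bars are
available for the real system. What the generator does *not* emulate:
gating/classification error (counts are noiseless functions of the true
state before the multiplicative draw), inter-well or inter-animal
variability, cell-cycle or single-cell heterogeneity, and detection floors
at very low counts. Passing recovery tests on these data therefore
demonstrates correctness of the estimation machinery under the declared
noise model, not robustness to everything a real FACS series can contain.

`reference_experiment()` packages the culture arms — 2-, 5- and 10-day
exchange for the 3-state model and 2-day for the 5-state — each with a
fixed, documented seed so every bundle regenerates bit-identically.

## Problem sizes used by the shipped checks

The test-suite and acceptance computations use the study-scale problems
directly: 9-day horizons on a 0.05-day output grid (181 grid points),
6-time-point observation designs, 5-parameter fits (single start for the
recovery studies, as the perturbed starts lie in the attraction basin), a
600-dataset Monte-Carlo check of the noise model on a frozen culture, and
100-draw randomized sweeps for the algebraic invariants.

## Known limitations

* Differentiation rate constants are time-invariant; the real coupling is
  likely nonlinear and time-dependent.
* The four biomolecule pools are coarse aggregates; no attempt is made to
  resolve individual cytokines.
* Full media exchange only (stocks reset, pools discarded); partial
  exchange fractions and volume changes are out of scope.
* Deterministic bulk ODEs: no stochastic, agent-based, spatial, or
  structured-population (PDE) dynamics, and no lymphoid branch.
* The defaults are calibrated to population-scale anchors, not to a raw
  single-cell dataset; absolute rates should be read as effective culture
  aggregates.
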