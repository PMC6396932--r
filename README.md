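# hscdyn

Feedback-mediated kinetics of hematopoietic stem cell (HSC) cultures, as a
set of deterministic ODE models with pulsed media exchange.

## The problem

Expanding hematopoietic stem and progenitor cells in vitro is hard because
the cells themselves reshape their medium: secreted biomolecules feed back
on self-renewal, quiescence, proliferation and differentiation, while the
culture consumes its cytokine (SCF) and nutrient stocks between media
changes. `hscdyn` is for quantitative cell biologists and culture engineers
who want to simulate, fit and interrogate this system: which parameters
dominate the expansion of each subset, how does media-exchange frequency
change the outcome, and is a direct progenitor-to-mature "jump" needed to
explain observed counts?

Two nested hierarchies are implemented, seeded with 5000 LSK-gate cells in
300 µL with 100 ng/mL SCF and a 10 mM nutrient stock:

* **3-state**: LSK → CMP → Terminal
* **5-state**: LT-HSC → ST-HSC → MPP → CMP → Terminal

Each compartment follows a balance of proliferation, differentiation and
apoptosis. The kernels respond to the environment through the
stimulator/inhibitor ratios $R_d$ = DiffS/DiffI and $R_p$ = ProS/ProI:

* self-renewal $f_i = f_{i,\max}/(1 + R_d + s_i[\mathrm{SCF}])$
* proliferation $PR_i = PR_{i,\max}(1 - e^{-[\mathrm{SCF}]R_p})$ (constant in the 5-state variant)
* quiescence $q = q_{\max} e^{-R_d}$
* jump $j = j_{\max} e^{-T_d}$, with $T_d = c_3\cdot\#\mathrm{Terminal}$ — the
  fraction of differentiation flux that bypasses CMP straight into Terminal
* apoptosis $DR_i = DR_{i,\max}/(1 + d_i[\mathrm{GC}])$
* secretion $c = m\,e^{-[\mathrm{pool}]}$ (constant in the 5-state variant)

Media exchange is an instantaneous event that refreshes SCF and nutrient and
discards the secreted pools. On top of the simulator the package provides
bounded least-squares parameter fitting on log-scale residuals, local
one-at-a-time parameter sensitivity analysis ($S = \langle\Delta O/O\rangle /
\langle\Delta P/P\rangle$ at a 1% perturbation, $|S| > 1$ flagged), and a
synthetic-data generator that stands in for flow-cytometry subset counts.
See `vignettes/hscdyn-methods.Rmd` for the full model account.

## Worked example

```r
library(hscdyn)

traj <- simulate_culture("three_state")   # calibrated defaults, 2-day exchange
glance(traj)
#> # A tibble: 1 × 6
#>   kind        horizon_day exchange_every_day n_grid total_final terminal_peak
#>   <chr>             <dbl>              <dbl>  <int>       <dbl>         <dbl>
#> 1 three_state           9                  2    181     637011.       636186.

sample_trajectory(traj, c(0.5, 1, 2, 4, 7, 9)) |>
  tidyr::pivot_wider(names_from = state, values_from = count)
#> # A tibble: 6 × 4
#>   time_day   LSK   CMP Terminal
#>      <dbl> <dbl> <dbl>    <dbl>
#> 1      0.5 2563. 215.     2586.
#> 2      1   1348. 161.     4966.
#> 3      2    419.  57.2   10443.
#> 4      4    295.  21.8   34428.
#> 5      7    468.  25.3  198668.
#> 6      9    778.  46.6  636186.
```

The trajectory shows the system's signature kinetics: Terminal cells expand
exponentially to a peak of ~6.4 × 10⁵; LSK cells are biphasic (decline to a
minimum of ~295 near day 4, then recovery to ~780 as inhibitors secreted by
the mature progeny lower the differentiation drive); CMP spikes to ~215
before day 1 and stays small — a transient compartment. `autoplot(traj)`
plots the three time courses on a log axis with exchange times marked.

Sensitivity analysis flags the high-impact parameters per state:

```r
sm <- sensitivity_matrix("three_state")
dplyr::count(dplyr::filter(sm, flagged), state, name = "high_impact")
#> # A tibble: 3 × 2
#>   state    high_impact
#>   <fct>          <int>
#> 1 LSK                4
#> 2 CMP                4
#> 3 Terminal           1
```

Terminal cells are the least sensitive compartment — only their own
proliferation rate moves them by more than 1% per 1% parameter change —
while the dynamic progenitor states respond to self-renewal, jump and
differentiation parameters. `autoplot(sm)` renders the state × parameter
heat map.

Fitting and synthetic data close the loop:

```r
obs <- generate_observations("three_state", noise = noise_model(cv = 0.15, seed = 1))
fit <- fit_params(obs, "three_state",
                  free = c("f_max_LSK", "PR_max_Terminal", "j_max_LSK"))
tidy(fit)    # start vs estimate per free parameter
glance(fit)  # loss, convergence, iterations
```

A thin command-line wrapper is installed at `inst/cli/hscdyn`
(subcommands `simulate`, `generate`, `sense`, `fit`, `report`); see
`?run_cli`.

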