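# nkabm

An on-lattice, stochastic agent-based simulator of the tumor
microenvironment under natural-killer (NK) cell adoptive therapy, for
researchers who want to explore dosing schedules, effector-to-target
ratios and cell-product properties in silico before (or alongside)
mouse experiments.

Tumor cells and three NK phenotypes — cytotoxic (N<sub>C</sub>),
exhausted (N<sub>E</sub>) and vigilant (N<sub>V</sub>) — interact on a
2D Moore-neighborhood grid (50 µm cells, ≤ 25 tumor cells per site,
4-hour steps) carrying a decaying cytokine field. The core rules:

* **Killing.** On contact, a cytotoxic agent kills with
  `pkill = logistic(c_NK + G_NK)^γ · (1 − p_evade)`, where
  `c_NK ~ truncN(μ_c, σ_c²)` is its baseline cytotoxicity,
  `G_NK = tanh(b Σ β_i g_i)` embeds per-cell expression profiles
  weighted by an effect-coefficient table, γ is the CAR-engineering
  exponent (0.5 CAR, 1.0 non-transduced) and `p_evade` is the target's
  evasion probability (raised by resistance mutations, lowered by
  CAR-target antigen expression).
* **Serial killing & exhaustion.** Each kill depletes a capacity
  `S0`; depletion can be linear, marker-accumulating (LAG3/PDCD1
  feedback into `pkill`), or marker-accelerated
  (`s = S0 − kills · e^{Σ x/(x50+x)}`). At s ≤ 0 the agent is
  exhausted and inert.
* **Proliferation.** Cytotoxic NK division follows
  `p_c·exp(w − b_pc·t)` with `w` a product of Hill saturation terms in
  local tumor load (half-max `B50 = 25`) and cytokine level
  (half-max `c50 = 70`), exponents 0.2; cytokines decay with their
  half-lives (IL-15 2.5 h, IL-21 0.2 h) and are deposited by armored
  products.
* **Memory.** On local clearance, tumor-experienced cytotoxic agents
  become vigilant (prob. 1.0); on re-exposure vigilant agents recall
  to cytotoxic (prob. 0.9) with capacity restored.

Around the simulator the package provides dosing-schedule in-silico
trials, MSE-driven coarse-to-fine grid-search calibration against
observed tumor-progression curves, random-forest sensitivity analysis
(impurity + held-out permutation importance), Mann-Whitney/BH group
comparison, and synthetic-data fixtures so everything runs with no
external data. See the vignette in `vignettes/` for the full model
description.

## Worked example

Treat 500 lymphoma cells with a CD19-CAR NK product at a 1:1
effector-to-target ratio and compare against matched tumor-only
controls:

```r
library(nkabm)

cfg <- simulation_config(
  grid = grid_config(60, 60), duration = 10, n_tumor_init = 500L, etr = 1,
  products = list(CAR19 = nk_product(name = "CAR19",
                  kill = nk_kill_params(mu_c = 0.5, gamma = 0.5))),
  cytokines = list(), replicates = 5L, seed = 42L)

agg  <- run_replicates(cfg)   # 5 seeded replicates
ctrl <- run_control(cfg)      # matched tumor-only runs

normalized_progression(agg, ctrl, obs_days = c(2, 5, 8))
#> [1] 0.0276 0.0000 0.0000

sapply(agg$replicates, auc_tumor_growth)      # fold-change AUC, days
#> mean 2.17, sd 0.05 across replicates
sapply(agg$replicates, time_to_clearance)     # days
#> 2.33 2.67 2.33 2.50 2.33
```

The normalized progression (treated tumor burden ÷ mean control burden,
the quantity calibration fits) drops to 2.8% of control by day 2 and
the tumor is durably cleared by ~day 2.5 in every replicate; the
aggregate record (`agg$mean`) also tracks phenotype counts — by day 10
the surviving NK population is almost entirely vigilant, the modeled
memory reservoir.

A thin CLI wraps the same functions:

```sh
nkabm fixtures --out fixtures/
nkabm run --config cfg.yaml --out results/ --seed 1 --replicates 5
```

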