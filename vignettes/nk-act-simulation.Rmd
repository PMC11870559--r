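---
title: "Modeling tumor and NK-cell dynamics on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor and NK-cell dynamics on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkabm)
```

## The model

`nkabm` simulates adoptive natural-killer (NK) cell therapy as a
stochastic agent-based model on a 2D square lattice with Moore
(8-neighbor) neighborhoods. Four agent types interact: tumor cells (B)
and three NK phenotypes — cytotoxic (N~C~), exhausted (N~E~) and
vigilant (N~V~). Each lattice cell is 50 µm across, holds at most
`BMax = 25` tumor cells (a hard carrying-capacity invariant), and
carries a scalar level for each cytokine species (e.g. IL-15, IL-21).
One model step is ΔT = 4 h, the approximate duration of one NK–tumor
conjugation-plus-attachment cycle, so one kill attempt per cytotoxic
agent per step is a structural assumption, not a tunable.

Agents commit to stochastic actions by comparing a uniform draw with a
per-step probability. All per-day rates r are mapped to per-step
probabilities as

* death: p = 1 − exp(−r·ΔT_days),
* division: p = min(exp(r·ΔT_days) − 1, 1),

so a population with division rate p and death rate d multiplies by
exactly exp(p − d) per day in expectation. This choice makes configured
rates recoverable from simulated trajectories by a log-linear fit,
which is also how the package's acceptance checks work.

### Cytotoxic killing

On contact (own cell or a Moore-1 neighbor), a cytotoxic agent kills a
uniformly chosen local tumor cell with probability

$$p_{kill} = \left[\frac{1}{1 + e^{-(c_{NK} + G_{NK})}}\right]^{\gamma}
(1 - p_{evade}),$$

where `c_NK ~ truncN(mu_c, sigma_c^2)` on [0, ∞) is drawn once at
birth, γ is the CAR engineering exponent (0.5 for CAR products, 1.0
for non-transduced cells; γ < 1 inflates the logistic kernel), and
`p_evade` belongs to the target. The genetic effect is
`G_NK = tanh(b Σ_i β_i g_i)`: a per-agent single-cell expression
profile g, drawn with replacement from a supplied pool, weighted by an
effect-coefficient table β and squashed to (−1, 1); `b = 0.1` scales
the sum. Coefficients are consumed exactly as supplied — any sign
convention (e.g. negating regression coefficients so positive means
pro-cytotoxic) is the table producer's responsibility, which avoids
silent double sign flips.

### Serial killing and exhaustion

Each cytotoxic agent carries a serial-killing capacity starting at
`S0`. Three depletion variants are implemented: linear depletion
(`EM1`, s = S0 − kills); linear depletion plus accumulation of
exhaustion-marker expression (+1 per kill on each flagged marker, by
default LAG3 and PDCD1), which feeds back into `p_kill` through the
genetic effect (`EM2`); and marker-accelerated depletion
`s = S0 − kills · exp(Σ x/(x50 + x))` (`EM3`). An agent reaching s ≤ 0
becomes exhausted: inert, non-proliferating (pE = 0), dying at rate dE.
The marker half-maximum `x50` defaults to 1 per marker and is exposed
in the configuration, as is the per-kill marker increment (+1,
dimensionless).

### Proliferation: cytokine-dependent vs vanilla model

The per-day division rate of a cytotoxic agent of age t steps is

$$p_c^*(t) = p_c \exp(w - b_{pc} t), \qquad
w = k_B \cdot \frac{c^{\gamma_2} + \delta}{c^{\gamma_2} +
c_{50}^{\gamma_2} + \delta}, \qquad
k_B = \frac{B^{\gamma_1} + \delta}{B^{\gamma_1} + B_{50}^{\gamma_1} +
\delta},$$

with B the tumor count in the Moore-1 region, c the local cytokine
level, half-maxima `B50 = 25` and `c50 = 70`, Hill exponents
γ1 = γ2 = 0.2, and δ = 1e-6 a small constant keeping w nonzero with a
negligible (≈1e-6) shift of the half-maximum positions. The grouping of
w is chosen so that c50 is exactly the cytokine half-maximum. The
realized rate is re-sampled each step from truncN(p_c*(t), σ_pc²) on
[0, ∞); σ_pc defaults to 0.01·p_c since no value is published. The
vanilla model (`model = "VM"`) forces w = 0 and is draw-for-draw
identical to CM at w = 0 under equal seeds. In tumor-free
autonomous-growth assays `k_B` is pinned to a constant (default 1.0)
rather than computed from the absent tumor load, preserving a
non-trivial cytokine effect.

### Vigilant transitions

A cytotoxic agent that has contacted tumor (`tumor_exposed`) and finds
zero tumor cells within Moore radius 1 at the end of a step converts to
vigilant with probability kB− = 1.0. Vigilant agents proliferate and
die slowly (pV = dV = 1e-3/day) and, on tumor re-exposure, recall to
cytotoxic with probability kB+ = 0.9, with killing capacity restored to
S0 (kill counter reset; accumulated marker expression is retained).
The restoration operationalizes "preserved effector function" and is
flagged as an assumption.

### Tumor cells

Tumor agents divide (lymphoma 0.455/day, glioblastoma 0.223/day), die
(1e-4/day, logged as programmed death, distinct from NK-mediated
death), move (probability 0.1/step, 1 cell), and mutate: each daughter
independently gains an immune-resistance mutation with probability
0.001, and every mutation adds 0.001 to the cell's evasion
probability — the same constant plays both roles. Evasion is

`p_evade = clip(p_base (1 − κ·antigen) + mutations · 0.001, 0, 1)`,

with κ = 0.5 the antigen scaling constant (no published value) and
antigen the normalized CAR-target (e.g. CD19) expression, drawn from an
optional tumor expression pool or fixed at 1. Baseline evasion defaults
to 0.1.

### Movement

All cells random-walk; NK agents additionally chemotax: each move event
spans `round_stochastic(v_N ΔT / l)` lattice sub-steps (39 µm/h × 4 h /
50 µm = 3.12 in expectation), and while any tumor exists each sub-step
picks the Moore-1 neighbor with the highest local (Moore-summed) tumor
count, falling back to the neighbor nearest the tumor centroid when the
local field is flat, ties uniform at random. Borders are absorbing
walls. Tumor movement respects the per-cell cap; moves into full cells
are refused.

### Cytokine field

Each species decays by 2^(−ΔT/t½) per step (IL-15 t½ = 2.5 h, IL-21
0.2 h) and each NK agent of a product armored with the species deposits
1.0 (dimensionless) into its own cell per step. There is no diffusion:
the decay law is published but production and transport are not, and
levels enter the dynamics only through the Hill ratio against c50, so
the deposit constant is the model's single free cytokine scale.

## Scheduling and conflict resolution

The reference picture of one step is a randomly ordered sweep over all
agents. `nkabm` implements each step as a sequence of vectorized
phases — NK movement, NK kill attempts, tumor demography and movement,
NK phenotype transitions, NK demography, cytokine update, dosing,
recording — and resolves simultaneous conflicts by uniformly random
priority: multiple claims on one tumor cell keep one random winner;
daughters admitted to a cell beyond capacity are redirected to a random
non-full Moore-1 neighbor or skipped; movement into over-full cells is
bounced back, iterating until the cap holds everywhere. This
reproduces the statistics of a random sequential sweep while keeping
desk-scale populations (tens of thousands of agents) fast in R, and
keeps `BMax` a hard invariant verified on a 20-day dense-growth stress
test.

All randomness flows from R's generator seeded once per replicate
(replicate r uses base seed + r − 1), so runs are bit-reproducible.

## Initial conditions and dosing

A run starts with `n_tumor_init` tumor cells (default 1000) and
`round(n_tumor_init · etr)` cytotoxic NK agents (100% cytotoxic at t0).
Two tumor geometries are supported:

* `"disk"` (default): cells packed at carrying capacity into the
  smallest central disk — the engrafted-mass picture used for in-vivo
  simulations; 1000 cells at cap 25 occupy ≥ 40 central cells.
* `"uniform"`: cells scattered over the whole grid. Intrinsic
  growth-rate assays use this geometry: a disk packed at capacity is
  front-limited from the first step and cannot express the configured
  exponential rate, exactly as a confluent culture cannot.

NK placement is `"periphery"` (boundary annulus; intravenous picture)
or `"adjacent"` (a ring hugging the tumor mass; intratumoral
injection, the glioblastoma preset). Follow-up doses add
`multiplier × n_tumor_init × etr` freshly sampled cytotoxic agents at
the configured day; rechallenge mode re-adds tumor boluses on a day
list, emulating repeated target addition scaled to lattice capacity.

## Calibration

`global_search()` fits parameters to observed normalized tumor
progression (treated burden ÷ mean tumor-only control burden, tumor
count standing in for radiance) in stages: (1) tumor growth parameters
against the control fold-change curve, then fixed; (2) an exhaustive
grid over NK parameters per group under each candidate
effector-to-target ratio, keeping the ETR with the lowest total MSE
across groups; (3) grid refinement around incumbents (spacing shrunk
4× per stage). Exhaustive grids were chosen over heuristic global
optimizers for reproducibility. Candidates are scored with a reduced
replicate count (default 5) and incumbents re-scored at the full
count; the result carries the top-10 sets per group and a stability
diagnostic (coefficient of variation of tumor progression across
replicates at each observed day). On simulator-generated data with the
truth inside the grid, the search returns the truth as the incumbent —
this closed-loop recovery is part of the test suite.

## Sensitivity analysis and statistics

`run_sweep()` executes the Cartesian product of parameter grids and
summarizes each run by the area under the tumor fold-change curve
(trapezoidal, over a configurable horizon) and time to sustained
clearance. `feature_importance()` fits a seeded 500-tree random forest
(via `ranger`) of the response on the parameters and reports mean
decrease in impurity normalized to sum to one, plus permutation
importance computed in-package as the mean held-out MSE increase over
≥10 independent permutations per feature (a multi-repeat, held-out
variant rather than the single out-of-bag pass built into forest
libraries). Group comparisons use two-tailed Mann-Whitney U tests with
Benjamini-Hochberg adjustment at α = 0.05.

## Synthetic data

The fixtures module makes the whole pipeline runnable offline. It
generates (i) effect tables with N(0, 0.5²) coefficients plus LAG3 and
PDCD1 rows carrying negative coefficients and marker flags; (ii)
non-negative log-normal expression pools aligned to the table; (iii)
observed-progression curves, either analytic exponentials with
multiplicative Gaussian noise or (preferred for recovery tests)
trajectories produced by the simulator at known parameters; and (iv)
deterministic micro-scenarios — isolated NK/tumor pairs, a clearance
board, a recall board, and a full-capacity board — whose one-step
outcome distributions are known in closed form. The synthetic pools
emulate the magnitude and non-negativity of normalized single-cell
profiles, not real count distributions, batch effects or gene-gene
correlation; passing tests therefore validate the agent rules and the
plumbing, not biological calibration to any real product.

Micro-scenario boards zero the phenotype death and proliferation rates
so that a single step measures exactly one transition probability; the
transition probabilities themselves are the calibrated constants.

## Defaults with no published value

Product-specific fitted values are not published ("vary by cell
product"); the package defaults are pc = 0.3/day, dC = 0.1/day,
μc = 0.5, S0 = 5, bpc = 0.02/step, dE = 0.1/day, σpc = 0.01·pc — orders
of magnitude consistent with the published fixed parameters, chosen
once and exposed in `nk_product()` for users to override with their own
calibrated values.

## Numerical choices

* Truncated normals are sampled exactly by inverse-CDF on the
  truncated interval [0, ∞).
* δ = 1e-6 in the Hill terms (1e-12 when verifying half-maximum
  positions by root finding).
* Ties in chemotaxis and target choice are broken uniformly at random;
  sub-cell displacement fractions are rounded stochastically so the
  expected displacement is exact.
* Degenerate inputs are safe: empty grids step without error, σ = 0
  distributions collapse to their means, `half_life = Inf` disables
  decay, and a fully frozen configuration is a fixed point of the step
  function.

## Problem sizes

The shipped tests and the reproduction script use desk-scale settings
chosen to give tight statistics at interactive runtimes: growth-rate
recovery uses 30 replicates of 1000 cells for 8–10 simulated days
(slope standard error ≪ the ±5% band), transition frequencies use 10⁴
agents × 10 seeds (3 binomial SE ≈ 0.003), mutation frequency
aggregates ≥10⁵ division events, and the capacity stress test runs 5
replicates of 20 days on a 60×60 grid, reaching ≈3×10⁴ agents.

## Known limitations

No cytokine diffusion or PDE transport; 2D only; no metabolic
competition, toxicity or host immunity beyond the four agent types;
exhausted agents are inert occupants; the vanilla/cytokine model choice
is per-product, not per-agent; and the in-vivo day-labeling offset
between engraftment and infusion is a bookkeeping field, not a
mechanism.
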