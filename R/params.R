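#' Grid configuration
#'
#' Geometry of the 2D lattice tumor microenvironment. Positions are
#' integer `(row, col)`, 1-based, origin at the top-left corner; borders
#' are absorbing (moves off the grid are clipped).
#'
#' @param width,height Grid dimensions in cells (each at least 3).
#' @param l Edge length of one grid cell in micrometers. With the default
#'   50 um a 100x100 grid covers a 5x5 mm field.
#' @param b_max Maximum number of tumor cells allowed per grid cell; a
#'   hard carrying-capacity invariant enforced at every step.
#' @param dt Model step length in hours. The default 4 h approximates one
#'   NK-tumor conjugation-plus-attachment cycle.
#' @return A `grid_config` list.
#' @export
grid_config <- function(width = 100L, height = 100L, l = 50, b_max = 25L,
                        dt = 4) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 3L, height >= 3L, l > 0, b_max >= 1L, dt > 0)
  structure(list(width = width, height = height, l = l,
                 b_max = as.integer(b_max), dt = dt),
            class = "grid_config")
}

#' Cytokine species parameters
#'
#' A cytokine species (e.g. IL-15, IL-21) lives on the lattice as a
#' dimensionless scalar field. Each step the field decays with the given
#' half-life and every NK agent armored with the species deposits a fixed
#' amount into its own cell. There is no diffusion: levels only enter the
#' model through Hill ratios against `c50`, so absolute units are
#' arbitrary.
#'
#' @param half_life Half-life in hours (IL-15: 2.5 h; IL-21: 0.2 h).
#'   `Inf` disables decay.
#' @param deposit_per_step Amount added per armored NK agent per step.
#' @param initial_level Uniform starting level of the field.
#' @return A `cytokine_params` list.
#' @export
cytokine_params <- function(half_life = 2.5, deposit_per_step = 1.0,
                            initial_level = 0) {
  stopifnot(half_life > 0, deposit_per_step >= 0, initial_level >= 0)
  structure(list(half_life = half_life,
                 deposit_per_step = deposit_per_step,
                 initial_level = initial_level),
            class = "cytokine_params")
}

#' NK cytotoxicity parameters
#'
#' Baseline cytotoxicity of a cytotoxic NK agent is drawn once at birth
#' from a normal distribution truncated to `[0, Inf)`. The CAR effect
#' exponent `gamma` raises the logistic kill kernel to a power: values
#' below 1 (CAR products, default fit 0.5) inflate the per-contact kill
#' probability relative to non-transduced cells (`gamma = 1`).
#'
#' @param mu_c Mean baseline cytotoxicity (dimensionless; product-specific).
#' @param sigma_c SD of baseline cytotoxicity (default 0.01).
#' @param gamma CAR effect exponent (> 0); 0.5 for CAR, 1.0 for NT.
#' @return An `nk_kill_params` list.
#' @export
nk_kill_params <- function(mu_c = 0.5, sigma_c = 0.01, gamma = 1.0) {
  stopifnot(sigma_c >= 0, gamma > 0)
  structure(list(mu_c = mu_c, sigma_c = sigma_c, gamma = gamma),
            class = "nk_kill_params")
}

#' NK proliferation parameters (cytokine-dependent or vanilla model)
#'
#' The per-day proliferation rate of a cytotoxic NK agent of age `t`
#' steps is `pc * exp(w - bpc * t)` where `w` is the product of two Hill
#' saturation terms in local tumor load and local cytokine level (see
#' [stimulus_terms()]). The vanilla model (`model = "VM"`) forces
#' `w = 0`. Each step the realised rate is re-sampled from a truncated
#' normal around this mean.
#'
#' @param pc Baseline proliferation rate, per day.
#' @param bpc Proliferation decay parameter, per step.
#' @param sigma_pc Sampling SD of the per-step rate; default `0.01 * pc`.
#' @param b50 Half-maximum tumor load (cells in the Moore-1 region).
#' @param c50 Half-maximum cytokine level (dimensionless).
#' @param gamma1,gamma2 Hill exponents for the tumor and cytokine terms.
#' @param delta Small positive constant keeping `w` nonzero at zero
#'   stimulus; negligible at the half-maximum points.
#' @param model `"CM"` (cytokine-dependent) or `"VM"` (vanilla, w = 0).
#' @param kb_autonomous Constant substituted for the tumor Hill term when
#'   the simulation runs in tumor-free autonomous-growth mode.
#' @return An `nk_prolif_params` list.
#' @export
nk_prolif_params <- function(pc = 0.3, bpc = 0.02, sigma_pc = 0.01 * pc,
                             b50 = 25, c50 = 70, gamma1 = 0.2, gamma2 = 0.2,
                             delta = 1e-6, model = c("CM", "VM"),
                             kb_autonomous = 1.0) {
  model <- match.arg(model)
  stopifnot(pc >= 0, bpc >= 0, sigma_pc >= 0, b50 > 0, c50 > 0, delta > 0)
  structure(list(pc = pc, bpc = bpc, sigma_pc = sigma_pc, b50 = b50,
                 c50 = c50, gamma1 = gamma1, gamma2 = gamma2, delta = delta,
                 model = model, kb_autonomous = kb_autonomous),
            class = "nk_prolif_params")
}

#' NK exhaustion parameters
#'
#' Serial-killing capacity (SKC) starts at `s0` and is depleted by kills.
#' Three exhaustion variants are supported:
#' * `EM1` — linear depletion, `s = s0 - kills`.
#' * `EM2` — linear depletion plus accumulation of exhaustion-marker
#'   expression (+1 per kill on each flagged marker), which feeds back
#'   into the kill probability through the genetic effect.
#' * `EM3` — marker accumulation as in EM2, and depletion accelerated
#'   exponentially by marker saturation:
#'   `s = s0 - kills * exp(sum(x / (x50 + x)))`.
#'
#' An agent whose SKC reaches zero (or below) becomes exhausted at the
#' end of the step.
#'
#' @param s0 Initial serial-killing capacity (integer >= 1).
#' @param variant One of `"EM1"`, `"EM2"`, `"EM3"`.
#' @param x50 Half-maximum constant for exhaustion-marker saturation
#'   (recycled over markers; used by EM3).
#' @return An `exhaustion_params` list.
#' @export
exhaustion_params <- function(s0 = 5L, variant = c("EM1", "EM2", "EM3"),
                              x50 = 1.0) {
  variant <- match.arg(variant)
  s0 <- as.integer(s0)
  stopifnot(s0 >= 1L, all(x50 > 0))
  structure(list(s0 = s0, variant = variant, x50 = x50),
            class = "exhaustion_params")
}

#' NK phenotype rates and transition probabilities
#'
#' Death and proliferation rates for the three NK phenotypes and the
#' probabilities governing the cytotoxic/vigilant switch: upon local
#' tumor clearance a tumor-exposed cytotoxic agent becomes vigilant with
#' probability `kb_minus`; a vigilant agent re-exposed to tumor recalls
#' to cytotoxic with probability `kb_plus` (its SKC restored to `s0`).
#'
#' @param d_c Cytotoxic NK death rate, per day (product-specific).
#' @param p_v,d_v Vigilant NK proliferation/death rates, per day.
#' @param p_e,d_e Exhausted NK proliferation/death rates, per day.
#' @param kb_minus Cytotoxic-to-vigilant transition probability.
#' @param kb_plus Vigilant-to-cytotoxic recall probability.
#' @return A `phenotype_rates` list.
#' @export
phenotype_rates <- function(d_c = 0.1, p_v = 1e-3, d_v = 1e-3, p_e = 0,
                            d_e = 0.1, kb_minus = 1.0, kb_plus = 0.9) {
  stopifnot(d_c >= 0, p_v >= 0, d_v >= 0, p_e >= 0, d_e >= 0,
            kb_minus >= 0, kb_minus <= 1, kb_plus >= 0, kb_plus <= 1)
  structure(list(d_c = d_c, p_v = p_v, d_v = d_v, p_e = p_e, d_e = d_e,
                 kb_minus = kb_minus, kb_plus = kb_plus),
            class = "phenotype_rates")
}

#' NK motility parameters
#'
#' NK agents move with probability `m_n` per step. The speed `v_n`
#' (um/hr) translates into `v_n * dt / l` lattice sub-steps per move
#' event, rounded stochastically so the expectation is exact. While any
#' tumor is present each sub-step climbs the local tumor-count gradient
#' (ties broken at random); otherwise sub-steps are a random walk.
#'
#' @param m_n Movement probability per step, in `[0, 1]`.
#' @param v_n Movement speed in um/hr.
#' @return A `motility_params` list.
#' @export
motility_params <- function(m_n = 0.9, v_n = 39) {
  stopifnot(m_n >= 0, m_n <= 1, v_n >= 0)
  structure(list(m_n = m_n, v_n = v_n), class = "motility_params")
}

#' Tumor cell parameters
#'
#' Tumor agents divide, die, move and accumulate immune-resistance
#' mutations. Each division the daughter independently gains a mutation
#' with probability `p_mutate`; every acquired mutation adds
#' `p_mutate_increment` to the cell's evasion probability. High
#' expression of the CAR target antigen (e.g. CD19) proportionally
#' reduces evasion by the factor `kappa_antigen` (see
#' [effective_evasion()]).
#'
#' @param p_b Proliferation rate, per day (lymphoma fit: 0.455;
#'   glioblastoma fit: 0.223).
#' @param d_b Death rate, per day.
#' @param p_mutate Per-division probability a daughter gains an
#'   immune-resistance mutation.
#' @param p_mutate_increment Evasion-probability gain per acquired
#'   mutation (defaults to `p_mutate`, the dual role the rate plays).
#' @param p_evade_base Baseline probability of evading a kill attempt.
#' @param kappa_antigen Scaling constant for antigen-dependent reduction
#'   of evasion, in `[0, 1]`.
#' @param m_b Movement probability per step.
#' @param v_b Movement speed in grid cells per step.
#' @return A `tumor_params` list.
#' @export
tumor_params <- function(p_b = 0.455, d_b = 1e-4, p_mutate = 1e-3,
                         p_mutate_increment = p_mutate, p_evade_base = 0.1,
                         kappa_antigen = 0.5, m_b = 0.1, v_b = 1L) {
  stopifnot(p_b >= 0, d_b >= 0,
            p_mutate >= 0, p_mutate <= 1,
            p_mutate_increment >= 0,
            p_evade_base >= 0, p_evade_base <= 1,
            kappa_antigen >= 0, kappa_antigen <= 1,
            m_b >= 0, m_b <= 1, v_b >= 0)
  structure(list(p_b = p_b, d_b = d_b, p_mutate = p_mutate,
                 p_mutate_increment = p_mutate_increment,
                 p_evade_base = p_evade_base, kappa_antigen = kappa_antigen,
                 m_b = m_b, v_b = as.integer(v_b)),
            class = "tumor_params")
}

#' Genetic-effect scaling parameter
#'
#' @param b Overall NK cytotoxicity genetic-effect coefficient (>= 0);
#'   scales the weighted expression sum inside the `tanh` link. `b = 0`
#'   switches genetic effects off.
#' @return A `genetic_effect_params` list.
#' @export
genetic_effect_params <- function(b = 0.1) {
  stopifnot(b >= 0)
  structure(list(b = b), class = "genetic_effect_params")
}

#' NK product definition
#'
#' Bundles every parameter block describing one NK cell product (e.g.
#' non-transduced "NT", "CAR19", "CAR19IL15"). Products differ in
#' cytotoxicity, proliferation, exhaustion, phenotype rates, and whether
#' they are armored with a cytokine transgene.
#'
#' @param name Product label.
#' @param kill [nk_kill_params()] block.
#' @param prolif [nk_prolif_params()] block.
#' @param exhaustion [exhaustion_params()] block.
#' @param rates [phenotype_rates()] block.
#' @param motility [motility_params()] block.
#' @param genetics [genetic_effect_params()] block.
#' @param armored `NA` or the name of the cytokine species this product
#'   secretes (must match a species in the simulation config).
#' @return An `nk_product` list.
#' @export
nk_product <- function(name = "NT",
                       kill = nk_kill_params(),
                       prolif = nk_prolif_params(),
                       exhaustion = exhaustion_params(),
                       rates = phenotype_rates(),
                       motility = motility_params(),
                       genetics = genetic_effect_params(),
                       armored = NA_character_) {
  structure(list(name = name, kill = kill, prolif = prolif,
                 exhaustion = exhaustion, rates = rates,
                 motility = motility, genetics = genetics,
                 armored = armored),
            class = "nk_product")
}

#' Dosing schedule
#'
#' Follow-up NK infusions. Each event adds
#' `multiplier * n_tumor_init * etr` freshly sampled cytotoxic NK agents
#' of the named product on the periphery annulus at the first step whose
#' elapsed time reaches `day`.
#'
#' @param day Numeric vector of dosing days.
#' @param product Character vector of product names (recycled).
#' @param multiplier Dose multipliers relative to the initial 1X dose
#'   (recycled).
#' @return A `dosing_schedule` data frame.
#' @export
dosing_schedule <- function(day = numeric(), product = character(),
                            multiplier = 1) {
  n <- length(day)
  stopifnot(all(multiplier > 0))
  out <- data.frame(day = as.numeric(day),
                    product = rep_len(as.character(product), n),
                    multiplier = rep_len(as.numeric(multiplier), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("dosing_schedule", "data.frame")
  out
}

#' Simulation configuration
#'
#' Top-level configuration of one in-silico experiment: the lattice, the
#' tumor parameter block, one or more NK products, cytokine species,
#' dosing, the effector-to-target ratio and initial populations.
#'
#' @param grid [grid_config()] block.
#' @param duration Simulated time in days.
#' @param etr Effector-to-target ratio (NK per tumor cell at dose time).
#'   May be written as a number (1, 0.2) or a string ratio (`"1:1"`,
#'   `"1:5"`, `"3:1"`).
#' @param n_tumor_init Initial tumor cell count (0 for tumor-free runs).
#' @param n_nk_init Initial NK count; default `round(n_tumor_init * etr)`.
#'   Must be given explicitly for tumor-free assays.
#' @param products Named list of [nk_product()] blocks; the first is the
#'   product infused at t0.
#' @param initial_product Name of the product present at t0.
#' @param tumor [tumor_params()] block.
#' @param cytokines Named list of [cytokine_params()], one per species.
#' @param dosing [dosing_schedule()] of follow-up infusions.
#' @param seed Base random seed; replicate r uses `seed + r - 1`.
#' @param replicates Number of replicate runs.
#' @param record_every Recording interval in steps.
#' @param assay_mode `"in_vivo"` (tumor + NK), `"autonomous_growth"`
#'   (tumor-free; the tumor Hill term is pinned at `kb_autonomous`), or
#'   `"rechallenge"` (periodic tumor boluses).
#' @param tumor_placement `"disk"` packs tumor cells into the smallest
#'   central disk at carrying capacity (engrafted-mass geometry);
#'   `"uniform"` scatters them uniformly over the grid (dispersed
#'   low-density seeding, appropriate for intrinsic growth-rate assays).
#' @param nk_placement `"periphery"` (boundary annulus, the default
#'   intravenous picture) or `"adjacent"` (ring around the tumor mass,
#'   mimicking intratumoral injection).
#' @param rechallenge_days,rechallenge_size Days and bolus size of tumor
#'   re-additions in rechallenge mode.
#' @param effect_table Optional gene-effect table (see
#'   [load_effect_table()]).
#' @param expression_pool Optional feature-by-cell expression matrix from
#'   which NK agents draw their profiles.
#' @param antigen_pool Optional numeric vector of normalized CAR-target
#'   antigen expression values sampled per tumor agent (default: all 1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(grid = grid_config(),
                              duration = 14,
                              etr = 1,
                              n_tumor_init = 1000L,
                              n_nk_init = NULL,
                              products = list(NT = nk_product()),
                              initial_product = names(products)[1],
                              tumor = tumor_params(),
                              cytokines = list(IL15 = cytokine_params()),
                              dosing = dosing_schedule(),
                              seed = 1L,
                              replicates = 1L,
                              record_every = 1L,
                              assay_mode = c("in_vivo", "autonomous_growth",
                                             "rechallenge"),
                              tumor_placement = c("disk", "uniform"),
                              nk_placement = c("periphery", "adjacent"),
                              rechallenge_days = numeric(),
                              rechallenge_size = 0L,
                              effect_table = NULL,
                              expression_pool = NULL,
                              antigen_pool = NULL) {
  assay_mode <- match.arg(assay_mode)
  tumor_placement <- match.arg(tumor_placement)
  nk_placement <- match.arg(nk_placement)
  etr <- parse_etr(etr)
  stopifnot(duration > 0, etr > 0 || n_tumor_init == 0L,
            replicates >= 1L, record_every >= 1L, n_tumor_init >= 0L)
  if (is.null(n_nk_init)) n_nk_init <- as.integer(round(n_tumor_init * etr))
  if (length(products) && is.null(names(products)))
    names(products) <- vapply(products, `[[`, "", "name")
  structure(list(grid = grid, duration = duration, etr = etr,
                 n_tumor_init = as.integer(n_tumor_init),
                 n_nk_init = as.integer(n_nk_init),
                 products = products, initial_product = initial_product,
                 tumor = tumor, cytokines = cytokines, dosing = dosing,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 record_every = as.integer(record_every),
                 assay_mode = assay_mode,
                 tumor_placement = tumor_placement,
                 nk_placement = nk_placement,
                 rechallenge_days = rechallenge_days,
                 rechallenge_size = as.integer(rechallenge_size),
                 effect_table = effect_table,
                 expression_pool = expression_pool,
                 antigen_pool = antigen_pool),
            class = "simulation_config")
}

#' Parse an effector-to-target ratio
#'
#' @param x A number or a string like `"1:5"` (NK:tumor).
#' @return The ratio as a single number.
#' @export
parse_etr <- function(x) {
  if (is.character(x)) {
    parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || anyNA(parts) || parts[2] <= 0)
      stop("malformed ETR string: ", x)
    return(parts[1] / parts[2])
  }
  as.numeric(x)
}

#' Preset configurations for the two calibrated disease models
#'
#' Returns a [simulation_config()] with the published lattice, tumor,
#' cytokine and transition parameters for the B-cell lymphoma or the
#' glioblastoma model. Product-specific values (pc, dC, mu_c, S0, bpc,
#' dE) were fitted per cell product and are not published; the presets
#' carry this package's documented defaults, which any user can
#' override.
#'
#' @param disease `"lymphoma"` or `"gbm"`.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A `simulation_config`.
#' @export
preset_config <- function(disease = c("lymphoma", "gbm"), ...) {
  disease <- match.arg(disease)
  base <- switch(disease,
    lymphoma = list(
      tumor = tumor_params(p_b = 0.455),
      etr = 1, replicates = 30L, duration = 14,
      cytokines = list(IL15 = cytokine_params(half_life = 2.5))),
    gbm = list(
      tumor = tumor_params(p_b = 0.223),
      etr = parse_etr("1:5"), replicates = 5L, duration = 37,
      nk_placement = "adjacent",
      cytokines = list(IL15 = cytokine_params(half_life = 2.5),
                       IL21 = cytokine_params(half_life = 0.2))))
  args <- utils::modifyList(base, list(...))
  do.call(simulation_config, args)
}
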