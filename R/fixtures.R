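# Synthetic-data fixtures: effect tables, expression pools, observed
# trajectories and micro-scenarios. Everything is a pure function of a
# spec plus seed, so all other modules are testable with no downloads.

#' Fixture generation spec
#'
#' @param n_genes Number of features in the synthetic effect table.
#' @param n_cells Number of cells in the synthetic expression pool.
#' @param markers Exhaustion-marker feature ids to include.
#' @param growth_treated,growth_control Per-day growth rates used by the
#'   analytic trajectory generator.
#' @param noise_sd Multiplicative noise SD of the trajectory generator.
#' @param days Sampling days of the trajectory generator.
#' @param seed RNG seed; identical specs regenerate byte-identical
#'   fixtures.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 20L, n_cells = 100L,
                         markers = c("LAG3", "PDCD1"),
                         growth_treated = 0.2, growth_control = 0.455,
                         noise_sd = 0.05, days = c(0, 7, 14),
                         seed = 1L) {
  stopifnot(n_genes >= 1L, n_cells >= 1L, noise_sd >= 0,
            !is.unsorted(days, strictly = TRUE))
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), markers = markers,
                 growth_treated = growth_treated,
                 growth_control = growth_control,
                 noise_sd = noise_sd, days = days, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Synthetic gene-effect table
#'
#' Stand-in for a fitted coefficient table: `n_genes` features with
#' coefficients drawn from `N(0, 0.5^2)`, plus the requested
#' exhaustion-marker rows (default LAG3 and PDCD1) carrying negative
#' coefficients and marker flags. The sign convention is
#' pro-cytotoxic-positive, so inhibitory-marker accumulation lowers the
#' kill probability.
#'
#' @param spec A [fixture_spec()].
#' @return A `gene_effect_table`.
#' @export
synth_effect_table <- function(spec = fixture_spec()) {
  if (length(spec$markers) && spec$n_genes < 2L)
    stop("need n_genes >= 2 when markers are requested")
  set.seed(spec$seed)
  n_other <- spec$n_genes - length(spec$markers)
  ids <- c(sprintf("GENE%03d", seq_len(n_other)), spec$markers)
  beta <- c(stats::rnorm(n_other, 0, 0.5),
            -abs(stats::rnorm(length(spec$markers), 0.5, 0.2)))
  as_effect_table(data.frame(
    feature_id = ids, beta = beta,
    is_exhaustion_marker = c(rep(FALSE, n_other),
                             rep(TRUE, length(spec$markers)))))
}

#' Synthetic expression pool
#'
#' Non-negative feature-by-cell matrix of log-normal draws with
#' per-feature scales, emulating normalized single-cell expression
#' profiles. Row names match [synth_effect_table()] feature ids.
#'
#' @param spec A [fixture_spec()].
#' @return A numeric matrix, `n_genes` x `n_cells`.
#' @export
synth_expression_pool <- function(spec = fixture_spec()) {
  set.seed(spec$seed + 1L)
  tab <- synth_effect_table(spec)
  scale <- stats::runif(spec$n_genes, 0.2, 1)
  mat <- matrix(stats::rlnorm(spec$n_genes * spec$n_cells,
                              meanlog = -0.5, sdlog = 0.6),
                spec$n_genes, spec$n_cells) * scale
  rownames(mat) <- tab$feature_id
  colnames(mat) <- sprintf("CELL%04d", seq_len(spec$n_cells))
  mat
}

#' Synthetic observed tumor-progression curve
#'
#' Analytic stand-in for normalized radiance curves:
#' `ratio(day) = exp((r_treated - r_control) * day) * (1 + eps)` with
#' `eps ~ N(0, noise_sd^2)`, clipped at zero, plus a control group
#' carrying the control fold-change curve
#' `exp(r_control * day) * (1 + eps)`. For calibration recovery tests
#' prefer simulator-generated curves via [run_replicates()].
#'
#' @param spec A [fixture_spec()].
#' @return An [observed_progression()] data frame with groups
#'   `"treated"` and `"control"`.
#' @export
synth_trajectory <- function(spec = fixture_spec()) {
  set.seed(spec$seed + 2L)
  nd <- length(spec$days)
  ratio <- exp((spec$growth_treated - spec$growth_control) * spec$days) *
    (1 + stats::rnorm(nd, 0, spec$noise_sd))
  ctrl <- exp(spec$growth_control * spec$days) *
    (1 + stats::rnorm(nd, 0, spec$noise_sd))
  observed_progression(data.frame(
    group = rep(c("treated", "control"), each = nd),
    day = rep(spec$days, 2),
    ratio = pmax(c(ratio, ctrl), 0)))
}

# Inert parameter blocks for micro-scenarios: no movement, no
# demography, so a single step exercises exactly one rule.
inert_tumor <- function(...) {
  tumor_params(p_b = 0, d_b = 0, m_b = 0, p_mutate = 0, ...)
}

inert_product <- function(name = "NT",
                          kill = nk_kill_params(sigma_c = 0),
                          prolif = nk_prolif_params(pc = 0, sigma_pc = 0),
                          exhaustion = exhaustion_params(),
                          rates = phenotype_rates(d_c = 0, d_v = 0, d_e = 0,
                                                  p_v = 0),
                          motility = motility_params(m_n = 0)) {
  nk_product(name = name, kill = kill, prolif = prolif,
             exhaustion = exhaustion, rates = rates, motility = motility)
}

#' Deterministic micro-scenario states
#'
#' Tiny hand-built model states with documented single-step outcome
#' distributions, used as oracles for the agent rules:
#'
#' * `one_nc_one_tumor` — `n` well-separated cytotoxic-NK/tumor pairs;
#'   after one step the kill frequency is Binomial(n, pkill).
#' * `clearance_event` — `n` tumor-exposed cytotoxic agents on a
#'   tumor-free grid; with `kb_minus = 1` all become vigilant in one
#'   step.
#' * `recall_event` — `n` vigilant agents each adjacent to an inert
#'   tumor cell; one step converts each back to cytotoxic with
#'   probability `kb_plus`.
#' * `full_capacity_cell` — a 3x3 grid with every cell at carrying
#'   capacity and division certain; one step adds no cells.
#'
#' @param name Scenario name.
#' @param n Number of replicated agents/pairs in the state.
#' @param mu_c Baseline cytotoxicity given to cytotoxic agents
#'   (degenerate, `sigma_c = 0`).
#' @param gamma CAR exponent for the kill kernel.
#' @param p_evade_base Tumor evasion probability (with
#'   `kappa_antigen = 0` so it applies as-is).
#' @param s0 Serial-killing capacity of the cytotoxic agents.
#' @param kb_minus,kb_plus Transition probabilities.
#' @return A model state ready for [step_model()].
#' @export
micro_scenario <- function(name = c("one_nc_one_tumor", "clearance_event",
                                    "recall_event", "full_capacity_cell"),
                           n = 1L, mu_c = 0.5, gamma = 1,
                           p_evade_base = 0, s0 = 1L,
                           kb_minus = 1.0, kb_plus = 0.9) {
  name <- match.arg(name)
  n <- as.integer(n)
  # pair scenarios: pairs on a spacing-4 sub-lattice so Moore-1
  # neighborhoods never overlap
  ncols <- max(3L, ceiling(sqrt(n)))
  side <- max(9L, 4L * (ncols + 1L))
  prod <- inert_product(
    kill = nk_kill_params(mu_c = mu_c, sigma_c = 0, gamma = gamma),
    prolif = nk_prolif_params(pc = 0, sigma_pc = 0),
    exhaustion = exhaustion_params(s0 = max(s0, 1L)),
    rates = phenotype_rates(d_c = 0, d_v = 0, d_e = 0, p_v = 0,
                            kb_minus = kb_minus, kb_plus = kb_plus),
    motility = motility_params(m_n = 0))
  base_cfg <- simulation_config(
    grid = grid_config(width = side, height = side),
    duration = 1, n_tumor_init = 0L, n_nk_init = 0L,
    products = list(NT = prod),
    tumor = inert_tumor(p_evade_base = p_evade_base, kappa_antigen = 0),
    cytokines = list(), replicates = 1L)

  model <- initialize_tme(base_cfg)
  pair_pos <- function(k) {
    i <- (k - 1L) %/% ncols; j <- (k - 1L) %% ncols
    cbind(3L + 4L * i, 3L + 4L * j)
  }
  ks <- seq_len(n)
  pos <- pair_pos(ks)

  if (name == "one_nc_one_tumor" || name == "recall_event") {
    model$tumor <- list(row = pos[, 1], col = pos[, 2] + 1L,
                        antigen = rep(1, n), mutations = rep(0L, n))
    model <- refresh_tumor_count(model)
  }
  if (name != "full_capacity_cell") {
    model$nk <- list(row = pos[, 1], col = pos[, 2],
                     phen = rep(if (name == "recall_event") PHEN_NV
                                else PHEN_NC, n),
                     c_nk = rep(mu_c, n), kills = rep(0, n),
                     s = rep(as.numeric(s0), n), age = rep(0L, n),
                     exposed = rep(name == "clearance_event", n),
                     product = rep(1L, n), static = rep(0, n),
                     markers = matrix(0, n, 0))
    model$n_nk0 <- n
  } else {
    cfg3 <- simulation_config(
      grid = grid_config(width = 3L, height = 3L),
      duration = 1, n_tumor_init = 9L * grid_config()$b_max,
      n_nk_init = 0L, products = list(NT = prod),
      tumor = tumor_params(p_b = 1e3, d_b = 0, m_b = 0, p_mutate = 0),
      cytokines = list(), tumor_placement = "disk")
    model <- initialize_tme(cfg3)
  }
  model
}

#' Write all fixture files to a directory
#'
#' Emits the synthetic effect table, expression pool and observed
#' trajectory in the tabular formats the other modules read.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- synth_effect_table(spec)
  pool <- synth_expression_pool(spec)
  traj <- synth_trajectory(spec)
  paths <- file.path(dir, c("synthetic_effect_table.csv",
                            "synthetic_expression_pool.csv",
                            "synthetic_observed_progression.csv"))
  utils::write.csv(tab, paths[1], row.names = FALSE)
  utils::write.csv(data.frame(feature_id = rownames(pool), pool,
                              check.names = FALSE),
                   paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(traj), paths[3], row.names = FALSE)
  invisible(paths)
}
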