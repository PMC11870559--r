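# Shared builders for small test configurations.

# Tumor-only growth configuration on a dispersed seeding so crowding
# does not bias the intrinsic growth rate.
growth_config <- function(p_b = 0.455, duration = 8, n = 1000L,
                          side = 100L, seed = 1L) {
  simulation_config(grid = grid_config(side, side), duration = duration,
                    n_tumor_init = n, n_nk_init = 0L,
                    tumor = tumor_params(p_b = p_b),
                    tumor_placement = "uniform", cytokines = list(),
                    replicates = 30L, seed = seed)
}

# Log-linear growth-rate estimate from a mean trajectory.
fit_growth_rate <- function(mean_record) {
  unname(stats::coef(stats::lm(log(B) ~ day, data = mean_record))[2])
}

# Inert two-population configuration: nothing moves, divides or dies
# unless a rate is switched on explicitly.
frozen_config <- function(...) {
  args <- utils::modifyList(list(
    grid = grid_config(20L, 20L), duration = 1,
    n_tumor_init = 50L, etr = 1,
    products = list(NT = nk_product(
      kill = nk_kill_params(sigma_c = 0),
      prolif = nk_prolif_params(pc = 0, sigma_pc = 0),
      rates = phenotype_rates(d_c = 0, d_v = 0, d_e = 0, p_v = 0,
                              kb_minus = 0),
      motility = motility_params(m_n = 0))),
    tumor = tumor_params(p_b = 0, d_b = 0, m_b = 0, p_mutate = 0,
                         p_evade_base = 0),
    cytokines = list(), seed = 1L), list(...))
  do.call(simulation_config, args)
}

# Small in-vivo configuration used by calibration and engine tests.
small_invivo_config <- function(...) {
  args <- utils::modifyList(list(
    grid = grid_config(40L, 40L), duration = 6,
    n_tumor_init = 200L, etr = 1,
    products = list(NT = nk_product(name = "NT")),
    cytokines = list(), replicates = 3L, seed = 11L), list(...))
  do.call(simulation_config, args)
}
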