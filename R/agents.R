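# Per-agent behavioral kernels. All functions here are pure and
# vectorized over agents; the engine composes them into steps.

#' Truncated-normal draw on [0, Inf)
#'
#' Inverse-CDF sampling, exact and vectorized. With `sd = 0` returns
#' `max(mean, 0)` (degenerate draw).
#'
#' @param n Number of draws.
#' @param mean,sd Mean and SD of the parent normal (recycled).
#' @return Non-negative numeric vector of length `n`.
#' @export
rtruncnorm0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- pmax(mean, 0)
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), lo, 1)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
    out[pos] <- pmax(out[pos], 0)  # guard against qnorm(1-eps) edge
  }
  out
}

#' Sample baseline cytotoxicity for new cytotoxic NK agents
#'
#' Draws `c_nk ~ truncN(mu_c, sigma_c^2)` on `[0, Inf)`.
#'
#' @param params An [nk_kill_params()].
#' @param n Number of agents.
#' @return Numeric vector of baseline cytotoxicities.
#' @export
sample_baseline_cytotoxicity <- function(params, n = 1L) {
  rtruncnorm0(n, params$mu_c, params$sigma_c)
}

#' Per-contact kill probability
#'
#' `pkill = logistic(c_nk + g_nk)^gamma * (1 - p_evade)`: the logistic
#' of baseline cytotoxicity plus genetic effect, raised to the CAR
#' exponent, scaled down by the target's evasion probability.
#'
#' @param c_nk Baseline cytotoxicity (vectorized).
#' @param g_nk Genetic effect in `(-1, 1)` (vectorized).
#' @param gamma CAR effect exponent (> 0).
#' @param p_evade Target evasion probability in `[0, 1]` (vectorized).
#' @return Kill probabilities in `[0, 1]`.
#' @export
compute_pkill <- function(c_nk, g_nk = 0, gamma = 1, p_evade = 0) {
  stopifnot(all(gamma > 0), all(p_evade >= 0 & p_evade <= 1))
  stats::plogis(c_nk + g_nk)^gamma * (1 - p_evade)
}

#' Effective evasion probability of tumor cells
#'
#' Baseline evasion is proportionally reduced by CAR-target antigen
#' expression (`* (1 - kappa * antigen)`) and increased additively by
#' `p_mutate_increment` per acquired resistance mutation, clipped to
#' `[0, 1]`.
#'
#' @param params A [tumor_params()].
#' @param antigen_expr Normalized antigen expression in `[0, 1]`
#'   (vectorized).
#' @param mutations Non-negative integer mutation counts (vectorized).
#' @return Evasion probabilities in `[0, 1]`.
#' @export
effective_evasion <- function(params, antigen_expr = 1, mutations = 0L) {
  p <- params$p_evade_base * (1 - params$kappa_antigen * antigen_expr) +
    mutations * params$p_mutate_increment
  pmin(pmax(p, 0), 1)
}

#' Hill stimulus terms of the NK proliferation model
#'
#' The tumor-stimulation term
#' `kb = (B^g1 + d) / (B^g1 + B50^g1 + d)` and the combined stimulus
#' `w = kb * (c^g2 + d) / (c^g2 + c50^g2 + d)`, both in `(0, 1)`. In
#' tumor-free autonomous-growth mode `kb` is pinned to the configured
#' constant (`kb_autonomous`, default 1) instead of being computed from
#' the (absent) tumor load.
#'
#' @param params An [nk_prolif_params()].
#' @param b_local Local tumor count (vectorized, >= 0).
#' @param c_local Local cytokine level (vectorized, >= 0).
#' @param autonomous Tumor-free assay mode flag.
#' @return `list(kb =, w =)` of vectors.
#' @export
stimulus_terms <- function(params, b_local, c_local, autonomous = FALSE) {
  stopifnot(all(b_local >= 0), all(c_local >= 0))
  d <- params$delta
  if (autonomous) {
    kb <- rep_len(params$kb_autonomous, max(length(b_local), length(c_local)))
  } else {
    bg <- b_local^params$gamma1
    kb <- (bg + d) / (bg + params$b50^params$gamma1 + d)
  }
  cg <- c_local^params$gamma2
  w <- kb * (cg + d) / (cg + params$c50^params$gamma2 + d)
  list(kb = kb, w = w)
}

#' Age- and stimulus-dependent NK proliferation rate
#'
#' Mean rate `pc * exp(w - bpc * t)` per day (`w` forced to 0 under the
#' vanilla model), then one truncated-normal draw per agent around that
#' mean with SD `sigma_pc`.
#'
#' @param params An [nk_prolif_params()].
#' @param age_t Agent age in steps (vectorized, >= 0).
#' @param w Stimulus term from [stimulus_terms()] (vectorized).
#' @return Sampled per-day proliferation rates (non-negative).
#' @export
proliferation_rate <- function(params, age_t, w = 0) {
  stopifnot(all(age_t >= 0))
  if (params$model == "VM") w <- 0
  n <- max(length(age_t), length(w))
  mean_rate <- params$pc * exp(rep_len(w, n) - params$bpc * rep_len(age_t, n))
  rtruncnorm0(n, mean_rate, params$sigma_pc)
}

#' Rate-to-step event probabilities
#'
#' Death events over one step of `dt_days` use
#' `p = 1 - exp(-rate * dt_days)`; division events use
#' `p = min(exp(rate * dt_days) - 1, 1)`. With both applied each step
#' the expected per-day growth factor of a population with division rate
#' `p` and death rate `d` is exactly `exp(p - d)`, so configured
#' per-day rates are recoverable from simulated trajectories by a
#' log-linear fit.
#'
#' @param rate Per-day rate (vectorized, >= 0).
#' @param dt_days Step length in days.
#' @return Per-step event probability in `[0, 1]`.
#' @name rate_to_step
NULL

#' @rdname rate_to_step
#' @export
p_step_death <- function(rate, dt_days) 1 - exp(-rate * dt_days)

#' @rdname rate_to_step
#' @export
p_step_division <- function(rate, dt_days) pmin(exp(rate * dt_days) - 1, 1)

#' Serial-killing capacity after a given kill history
#'
#' EM1/EM2: `s = s0 - kills`. EM3: `s = s0 - kills * exp(g_exh)` with
#' `g_exh = sum(x / (x50 + x))` over the agent's current
#' exhaustion-marker values `x`.
#'
#' @param exh An [exhaustion_params()].
#' @param kills Cumulative kill counts (vectorized).
#' @param markers Numeric matrix (agents x markers) of current
#'   exhaustion-marker expression; ignored under EM1/EM2.
#' @return Remaining capacities (may be <= 0, which marks exhaustion).
#' @export
skc_remaining <- function(exh, kills, markers = NULL) {
  if (exh$variant == "EM3" && !is.null(markers) && ncol(markers)) {
    x50 <- rep_len(exh$x50, ncol(markers))
    g_exh <- rowSums(sweep(markers, 2, x50,
                           function(x, h) x / (h + x)))
    exh$s0 - kills * exp(g_exh)
  } else {
    exh$s0 - kills
  }
}
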