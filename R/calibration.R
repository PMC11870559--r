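# Calibration: fit model parameters to observed normalized
# tumor-progression curves by iterative coarse-to-fine grid search
# minimizing mean squared error.

#' Observed tumor-progression table
#'
#' @param df Data frame with columns `group`, `day`, `ratio`. The
#'   `ratio` is normalized tumor progression: treated burden divided by
#'   the mean tumor-only control burden at the same day. A group named
#'   `"control"` is interpreted as the tumor-only fold-change curve
#'   (used to fix the tumor growth rate first).
#' @return An `observed_progression` data frame.
#' @export
observed_progression <- function(df) {
  need <- c("group", "day", "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observed progression missing column(s): ",
         paste(miss, collapse = ", "))
  stopifnot(all(df$ratio >= 0))
  for (g in unique(df$group)) {
    d <- df$day[df$group == g]
    if (is.unsorted(d, strictly = TRUE))
      stop("days must be strictly increasing within group ", g)
  }
  class(df) <- c("observed_progression", "data.frame")
  df
}

#' Normalized tumor progression of a treated run
#'
#' Divides the mean treated tumor count by the mean control tumor count
#' at each observation day (tumor count standing in for radiance, to
#' which it is assumed proportional).
#'
#' @param treated,control Aggregate records (`$mean` from
#'   [run_replicates()]), or plain data frames with `day` and `B`.
#' @param obs_days Days at which to evaluate (linear interpolation
#'   between recorded steps).
#' @return Numeric vector of ratios at `obs_days`.
#' @export
normalized_progression <- function(treated, control, obs_days) {
  tr <- if (is.list(treated) && !is.data.frame(treated)) treated$mean else treated
  ct <- if (is.list(control) && !is.data.frame(control)) control$mean else control
  tv <- stats::approx(tr$day, tr$B, xout = obs_days)$y
  cv <- stats::approx(ct$day, ct$B, xout = obs_days)$y
  if (anyNA(tv) || anyNA(cv))
    stop("observation days outside the simulated range")
  bad <- which(cv <= 0)
  if (length(bad))
    stop("control tumor count is zero at day ", obs_days[bad[1]])
  tv / cv
}

#' Mean squared error between simulated and observed ratios
#'
#' @param sim,obs Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse_loss <- function(sim, obs) {
  if (length(sim) != length(obs))
    stop("length mismatch: ", length(sim), " vs ", length(obs))
  mean((sim - obs)^2)
}

#' Search-space definition for calibration
#'
#' @param tumor Named list of candidate grids for tumor parameters fit
#'   first against the control curve (typically `p_b`, optionally
#'   `d_b`).
#' @param nk Named list of candidate grids for NK/product parameters fit
#'   per group (names are config paths such as `"kill.mu_c"`,
#'   `"prolif.pc"`, `"exhaustion.s0"`, `"rates.d_c"`).
#' @param etr Candidate effector-to-target ratios.
#' @param refine_stages Number of refinement stages after the coarse
#'   pass.
#' @param refine_factor Grid-spacing shrink factor per stage.
#' @return A `search_space` list.
#' @export
search_space <- function(tumor = list(), nk = list(), etr = 1,
                         refine_stages = 1L, refine_factor = 4) {
  stopifnot(length(etr) >= 1,
            all(vapply(c(tumor, nk), length, 0L) >= 1L))
  structure(list(tumor = tumor, nk = nk, etr = etr,
                 refine_stages = as.integer(refine_stages),
                 refine_factor = refine_factor),
            class = "search_space")
}

# Set a dotted-path field ("prolif.pc") inside an nk_product or config.
set_path <- function(obj, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1L) { obj[[keys]] <- value; return(obj) }
  obj[[keys[1]]] <- set_path(obj[[keys[1]]], paste(keys[-1], collapse = "."),
                             value)
  obj
}

apply_nk_params <- function(config, group, values) {
  prod <- config$products[[group]]
  for (nm in names(values)) prod <- set_path(prod, nm, values[[nm]])
  config$products[[group]] <- prod
  config
}

simulate_group_ratio <- function(config, group, etr, obs_days, replicates,
                                 control) {
  cfg <- config
  cfg$etr <- etr
  cfg$n_nk_init <- as.integer(round(cfg$n_tumor_init * etr))
  cfg$initial_product <- group
  agg <- run_replicates(cfg, replicates)
  normalized_progression(agg, control, obs_days)
}

expand_candidates <- function(grids) {
  if (!length(grids)) return(data.frame(row.names = 1))
  expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
}

refine_grid <- function(grid, best, factor) {
  if (length(grid) < 2) return(sort(unique(grid)))
  span <- diff(range(grid)) / factor
  lo <- max(min(grid), best - span / 2)
  hi <- min(max(grid), best + span / 2)
  sort(unique(c(best, seq(lo, hi, length.out = length(grid)))))
}

#' Coarse-to-fine global search calibration
#'
#' Stage 1 fits the tumor growth parameters to the control (tumor-only
#' fold-change) curve and fixes them. Stage 2 grid-searches the NK
#' parameters for every group under each candidate ETR, selecting the
#' ETR minimizing the total MSE across groups. Further stages shrink
#' each parameter grid around the incumbent and re-search. Candidates
#' are scored with a reduced replicate count; incumbents are re-scored
#' at the full count.
#'
#' @param space A [search_space()].
#' @param obs An [observed_progression()] table. Treated group names
#'   must match product names in `base_config`.
#' @param base_config A [simulation_config()] holding everything not
#'   searched.
#' @param search_replicates Replicates per candidate evaluation.
#' @param final_replicates Replicates for re-scoring incumbents.
#' @param top_k Number of best parameter sets retained per group.
#' @return A `calibration_result`: fixed tumor parameters, per-group
#'   top-k tables, the selected ETR, per-group and total MSE, and
#'   CV-over-time stability diagnostics of the best fits.
#' @export
global_search <- function(space, obs, base_config,
                          search_replicates = 5L,
                          final_replicates = base_config$replicates,
                          top_k = 10L) {
  groups <- setdiff(unique(obs$group), "control")
  miss <- setdiff(groups, names(base_config$products))
  if (length(miss))
    stop("observed groups without a product block: ",
         paste(miss, collapse = ", "))

  # ---- stage 1: tumor growth parameters against the control curve
  ctrl_obs <- obs[obs$group == "control", , drop = FALSE]
  cfg <- base_config
  tumor_best <- list()
  if (length(space$tumor)) {
    if (!nrow(ctrl_obs))
      stop("tumor parameter search requires a 'control' group")
    cand <- expand_candidates(space$tumor)
    scores <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ci <- cfg
      for (nm in names(cand)) ci$tumor[[nm]] <- cand[i, nm]
      agg <- run_control(ci, search_replicates)
      sim <- stats::approx(agg$mean$day, agg$mean$fold_B,
                           xout = ctrl_obs$day)$y
      scores[i] <- mse_loss(sim, ctrl_obs$ratio)
    }
    best <- which.min(scores)
    tumor_best <- as.list(cand[best, , drop = FALSE])
    for (nm in names(tumor_best)) cfg$tumor[[nm]] <- tumor_best[[nm]]
  }

  obs_days <- sort(unique(obs$day[obs$group != "control"]))
  control <- run_control(cfg, search_replicates)

  score_candidates <- function(grids, group, etr) {
    cand <- expand_candidates(grids)
    mse <- numeric(nrow(cand))
    g_obs <- obs[obs$group == group, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      ci <- apply_nk_params(cfg, group, as.list(cand[i, , drop = FALSE]))
      sim <- simulate_group_ratio(ci, group, etr, g_obs$day,
                                  search_replicates, control)
      mse[i] <- mse_loss(sim, g_obs$ratio)
    }
    cand$mse <- mse
    cand[order(cand$mse), , drop = FALSE]
  }

  # ---- stage 2: ETR selection with coarse NK grids
  etr_total <- numeric(length(space$etr))
  etr_tables <- vector("list", length(space$etr))
  for (e in seq_along(space$etr)) {
    tabs <- lapply(groups, function(g)
      score_candidates(space$nk, g, space$etr[e]))
    names(tabs) <- groups
    etr_tables[[e]] <- tabs
    etr_total[e] <- sum(vapply(tabs, function(t) t$mse[1], 0))
  }
  best_e <- which.min(etr_total)
  etr_sel <- space$etr[best_e]
  tabs <- etr_tables[[best_e]]

  # ---- stage 3+: refine grids around incumbents under the chosen ETR
  grids <- space$nk
  for (stage in seq_len(space$refine_stages)) {
    for (g in groups) {
      inc <- tabs[[g]][1, names(grids), drop = FALSE]
      ref <- grids
      for (nm in names(grids))
        ref[[nm]] <- refine_grid(grids[[nm]], inc[[nm]],
                                 space$refine_factor^stage)
      tab2 <- score_candidates(ref, g, etr_sel)
      merged <- rbind(tabs[[g]], tab2)
      tabs[[g]] <- merged[order(merged$mse), , drop = FALSE]
    }
  }

  # ---- final re-scoring of incumbents at full replicates + stability
  result_groups <- list()
  for (g in groups) {
    top <- utils::head(tabs[[g]], top_k)
    g_obs <- obs[obs$group == g, , drop = FALSE]
    ci <- apply_nk_params(cfg, g, as.list(top[1, names(space$nk),
                                              drop = FALSE]))
    ci$etr <- etr_sel
    ci$n_nk_init <- as.integer(round(ci$n_tumor_init * etr_sel))
    ci$initial_product <- g
    agg <- run_replicates(ci, final_replicates)
    ctrl_full <- run_control(cfg, final_replicates)
    sim <- normalized_progression(agg, ctrl_full, g_obs$day)
    final_mse <- mse_loss(sim, g_obs$ratio)
    # stability: CV of tumor progression across replicates per obs day
    per_rep <- vapply(agg$replicates, function(r)
      stats::approx(r$day, r$B, xout = g_obs$day)$y,
      numeric(nrow(g_obs)))
    per_rep <- matrix(per_rep, nrow = nrow(g_obs))
    mu <- rowMeans(per_rep)
    cv <- apply(per_rep, 1, stats::sd) / ifelse(mu > 0, mu, NA)
    result_groups[[g]] <- list(top = top, final_mse = final_mse,
                               best_ratio = sim,
                               stability = data.frame(day = g_obs$day,
                                                      cv = cv))
  }
  structure(list(tumor = tumor_best, groups = result_groups,
                 etr = etr_sel,
                 mse_by_group = vapply(result_groups,
                                       function(x) x$final_mse, 0),
                 total_mse = sum(vapply(result_groups,
                                        function(x) x$final_mse, 0)),
                 etr_total_mse = stats::setNames(etr_total,
                                                 as.character(space$etr))),
            class = "calibration_result")
}
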