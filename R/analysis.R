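# Post-simulation analytics: tumor-growth AUC, time to clearance,
# perturbation sweeps with random-forest feature importance, and group
# statistical comparison.

#' Area under the tumor-growth curve
#'
#' Trapezoidal integral of the tumor trajectory (fold change by
#' default) against time in days over `[0, horizon]`.
#'
#' @param record A time-series record data frame.
#' @param horizon Upper integration limit in days.
#' @param column Trajectory column; `"fold_B"` (default) or `"B"`.
#' @return The AUC (days x trajectory units).
#' @export
auc_tumor_growth <- function(record, horizon = max(record$day),
                             column = "fold_B") {
  if (horizon > max(record$day) + 1e-9)
    stop("horizon ", horizon, " beyond recorded range ", max(record$day))
  keep <- record$day <= horizon + 1e-9
  x <- record$day[keep]; y <- record[[column]][keep]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Time to sustained tumor clearance
#'
#' First recorded day at which the tumor count is zero and stays zero
#' until the end of the record; `NA` if the tumor is never (durably)
#' cleared.
#'
#' @param record A time-series record data frame.
#' @return A day, or `NA_real_`.
#' @export
time_to_clearance <- function(record) {
  zero <- record$B == 0
  if (!any(zero)) return(NA_real_)
  # last index from which everything is zero
  run <- rev(cumprod(rev(zero)))
  idx <- which(run == 1)
  if (!length(idx)) return(NA_real_)
  record$day[idx[1]]
}

#' Parameter perturbation sweep
#'
#' Runs the simulator over the Cartesian product of the supplied
#' parameter grids and summarizes each run by tumor-growth AUC and time
#' to clearance. Parameter names use dotted config paths relative to
#' the initial product (`"exhaustion.s0"`, `"kill.mu_c"`,
#' `"prolif.pc"`, ...) or `"etr"`.
#'
#' @param base_config A [simulation_config()].
#' @param grids Named list of value vectors.
#' @param runs Replicate runs per combination.
#' @param horizon AUC horizon in days.
#' @return A data frame: one row per run with the parameter values,
#'   `replicate`, `auc`, and `clearance_day`.
#' @export
run_sweep <- function(base_config, grids, runs = 3L,
                      horizon = base_config$duration) {
  stopifnot(length(grids) >= 1L, runs >= 1L)
  cand <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cand) * runs)
  k <- 0L
  group <- base_config$initial_product
  for (i in seq_len(nrow(cand))) {
    cfg <- base_config
    for (nm in names(cand)) {
      if (nm == "etr") {
        cfg$etr <- cand[i, nm]
        cfg$n_nk_init <- as.integer(round(cfg$n_tumor_init * cfg$etr))
      } else {
        cfg <- apply_nk_params(cfg, group, stats::setNames(
          list(cand[i, nm]), nm))
      }
    }
    for (r in seq_len(runs)) {
      rec <- run_simulation(cfg, seed = cfg$seed + (i - 1L) * runs + r - 1L)$record
      k <- k + 1L
      out[[k]] <- cbind(cand[i, , drop = FALSE],
                        data.frame(replicate = r,
                                   auc = auc_tumor_growth(rec, horizon),
                                   clearance_day = time_to_clearance(rec)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Random-forest feature importance of sweep parameters
#'
#' Fits a seeded random-forest regressor of the response on the swept
#' parameters and reports mean decrease in impurity (MDI, normalized to
#' sum to 1) and permutation importance (PI): the mean increase in
#' held-out MSE over `pi_repeats` independent permutations of each
#' feature on a held-out split.
#'
#' @param sweep Data frame from [run_sweep()] (or any table of
#'   predictors plus a response column).
#' @param response Response column name (default `"auc"`).
#' @param features Predictor column names; default every swept
#'   parameter column.
#' @param num_trees Forest size.
#' @param pi_repeats Permutation repeats per feature (>= 10 advised).
#' @param holdout Fraction of rows held out for PI.
#' @param seed RNG seed for fitting, the split and the permutations.
#' @return An `importance_report` data frame: `feature`, `mdi`, `pi`.
#' @export
feature_importance <- function(sweep, response = "auc", features = NULL,
                               num_trees = 500L, pi_repeats = 10L,
                               holdout = 0.3, seed = 1L) {
  if (is.null(features))
    features <- setdiff(names(sweep),
                        c(response, "replicate", "auc", "clearance_day"))
  stopifnot(length(features) >= 1L)
  dat <- sweep[, c(features, response)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 20L) stop("need at least 20 complete rows")
  y <- dat[[response]]
  if (stats::sd(y) == 0) {
    warning("constant response; importances are degenerate zeros")
    return(structure(data.frame(feature = features, mdi = 0, pi = 0),
                     class = c("importance_report", "data.frame")))
  }
  set.seed(seed)
  n <- nrow(dat)
  test <- sample.int(n, max(2L, round(holdout * n)))
  train <- setdiff(seq_len(n), test)
  fo <- stats::as.formula(paste(response, "~",
                                paste(features, collapse = "+")))
  fit <- ranger::ranger(fo, data = dat[train, , drop = FALSE],
                        num.trees = num_trees, importance = "impurity",
                        seed = seed)
  mdi <- fit$variable.importance[features]
  mdi <- pmax(mdi, 0)
  mdi <- if (sum(mdi) > 0) mdi / sum(mdi) else mdi
  base_mse <- mean((stats::predict(fit, dat[test, , drop = FALSE])$predictions -
                      y[test])^2)
  pi <- vapply(features, function(f) {
    incr <- numeric(pi_repeats)
    for (r in seq_len(pi_repeats)) {
      d <- dat[test, , drop = FALSE]
      d[[f]] <- sample(d[[f]])
      incr[r] <- mean((stats::predict(fit, d)$predictions - y[test])^2) -
        base_mse
    }
    mean(incr)
  }, 0)
  structure(data.frame(feature = features, mdi = as.numeric(mdi),
                       pi = as.numeric(pi), row.names = NULL),
            class = c("importance_report", "data.frame"))
}

#' Pairwise group comparison of AUC samples
#'
#' Two-tailed Mann-Whitney U test for every pair of groups with
#' Benjamini-Hochberg adjustment across the pair family.
#'
#' @param samples Named list of numeric vectors (>= 3 values each), or
#'   a data frame with columns `group` and `auc`.
#' @param alpha Significance level for the flags.
#' @return Data frame: `group1`, `group2`, `p`, `p_adj`, `significant`.
#' @export
compare_groups <- function(samples, alpha = 0.05) {
  if (is.data.frame(samples))
    samples <- split(samples$auc, samples$group)
  if (length(samples) < 2L) stop("need at least two groups")
  if (any(vapply(samples, length, 0L) < 3L))
    stop("every group needs at least 3 samples")
  pairs <- utils::combn(names(samples), 2)
  p <- apply(pairs, 2, function(gp)
    suppressWarnings(stats::wilcox.test(samples[[gp[1]]], samples[[gp[2]]],
                                        alternative = "two.sided"))$p.value)
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p = p, p_adj = p_adj, significant = p_adj < alpha)
}
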