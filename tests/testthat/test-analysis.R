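test_that("tumor-growth AUC is the trapezoidal integral", {
  rec <- data.frame(day = c(0, 1, 2), fold_B = c(1, 2, 3))
  expect_equal(auc_tumor_growth(rec), 4)
  flat <- data.frame(day = seq(0, 35, by = 0.5), fold_B = 1)
  expect_equal(auc_tumor_growth(flat, 35), 35)
  zero <- data.frame(day = 0:10, fold_B = 0)
  expect_equal(auc_tumor_growth(zero), 0)
  expect_error(auc_tumor_growth(rec, horizon = 5), "beyond recorded range")
  # additivity over contiguous intervals
  rec2 <- data.frame(day = 0:6, fold_B = c(1, 3, 2, 5, 4, 4, 7))
  expect_equal(auc_tumor_growth(rec2, 3) +
                 sum(diff(rec2$day[4:7]) *
                       (head(rec2$fold_B[4:7], -1) +
                          tail(rec2$fold_B[4:7], -1)) / 2),
               auc_tumor_growth(rec2, 6))
})

test_that("time to clearance requires sustained zero", {
  rec <- data.frame(day = 0:3, B = c(100, 50, 0, 0))
  expect_equal(time_to_clearance(rec), 2)
  expect_true(is.na(time_to_clearance(data.frame(day = 0:3,
                                                 B = c(4, 3, 2, 1)))))
  trans <- data.frame(day = 0:4, B = c(100, 0, 10, 0, 0))
  expect_equal(time_to_clearance(trans), 3)
})

test_that("sweeps tabulate AUC per parameter combination", {
  cfg <- small_invivo_config(duration = 3)
  sw <- run_sweep(cfg, grids = list("exhaustion.s0" = c(1L, 8L)),
                  runs = 2L)
  expect_equal(nrow(sw), 4L)
  expect_true(all(c("exhaustion.s0", "replicate", "auc",
                    "clearance_day") %in% names(sw)))
  expect_true(all(is.finite(sw$auc)))
  # higher serial-killing capacity cannot hurt tumor control on average
  agg <- tapply(sw$auc, sw$`exhaustion.s0`, mean)
  expect_lte(agg["8"], agg["1"] * 1.5)
})

test_that("random-forest importance isolates the informative feature", {
  set.seed(10)
  n <- 300
  dat <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  dat$auc <- 5 * dat$a^2 + rnorm(n, 0, 0.01)
  rep_ <- feature_importance(dat, response = "auc",
                             features = c("a", "b", "c"), seed = 2)
  expect_equal(sum(rep_$mdi), 1, tolerance = 1e-9)
  expect_gt(rep_$mdi[rep_$feature == "a"], 0.8)
  expect_gt(rep_$pi[rep_$feature == "a"],
            10 * max(abs(rep_$pi[rep_$feature != "a"])))
  # pure-noise response: permutation importances hover near zero
  set.seed(11)
  dat2 <- data.frame(a = runif(n), b = runif(n))
  dat2$auc <- rnorm(n)
  rep2 <- feature_importance(dat2, response = "auc",
                             features = c("a", "b"), seed = 3)
  expect_lt(max(abs(rep2$pi)), var(dat2$auc))
  # constant response degenerates with a warning
  dat3 <- data.frame(a = runif(30), auc = 1)
  expect_warning(rep3 <- feature_importance(dat3, response = "auc",
                                            features = "a"),
                 "constant response")
  expect_equal(rep3$mdi, 0)
})

test_that("group comparison uses exact two-sided rank tests with BH adjustment", {
  res <- compare_groups(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(res$p, 0.1)
  same <- compare_groups(list(a = c(1, 5, 9), b = c(1, 5, 9)))
  expect_gt(same$p, 0.9)
  expect_false(same$significant)
  # three groups: BH keeps adjusted p monotone in raw-p rank and >= raw
  set.seed(1)
  three <- compare_groups(list(a = rnorm(8), b = rnorm(8, 2),
                               c = rnorm(8, 0.3)))
  expect_true(all(three$p_adj >= three$p - 1e-12))
  o <- order(three$p)
  expect_true(all(diff(three$p_adj[o]) >= -1e-12))
  expect_error(compare_groups(list(a = 1:3)), "at least two groups")
  expect_error(compare_groups(list(a = 1:3, b = 1:2)), "at least 3 samples")
})
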