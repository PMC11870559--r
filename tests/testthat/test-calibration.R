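test_that("normalized progression divides treated by control means", {
  treated <- data.frame(day = c(0, 1), B = c(1000, 2000))
  control <- data.frame(day = c(0, 1), B = c(1000, 4000))
  expect_equal(normalized_progression(treated, control, c(0, 1)),
               c(1.0, 0.5))
  expect_equal(normalized_progression(treated, treated, c(0, 1)), c(1, 1))
  cleared <- data.frame(day = c(0, 1), B = c(1000, 0))
  expect_equal(normalized_progression(cleared, control, 1), 0)
  zero <- data.frame(day = c(0, 1), B = c(1000, 0))
  expect_error(normalized_progression(treated, zero, 1), "zero at day 1")
})

test_that("MSE loss is the mean squared difference", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(1, 2), c(1, 4)), 2)
  expect_error(mse_loss(1:3, 1:2), "length mismatch")
  # appending a perfectly matched point keeps a perfect fit perfect
  expect_equal(mse_loss(c(1, 2, 7), c(1, 2, 7)), 0)
})

test_that("observed progression validates its schema", {
  ok <- observed_progression(data.frame(group = "g", day = c(0, 7),
                                        ratio = c(1, 0.5)))
  expect_s3_class(ok, "observed_progression")
  expect_error(observed_progression(data.frame(group = "g", day = c(7, 0),
                                               ratio = c(1, 1))),
               "strictly increasing")
  expect_error(observed_progression(data.frame(group = "g", day = 0)),
               "missing column")
})

test_that("single-candidate search returns that candidate with its MSE", {
  cfg <- small_invivo_config()
  obs_days <- c(2, 4, 6)
  set.seed(1)
  truth <- run_replicates(cfg, 2L)
  ctrl <- run_control(cfg, 2L)
  obs <- observed_progression(data.frame(
    group = "NT", day = obs_days,
    ratio = normalized_progression(truth, ctrl, obs_days)))
  sp <- search_space(nk = list("kill.mu_c" = 0.5), etr = 1,
                     refine_stages = 0L)
  res <- global_search(sp, obs, cfg, search_replicates = 2L,
                       final_replicates = 2L)
  expect_s3_class(res, "calibration_result")
  expect_equal(nrow(res$groups$NT$top), 1L)
  expect_equal(res$groups$NT$top$kill.mu_c, 0.5)
  expect_gte(res$groups$NT$top$mse, 0)
  expect_equal(res$etr, 1)
  expect_equal(res$total_mse, sum(res$mse_by_group))
})

test_that("calibration recovers a grid-interior truth from simulated data", {
  cfg <- small_invivo_config(seed = 21L)
  # truth: moderately cytotoxic product at ETR 1
  truth_mu <- 0.5
  cfg_truth <- cfg
  cfg_truth$products$NT$kill$mu_c <- truth_mu
  obs_days <- c(2, 4, 6)
  truth <- run_replicates(cfg_truth, 5L)
  ctrl <- run_control(cfg, 5L)
  obs <- observed_progression(data.frame(
    group = "NT", day = obs_days,
    ratio = normalized_progression(truth, ctrl, obs_days)))
  # candidates differ strongly in effect so recovery is unambiguous
  sp <- search_space(nk = list("kill.mu_c" = c(-3, truth_mu, 4)),
                     etr = 1, refine_stages = 0L)
  res <- global_search(sp, obs, cfg, search_replicates = 3L,
                       final_replicates = 3L)
  expect_equal(res$groups$NT$top$kill.mu_c[1], truth_mu)
  # stability diagnostics cover the observed days
  expect_equal(res$groups$NT$stability$day, obs_days)
})

test_that("ETR selection minimizes total MSE and zero-effect fits a control-like curve", {
  cfg <- small_invivo_config(seed = 31L)
  obs_days <- c(2, 4, 6)
  ctrl <- run_control(cfg, 3L)
  # observed curve equals the control: an instantly-dying NK product
  # (zero effect) must win over a potent one
  obs <- observed_progression(data.frame(
    group = "NT", day = obs_days, ratio = c(1, 1, 1)))
  sp <- search_space(nk = list("rates.d_c" = c(0.1, 500)),
                     etr = c(0.5, 1), refine_stages = 0L)
  res <- global_search(sp, obs, cfg, search_replicates = 3L,
                       final_replicates = 3L)
  expect_equal(res$groups$NT$top$`rates.d_c`[1], 500)
  expect_equal(unname(res$etr_total_mse[as.character(res$etr)]),
               min(res$etr_total_mse))
})

test_that("grid refinement never worsens the best MSE", {
  cfg <- small_invivo_config(seed = 41L)
  obs_days <- c(2, 4)
  obs <- observed_progression(data.frame(
    group = "NT", day = obs_days, ratio = c(0.6, 0.3)))
  sp0 <- search_space(nk = list("kill.mu_c" = c(-1, 0.5, 2)), etr = 1,
                      refine_stages = 0L)
  sp1 <- search_space(nk = list("kill.mu_c" = c(-1, 0.5, 2)), etr = 1,
                      refine_stages = 1L)
  r0 <- global_search(sp0, obs, cfg, search_replicates = 2L,
                      final_replicates = 2L)
  r1 <- global_search(sp1, obs, cfg, search_replicates = 2L,
                      final_replicates = 2L)
  expect_lte(r1$groups$NT$top$mse[1], r0$groups$NT$top$mse[1])
})

test_that("stage one fixes tumor growth from the control curve", {
  cfg <- small_invivo_config(seed = 51L)
  cfg$tumor <- tumor_params(p_b = 0.455)
  days <- c(2, 4, 6)
  ctrl <- run_control(cfg, 3L)
  ctrl_curve <- approx(ctrl$mean$day, ctrl$mean$fold_B, xout = days)$y
  obs <- observed_progression(rbind(
    data.frame(group = "control", day = days, ratio = ctrl_curve),
    data.frame(group = "NT", day = days, ratio = c(0.8, 0.6, 0.4))))
  sp <- search_space(tumor = list(p_b = c(0.1, 0.455, 0.9)),
                     nk = list("kill.mu_c" = 0.5), etr = 1,
                     refine_stages = 0L)
  res <- global_search(sp, obs, cfg, search_replicates = 2L,
                       final_replicates = 2L)
  expect_equal(res$tumor$p_b, 0.455)
})
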