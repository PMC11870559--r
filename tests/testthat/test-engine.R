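test_that("initialization places populations per the ETR and geometry", {
  cfg <- simulation_config(n_tumor_init = 1000L, etr = 1,
                           cytokines = list(), seed = 2L)
  set.seed(2)
  m <- initialize_tme(cfg)
  expect_equal(length(m$nk$row), 1000L)
  expect_equal(length(m$tumor$row), 1000L)
  # 1000 tumor cells at cap 25 occupy at least ceiling(1000/25) cells
  expect_gte(sum(m$grid$tumor_count > 0), 40L)
  expect_lte(max(m$grid$tumor_count), 25L)
  # central disk: occupied cells hug the grid center
  occ <- which(m$grid$tumor_count > 0, arr.ind = TRUE)
  expect_lt(max(sqrt((occ[, 1] - 50.5)^2 + (occ[, 2] - 50.5)^2)), 8)

  cfg5 <- simulation_config(n_tumor_init = 1000L, etr = "1:5",
                            cytokines = list(), seed = 2L)
  set.seed(2)
  expect_equal(length(initialize_tme(cfg5)$nk$row), 200L)
  expect_equal(parse_etr("3:1"), 3)
})

test_that("degenerate steps are safe: empty grid and frozen dynamics", {
  cfg <- frozen_config(n_tumor_init = 0L, n_nk_init = 0L)
  set.seed(1)
  m <- initialize_tme(cfg)
  m <- step_model(m)
  rec <- m$record[[length(m$record)]]
  expect_equal(rec$B + rec$NC + rec$NE + rec$NV, 0)

  cfg2 <- frozen_config()
  set.seed(1)
  m2 <- initialize_tme(cfg2)
  snap <- list(t = m2$tumor, nk = m2$nk)
  m2 <- step_model(m2)
  expect_identical(m2$tumor, snap$t)
  expect_identical(m2$nk[c("row", "col", "phen", "c_nk", "kills", "s")],
                   snap$nk[c("row", "col", "phen", "c_nk", "kills", "s")])
})

test_that("identical seeds give bit-identical records", {
  cfg <- small_invivo_config()
  a <- run_simulation(cfg, seed = 123)$record
  b <- run_simulation(cfg, seed = 123)$record
  expect_identical(a, b)
  c <- run_simulation(cfg, seed = 124)$record
  expect_false(identical(a, c))
})

test_that("replicate aggregation is pointwise and seeded by offset", {
  cfg <- small_invivo_config()
  agg1 <- run_replicates(cfg, 1L)
  expect_equal(agg1$mean$B, agg1$replicates[[1]]$B)
  expect_true(all(agg1$sd$B == 0))
  agg3 <- run_replicates(cfg, 3L)
  expect_length(agg3$replicates, 3L)
  expect_identical(agg3$replicates[[2]],
                   run_simulation(cfg, seed = cfg$seed + 1L)$record)
  mb <- sapply(agg3$replicates, function(r) r$B[10])
  expect_equal(agg3$mean$B[10], mean(mb))
  expect_equal(agg3$sd$B[10], sd(mb))
})

test_that("population deltas reconcile with logged births and deaths", {
  cfg <- small_invivo_config(duration = 4)
  out <- run_simulation(cfg, seed = 7)
  rec <- out$record
  last <- rec[nrow(rec), ]
  # tumor conservation: B(T) = B(0) + divisions - all deaths
  expect_equal(last$B,
               rec$B[1] + last$divisions_cum -
                 last$deaths_cytotoxic_cum - last$deaths_programmed_cum)
  # cumulative death causes are non-decreasing and partition total deaths
  expect_true(all(diff(rec$deaths_cytotoxic_cum) >= 0))
  expect_true(all(diff(rec$deaths_programmed_cum) >= 0))
})

test_that("dosing events add multiplier-scaled fresh cytotoxic cohorts", {
  base <- frozen_config(n_tumor_init = 100L, etr = 1, duration = 2,
                        record_every = 6L)
  base$n_nk_init <- 100L
  base$dosing <- dosing_schedule(day = c(0.5, 1, 1), product = "NT",
                                 multiplier = c(1, 2, 2))
  set.seed(9)
  m <- initialize_tme(base)
  expect_equal(length(m$nk$row), 100L)
  steps_per_day <- 6L
  for (k in seq_len(2 * steps_per_day)) m <- step_model(m)
  # 1X = 100 agents; doses: 1X at day 0.5, two 2X at day 1
  expect_equal(length(m$nk$row), 100L + 100L + 200L + 200L)
  expect_true(all(m$nk$phen == nkabm:::PHEN_NC))
  expect_error(apply_dose(m, "NOPE", 1), "unknown NK product")
})

test_that("tumor-only dynamics reduce to exponential growth at the configured rate", {
  cfg <- growth_config(p_b = 0.35, duration = 6, n = 500L, side = 80L)
  agg <- run_replicates(cfg, 8L)
  slope <- fit_growth_rate(agg$mean)
  expect_equal(slope, 0.35 - 1e-4, tolerance = 0.05)
})

test_that("per-division mutation frequency matches the configured probability", {
  cfg <- growth_config(p_b = 0.455, duration = 7, n = 1000L)
  rec <- run_simulation(cfg, seed = 31)$record
  last <- rec[nrow(rec), ]
  expect_gt(last$divisions_cum, 2e4)
  freq <- last$mutated_cum / last$divisions_cum
  se <- sqrt(1e-3 * (1 - 1e-3) / last$divisions_cum)
  expect_lt(abs(freq - 1e-3), 3 * se)
})

test_that("rechallenge mode re-adds tumor boluses on schedule", {
  cfg <- frozen_config(assay_mode = "rechallenge",
                       rechallenge_days = c(0.5, 1), duration = 1.5,
                       record_every = 1L)
  cfg$rechallenge_size <- 40L
  cfg$n_nk_init <- 0L
  set.seed(3)
  m <- initialize_tme(cfg)
  for (k in 1:9) m <- step_model(m)
  expect_equal(length(m$tumor$row), 50L + 40L + 40L)
  expect_lte(max(m$grid$tumor_count), cfg$grid$b_max)
})

test_that("config YAML round-trips through the reader", {
  cfg <- small_invivo_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  back <- read_config_yaml(path)
  expect_equal(back$grid$width, cfg$grid$width)
  expect_equal(back$tumor$p_b, cfg$tumor$p_b)
  expect_equal(back$etr, cfg$etr)
  expect_equal(back$products$NT$kill$mu_c, cfg$products$NT$kill$mu_c)
  rec1 <- run_simulation(cfg, seed = 5)$record
  rec2 <- run_simulation(back, seed = 5)$record
  expect_identical(rec1, rec2)
})
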