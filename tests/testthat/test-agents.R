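test_that("baseline cytotoxicity draws are truncated normal", {
  expect_equal(sample_baseline_cytotoxicity(
    nk_kill_params(mu_c = 0.5, sigma_c = 0)), 0.5)
  set.seed(1)
  x <- sample_baseline_cytotoxicity(
    nk_kill_params(mu_c = 0.5, sigma_c = 0.01), 1e5)
  expect_true(all(x >= 0))
  # far from the truncation boundary the sample moments match
  expect_equal(sd(x), 0.01, tolerance = 3 / sqrt(1e5))
  expect_equal(mean(x), 0.5, tolerance = 3 * 0.01 / sqrt(1e5))
  set.seed(2)
  y <- sample_baseline_cytotoxicity(nk_kill_params(mu_c = 0, sigma_c = 0.01),
                                    1e4)
  expect_true(all(y >= 0))
})

test_that("kill probability follows the logistic-power-evasion form", {
  expect_equal(compute_pkill(0, 0, 1, 0), 0.5)
  expect_equal(compute_pkill(0, 0, 0.5, 0), sqrt(0.5))
  expect_equal(compute_pkill(0, 0, 0.5, 0), 0.70711, tolerance = 1e-5)
  expect_equal(compute_pkill(2, 0, 1, 0.2), 0.8 * plogis(2))
  expect_equal(compute_pkill(2, 0, 1, 0.2), 0.70464, tolerance = 1e-5)
})

test_that("kill probability is monotone and CAR exponent advantages hold", {
  x <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(compute_pkill(x, 0, 1, 0)) > 0))
  ev <- seq(0, 1, by = 0.1)
  expect_true(all(diff(compute_pkill(0.5, 0, 1, ev)) < 0))
  # for any logistic base in (0,1), gamma = 0.5 beats gamma = 1
  for (c_nk in c(-2, 0, 1.5))
    expect_gt(compute_pkill(c_nk, 0, 0.5, 0), compute_pkill(c_nk, 0, 1, 0))
  expect_true(all(compute_pkill(c(-50, 50), 0, 0.5, c(0, 1)) >= 0 &
                    compute_pkill(c(-50, 50), 0, 0.5, c(0, 1)) <= 1))
})

test_that("effective evasion combines antigen downregulation and mutations", {
  tp <- tumor_params(p_evade_base = 0.1, kappa_antigen = 0.5,
                     p_mutate_increment = 1e-3)
  expect_equal(effective_evasion(tp, antigen_expr = 0, mutations = 0L), 0.1)
  expect_equal(effective_evasion(tp, antigen_expr = 1, mutations = 0L), 0.05)
  expect_equal(effective_evasion(tp, antigen_expr = 0, mutations = 2L),
               0.1 + 2e-3)
  # clipping
  expect_equal(effective_evasion(tp, 0, 2000L), 1)
  many <- effective_evasion(tp, runif(100), sample(0:5, 100, TRUE))
  expect_true(all(many >= 0 & many <= 1))
})

test_that("Hill stimulus terms sit at half maximum at B50 and c50", {
  p <- nk_prolif_params(b50 = 25, c50 = 70, gamma1 = 0.2, gamma2 = 0.2,
                        delta = 1e-12)
  st <- stimulus_terms(p, b_local = 25, c_local = 70)
  expect_equal(st$kb, 0.5, tolerance = 1e-9)
  expect_equal(st$w, 0.25, tolerance = 1e-9)
  p6 <- nk_prolif_params(delta = 1e-6)
  expect_equal(stimulus_terms(p6, 0, 0)$kb, 1e-6 / (25^0.2 + 1e-6),
               tolerance = 1e-9)
  expect_equal(stimulus_terms(p6, 0, 0)$kb, 5.25e-7, tolerance = 1e-2)
  # bounds and monotonicity
  b <- c(0, 1, 5, 25, 100, 1e4)
  ks <- stimulus_terms(p6, b, 70)$kb
  expect_true(all(ks > 0 & ks < 1))
  expect_true(all(diff(ks) > 0))
  cs <- stimulus_terms(p6, 25, c(0, 10, 70, 500, 1e4))$w
  expect_true(all(cs > 0 & cs < 1))
  expect_true(all(diff(cs) > 0))
  # autonomous-growth mode pins the tumor term
  expect_equal(stimulus_terms(p6, 0, 70, autonomous = TRUE)$kb, 1)
})

test_that("proliferation rate follows pc * exp(w - bpc t) and VM forces w = 0", {
  vm <- nk_prolif_params(pc = 0.3, bpc = 0.02, sigma_pc = 0, model = "VM")
  expect_equal(proliferation_rate(vm, age_t = 0, w = 0.7), 0.3)
  cm <- nk_prolif_params(pc = 0.3, bpc = 0.02, sigma_pc = 0, model = "CM")
  expect_equal(proliferation_rate(cm, age_t = 10, w = 0.25),
               0.3 * exp(0.05))
  expect_equal(proliferation_rate(cm, age_t = 10, w = 0.25), 0.31538,
               tolerance = 1e-5)
  # VM is CM at w = 0 draw-for-draw under identical seeds
  vm_s <- nk_prolif_params(pc = 0.3, bpc = 0.02, sigma_pc = 0.01, model = "VM")
  cm_s <- nk_prolif_params(pc = 0.3, bpc = 0.02, sigma_pc = 0.01, model = "CM")
  set.seed(8); a <- proliferation_rate(vm_s, 0:20, w = 0.9)
  set.seed(8); b <- proliferation_rate(cm_s, 0:20, w = 0)
  expect_identical(a, b)
})

test_that("rate-to-step conversion matches the published division example", {
  expect_equal(p_step_division(0.455, 4 / 24), exp(0.455 / 6) - 1)
  expect_equal(p_step_division(0.455, 4 / 24), 0.07877, tolerance = 1e-3)
  expect_equal(p_step_death(0, 4 / 24), 0)
  # expected per-day growth factor is exp(rate)
  g_step <- (1 + p_step_division(0.455, 1 / 6)) *
    (1 - p_step_death(1e-4, 1 / 6))
  expect_equal(g_step^6, exp(0.455 - 1e-4), tolerance = 1e-12)
})

test_that("serial killing capacity depletes per exhaustion variant", {
  em1 <- exhaustion_params(s0 = 5, variant = "EM1")
  expect_equal(skc_remaining(em1, 2), 3)
  expect_equal(skc_remaining(em1, 5), 0)
  em3 <- exhaustion_params(s0 = 5, variant = "EM3", x50 = 1)
  m <- matrix(1, 1, 1)
  expect_equal(skc_remaining(em3, 1, m), 5 - exp(0.5))
  expect_equal(skc_remaining(em3, 1, m), 3.35128, tolerance = 1e-5)
  # EM3 depletes at least as fast as EM1 for the same kill history
  m2 <- matrix(c(2, 3), 1, 2)
  expect_lt(skc_remaining(exhaustion_params(s0 = 5, variant = "EM3",
                                            x50 = 1), 2, m2),
            skc_remaining(em1, 2))
})

test_that("kill attempts deplete capacity and trigger exhaustion in-engine", {
  # guaranteed kills: huge cytotoxicity, no evasion, s0 = 2
  run_pair <- function(steps) {
    set.seed(42)
    m <- micro_scenario("one_nc_one_tumor", n = 200L, mu_c = 30,
                        gamma = 1, p_evade_base = 0, s0 = 2L)
    # give every NK agent several adjacent targets
    extra <- list(row = rep(m$tumor$row, 3), col = rep(m$tumor$col, 3),
                  antigen = rep(1, 3 * length(m$tumor$row)),
                  mutations = rep(0L, 3 * length(m$tumor$row)))
    m$tumor <- nkabm:::bind_tumor(m$tumor, extra)
    m <- nkabm:::refresh_tumor_count(m)
    for (k in seq_len(steps)) m <- step_model(m)
    m
  }
  m1 <- run_pair(1)
  expect_true(all(m1$nk$kills == 1))
  expect_true(all(m1$nk$s == 1))
  expect_true(all(m1$nk$phen == nkabm:::PHEN_NC))
  m3 <- run_pair(3)   # capacity 2 exhausted after 2 kills
  expect_true(all(m3$nk$kills == 2))
  expect_true(all(m3$nk$s == 0))
  expect_true(all(m3$nk$phen == nkabm:::PHEN_NE))
  # exhausted agents stop killing: two tumors per pair survive
  expect_equal(length(m3$tumor$row), 2L * 200L)
})

test_that("NK displacement expectation matches speed times step over cell size", {
  expect_equal(39 * 4 / 50, 3.12)
  set.seed(3)
  n <- nkabm:::stoch_round(rep(3.12, 2e4), 2e4)
  expect_true(all(n %in% c(3, 4)))
  expect_equal(mean(n), 3.12, tolerance = 3 * 0.5 / sqrt(2e4))
})

test_that("NK agents climb the tumor gradient and immobile agents stay put", {
  cfg <- frozen_config()
  cfg$grid <- grid_config(41L, 41L)
  cfg$n_tumor_init <- 0L; cfg$n_nk_init <- 0L
  set.seed(4)
  m <- initialize_tme(cfg)
  # tumor cluster east, NK west on the same row
  m$tumor <- list(row = rep(21L, 10), col = rep(35L, 10),
                  antigen = rep(1, 10), mutations = rep(0L, 10))
  m <- nkabm:::refresh_tumor_count(m)
  m$nk <- list(row = 21L, col = 5L, phen = nkabm:::PHEN_NC, c_nk = 0,
               kills = 0, s = 1, age = 0L, exposed = FALSE, product = 1L,
               static = 0, markers = matrix(0, 1, 0))
  m$cfg$products$NT$motility <- motility_params(m_n = 1, v_n = 39)
  cols <- m$nk$col
  for (k in 1:12) { m <- step_model(m); cols <- c(cols, m$nk$col) }
  # strict approach phase: the column never retreats before first contact
  arrive <- which(cols >= 34L)[1]
  expect_false(is.na(arrive))
  expect_true(all(diff(cols[seq_len(arrive)]) >= 0))

  # m_n = 0 freezes positions
  set.seed(5)
  m2 <- micro_scenario("one_nc_one_tumor", n = 20L, mu_c = -50)
  pos0 <- cbind(m2$nk$row, m2$nk$col)
  m2 <- step_model(m2)
  expect_identical(cbind(m2$nk$row, m2$nk$col), pos0)
})
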