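test_that("a light step with zero basal rates leaves TMRM flat", {
  p <- model_parameters(Konc = 0, Konm = 0)
  res <- run_photo_step(p, dose = 5, kon_multiplier = 1, horizon = 600)
  tm <- res$trajectory$tmrm_m
  pre <- res$pre_step_state[["tmrm_m"]]
  expect_true(all(abs(tm / pre - 1) < 0.01))
})

test_that("the default light step depolarizes and loses mitochondrial TMRM", {
  res <- run_photo_step(dose = 5, kon_multiplier = 10, horizon = 1800)
  tr <- res$trajectory
  u <- tr$tht_mphoto[tr$time_s >= 120]
  expect_true(all(diff(u) >= 0))                      # monotone rise
  expect_gt(tail(u, 1), 0.9 * max(u))                 # near plateau
  expect_lt(tail(tr$tmrm_m, 1), res$pre_step_state[["tmrm_m"]])
  # normalized views are bounded by 1
  expect_true(all(res$normalized$tht_mphoto <= 1 + 1e-12))
})

test_that("decoupled control: photo pool rises but TMRM is untouched", {
  p <- model_parameters(delta = 0)
  res <- run_photo_step(p, dose = 5, kon_multiplier = 10, horizon = 600)
  tr <- res$trajectory
  expect_gt(tail(tr$tht_mphoto, 1), 0)
  expect_true(all(abs(tr$tmrm_m / res$pre_step_state[["tmrm_m"]] - 1)
                  < 1e-6))
})

test_that("phase grid normalization and monotonicity invariants hold", {
  g <- run_phase_grid(doses = c(0, 0.5, 5), photo_levels = c(0, 2, 10))
  expect_equal(unname(g[, 1]), rep(1, 3))             # light-off column
  expect_equal(unname(g[1, ]), rep(1, 3))             # zero-dose row
  expect_true(all(g <= 1 + 1e-6))
  expect_true(all(apply(g, 1, function(r) all(diff(r) <= 1e-6))))
  expect_true(all(apply(g, 2, function(cc) all(diff(cc) <= 1e-6))))
})

test_that("a single-value sensitivity sweep reproduces the plain grid", {
  doses <- c(0, 1, 5)
  levels <- c(0, 5)
  sens <- run_sensitivity(vary = "n", values = 4, doses = doses,
                          photo_levels = levels)
  plain <- run_phase_grid(doses = doses, photo_levels = levels)
  expect_equal(unclass(sens$grids[[1]]), unclass(plain),
               ignore_attr = TRUE)
})

test_that("doubling the half-saturations does not lower the threshold dose", {
  doses <- c(0, 0.5, 1, 2, 5)
  levels <- c(0, 10)
  sens <- run_sensitivity(vary = "K", values = c(1, 2), doses = doses,
                          photo_levels = levels)
  thr <- sens$threshold_dose
  expect_true(is.na(thr[2]) || (!is.na(thr[1]) && thr[2] >= thr[1]))
})

test_that("mock FCCP runs are flat and true runs lose TMRM", {
  mock <- run_fccp_experiment(mock = TRUE)
  fccp <- run_fccp_experiment(mock = FALSE)
  s_mock <- mock$summary
  s_fccp <- fccp$summary
  expect_gt(tail(s_mock$tmrm_mito, 1) / s_mock$tmrm_mito[1], 0.99)
  expect_lt(tail(s_mock$tmrm_mito, 1) / s_mock$tmrm_mito[1], 1.01)
  expect_lt(tail(s_fccp$tmrm_mito, 1), tail(s_mock$tmrm_mito, 1))
})

test_that("an irreversibly bound photo pool blunts the ThT loss on FCCP", {
  p <- model_parameters(Koffm = 0)
  fccp <- run_fccp_experiment(p, initial_tht_mphoto = 5)
  s <- fccp$summary
  tht_frac_lost <- 1 - tail(s$tht_mito, 1) / s$tht_mito[1]
  tmrm_frac_lost <- 1 - tail(s$tmrm_mito, 1) / s$tmrm_mito[1]
  expect_gt(s$tht_mito[1], 0)
  expect_gt(fccp$trajectory$tht_mphoto[1], 0)
  expect_lt(tht_frac_lost, tmrm_frac_lost)
})

test_that("equilibration curves rise monotonically to their plateau", {
  res <- run_equilibration(horizon = 1200)
  s <- res$summary
  expect_true(all(s$tht_norm[s$time_s <= 120] == 0))
  expect_true(all(diff(s$tht_norm[s$time_s >= 120]) >= -1e-9))
  expect_true(all(diff(s$tmrm_norm[s$time_s >= 121]) >= -1e-9))
  expect_equal(max(s$tht_norm), 1)
  expect_equal(max(s$tmrm_norm), 1)
  # plateau: by the end both dyes are within 5% of their final level
  expect_gt(tail(s$tht_norm, 1), 0.95)
  expect_gt(tail(s$tmrm_norm, 1), 0.95)
})

test_that("doubling ThT permeabilities roughly halves its half-rise time", {
  # horizon long enough for a true plateau, so the min-max curve's
  # half-rise reflects the transport timescale
  t50 <- function(mult) {
    p <- model_parameters(
      Konc = 0, Konm = 0,
      tht = dye_spec("ThT", 1L, 10 * mult, 50 * mult, TRUE))
    res <- run_equilibration(p, horizon = 1200, dt = 0.25)
    s <- res$summary
    s$time_s[min(which(s$tht_norm >= 0.5))] - 120
  }
  t1 <- t50(1)
  t2 <- t50(2)
  expect_equal(t2 / t1, 0.5, tolerance = 0.1)
})
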