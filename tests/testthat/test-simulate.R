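test_that("without fluxes or reactions the state is frozen", {
  p <- inert_params(tht_ext = 5, tmrm_ext = 0.025)
  init <- model_state(tht_c = 1, tht_m = 2, tht_cphoto = 0.5,
                      tht_mphoto = 0.25, tmrm_c = 0.1, tmrm_m = 3)
  tr <- simulate_model(p, init, NULL, times = seq(0, 600, by = 60))
  for (v in c("tht_c", "tht_m", "tht_cphoto", "tht_mphoto",
              "tmrm_c", "tmrm_m"))
    expect_lt(max(abs(tr[[v]] - init[[v]])), 1e-10)
})

test_that("dark equilibrium reaches the Nernst ratio on both membranes", {
  vt <- thermal_voltage_mV()
  for (dpsi in c(-60, -150)) {
    p <- model_parameters(Konc = 0, Konm = 0, dpsi_m0 = dpsi,
                          tht_ext = 0.2, tmrm_ext = 0.025)
    ss <- steady_state(p, kon_scale = 0)
    expect_equal(ss[["tht_c"]] / p$tht_ext, exp(40 / vt), tolerance = 1e-3)
    expect_equal(ss[["tht_m"]] / ss[["tht_c"]], exp(-dpsi / vt),
                 tolerance = 1e-3)
    expect_equal(ss[["tmrm_m"]] / ss[["tmrm_c"]], exp(-dpsi / vt),
                 tolerance = 1e-3)
  }
})

test_that("total ThT is conserved when the plasma membrane is sealed", {
  p <- model_parameters(
    tht_ext = 0, tmrm_ext = 0,
    tht = dye_spec("ThT", 1L, 0, 50, TRUE),
    tmrm = dye_spec("TMRM", 1L, 0, 0.2, FALSE))
  init <- model_state(tht_c = 10, tht_m = 100, tmrm_c = 0.05, tmrm_m = 10)
  tr <- simulate_model(p, init, NULL, times = seq(0, 1200, by = 15),
                       kon_scale = 3)
  total <- tr$tht_c + tr$tht_m + tr$tht_cphoto + tr$tht_mphoto
  expect_lt(max(abs(total / total[1] - 1)), 1e-8)
})

test_that("adaptive trajectories match a fixed-step RK4 reference", {
  p <- bath_params()
  pre <- steady_state(p, kon_scale = 0)
  out_times <- seq(0, 60, by = 1)
  tr <- simulate_model(p, pre, NULL, times = out_times, kon_scale = 10)
  rhs <- thtmito:::make_rhs(p, kon_scale = 10)
  rk <- deSolve::rk4(unname(pre[1:6]), times = seq(0, 60, by = 0.001),
                     func = rhs, parms = NULL)
  rk_at <- rk[rk[, 1] %in% out_times, -1, drop = FALSE]
  for (k in 1:6) {
    scale <- max(abs(rk_at[, k]), 1e-12)
    expect_lt(max(abs(tr[[k + 1]] - rk_at[, k])) / scale, 1e-5)
  }
})

test_that("steady state satisfies its own residual definition", {
  p <- bath_params()
  ss <- steady_state(p, kon_scale = 2)
  res <- ode_rhs(ss, p, kon_scale = 2)
  expect_true(all(abs(res) < 1e-10))
  # trivial fixed point: empty bath, empty cell
  p0 <- model_parameters(tht_ext = 0, tmrm_ext = 0)
  expect_equal(unname(steady_state(p0)[1:6]), rep(0, 6))
})

test_that("raising Konm never raises steady mitochondrial TMRM", {
  p <- bath_params()
  konm_ladder <- c(0.001, 0.002, 0.005, 0.01, 0.02)
  tm <- vapply(konm_ladder, function(k) {
    pk <- p
    pk$Konm <- k
    steady_state(pk, kon_scale = 5)[["tmrm_m"]]
  }, numeric(1))
  expect_true(all(diff(tm) <= 1e-6 * tm[-length(tm)]))
})

test_that("with delta = 0 TMRM ignores the presence of ThT", {
  base <- model_parameters(delta = 0, tht_ext = 0, tmrm_ext = 0.025)
  with_tht <- model_parameters(delta = 0, tht_ext = 5, tmrm_ext = 0.025)
  times <- seq(0, 900, by = 15)
  tr0 <- simulate_model(base, model_state(), NULL, times, kon_scale = 10)
  tr1 <- simulate_model(with_tht, model_state(), NULL, times,
                        kon_scale = 10)
  expect_gt(max(tr1$tht_mphoto), 0)
  expect_equal(tr1$tmrm_m, tr0$tmrm_m, tolerance = 1e-7)
  expect_equal(tr1$tmrm_c, tr0$tmrm_c, tolerance = 1e-7)
})

test_that("events change the bath, the light level and the potential", {
  p <- model_parameters(tmrm_ext = 0.025)
  sched <- event_schedule(ev_set_reservoir(60, "tht", 1),
                          ev_scale_kon(120, 5),
                          ev_fccp(300, target = -10, tau = 60))
  tr <- simulate_model(p, model_state(), sched,
                       times = seq(0, 600, by = 5), kon_scale = 0)
  expect_equal(max(tr$tht_c[tr$time_s <= 60]), 0)
  expect_gt(max(tr$tht_c), 1)                 # dye entered after addition
  expect_equal(max(tr$tht_mphoto[tr$time_s <= 120]), 0)
  expect_gt(max(tr$tht_mphoto), 0)            # photosensitization after light
  # potential relaxes toward the FCCP target after 300 s
  expect_lt(abs(tr$dpsi_m_mV[1] - (-150)), 1e-9)
  expect_gt(tail(tr$dpsi_m_mV, 1), -25)
  # trajectory invariant: potential column equals the linear coupling
  expect_error(event_schedule(ev_scale_kon(10, 1), ev_scale_kon(5, 2)),
               "increasing")
})

test_that("trajectory potential column obeys the linear coupling", {
  p <- bath_params()
  pre <- steady_state(p, kon_scale = 0)
  tr <- simulate_model(p, pre, event_schedule(ev_scale_kon(120, 10)),
                       times = seq(0, 600, by = 15), kon_scale = 0)
  expect_equal(tr$dpsi_m_mV, p$delta * tr$tht_mphoto + p$dpsi_m0,
               tolerance = 1e-12)
  expect_true(all(tr$tht_c >= 0))
})
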