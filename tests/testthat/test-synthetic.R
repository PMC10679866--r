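test_that("mask generation is deterministic, disjoint and complete", {
  m1 <- generate_masks(20, c(256, 256), seed = 7)
  m2 <- generate_masks(20, c(256, 256), seed = 7)
  expect_identical(m1, m2)
  labs <- setdiff(unique(as.integer(m1)), 0L)
  expect_setequal(labs, 1:20)
  expect_gt(min(table(m1[m1 > 0])), 50)   # every cell has real area
  single <- generate_masks(1, c(64, 64), seed = 3)
  expect_setequal(setdiff(unique(as.integer(single)), 0L), 1L)
  expect_error(generate_masks(500, c(32, 32)), "larger shape")
})

test_that("mito templates stay inside their cells with sane coverage", {
  m <- generate_masks(12, c(256, 256), seed = 9)
  t1 <- generate_mito_template(m, seed = 5)
  t2 <- generate_mito_template(m, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1[m == 0] == 0))
  expect_true(all(t1 >= 0 & t1 <= 1))
  cov <- vapply(1:12, function(l) sum(t1[m == l] > 0) / sum(m == l),
                numeric(1))
  expect_true(all(cov >= 0.1 & cov <= 0.3))
})

test_that("noiseless rendering round-trips through trace extraction", {
  m <- generate_masks(6, c(128, 128), seed = 2)
  tmpl <- generate_mito_template(m, seed = 2)
  sc <- synthetic_scene(m, tmpl, sigma_gain = 0, alpha = 0,
                        sigma_read = 0, seed = 2)
  cond <- condition_spec("mock", n_frames = 4)
  traj <- thtmito:::condition_trajectory(cond)
  rl <- render_timelapse(sc, traj, cond, seed = 3)
  ts <- extract_traces(rl$stack, m, times = rl$times)
  merged <- merge(as.data.frame(ts), rl$ground_truth,
                  by = c("cell_id", "channel", "time_s"))
  expect_equal(merged$value, merged$true_mean, tolerance = 1e-9)
  expect_equal(rl$clip_fraction, 0)
})

test_that("rendered gain variability matches the lognormal model", {
  m <- generate_masks(50, c(384, 384), seed = 13)
  tmpl <- generate_mito_template(m, seed = 13)
  sigma_gain <- 0.15
  sc <- synthetic_scene(m, tmpl, sigma_gain = sigma_gain, alpha = 0,
                        sigma_read = 0, seed = 17)
  # per-cell plateau signal is proportional to the cell gain, so the
  # log-SD of extracted means (template coverage varies a little per
  # cell) tracks sigma_gain
  expect_equal(stats::sd(log(sc$gains)), sigma_gain, tolerance = 0.2 * 3)
  expect_equal(mean(log(sc$gains)), 0, tolerance = 3 * sigma_gain /
                 sqrt(50))
})

test_that("trace generation is deterministic and noise-free when asked", {
  cond <- condition_spec("mock", n_cells = 4)
  traj <- thtmito:::condition_trajectory(cond)
  g0 <- generate_trace_set(cond, seed = 5, sigma_gain = 0,
                           sigma_trace = 0, trajectory = traj)
  for (cid in 1:4) {
    v <- g0$traces$value[g0$traces$cell_id == cid &
                           g0$traces$channel == "tmrm"]
    expect_equal(v, g0$ground_truth$tmrm)
  }
  g1 <- generate_trace_set(cond, seed = 9, trajectory = traj)
  g2 <- generate_trace_set(cond, seed = 9, trajectory = traj)
  expect_identical(g1$traces, g2$traces)
})

test_that("mock ratios center at 1; dose-light ratios fall below mock", {
  mock <- condition_spec("mock", n_cells = 20)
  mock_traj <- thtmito:::condition_trajectory(mock)
  g <- generate_trace_set(mock, seed = 23, trajectory = mock_traj)
  r <- final_initial_ratio(g$traces)
  r_tmrm <- r$ratio[r$channel == "tmrm"]
  se <- stats::sd(r_tmrm) / sqrt(length(r_tmrm))
  expect_lt(abs(mean(r_tmrm) - 1), 3 * se + 0.01)

  dose <- condition_spec("dose_light", tht_dose = 5, n_cells = 20,
                         n_frames = 41)
  g_dose <- generate_trace_set(dose, seed = 29)
  r_dose <- final_initial_ratio(g_dose$traces)
  expect_lt(mean(r_dose$ratio[r_dose$channel == "tmrm"]), mean(r_tmrm))
})

test_that("the analytic colocalization expectation matches measurement", {
  m <- generate_masks(20, c(320, 320), seed = 37, radius_range = c(14, 20))
  tmpl <- generate_mito_template(m, seed = 37)
  cond <- condition_spec("mock", n_frames = 5)
  traj <- thtmito:::condition_trajectory(cond)
  expect_gt(sum(m > 0), 1e4)
  for (noise in list(c(0.05, 2), c(0.3, 8))) {
    sc <- synthetic_scene(m, tmpl, alpha = noise[1], sigma_read = noise[2],
                          seed = 41)
    rl <- render_timelapse(sc, traj, cond, seed = 43)
    meas <- pixel_correlation(rl$stack[1, 1, , ], rl$stack[1, 2, , ],
                              m > 0)
    expect_lt(abs(meas$r_squared - rl$expected_r2), 0.05)
  }
})
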