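make_ts <- function(values_by_cell, channel = "tmrm", times = NULL,
                    condition = "mock") {
  rows <- lapply(seq_along(values_by_cell), function(i) {
    v <- values_by_cell[[i]]
    t <- if (is.null(times)) seq_along(v) - 1 else times
    data.frame(cell_id = i, condition = condition, channel = channel,
               time_s = t, value = v)
  })
  as_trace_set(do.call(rbind, rows))
}

test_that("baseline normalization divides by the first-frames mean", {
  expect_equal(normalize_to_baseline(c(100, 100, 100, 50)),
               c(1, 1, 1, 0.5))
  expect_equal(normalize_to_baseline(c(90, 100, 110, 55)),
               c(0.9, 1, 1.1, 0.55))
  expect_equal(normalize_to_baseline(rep(7, 5)), rep(1, 5))
  expect_error(normalize_to_baseline(c(0, 0, 0, 1)), "> 0")
  expect_error(normalize_to_baseline(c(1, 2)), "shorter")
  ts <- make_ts(list(c(100, 100, 100, 50), c(10, 10, 10, 20)))
  nts <- normalize_to_baseline(ts)
  expect_equal(nts$value[nts$cell_id == 2], c(1, 1, 1, 2))
})

test_that("min-max normalization is an exact affine map onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  v <- c(0, 0.3, 1)
  expect_equal(minmax_normalize(v), v)      # idempotent on [0,1] endpoints
  expect_error(minmax_normalize(rep(3, 4)), "constant")
})

test_that("final/initial ratio reads loss and gain correctly", {
  expect_equal(final_initial_ratio(c(100, 70, 50)), 0.5)
  expect_equal(final_initial_ratio(rep(3, 7)), 1)
  expect_equal(final_initial_ratio(c(80, 40, 100)), 1.25)
  expect_error(final_initial_ratio(c(0, 1)), "> 0")
  expect_error(final_initial_ratio(5), "two frames")
})

test_that("the response ratio is invariant to baseline normalization", {
  set.seed(21)
  for (i in 1:10) {
    v <- runif(12, 10, 100)
    expect_equal(final_initial_ratio(normalize_to_baseline(v)),
                 final_initial_ratio(v))
  }
})

test_that("trace extraction takes per-label means", {
  stack <- array(7, c(2, 2, 4, 4))
  masks <- matrix(0L, 4, 4)
  masks[1, 1:2] <- 1L
  masks[3, 3] <- 2L
  ts <- extract_traces(stack, masks)
  expect_true(all(ts$value == 7))
  stack2 <- array(0, c(1, 1, 2, 2))
  stack2[1, 1, , ] <- matrix(c(10, 30, 20, 0), 2, 2)
  m2 <- matrix(c(1L, 2L, 1L, 0L), 2, 2)
  ts2 <- extract_traces(stack2, m2, channels = "tht")
  expect_equal(ts2$value[ts2$cell_id == 1], 15)
  expect_equal(ts2$value[ts2$cell_id == 2], 30)
  expect_error(extract_traces(stack, matrix(0L, 4, 4)), "no labelled")
})

test_that("Mann-Whitney U matches hand-computed exact cases", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), method = "exact")
  expect_equal(same$U, 4.5)
  expect_equal(same$p_value, 1)
  sep <- compare_groups(c(1, 2, 3), c(10, 20, 30), method = "exact")
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)      # 2/20 arrangements as extreme
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("exact U p-values agree with brute-force pair counting", {
  set.seed(31)
  for (rep in 1:12) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    a <- sample(1:5, n1, replace = TRUE)   # integer data forces ties
    b <- sample(2:7, n2, replace = TRUE)
    got <- compare_groups(a, b, method = "exact")$p_value
    expect_equal(got, brute_force_u_p(a, b), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact branch for n of 8-12", {
  set.seed(41)
  for (sizes in list(c(8, 8), c(8, 12), c(10, 10), c(12, 8))) {
    a <- rnorm(sizes[1])
    b <- rnorm(sizes[2], mean = 0.5)
    pe <- compare_groups(a, b, method = "exact")$p_value
    pn <- compare_groups(a, b, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("cross-check against wilcox.test on tie-free data", {
  set.seed(51)
  a <- rnorm(9)
  b <- rnorm(10, 1)
  ours <- compare_groups(a, b, method = "exact")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("population aggregation gives pointwise mean and sample SD", {
  ts <- make_ts(list(c(0, 0), c(2, 2)))
  agg <- aggregate_population(ts)
  expect_equal(agg$mean, c(1, 1))
  expect_equal(agg$sd, c(sqrt(2), sqrt(2)))
  ts_same <- make_ts(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(aggregate_population(ts_same)$sd, rep(0, 3))
  expect_error(aggregate_population(make_ts(list(c(1, 2)))), "fewer than 2")
})

test_that("pixel correlation is exact on linear data and null on noise", {
  a <- matrix(runif(400), 20, 20)
  b <- 2 * a + 1
  res <- pixel_correlation(a, b)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 1)          # min-max normalization equalizes
  set.seed(61)
  x <- matrix(rnorm(10000), 100, 100)
  y <- matrix(rnorm(10000), 100, 100)
  expect_lt(abs(pixel_correlation(x, y)$pearson_r), 0.05)
  expect_error(pixel_correlation(a, matrix(1, 20, 20)), "zero variance")
})

test_that("pixel correlation is symmetric and affine-invariant", {
  set.seed(71)
  a <- matrix(runif(900), 30, 30)
  b <- matrix(0.6 * a + 0.2 * runif(900), 30, 30)
  r_ab <- pixel_correlation(a, b)
  r_ba <- pixel_correlation(b, a)
  expect_equal(r_ab$pearson_r, r_ba$pearson_r)
  r_scaled <- pixel_correlation(5 * a + 3, b)
  expect_equal(r_scaled$pearson_r, r_ab$pearson_r, tolerance = 1e-12)
  expect_equal(r_ab$r_squared, r_ab$pearson_r^2, tolerance = 1e-12)
})

test_that("dose-time compilation lays out rows by ascending dose", {
  flat <- make_ts(list(rep(1, 4), rep(1, 4)))
  declining <- make_ts(list(c(1, 0.9, 0.7, 0.4), c(1, 0.8, 0.6, 0.4)))
  m <- compile_dose_time_matrix(list("5" = declining, "0.2" = flat))
  expect_equal(attr(m, "dose_axis"), c(0.2, 5))
  expect_equal(unname(m[1, ]), rep(1, 4))
  expect_lt(min(m[2, ]), min(m[1, ]))
  expect_error(compile_dose_time_matrix(list(flat)), "named")
  short <- make_ts(list(rep(1, 3), rep(1, 3)), times = c(0, 1, 2))
  expect_error(compile_dose_time_matrix(list("1" = flat, "2" = short)),
               "time grid")
})
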