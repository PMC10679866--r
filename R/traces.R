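#' Build a per-cell fluorescence trace
#'
#' @param cell_id Integer cell identifier.
#' @param condition Condition label (e.g. `"mock"`, `"fccp"`).
#' @param channel Channel name (e.g. `"tht"`, `"tmrm"`).
#' @param times Strictly increasing frame times, s.
#' @param values Non-negative fluorescence values (arbitrary units).
#'
#' @return A `trace_set` data.frame with one row per frame.
#' @export
cell_trace <- function(cell_id, condition, channel, times, values) {
  stopifnot(length(times) == length(values),
            !is.unsorted(times, strictly = TRUE),
            all(is.finite(values)))
  as_trace_set(data.frame(cell_id = as.integer(cell_id),
                          condition = as.character(condition),
                          channel = as.character(channel),
                          time_s = as.numeric(times),
                          value = as.numeric(values)))
}

#' Assemble a collection of cell traces sharing one time grid
#'
#' @param df Long-format data.frame with columns `cell_id`, `condition`,
#'   `channel`, `time_s`, `value`.
#'
#' @return The validated data.frame with class `trace_set`.
#' @export
as_trace_set <- function(df) {
  need <- c("cell_id", "condition", "channel", "time_s", "value")
  if (!all(need %in% names(df)))
    stop("trace_set needs columns: ", paste(need, collapse = ", "))
  grids <- tapply(df$time_s, interaction(df$cell_id, df$channel, drop = TRUE),
                  function(t) paste(signif(sort(t), 10), collapse = ","))
  if (length(unique(grids)) > 1L)
    stop("all traces in a trace_set must share one time grid")
  class(df) <- c("trace_set", "data.frame")
  df
}

trace_time_grid <- function(ts) sort(unique(ts$time_s))

# apply f(values-ordered-by-time) per (cell_id, channel), returning the
# modified trace_set
map_traces <- function(ts, f) {
  ts <- ts[order(ts$cell_id, ts$channel, ts$time_s), ]
  key <- interaction(ts$cell_id, ts$channel, drop = TRUE)
  ts$value <- unsplit(lapply(split(ts$value, key), f), key)
  ts
}

#' Baseline normalization of fluorescence traces
#'
#' Divides every value by the mean of the first `n_baseline` frames, so a
#' trace starts at 1 on average and later frames read as fold change from
#' baseline (the frames preceding a perturbation).
#'
#' @param x Numeric vector of trace values (time-ordered) or a `trace_set`.
#' @param n_baseline Number of leading frames defining the baseline
#'   (default 3).
#'
#' @return Same shape as `x`, dimensionless.
#' @export
#' @examples
#' normalize_to_baseline(c(100, 100, 100, 50))
normalize_to_baseline <- function(x, n_baseline = 3) {
  UseMethod("normalize_to_baseline")
}

#' @export
normalize_to_baseline.default <- function(x, n_baseline = 3) {
  if (length(x) < n_baseline)
    stop("trace shorter than the baseline window")
  b <- mean(x[seq_len(n_baseline)])
  if (!is.finite(b) || b <= 0) stop("baseline mean must be > 0")
  x / b
}

#' @export
normalize_to_baseline.trace_set <- function(x, n_baseline = 3) {
  map_traces(x, function(v) normalize_to_baseline.default(v, n_baseline))
}

#' Min-max normalization
#'
#' Affine rescaling to `[0, 1]`: the minimum maps to 0 and the maximum
#' to 1. A constant trace is degenerate and raises an error.
#'
#' @param x Numeric vector or `trace_set`.
#' @return Same shape as `x`, in `[0, 1]`.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(x) UseMethod("minmax_normalize")

#' @export
minmax_normalize.default <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) stop("constant trace: min-max normalization undefined")
  (x - lo) / (hi - lo)
}

#' @export
minmax_normalize.trace_set <- function(x) {
  map_traces(x, minmax_normalize.default)
}

#' Final/initial response ratio of a trace
#'
#' Ratio of the last frame to the first frame: 1 means unchanged, values
#' below 1 mean fluorescence loss over the experiment.
#'
#' @param x Numeric vector (time-ordered) or a `trace_set`.
#' @return A single ratio, or for a `trace_set` a data.frame with one row
#'   per (cell, channel).
#' @export
#' @examples
#' final_initial_ratio(c(100, 80, 50))  # 0.5
final_initial_ratio <- function(x) UseMethod("final_initial_ratio")

#' @export
final_initial_ratio.default <- function(x) {
  if (length(x) < 2L) stop("trace needs at least two frames")
  if (x[1L] <= 0) stop("first-frame value must be > 0")
  x[length(x)] / x[1L]
}

#' @export
final_initial_ratio.trace_set <- function(x) {
  x <- x[order(x$cell_id, x$channel, x$time_s), ]
  key <- interaction(x$cell_id, x$channel, drop = TRUE)
  parts <- split(x, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(cell_id = d$cell_id[1L], condition = d$condition[1L],
               channel = d$channel[1L],
               ratio = final_initial_ratio.default(d$value))
  }))
  rownames(out) <- NULL
  out
}

#' Extract per-cell mean-intensity traces from an image stack
#'
#' For every nonzero label in the mask, the mean pixel value under that
#' label is taken per frame and channel — the downstream analogue of
#' manually outlining each cell and measuring its mean fluorescence.
#'
#' @param stack 4-D numeric array `[frame, channel, y, x]`.
#' @param masks Integer label matrix (`0` = background) matching the
#'   frames' spatial dimensions.
#' @param channels Channel names, one per channel plane.
#' @param times Frame times, s (defaults to 0-based frame index).
#' @param condition Condition label stored with the traces.
#'
#' @return A `trace_set` with one trace per (cell, channel).
#' @export
extract_traces <- function(stack, masks, channels = c("tht", "tmrm"),
                           times = NULL, condition = "unknown") {
  stopifnot(length(dim(stack)) == 4L, is.matrix(masks))
  if (!all(dim(stack)[3:4] == dim(masks)))
    stop("mask dimensions must match the image frames")
  if (any(masks < 0) || any(masks != round(masks)))
    stop("masks must contain non-negative integer labels")
  n_frames <- dim(stack)[1L]
  n_chan <- dim(stack)[2L]
  if (length(channels) != n_chan)
    stop("need one channel name per channel plane")
  if (is.null(times)) times <- seq_len(n_frames) - 1
  labels <- sort(setdiff(unique(as.integer(masks)), 0L))
  if (!length(labels)) stop("mask contains no labelled cells")
  idx <- lapply(labels, function(l) which(masks == l))
  empty <- labels[lengths(idx) == 0L]
  if (length(empty)) stop("empty label(s): ", paste(empty, collapse = ", "))
  rows <- vector("list", length(labels) * n_chan)
  k <- 0L
  for (ci in seq_len(n_chan)) {
    for (li in seq_along(labels)) {
      vals <- vapply(seq_len(n_frames), function(fr) {
        plane <- stack[fr, ci, , ]
        mean(plane[idx[[li]]])
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- data.frame(cell_id = labels[li], condition = condition,
                              channel = channels[ci], time_s = times,
                              value = vals)
    }
  }
  as_trace_set(do.call(rbind, rows))
}

#' Mann-Whitney U comparison of two groups of response ratios
#'
#' Two-sided rank-sum test with midrank tie handling. The exact null
#' distribution is enumerated over all assignments of the pooled ranks
#' when the combined sample size is at most `exact_limit`; larger samples
#' use the tie-corrected normal approximation with continuity correction.
#'
#' @param ratios_a,ratios_b Numeric vectors (each length >= 3 for a
#'   meaningful comparison; length >= 1 required).
#' @param method `"auto"` (exact when n1+n2 <= `exact_limit`), `"exact"`,
#'   or `"normal"`.
#' @param exact_limit Combined-size cutoff for the exact branch.
#'
#' @return A `group_comparison` list: `U` (statistic for the first group),
#'   `p_value`, `n1`, `n2`, `mean_a`, `mean_b`, `method`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(10, 20, 30))$p_value  # exact: 0.1
compare_groups <- function(ratios_a, ratios_b,
                           method = c("auto", "exact", "normal"),
                           exact_limit = 20L) {
  method <- match.arg(method)
  if (!length(ratios_a) || !length(ratios_b)) stop("empty group")
  stopifnot(all(is.finite(ratios_a)), all(is.finite(ratios_b)))
  n1 <- length(ratios_a)
  n2 <- length(ratios_b)
  pooled <- c(ratios_a, ratios_b)
  r <- rank(pooled)  # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto")
    method <- if (n1 + n2 <= exact_limit) "exact" else "normal"
  p <- if (method == "exact") u_exact_p(r, n1, u_obs)
       else u_normal_p(r, n1, n2, u_obs)
  structure(list(U = u_obs, p_value = p, n1 = n1, n2 = n2,
                 mean_a = mean(ratios_a), mean_b = mean(ratios_b),
                 method = method),
            class = "group_comparison")
}

# exact two-sided p by enumerating all C(n1+n2, n1) assignments of the
# (midrank) pooled ranks to group A
u_exact_p <- function(r, n1, u_obs) {
  n <- length(r)
  picks <- utils::combn(n, n1)
  offset <- n1 * (n1 + 1) / 2
  u_all <- colSums(matrix(r[picks], nrow = n1)) - offset
  mu <- n1 * (n - n1) / 2
  eps <- 1e-9
  dev <- abs(u_obs - mu)
  mean(abs(u_all - mu) >= dev - eps)
}

# large-sample branch: continuity-corrected normal with a fourth-moment
# Edgeworth correction. The permutation distribution of the rank sum is
# symmetric (the midrank multiset is invariant under rank reversal), so
# only the kurtosis term enters; its exact value follows from the
# finite-population moments of a without-replacement sample sum over the
# midrank population, which handles ties exactly.
u_normal_p <- function(r, n1, n2, u_obs) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  d <- r - mean(r)
  s2 <- sum(d^2)
  s4 <- sum(d^4)
  p1 <- n1 / n
  p2 <- p1 * (n1 - 1) / (n - 1)
  p3 <- p2 * (n1 - 2) / (n - 2)
  p4 <- p3 * (n1 - 3) / (n - 3)
  sigma2 <- (p1 - p2) * s2
  if (sigma2 <= 0) return(1)
  # E[(T - ET)^4] for the rank-sum T, by index-pattern expansion
  mu4 <- p1 * s4 - 4 * p2 * s4 + 3 * p2 * (s2^2 - s4) +
    6 * p3 * (2 * s4 - s2^2) + p4 * (3 * s2^2 - 6 * s4)
  g2 <- mu4 / sigma2^2 - 3
  z <- max((abs(u_obs - mu) - 0.5) / sqrt(sigma2), 0)
  tail1 <- stats::pnorm(-z) +
    stats::dnorm(z) * (g2 / 24) * (z^3 - 3 * z)
  if (tail1 <= 0) tail1 <- stats::pnorm(-z)  # far tail: correction overshoots
  min(1, max(2 * tail1, .Machine$double.xmin))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  cat(sprintf("  group means: %.4g vs %.4g\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Population mean and SD band of a trace set
#'
#' Pointwise mean and sample standard deviation (n-1 denominator) across
#' cells, per channel — the summary drawn as a mean line with an SD
#' ribbon.
#'
#' @param ts A `trace_set` with at least two cells per channel.
#' @return data.frame: `channel`, `time_s`, `mean`, `sd`, `n`.
#' @export
aggregate_population <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  out <- do.call(rbind, lapply(split(as.data.frame(ts), ts$channel),
                               function(d) {
    n_cells <- length(unique(d$cell_id))
    if (n_cells < 2L)
      stop("population SD undefined with fewer than 2 traces")
    tf <- factor(d$time_s, levels = sort(unique(d$time_s)))
    agg <- do.call(rbind, lapply(split(d$value, tf), function(v) {
      c(mean = mean(v), sd = stats::sd(v), n = length(v))
    }))
    data.frame(channel = d$channel[1L],
               time_s = sort(unique(d$time_s)),
               mean = agg[, "mean"], sd = agg[, "sd"], n = agg[, "n"])
  }))
  out <- out[order(out$channel, out$time_s), ]
  rownames(out) <- NULL
  out
}

#' Pixel-wise colocalization of two channels
#'
#' Min-max normalizes both channels over the masked pixels, fits channel B
#' on channel A by ordinary least squares and reports the Pearson
#' correlation — the standard scatter-plot colocalization analysis of a
#' two-channel image.
#'
#' @param img_a,img_b Numeric matrices of identical shape.
#' @param mask Logical or 0/1 matrix selecting pixels (>= 10 required);
#'   `NULL` uses all pixels.
#' @param normalize Min-max normalize both channels first (default TRUE).
#'
#' @return A `correlation_result`: `pearson_r`, `r_squared`, `slope`,
#'   `intercept`, `n_pixels`.
#' @export
pixel_correlation <- function(img_a, img_b, mask = NULL, normalize = TRUE) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  if (is.null(mask)) mask <- array(TRUE, dim(img_a))
  stopifnot(all(dim(mask) == dim(img_a)))
  sel <- which(mask != 0)
  if (length(sel) < 10L) stop("mask must select at least 10 pixels")
  a <- as.numeric(img_a[sel])
  b <- as.numeric(img_b[sel])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a channel: correlation undefined")
  if (normalize) {
    a <- minmax_normalize.default(a)
    b <- minmax_normalize.default(b)
  }
  fit <- stats::lm.fit(cbind(1, a), b)
  r <- stats::cor(a, b)
  structure(list(pearson_r = r, r_squared = r^2,
                 slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 n_pixels = length(sel)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("pixel correlation: r = %.4f (R^2 = %.4f), B = %.3f*A + %.3f, %d px\n",
              x$pearson_r, x$r_squared, x$slope, x$intercept, x$n_pixels))
  invisible(x)
}

#' Compile dose-by-time response matrix
#'
#' Stacks population-mean TMRM traces from experiments at different ThT
#' doses into a matrix with one row per dose (ascending) and one column
#' per frame — the experimental counterpart of the simulated phase grid,
#' with exposure time standing in for light dose.
#'
#' @param tracesets Named list of `trace_set`s; names are the ThT doses
#'   (uM) and all sets must share the time grid. Traces are expected to be
#'   baseline-normalized.
#' @param channel Channel to compile (default `"tmrm"`).
#'
#' @return Matrix `[dose x time]` of population means, with `dose_axis`
#'   and `time_axis` attributes.
#' @export
compile_dose_time_matrix <- function(tracesets, channel = "tmrm") {
  if (!length(tracesets) || is.null(names(tracesets)))
    stop("'tracesets' must be a named list keyed by dose")
  doses <- as.numeric(names(tracesets))
  if (anyNA(doses)) stop("traceset names must be numeric doses")
  ord <- order(doses)
  doses <- doses[ord]
  tracesets <- tracesets[ord]
  grids <- lapply(tracesets, trace_time_grid)
  tgrid <- grids[[1L]]
  if (!all(vapply(grids, function(g)
    length(g) == length(tgrid) && all(g == tgrid), logical(1))))
    stop("all tracesets must share one time grid")
  rows <- lapply(tracesets, function(ts) {
    d <- ts[ts$channel == channel, ]
    if (!nrow(d)) stop("missing channel '", channel, "' in a traceset")
    tf <- factor(d$time_s, levels = tgrid)
    vapply(split(d$value, tf), mean, numeric(1))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(dose = format(doses, trim = TRUE),
                      time_s = format(tgrid, trim = TRUE))
  structure(m, dose_axis = doses, time_axis = tgrid)
}
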