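# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Experimental condition for synthetic data
#'
#' Bundles the imaging cadence and perturbation of one synthetic
#' time-lapse experiment. Defaults follow the study designs the generator
#' emulates: FCCP/mock runs use 1-min frames over 9 min with the addition
#' at 2 min; dose-light runs use 15-s frames over 20 min with continuous
#' illumination.
#'
#' @param name `"mock"`, `"fccp"` or `"dose_light"`.
#' @param tht_dose,tmrm_dose Bath concentrations, uM.
#' @param kon_multiplier Light-level multiplier during imaging
#'   (dose-light only).
#' @param event_time Perturbation time, s (FCCP/mock).
#' @param frame_interval Frame spacing, s.
#' @param n_frames Number of frames.
#' @param n_cells Number of cells.
#'
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name = c("mock", "fccp", "dose_light"),
                           tht_dose = 0.2, tmrm_dose = 0.025,
                           kon_multiplier = 10,
                           event_time = 120,
                           frame_interval = if (match.arg(name) == "dose_light") 15 else 60,
                           n_frames = if (match.arg(name) == "dose_light") 81 else 10,
                           n_cells = 20) {
  name <- match.arg(name)
  stopifnot(tht_dose >= 0, tmrm_dose >= 0, kon_multiplier >= 0,
            frame_interval > 0, n_frames >= 2, n_cells >= 1)
  structure(list(name = name, tht_dose = tht_dose, tmrm_dose = tmrm_dose,
                 kon_multiplier = kon_multiplier, event_time = event_time,
                 frame_interval = frame_interval, n_frames = n_frames,
                 n_cells = n_cells),
            class = "condition_spec")
}

#' Generate non-overlapping cell label masks
#'
#' Places `n_cells` jittered ellipses on a grid layout, guaranteeing
#' pairwise-disjoint, simply connected labelled regions. Deterministic for
#' a fixed seed.
#'
#' @param n_cells Number of cells (>= 1).
#' @param shape Image shape `c(ny, nx)`.
#' @param seed Integer seed.
#' @param radius_range Semi-axis range in pixels before grid-capacity
#'   shrinking.
#'
#' @return Integer label matrix (0 background, labels `1..n_cells`).
#' @export
generate_masks <- function(n_cells, shape = c(256, 256), seed = 1,
                           radius_range = c(10, 16)) {
  stopifnot(n_cells >= 1, length(shape) == 2L, all(shape >= 16))
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  box_y <- floor(shape[1L] / nrow_grid)
  box_x <- floor(shape[2L] / ncol_grid)
  max_r <- floor((min(box_y, box_x) - 2) / 2) - 1
  if (max_r < 4)
    stop("cannot place ", n_cells, " cells on a ",
         paste(shape, collapse = "x"), " image; use a larger shape")
  r_hi <- min(radius_range[2L], max_r)
  r_lo <- min(radius_range[1L], r_hi)
  with_seed(seed, {
    masks <- matrix(0L, shape[1L], shape[2L])
    for (k in seq_len(n_cells)) {
      gi <- (k - 1L) %/% ncol_grid
      gj <- (k - 1L) %% ncol_grid
      a <- stats::runif(1, r_lo, r_hi)          # semi-axes
      b <- stats::runif(1, 0.6 * a, a)
      th <- stats::runif(1, 0, pi)
      slack_y <- max(box_y / 2 - a - 1, 0)
      slack_x <- max(box_x / 2 - a - 1, 0)
      cy <- gi * box_y + box_y / 2 + stats::runif(1, -slack_y, slack_y)
      cx <- gj * box_x + box_x / 2 + stats::runif(1, -slack_x, slack_x)
      ys <- max(1, floor(cy - a)):min(shape[1L], ceiling(cy + a))
      xs <- max(1, floor(cx - a)):min(shape[2L], ceiling(cx + a))
      yy <- matrix(ys, length(ys), length(xs))
      xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
      v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      sub <- masks[ys, xs]
      sub[inside] <- k
      masks[ys, xs] <- sub
    }
    masks
  })
}

#' Generate a filamentous mitochondrial-network template
#'
#' Draws, inside each cell mask, persistent random-walk filaments dilated
#' to 2-3 px, producing a connected network covering 10-30% of the cell
#' area. Skeleton pixels carry weight 1, the dilated rim 0.6; weights are
#' zero outside the cell. Deterministic for a fixed seed.
#'
#' @param masks Label matrix from [generate_masks()].
#' @param seed Integer seed.
#' @param coverage Target per-cell area-fraction window.
#'
#' @return Numeric weight matrix in `[0, 1]`, zero outside all cells.
#' @export
generate_mito_template <- function(masks, seed = 1,
                                   coverage = c(0.1, 0.3)) {
  stopifnot(is.matrix(masks))
  labels <- sort(setdiff(unique(as.integer(masks)), 0L))
  tmpl <- matrix(0, nrow(masks), ncol(masks))
  with_seed(seed, {
    for (l in labels) {
      cell_px <- which(masks == l, arr.ind = TRUE)
      area <- nrow(cell_px)
      centroid <- round(colMeans(cell_px))
      skel <- matrix(FALSE, nrow(masks), ncol(masks))
      target <- mean(coverage)
      steps_per_walk <- max(8L, round(area * 0.02))
      for (w in 1:200) {
        # start each filament at a random in-cell pixel (first at centroid)
        pos <- if (w == 1L && masks[centroid[1L], centroid[2L]] == l)
          centroid else cell_px[sample.int(area, 1L), ]
        dir <- stats::runif(1, 0, 2 * pi)
        for (s in seq_len(steps_per_walk)) {
          skel[pos[1L], pos[2L]] <- TRUE
          dir <- dir + stats::rnorm(1, 0, 0.6)   # persistent turning
          stp <- round(c(sin(dir), cos(dir)))
          nxt <- pos + stp
          if (nxt[1L] < 1 || nxt[1L] > nrow(masks) ||
              nxt[2L] < 1 || nxt[2L] > ncol(masks) ||
              masks[nxt[1L], nxt[2L]] != l) {
            dir <- stats::runif(1, 0, 2 * pi)    # bounce off the boundary
            next
          }
          pos <- nxt
        }
        dil <- dilate3x3(skel) & masks == l
        if (sum(dil) / area >= coverage[1L] * 1.1 ||
            sum(dil) / area >= target) break
      }
      dil <- dilate3x3(skel) & masks == l
      rim <- dil & !skel
      tmpl[skel] <- 1
      tmpl[rim] <- 0.6
    }
  })
  tmpl
}

# binary dilation with a 3x3 structuring element
dilate3x3 <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  out <- m
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  for (k in seq_len(nrow(shifts))) {
    dy <- shifts$dy[k]
    dx <- shifts$dx[k]
    if (dy == 0 && dx == 0) next
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- out[ys, xs] | m[ys - dy, xs - dx]
  }
  out
}

#' Synthetic two-channel imaging scene
#'
#' Static description of a rendered field of view: label masks, the
#' mitochondrial template, per-cell gains, and the noise model. Pixel
#' means are `background + gain * (template * mito_pool +
#' (1 - template) * cyto_pool)`; noise adds a signal-dependent Gaussian
#' term of variance `alpha * mean` (Poisson-like) plus read noise of SD
#' `sigma_read`. The ThT channel sums the free and photosensitized pools
#' with their brightness weights.
#'
#' @param masks Label matrix.
#' @param template Weight matrix from [generate_mito_template()].
#' @param background Background offset, ADU.
#' @param gain_scale Mean signal per uM of dye, ADU.
#' @param sigma_gain SD of log cell-to-cell gain (lognormal multiplier).
#' @param alpha Signal-dependent noise variance slope (ADU).
#' @param sigma_read Gaussian read-noise SD, ADU.
#' @param brightness_free,brightness_photo Relative brightness of the free
#'   and photosensitized ThT pools.
#' @param seed Integer seed (draws the per-cell gains; the same stream
#'   seeds rendering noise).
#'
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(masks, template, background = 100,
                            gain_scale = 10, sigma_gain = 0.15,
                            alpha = 0.05, sigma_read = 2,
                            brightness_free = 1, brightness_photo = 1,
                            seed = 1) {
  stopifnot(all(dim(masks) == dim(template)),
            all(template[masks == 0] == 0),
            background >= 0, gain_scale > 0, sigma_gain >= 0,
            alpha >= 0, sigma_read >= 0)
  labels <- sort(setdiff(unique(as.integer(masks)), 0L))
  gains <- with_seed(seed,
    stats::rlnorm(length(labels), meanlog = 0, sdlog = sigma_gain))
  structure(list(masks = masks, template = template,
                 labels = labels, gains = gains,
                 background = background, gain_scale = gain_scale,
                 sigma_gain = sigma_gain, alpha = alpha,
                 sigma_read = sigma_read,
                 brightness_free = brightness_free,
                 brightness_photo = brightness_photo, seed = seed),
            class = "synthetic_scene")
}

# channel pool concentrations (mito, cyto) from a trajectory row
channel_pools <- function(row, scene) {
  list(
    tht = c(mito = row$tht_m * scene$brightness_free +
              row$tht_mphoto * scene$brightness_photo,
            cyto = row$tht_c * scene$brightness_free +
              row$tht_cphoto * scene$brightness_photo),
    tmrm = c(mito = row$tmrm_m, cyto = row$tmrm_c)
  )
}

#' Render a two-channel synthetic time-lapse
#'
#' Evaluates the scene's pixel-mean model on a model trajectory at the
#' condition's frame times and adds noise draws, yielding a 16-bit-range
#' image stack plus the noiseless per-cell ground truth.
#'
#' @param scene A [synthetic_scene()].
#' @param trajectory A `dye_trajectory` covering the frame times.
#' @param condition A [condition_spec()].
#' @param seed Integer seed for the noise draws.
#'
#' @return List: `stack` (array `[frame, channel, y, x]`, channels
#'   tht/tmrm), `times`, `ground_truth` (per cell/frame/channel noiseless
#'   mean under the mask), `clip_fraction`, `expected_r2` (analytic
#'   colocalization expectation for the first frame, masked pixels).
#' @export
render_timelapse <- function(scene, trajectory, condition, seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(condition, "condition_spec"))
  ft <- frame_times(condition)
  if (min(ft) < min(trajectory$time_s) || max(ft) > max(trajectory$time_s))
    stop("trajectory does not cover the condition's frame times")
  ny <- nrow(scene$masks)
  nx <- ncol(scene$masks)
  gain_img <- matrix(0, ny, nx)
  for (i in seq_along(scene$labels))
    gain_img[scene$masks == scene$labels[i]] <- scene$gains[i]
  interp <- function(col) stats::approx(trajectory$time_s, col, xout = ft)$y
  pools <- list(
    tht_m = interp(trajectory$tht_m * scene$brightness_free +
                     trajectory$tht_mphoto * scene$brightness_photo),
    tht_c = interp(trajectory$tht_c * scene$brightness_free +
                     trajectory$tht_cphoto * scene$brightness_photo),
    tmrm_m = interp(trajectory$tmrm_m),
    tmrm_c = interp(trajectory$tmrm_c))
  stack <- array(0, c(length(ft), 2L, ny, nx))
  gt <- vector("list", 2L * length(ft))
  clipped <- 0
  total <- 0
  cell_idx <- lapply(scene$labels, function(l) which(scene$masks == l))
  with_seed(seed, {
    for (fr in seq_along(ft)) {
      for (ci in 1:2) {
        mito <- if (ci == 1L) pools$tht_m[fr] else pools$tmrm_m[fr]
        cyto <- if (ci == 1L) pools$tht_c[fr] else pools$tmrm_c[fr]
        mean_img <- scene$background + scene$gain_scale * gain_img *
          (scene$template * mito +
             (1 - scene$template) * (scene$masks > 0) * cyto)
        noisy <- mean_img + stats::rnorm(
          ny * nx, 0, sqrt(scene$alpha * mean_img + scene$sigma_read^2))
        clipped <- clipped + sum(noisy < 0 | noisy > 65535)
        total <- total + length(noisy)
        stack[fr, ci, , ] <- pmin(pmax(noisy, 0), 65535)
        gt[[(fr - 1L) * 2L + ci]] <- data.frame(
          frame = fr, time_s = ft[fr],
          channel = c("tht", "tmrm")[ci],
          cell_id = scene$labels,
          true_mean = vapply(cell_idx, function(ix) mean(mean_img[ix]),
                             numeric(1)))
      }
    }
  })
  gt <- do.call(rbind, gt)
  exp_r2 <- coloc_expected_r2(scene, trajectory, ft[1L])
  list(stack = stack, times = ft, ground_truth = gt,
       clip_fraction = clipped / total, expected_r2 = exp_r2)
}

#' @rdname render_timelapse
#' @param t_frame Time point at which the expectation is evaluated, s.
#' @export
#' @details `coloc_expected_r2` computes the analytic expectation of the
#'   squared Pearson correlation between the two rendered channels over
#'   the in-cell pixels: noise is independent of the noiseless signal, so
#'   \eqn{E[r^2] \approx Cov(S_A,S_B)^2 / ((Var S_A + \bar v_A)(Var S_B +
#'   \bar v_B))} with \eqn{S} the noiseless pixel means and \eqn{\bar v}
#'   the mean per-pixel noise variance.
coloc_expected_r2 <- function(scene, trajectory, t_frame) {
  row <- as.list(vapply(
    c("tht_m", "tht_c", "tht_cphoto", "tht_mphoto", "tmrm_m", "tmrm_c"),
    function(v) stats::approx(trajectory$time_s, trajectory[[v]],
                              xout = t_frame)$y, numeric(1)))
  pools <- channel_pools(row, scene)
  gain_img <- matrix(0, nrow(scene$masks), ncol(scene$masks))
  for (i in seq_along(scene$labels))
    gain_img[scene$masks == scene$labels[i]] <- scene$gains[i]
  sel <- scene$masks > 0
  mean_ch <- function(p) {
    img <- scene$background + scene$gain_scale * gain_img *
      (scene$template * p[["mito"]] + (1 - scene$template) * p[["cyto"]])
    img[sel]
  }
  sa <- mean_ch(pools$tht)
  sb <- mean_ch(pools$tmrm)
  va <- mean(scene$alpha * sa + scene$sigma_read^2)
  vb <- mean(scene$alpha * sb + scene$sigma_read^2)
  cv <- stats::cov(sa, sb)
  cv^2 / ((stats::var(sa) + va) * (stats::var(sb) + vb))
}

frame_times <- function(condition) {
  seq(0, by = condition$frame_interval,
      length.out = condition$n_frames)
}

# model trajectory realizing a synthetic condition, sampled on its frames
condition_trajectory <- function(condition, params = model_parameters()) {
  ft <- frame_times(condition)
  horizon <- max(ft)
  switch(condition$name,
    mock = run_fccp_experiment(params, tht_dose = condition$tht_dose,
                               tmrm_dose = condition$tmrm_dose,
                               t_add = condition$event_time,
                               horizon = horizon,
                               frame_interval = condition$frame_interval,
                               mock = TRUE)$trajectory,
    fccp = run_fccp_experiment(params, tht_dose = condition$tht_dose,
                               tmrm_dose = condition$tmrm_dose,
                               t_add = condition$event_time,
                               horizon = horizon,
                               frame_interval = condition$frame_interval,
                               mock = FALSE)$trajectory,
    dose_light = {
      # dyes pre-equilibrated in the dark; illumination from the first frame
      p <- replace_doses(params, condition$tht_dose, condition$tmrm_dose)
      eq <- steady_state(p, kon_scale = 0)
      simulate_model(p, eq, NULL, times = ft,
                     kon_scale = condition$kon_multiplier)
    })
}

#' Generate a synthetic per-cell trace set (image-free shortcut)
#'
#' Per-cell traces are the condition's model trajectory (mitochondrial
#' signal per channel) multiplied by a lognormal per-cell gain and by
#' frame-wise multiplicative noise `1 + e`, `e ~ N(0, sigma_trace)`.
#'
#' @param condition A [condition_spec()].
#' @param params Model parameters.
#' @param seed Integer seed.
#' @param sigma_gain SD of log per-cell gain.
#' @param sigma_trace SD of the multiplicative frame noise.
#' @param trajectory Optional precomputed trajectory for this condition
#'   (skips the model run; useful when generating many replicates).
#'
#' @return List: `traces` (a `trace_set`), `ground_truth` (noiseless
#'   per-channel trajectory at the frame times), `condition`.
#' @export
generate_trace_set <- function(condition, params = model_parameters(),
                               seed = 1, sigma_gain = 0.15,
                               sigma_trace = 0.03, trajectory = NULL) {
  stopifnot(inherits(condition, "condition_spec"))
  if (is.null(trajectory))
    trajectory <- condition_trajectory(condition, params)
  ft <- frame_times(condition)
  sig <- data.frame(
    time_s = ft,
    tht = stats::approx(trajectory$time_s,
                        trajectory$tht_m + trajectory$tht_mphoto,
                        xout = ft)$y,
    tmrm = stats::approx(trajectory$time_s, trajectory$tmrm_m, xout = ft)$y)
  rows <- with_seed(seed, {
    lapply(seq_len(condition$n_cells), function(i) {
      g <- stats::rlnorm(1, 0, sigma_gain)
      do.call(rbind, lapply(c("tht", "tmrm"), function(ch) {
        eps <- stats::rnorm(length(ft), 0, sigma_trace)
        data.frame(cell_id = i, condition = condition$name, channel = ch,
                   time_s = ft, value = sig[[ch]] * g * (1 + eps))
      }))
    })
  })
  traces <- as_trace_set(do.call(rbind, rows))
  list(traces = traces, ground_truth = sig, condition = condition)
}
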