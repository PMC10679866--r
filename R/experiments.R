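#' In-silico photosensitization step experiment
#'
#' Equilibrates both dyes to steady state in the dark (or at a basal light
#' level), then switches the light-level multiplier on `Konc`/`Konm` at
#' `t_step` and follows the response: the photosensitized mitochondrial
#' ThT pool rises to a new plateau and, through the linear depolarization
#' coupling, mitochondrial TMRM is lost.
#'
#' @param params A [model_parameters()] object; `tht_ext`/`tmrm_ext` are
#'   overridden by `dose` and `tmrm_dose`.
#' @param dose Bath ThT concentration, uM.
#' @param tmrm_dose Bath TMRM concentration, uM (default 0.025, i.e. 25 nM).
#' @param kon_multiplier Light-level multiplier applied at `t_step`.
#' @param basal_kon Light-level multiplier before the step (default 0,
#'   dark).
#' @param t_step Step time, s.
#' @param horizon End of the simulated window, s.
#' @param dt Output sampling interval, s.
#'
#' @return An `experiment_result` list: `label`, `trajectory`
#'   (a `dye_trajectory`), `normalized` (each state variable divided by
#'   its trajectory maximum; all-zero variables left at zero),
#'   `pre_step_state`, and `config` (complete enough to re-run
#'   identically).
#' @export
#' @examples
#' \donttest{
#' res <- run_photo_step(model_parameters(), dose = 5, horizon = 600)
#' range(res$normalized$tmrm_m)
#' }
run_photo_step <- function(params = model_parameters(), dose = 5,
                           tmrm_dose = 0.025, kon_multiplier = 10,
                           basal_kon = 0, t_step = 120, horizon = 1800,
                           dt = 5) {
  stopifnot(t_step < horizon, dose >= 0, kon_multiplier >= 0)
  p <- replace_doses(params, dose, tmrm_dose)
  pre <- steady_state(p, kon_scale = basal_kon)
  times <- sort(unique(c(seq(0, horizon, by = dt), t_step)))
  traj <- simulate_model(p, pre,
                         event_schedule(ev_scale_kon(t_step, kon_multiplier)),
                         times = times, kon_scale = basal_kon)
  norm <- traj
  for (v in state_names()) {
    mx <- max(traj[[v]])
    if (mx > 0) norm[[v]] <- traj[[v]] / mx
  }
  experiment_result("photo_step", trajectory = traj, normalized = norm,
                    pre_step_state = pre,
                    config = list(dose = dose, tmrm_dose = tmrm_dose,
                                  kon_multiplier = kon_multiplier,
                                  basal_kon = basal_kon, t_step = t_step,
                                  horizon = horizon, dt = dt,
                                  parameters = p))
}

#' Steady-state phase grid over ThT dose and light level
#'
#' For every combination of bath ThT dose and light-level multiplier the
#' model is driven to steady state and mitochondrial TMRM is normalized by
#' the same-dose, light-off steady state, so the light-off column is
#' exactly 1 and entries read as the fraction of baseline TMRM retained.
#' Within each dose row the integration is warm-started from the previous
#' light level's steady state, mirroring a gradual increase in exposure.
#'
#' @param params A [model_parameters()] object.
#' @param doses Ascending bath ThT concentrations, uM.
#' @param photo_levels Ascending light-level multipliers on `Konc`/`Konm`
#'   (first level 0 recommended: it is the normalization reference).
#' @param tmrm_dose Bath TMRM concentration, uM.
#'
#' @return A `phase_grid`: matrix `[dose x photo]` of normalized
#'   steady-state mitochondrial TMRM, with `dose_axis`/`photo_axis`
#'   attributes; rows ascend in dose, columns in light level.
#' @export
run_phase_grid <- function(params = model_parameters(),
                           doses = default_dose_axis(),
                           photo_levels = default_photo_axis(),
                           tmrm_dose = 0.025) {
  stopifnot(length(doses) >= 1, length(photo_levels) >= 1,
            !is.unsorted(doses, strictly = TRUE),
            !is.unsorted(photo_levels, strictly = TRUE))
  grid <- matrix(NA_real_, length(doses), length(photo_levels),
                 dimnames = list(dose = format(doses, trim = TRUE),
                                 photo = format(photo_levels, trim = TRUE)))
  for (i in seq_along(doses)) {
    p <- replace_doses(params, doses[i], tmrm_dose)
    ref_state <- withCallingHandlers(
      steady_state(p, kon_scale = 0),
      error = function(e) stop(sprintf(
        "phase grid cell (dose %g, light-off reference) failed: %s",
        doses[i], conditionMessage(e)))
    )
    ref <- ref_state[["tmrm_m"]]
    st <- ref_state
    for (j in seq_along(photo_levels)) {
      st <- tryCatch(
        steady_state(p, initial = st, kon_scale = photo_levels[j]),
        error = function(e) stop(sprintf(
          "phase grid cell (dose %g, level %g) failed: %s",
          doses[i], photo_levels[j], conditionMessage(e))))
      grid[i, j] <- st[["tmrm_m"]] / ref
    }
  }
  structure(grid, class = c("phase_grid", "matrix"),
            dose_axis = doses, photo_axis = photo_levels,
            tmrm_dose = tmrm_dose, parameters = params)
}

#' @rdname run_phase_grid
#' @export
default_dose_axis <- function() c(0, 0.2, 0.45, 0.7, 1, 1.8, 3, 5)

#' @rdname run_phase_grid
#' @export
default_photo_axis <- function() c(0, 0.5, 1, 2, 3.5, 5, 7.5, 10)

#' Sensitivity sweep of the phase grid
#'
#' Recomputes the phase grid while varying one of the Hill-term parameter
#' groups: the cooperativity `n`, the half-saturations `K` (`Km` and `Kc`
#' scaled together), or the dissociation rates `Koff` (`Koffm`/`Koffc`
#' together). For each grid a threshold dose is reported: the smallest
#' dose whose normalized TMRM falls below 0.5 at the maximum light level
#' (`NA` if none does).
#'
#' @param params Baseline [model_parameters()].
#' @param vary One of `"n"`, `"K"`, `"Koff"`.
#' @param values Parameter values (for `"K"`/`"Koff"`, multipliers on the
#'   baseline pair).
#' @inheritParams run_phase_grid
#'
#' @return List with `grids` (one `phase_grid` per value), `threshold_dose`
#'   (numeric per value) and `values`.
#' @export
run_sensitivity <- function(params = model_parameters(),
                            vary = c("n", "K", "Koff"), values,
                            doses = default_dose_axis(),
                            photo_levels = default_photo_axis(),
                            tmrm_dose = 0.025) {
  vary <- match.arg(vary)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  grids <- vector("list", length(values))
  for (k in seq_along(values)) {
    v <- values[k]
    pk <- params
    if (vary == "n") {
      if (v < 1) stop("Hill coefficient values must be >= 1")
      pk$n <- v
    } else if (vary == "K") {
      if (v <= 0) stop("K multipliers must be > 0")
      pk$Km <- params$Km * v
      pk$Kc <- params$Kc * v
    } else {
      if (v < 0) stop("Koff multipliers must be >= 0")
      pk$Koffm <- params$Koffm * v
      pk$Koffc <- params$Koffc * v
    }
    grids[[k]] <- run_phase_grid(pk, doses = doses,
                                 photo_levels = photo_levels,
                                 tmrm_dose = tmrm_dose)
  }
  thr <- vapply(grids, threshold_dose, numeric(1))
  list(vary = vary, values = values, grids = grids, threshold_dose = thr)
}

#' @rdname run_sensitivity
#' @param grid A `phase_grid`.
#' @param cutoff Normalized-TMRM cutoff defining depolarization.
#' @export
threshold_dose <- function(grid, cutoff = 0.5) {
  doses <- attr(grid, "dose_axis")
  last_col <- grid[, ncol(grid)]
  hit <- which(last_col < cutoff)
  if (length(hit)) doses[min(hit)] else NA_real_
}

#' FCCP depolarization experiment
#'
#' Equilibrates both dyes, then (unless `mock`) collapses the basal
#' mitochondrial potential by an exponential relaxation toward `target`
#' with time constant `tau`, emulating addition of the protonophore FCCP.
#' Mitochondrial TMRM and total mitochondrial ThT (free plus
#' photosensitized) are followed at 1-min frames over a 9-min window by
#' default.
#'
#' @param params A [model_parameters()] object.
#' @param tht_dose,tmrm_dose Bath concentrations, uM.
#' @param t_add FCCP (or mock) addition time, s.
#' @param horizon Window end, s.
#' @param frame_interval Sampling interval, s.
#' @param mock If `TRUE`, no perturbation is applied (vehicle control).
#' @param target,tau FCCP relaxation target (mV) and time constant (s).
#' @param kon_scale_equil Light level during equilibration and imaging
#'   (default 0, dark).
#' @param initial_tht_mphoto If non-`NULL`, the equilibration starts from
#'   a pre-loaded photosensitized mitochondrial pool of this size (uM) —
#'   the state left behind by earlier illumination. With `Koffm = 0` the
#'   pool is permanent and survives the FCCP-driven loss of free dye.
#'
#' @return An `experiment_result` with the trajectory and a `summary`
#'   data.frame (`time_s`, `tmrm_mito`, `tht_mito`).
#' @export
run_fccp_experiment <- function(params = model_parameters(),
                                tht_dose = 0.2, tmrm_dose = 0.025,
                                t_add = 120, horizon = 540,
                                frame_interval = 60, mock = FALSE,
                                target = -10, tau = 60,
                                kon_scale_equil = 0,
                                initial_tht_mphoto = NULL) {
  stopifnot(t_add < horizon)
  p <- replace_doses(params, tht_dose, tmrm_dose)
  init <- if (is.null(initial_tht_mphoto)) model_state()
          else model_state(tht_mphoto = initial_tht_mphoto)
  eq <- steady_state(p, initial = init, kon_scale = kon_scale_equil)
  times <- sort(unique(c(seq(0, horizon, by = frame_interval), t_add)))
  sched <- if (mock) event_schedule() else
    event_schedule(ev_fccp(t_add, target = target, tau = tau))
  traj <- simulate_model(p, eq, sched, times = times,
                         kon_scale = kon_scale_equil)
  summary <- data.frame(time_s = traj$time_s,
                        tmrm_mito = traj$tmrm_m,
                        tht_mito = traj$tht_m + traj$tht_mphoto)
  experiment_result(if (mock) "fccp_mock" else "fccp",
                    trajectory = traj, summary = summary,
                    config = list(tht_dose = tht_dose, tmrm_dose = tmrm_dose,
                                  t_add = t_add, horizon = horizon,
                                  frame_interval = frame_interval,
                                  mock = mock, target = target, tau = tau,
                                  kon_scale_equil = kon_scale_equil,
                                  parameters = p))
}

#' Dye equilibration experiment
#'
#' Starts from a dye-free cell, adds both dyes to the bath at `t_add`, and
#' returns min-max-normalized rise curves of total cellular ThT (all four
#' pools) and TMRM (both pools), emulating the equilibration time courses
#' recorded after bath application.
#'
#' @inheritParams run_fccp_experiment
#' @param dt Output sampling interval, s.
#' @param kon_scale Light level throughout (default 0).
#'
#' @return An `experiment_result` whose `summary` holds `time_s`,
#'   `tht_norm`, `tmrm_norm` (normalized to `[0, 1]`).
#' @export
run_equilibration <- function(params = model_parameters(),
                              tht_dose = 0.2, tmrm_dose = 0.025,
                              t_add = 120, horizon = 1200, dt = 1,
                              kon_scale = 0) {
  stopifnot(t_add < horizon)
  p <- replace_doses(params, 0, 0)
  times <- sort(unique(c(seq(0, horizon, by = dt), t_add)))
  sched <- event_schedule(ev_set_reservoir(t_add, "tht", tht_dose),
                          ev_set_reservoir(t_add + 1e-6, "tmrm", tmrm_dose))
  traj <- simulate_model(p, model_state(), sched, times = times,
                         kon_scale = kon_scale)
  tot_tht <- traj$tht_c + traj$tht_m + traj$tht_cphoto + traj$tht_mphoto
  tot_tmrm <- traj$tmrm_c + traj$tmrm_m
  summary <- data.frame(time_s = traj$time_s,
                        tht_norm = minmax_normalize(tot_tht),
                        tmrm_norm = minmax_normalize(tot_tmrm))
  experiment_result("equilibration", trajectory = traj, summary = summary,
                    config = list(tht_dose = tht_dose, tmrm_dose = tmrm_dose,
                                  t_add = t_add, horizon = horizon, dt = dt,
                                  kon_scale = kon_scale, parameters = p))
}

replace_doses <- function(params, tht_dose, tmrm_dose) {
  p <- params
  p$tht_ext <- tht_dose
  p$tmrm_ext <- tmrm_dose
  p
}

experiment_result <- function(label, ...) {
  structure(c(list(label = label), list(...)), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$label, "\n")
  if (!is.null(x$trajectory))
    cat(sprintf("  trajectory: %d time points, %g..%g s\n",
                nrow(x$trajectory), min(x$trajectory$time_s),
                max(x$trajectory$time_s)))
  invisible(x)
}
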