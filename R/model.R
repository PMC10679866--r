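#' Time-derivatives of the model state
#'
#' Right-hand side of the six-variable ODE system. Free ThT and TMRM move
#' between the bath, cytosol and mitochondrial matrix by [ghk_flux()];
#' ThT additionally feeds per-compartment bound/photosensitized pools
#' through [hill_rate()] with first-order release, and the photosensitized
#' mitochondrial pool depolarizes the inner membrane via
#' [mito_potential()]. Sign convention: the mitochondrial flux J_m runs
#' from matrix to cytosol, the plasma flux J_c from cytosol to bath, so
#' at a resting (negative-inside) potential both fluxes pump the cationic
#' dyes inward until the Nernst ratio is met.
#'
#' @param state Named state vector from [model_state()].
#' @param params A [model_parameters()] object.
#' @param effective_dpsi_m0 Basal mitochondrial potential to use, mV
#'   (defaults to `params$dpsi_m0`; time-varying during FCCP emulation).
#' @param kon_scale Light-level multiplier applied to `Konc` and `Konm`
#'   (0 = dark).
#'
#' @return Named numeric vector of d(state)/dt, uM s^-1.
#' @export
ode_rhs <- function(state, params, effective_dpsi_m0 = params$dpsi_m0,
                    kon_scale = 1) {
  if (!all(is.finite(state))) stop("non-finite model state")
  s <- pmax(state, 0)
  pc <- params$constants
  xfac <- function(z, dpsi) {
    z * pc$faraday * (dpsi / 1000) / (pc$gas_constant * pc$temperature)
  }
  dpsi_m <- mito_potential(s[["tht_mphoto"]], params$delta, effective_dpsi_m0)
  x_pm_tht <- xfac(params$tht$charge, params$dpsi_pm)
  x_pm_tmrm <- xfac(params$tmrm$charge, params$dpsi_pm)
  x_m_tht <- xfac(params$tht$charge, dpsi_m)
  x_m_tmrm <- xfac(params$tmrm$charge, dpsi_m)

  j_c_tht <- ghk_core(params$tht$permeability_plasma, params$tht$charge,
                      x_pm_tht, s[["tht_c"]], params$tht_ext)
  j_m_tht <- ghk_core(params$tht$permeability_mito, params$tht$charge,
                      x_m_tht, s[["tht_m"]], s[["tht_c"]])
  j_c_tmrm <- ghk_core(params$tmrm$permeability_plasma, params$tmrm$charge,
                       x_pm_tmrm, s[["tmrm_c"]], params$tmrm_ext)
  j_m_tmrm <- ghk_core(params$tmrm$permeability_mito, params$tmrm$charge,
                       x_m_tmrm, s[["tmrm_m"]], s[["tmrm_c"]])

  hc <- hill_rate(s[["tht_c"]], kon_scale * params$Konc, params$Kc, params$n)
  hm <- hill_rate(s[["tht_m"]], kon_scale * params$Konm, params$Km, params$n)

  c(tht_c = -j_c_tht + j_m_tht - hc + params$Koffc * s[["tht_cphoto"]],
    tht_m = -j_m_tht - hm + params$Koffm * s[["tht_mphoto"]],
    tht_cphoto = hc - params$Koffc * s[["tht_cphoto"]],
    tht_mphoto = hm - params$Koffm * s[["tht_mphoto"]],
    tmrm_c = -j_c_tmrm + j_m_tmrm,
    tmrm_m = -j_m_tmrm)
}

# fast closure for deSolve: precomputes everything constant within a
# segment; dpsi_m0_fun(t) supplies the (possibly relaxing) basal potential
make_rhs <- function(params, kon_scale = 1, dpsi_m0_fun = NULL) {
  pc <- params$constants
  vt <- pc$gas_constant * pc$temperature / pc$faraday * 1000  # mV
  z_tht <- params$tht$charge
  z_tmrm <- params$tmrm$charge
  x_pm_tht <- z_tht * params$dpsi_pm / vt
  x_pm_tmrm <- z_tmrm * params$dpsi_pm / vt
  p_pm_tht <- params$tht$permeability_plasma
  p_mm_tht <- params$tht$permeability_mito
  p_pm_tmrm <- params$tmrm$permeability_plasma
  p_mm_tmrm <- params$tmrm$permeability_mito
  konc <- kon_scale * params$Konc
  konm <- kon_scale * params$Konm
  koffc <- params$Koffc
  koffm <- params$Koffm
  kc <- params$Kc
  km <- params$Km
  hn <- params$n
  delta <- params$delta
  dpsi_m0 <- params$dpsi_m0
  tht_ext <- params$tht_ext
  tmrm_ext <- params$tmrm_ext

  function(t, y, parms) {
    y <- pmax(y, 0)
    base_pot <- if (is.null(dpsi_m0_fun)) dpsi_m0 else dpsi_m0_fun(t)
    dpsi_m <- delta * y[4L] + base_pot
    x_m_tht <- z_tht * dpsi_m / vt
    x_m_tmrm <- z_tmrm * dpsi_m / vt

    j_c_tht <- ghk_core(p_pm_tht, z_tht, x_pm_tht, y[1L], tht_ext)
    j_m_tht <- ghk_core(p_mm_tht, z_tht, x_m_tht, y[2L], y[1L])
    j_c_tmrm <- ghk_core(p_pm_tmrm, z_tmrm, x_pm_tmrm, y[5L], tmrm_ext)
    j_m_tmrm <- ghk_core(p_mm_tmrm, z_tmrm, x_m_tmrm, y[6L], y[5L])

    cn <- (y[1L] / kc)^hn
    hc <- konc * cn / (1 + cn)
    mn <- (y[2L] / km)^hn
    hm <- konm * mn / (1 + mn)

    list(c(-j_c_tht + j_m_tht - hc + koffc * y[3L],
           -j_m_tht - hm + koffm * y[4L],
           hc - koffc * y[3L],
           hm - koffm * y[4L],
           -j_c_tmrm + j_m_tmrm,
           -j_m_tmrm))
  }
}

#' Event schedule for a simulation
#'
#' Ordered list of perturbations applied during [simulate_model()]:
#' dye addition to the bath ([ev_set_reservoir()]), light on/off as a
#' rescaling of the maximal photosensitization rates ([ev_scale_kon()]),
#' and FCCP-style exponential relaxation of the basal mitochondrial
#' potential ([ev_fccp()]).
#'
#' @param ... Event objects created by the `ev_*` constructors.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(...) {
  evs <- list(...)
  if (length(evs)) {
    stopifnot(all(vapply(evs, inherits, logical(1), "model_event")))
    tms <- vapply(evs, function(e) e$time, numeric(1))
    if (any(tms < 0)) stop("event times must be >= 0")
    if (is.unsorted(tms, strictly = TRUE))
      stop("event times must be strictly increasing")
  }
  structure(evs, class = "event_schedule")
}

#' @rdname event_schedule
#' @param time Event time, s.
#' @param dye `"tht"` or `"tmrm"`.
#' @param value New bath concentration, uM.
#' @export
ev_set_reservoir <- function(time, dye = c("tht", "tmrm"), value) {
  dye <- match.arg(dye)
  stopifnot(time >= 0, value >= 0, is.finite(value))
  structure(list(time = time, type = "set_reservoir", dye = dye,
                 value = value), class = "model_event")
}

#' @rdname event_schedule
#' @param factor New light-level multiplier on `Konc`/`Konm` (absolute
#'   setting, not compounding; 0 = light off).
#' @export
ev_scale_kon <- function(time, factor) {
  stopifnot(time >= 0, factor >= 0, is.finite(factor))
  structure(list(time = time, type = "scale_kon", factor = factor),
            class = "model_event")
}

#' @rdname event_schedule
#' @param target Potential the basal mitochondrial potential relaxes
#'   toward, mV (default -10, a collapsed potential).
#' @param tau Relaxation time constant, s.
#' @export
ev_fccp <- function(time, target = -10, tau = 60) {
  stopifnot(time >= 0, tau > 0, is.finite(target))
  structure(list(time = time, type = "fccp", target = target, tau = tau),
            class = "model_event")
}

#' Integrate the model over a time grid
#'
#' Piecewise integration with the stiff-capable adaptive solver
#' [deSolve::lsode()] (BDF): the grid is split at event times, each segment is
#' integrated with the then-current bath concentrations, light level and
#' basal-potential program, and the state carries continuously across
#' events. Concentrations are clipped at zero in the returned trajectory;
#' an excursion below `-100 * atol` triggers re-integration of the segment
#' at tighter tolerance.
#'
#' @param params A [model_parameters()] object.
#' @param initial Initial state from [model_state()].
#' @param schedule An [event_schedule()] (or `NULL` for none).
#' @param times Strictly increasing output time grid, s.
#' @param kon_scale Initial light-level multiplier (default 1).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-12 uM).
#'
#' @return A `dye_trajectory`: data.frame with columns `time_s`, the six
#'   state variables and `dpsi_m_mV`, with the resolved parameters,
#'   schedule and solver settings in attributes.
#' @export
#' @examples
#' p <- model_parameters(tht_ext = 0.2, tmrm_ext = 0.025)
#' tr <- simulate_model(p, model_state(), times = seq(0, 300, by = 15),
#'                      kon_scale = 0)
#' tail(tr, 2)
simulate_model <- function(params, initial, schedule = NULL,
                           times, kon_scale = 1,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "model_parameters"))
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (is.null(schedule)) schedule <- event_schedule()
  ev_times <- vapply(schedule, function(e) e$time, numeric(1))
  if (length(ev_times) &&
      (any(ev_times <= times[1L]) || any(ev_times >= times[length(times)])))
    stop("event times must lie strictly inside the time grid span")

  bounds <- c(times[1L], ev_times, times[length(times)])
  cur <- list(params = params, kon_scale = kon_scale,
              pot = list(mode = "const"))
  state <- unname(initial[state_names()])
  out_t <- numeric(0)
  out_y <- NULL
  out_pot <- numeric(0)

  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]
    t1 <- bounds[seg + 1L]
    if (seg > 1L) {  # apply the event opening this segment
      ev <- schedule[[seg - 1L]]
      if (ev$type == "set_reservoir") {
        if (ev$dye == "tht") cur$params$tht_ext <- ev$value
        else cur$params$tmrm_ext <- ev$value
      } else if (ev$type == "scale_kon") {
        cur$kon_scale <- ev$factor
      } else if (ev$type == "fccp") {
        from <- dpsi_m0_at(cur$pot, t0, cur$params$dpsi_m0)
        cur$pot <- list(mode = "relax", t0 = t0, from = from,
                        target = ev$target, tau = ev$tau)
      }
    }
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    pot <- cur$pot
    base0 <- cur$params$dpsi_m0
    pfun <- if (pot$mode == "const") NULL else
      function(t) pot$target + (pot$from - pot$target) * exp(-(t - pot$t0) / pot$tau)
    rhs <- make_rhs(cur$params, kon_scale = cur$kon_scale, dpsi_m0_fun = pfun)
    sol <- integrate_segment(rhs, state, seg_times, rtol, atol, seg)
    state <- sol[nrow(sol), -1L]
    keep <- seg_times %in% times
    out_t <- c(out_t, sol[keep, 1L])
    out_y <- rbind(out_y, sol[keep, -1L, drop = FALSE])
    out_pot <- c(out_pot, vapply(sol[keep, 1L], dpsi_m0_at,
                                 numeric(1), pot = pot, base = base0))
  }

  dup <- duplicated(out_t)
  out_t <- out_t[!dup]
  out_y <- pmax(out_y[!dup, , drop = FALSE], 0)
  out_pot <- out_pot[!dup]
  colnames(out_y) <- state_names()
  traj <- data.frame(time_s = out_t, out_y,
                     dpsi_m_mV = params$delta * out_y[, "tht_mphoto"] + out_pot)
  rownames(traj) <- NULL
  structure(traj,
            class = c("dye_trajectory", "data.frame"),
            parameters = params, schedule = schedule,
            solver = list(method = "lsode-bdf", rtol = rtol, atol = atol,
                          kon_scale = kon_scale))
}

dpsi_m0_at <- function(pot, t, base) {
  if (pot$mode == "const") base
  else pot$target + (pot$from - pot$target) * exp(-max(t - pot$t0, 0) / pot$tau)
}

integrate_segment <- function(rhs, state, seg_times, rtol, atol, seg_id) {
  for (attempt in 1:2) {
    sol <- try(deSolve::lsode(y = state, times = seg_times, func = rhs,
                              parms = NULL, rtol = rtol, atol = atol,
                              mf = 22, maxsteps = 200000), silent = TRUE)
    bad <- inherits(sol, "try-error") || anyNA(sol) ||
      attr(sol, "istate")[1L] < 0
    if (!bad && min(sol[, -1L]) >= -100 * atol) return(unclass(sol))
    if (attempt == 2L) {
      if (bad) stop(sprintf("ODE solver failed in segment %d", seg_id))
      return(unclass(sol))
    }
    rtol <- rtol / 100
  }
}

#' Steady state of the model
#'
#' Long-horizon integration with a residual stopping rule, followed by a
#' Newton polish: integration proceeds in blocks until the largest
#' component of [ode_rhs()] is small, then damped Newton iterations with a
#' finite-difference Jacobian drive it below `atol`
#' (default 1e-10 uM s^-1). Deterministic for fixed inputs.
#'
#' @inheritParams simulate_model
#' @param kon_scale Light-level multiplier held constant throughout.
#' @param atol Residual tolerance on max |d state/dt|, uM s^-1.
#' @param block Block length for the staged integration, s.
#' @param max_time Maximum integration horizon, s.
#'
#' @return A named state vector (layout as [model_state()]), with the final
#'   residual in attribute `"residual"`.
#' @export
steady_state <- function(params, initial = model_state(), kon_scale = 1,
                         atol = 1e-10, block = 2000, max_time = 4e5) {
  rhs <- make_rhs(params, kon_scale = kon_scale)
  fres <- function(y) unlist(rhs(0, y, NULL))
  state <- unname(initial[state_names()])
  t_done <- 0
  res <- max(abs(fres(state)))
  while (t_done < max_time) {
    sol <- deSolve::lsode(y = state, times = c(0, block), func = rhs,
                          parms = NULL, rtol = 1e-9, atol = 1e-11,
                          mf = 22, maxsteps = 200000)
    if (anyNA(sol) || attr(sol, "istate")[1L] < 0)
      stop("steady-state integration failed")
    state <- pmax(sol[2L, -1L], 0)
    t_done <- t_done + block
    res <- max(abs(fres(state)))
    if (res < atol) break
    if (res < 1e-3) {  # close enough for Newton to take over
      polished <- newton_polish(fres, state, atol)
      if (!is.null(polished) &&
          max(abs(polished - state) / pmax(abs(state), 1e-6)) < 0.2) {
        state <- polished
        res <- max(abs(fres(state)))
        break
      }
    }
  }
  if (res >= atol)
    stop(sprintf(
      "no steady state within %g s: residual %.3g uM/s exceeds %g",
      max_time, res, atol))
  out <- stats::setNames(as.numeric(state), state_names())
  attr(out, "residual") <- res
  out
}

# damped Newton with forward-difference Jacobian; returns NULL when it
# fails to reduce the residual (caller keeps integrating instead)
newton_polish <- function(fres, state, atol, max_iter = 20L) {
  y <- state
  res <- max(abs(fres(y)))
  for (it in seq_len(max_iter)) {
    if (res < atol) return(pmax(y, 0))
    f0 <- fres(y)
    jac <- matrix(0, length(y), length(y))
    for (j in seq_along(y)) {
      h <- max(1e-7 * abs(y[j]), 1e-10)
      yp <- y
      yp[j] <- yp[j] + h
      jac[, j] <- (fres(yp) - f0) / h
    }
    step <- try(solve(jac, -f0), silent = TRUE)
    if (inherits(step, "try-error")) return(NULL)
    lambda <- 1
    repeat {
      y_new <- pmax(y + lambda * step, 0)
      res_new <- max(abs(fres(y_new)))
      if (res_new < res || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (res_new >= res) return(NULL)
    y <- y_new
    res <- res_new
  }
  if (res < atol) pmax(y, 0) else NULL
}
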