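#' Physical constants for flux calculations
#'
#' Bundle of the Faraday constant, the gas constant and the absolute
#' temperature used inside the Goldman-Hodgkin-Katz flux term.
#'
#' @param faraday Faraday constant, C mol^-1.
#' @param gas_constant Molar gas constant, J mol^-1 K^-1.
#' @param temperature Absolute temperature, K. Default 310.15 K (37 C).
#'
#' @return An object of class `physical_constants`.
#' @export
#' @examples
#' pc <- physical_constants()
#' # thermal voltage RT/F in mV, ~26.7 mV at 37 C
#' 1000 * pc$gas_constant * pc$temperature / pc$faraday
physical_constants <- function(faraday = 96485.33212,
                               gas_constant = 8.314462618,
                               temperature = 310.15) {
  stopifnot(
    is.numeric(faraday), length(faraday) == 1L, is.finite(faraday), faraday > 0,
    is.numeric(gas_constant), length(gas_constant) == 1L,
    is.finite(gas_constant), gas_constant > 0,
    is.numeric(temperature), length(temperature) == 1L,
    is.finite(temperature), temperature > 0
  )
  structure(
    list(faraday = faraday, gas_constant = gas_constant,
         temperature = temperature),
    class = "physical_constants"
  )
}

#' Membrane-transport description of a dye
#'
#' @param name Identifier, e.g. `"ThT"` or `"TMRM"`.
#' @param charge Net charge of the dye (dimensionless integer); +1 for both
#'   default dyes.
#' @param permeability_plasma Effective plasma-membrane permeability, s^-1
#'   (volume-lumped).
#' @param permeability_mito Effective inner-mitochondrial-membrane
#'   permeability, s^-1.
#' @param photoactive Whether the dye has a photosensitized bound pool
#'   (`TRUE` for ThT, `FALSE` for TMRM).
#'
#' @return An object of class `dye_spec`.
#' @export
dye_spec <- function(name, charge = 1L, permeability_plasma,
                     permeability_mito, photoactive = FALSE) {
  stopifnot(
    is.character(name), length(name) == 1L,
    is.numeric(charge), length(charge) == 1L, charge == round(charge),
    is.numeric(permeability_plasma), length(permeability_plasma) == 1L,
    permeability_plasma >= 0, is.finite(permeability_plasma),
    is.numeric(permeability_mito), length(permeability_mito) == 1L,
    permeability_mito >= 0, is.finite(permeability_mito),
    is.logical(photoactive), length(photoactive) == 1L
  )
  structure(
    list(name = name, charge = as.integer(charge),
         permeability_plasma = permeability_plasma,
         permeability_mito = permeability_mito,
         photoactive = photoactive),
    class = "dye_spec"
  )
}

#' Model parameters for the two-compartment dye model
#'
#' Full parameter set of the kinetic model: per-compartment Hill
#' binding/photosensitization rates for ThT, the linear depolarization
#' coupling, membrane potentials, extracellular reservoir concentrations,
#' and the membrane-transport description of both dyes.
#'
#' The defaults are a documented calibration (see the package vignette)
#' chosen so that, at 37 C with a basal mitochondrial potential of -150 mV
#' and a plasma potential of -40 mV, micromolar bath ThT accumulates to
#' hundreds of micromolar in the mitochondrial matrix, the Hill term
#' half-saturates between the matrix levels reached from 0.2 and 1 uM bath
#' doses, and saturated photosensitized ThT can depolarize by well over
#' 100 mV.
#'
#' @param Konc,Konm Maximal binding/photosensitization rate in cytosol and
#'   mitochondria, uM s^-1, at unit light level (scaled by the light
#'   multiplier during simulated illumination).
#' @param Koffc,Koffm Dissociation/desensitization rates, s^-1.
#' @param Kc,Km Half-saturation ThT concentrations of the Hill term, uM.
#' @param n Hill cooperativity coefficient (>= 1).
#' @param delta Depolarization scaling, mV uM^-1 (>= 0): each uM of
#'   photosensitized mitochondrial ThT moves the potential `delta` mV
#'   toward 0.
#' @param dpsi_m0 Basal mitochondrial membrane potential, mV (< 0).
#' @param dpsi_pm Plasma membrane potential, mV (< 0), held constant.
#' @param tht_ext,tmrm_ext Extracellular reservoir concentrations, uM;
#'   the bath is treated as an infinite reservoir changed only by schedule
#'   events.
#' @param tht,tmrm [dye_spec()] objects for the two dyes.
#' @param constants A [physical_constants()] object.
#'
#' @return An object of class `model_parameters`.
#' @export
#' @examples
#' p <- model_parameters(tht_ext = 5, tmrm_ext = 0.025)
#' p$Km
model_parameters <- function(Konc = 0.002, Konm = 0.002,
                             Koffc = 0.002, Koffm = 0.002,
                             Kc = 50, Km = 500, n = 4,
                             delta = 15,
                             dpsi_m0 = -150, dpsi_pm = -40,
                             tht_ext = 0, tmrm_ext = 0,
                             tht = dye_spec("ThT", 1L,
                                            permeability_plasma = 10,
                                            permeability_mito = 50,
                                            photoactive = TRUE),
                             tmrm = dye_spec("TMRM", 1L,
                                             permeability_plasma = 0.02,
                                             permeability_mito = 0.2,
                                             photoactive = FALSE),
                             constants = physical_constants()) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(Kc) || Kc <= 0) stop("'Kc' must be a single positive number")
  if (!num1(Km) || Km <= 0) stop("'Km' must be a single positive number")
  if (!num1(n) || n < 1) stop("Hill coefficient 'n' must be >= 1")
  if (!num1(delta) || delta < 0) stop("'delta' must be >= 0")
  if (!num1(dpsi_m0) || dpsi_m0 >= 0)
    stop("'dpsi_m0' (basal mitochondrial potential) must be < 0 mV")
  if (!num1(dpsi_pm) || dpsi_pm >= 0)
    stop("'dpsi_pm' (plasma membrane potential) must be < 0 mV")
  if (!num1(tht_ext) || tht_ext < 0) stop("'tht_ext' must be >= 0")
  if (!num1(tmrm_ext) || tmrm_ext < 0) stop("'tmrm_ext' must be >= 0")
  for (nm in c("Konc", "Konm", "Koffc", "Koffm")) {
    v <- get(nm, inherits = FALSE)
    if (!num1(v) || v < 0) stop(sprintf("'%s' must be >= 0", nm))
  }
  stopifnot(inherits(tht, "dye_spec"), inherits(tmrm, "dye_spec"),
            inherits(constants, "physical_constants"))
  structure(
    list(Konc = Konc, Konm = Konm, Koffc = Koffc, Koffm = Koffm,
         Kc = Kc, Km = Km, n = n, delta = delta,
         dpsi_m0 = dpsi_m0, dpsi_pm = dpsi_pm,
         tht_ext = tht_ext, tmrm_ext = tmrm_ext,
         tht = tht, tmrm = tmrm, constants = constants),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Two-compartment dye model parameters\n")
  cat(sprintf("  Hill: Konc=%g Konm=%g uM/s, Koffc=%g Koffm=%g /s, Kc=%g Km=%g uM, n=%g\n",
              x$Konc, x$Konm, x$Koffc, x$Koffm, x$Kc, x$Km, x$n))
  cat(sprintf("  Potentials: dpsi_m0=%g mV, dpsi_pm=%g mV, delta=%g mV/uM\n",
              x$dpsi_m0, x$dpsi_pm, x$delta))
  cat(sprintf("  Bath: ThT=%g uM, TMRM=%g uM\n", x$tht_ext, x$tmrm_ext))
  cat(sprintf("  ThT:  P_pm=%g P_mm=%g /s;  TMRM: P_pm=%g P_mm=%g /s\n",
              x$tht$permeability_plasma, x$tht$permeability_mito,
              x$tmrm$permeability_plasma, x$tmrm$permeability_mito))
  invisible(x)
}

#' Construct a model state vector
#'
#' The six concentration state variables of the model, in uM: free cytosolic
#' and mitochondrial ThT, bound/photosensitized cytosolic and mitochondrial
#' ThT, and cytosolic and mitochondrial TMRM.
#'
#' @param tht_c,tht_m,tht_cphoto,tht_mphoto,tmrm_c,tmrm_m Concentrations, uM.
#' @return Named numeric vector of length 6.
#' @export
model_state <- function(tht_c = 0, tht_m = 0, tht_cphoto = 0,
                        tht_mphoto = 0, tmrm_c = 0, tmrm_m = 0) {
  s <- c(tht_c = tht_c, tht_m = tht_m, tht_cphoto = tht_cphoto,
         tht_mphoto = tht_mphoto, tmrm_c = tmrm_c, tmrm_m = tmrm_m)
  if (!all(is.finite(s))) stop("state values must be finite")
  if (any(s < 0)) stop("state concentrations must be >= 0")
  s
}

state_names <- function() {
  c("tht_c", "tht_m", "tht_cphoto", "tht_mphoto", "tmrm_c", "tmrm_m")
}
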