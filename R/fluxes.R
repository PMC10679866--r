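#' Goldman-Hodgkin-Katz flux across a membrane
#'
#' Potential-driven passive flux of a charged solute between two
#' compartments under the constant-field assumption,
#' \deqn{J = P\,Z\,x\,\frac{c_{in} - c_{out}e^{-x}}{1 - e^{-x}},\qquad
#'       x = \frac{Z F \Delta\Psi}{R T},}
#' with \eqn{P} an effective per-second permeability that lumps membrane
#' area, compartment volume and the constant-field prefactor, so the flux
#' carries units of uM s^-1. Positive flux runs from the inner to the outer
#' compartment. The removable singularity at \eqn{x = 0} is evaluated by a
#' series expansion; at \eqn{x = 0} exactly the Fickian limit
#' \eqn{P Z (c_{in} - c_{out})} is returned. The flux is zero exactly at the
#' Nernst ratio \eqn{c_{in} = c_{out} e^{-x}}.
#'
#' @param permeability Effective permeability P, s^-1 (>= 0).
#' @param charge Solute charge Z (integer, nonzero for a driven flux).
#' @param dpsi Membrane potential (inner minus outer), mV.
#' @param c_in,c_out Concentrations in the inner and outer compartment, uM.
#' @param constants A [physical_constants()] object.
#'
#' @return Flux in uM s^-1 (vectorized over `dpsi`, `c_in`, `c_out`).
#' @export
#' @examples
#' pc <- physical_constants()
#' ghk_flux(1, 1, 0, 2, 1, pc)            # Fickian limit: P*(c_in - c_out)
#' ghk_flux(1, 1, -150, 1, 1, pc)         # strong inward driving force < 0
ghk_flux <- function(permeability, charge, dpsi, c_in, c_out,
                     constants = physical_constants()) {
  if (any(!is.finite(dpsi))) stop("'dpsi' must be finite")
  if (any(!is.finite(c_in)) || any(c_in < 0) ||
      any(!is.finite(c_out)) || any(c_out < 0))
    stop("concentrations must be finite and >= 0")
  if (!is.numeric(permeability) || any(permeability < 0))
    stop("'permeability' must be >= 0")
  x <- charge * constants$faraday * (dpsi / 1000) /
    (constants$gas_constant * constants$temperature)
  ghk_core(permeability, charge, x, c_in, c_out)
}

# core in terms of the reduced potential x = Z*F*dPsi/(R*T);
# f(x) = x / (1 - e^{-x}) is computed by series for |x| < 1e-5 so the
# branch switch agrees with the direct formula to ~1e-9 relative
ghk_core <- function(permeability, charge, x, c_in, c_out) {
  em1 <- expm1(-x)                      # e^{-x} - 1, accurate near 0
  small <- abs(x) < 1e-5
  f <- numeric(length(x))
  f[!small] <- x[!small] / (-em1[!small])
  xs <- x[small]
  f[small] <- 1 + xs / 2 + xs^2 / 12    # x/(1 - e^{-x}) = 1 + x/2 + x^2/12 + O(x^4)
  permeability * charge * f * (c_in - c_out - c_out * em1)
}

#' Hill-type binding/photosensitization rate
#'
#' Cooperative saturating rate law \eqn{k_{on} c^n / (K^n + c^n)} used for
#' the combined nonspecific-binding-plus-photosensitization reaction of
#' ThT in each compartment. Monotone non-decreasing in `c`, bounded by
#' `kon`, and exactly `kon/2` at `c = k_half`.
#'
#' @param c Free dye concentration, uM (>= 0, vectorized).
#' @param kon Maximal rate, uM s^-1.
#' @param k_half Half-saturation concentration, uM (> 0).
#' @param n Cooperativity coefficient (>= 1).
#'
#' @return Rate in uM s^-1.
#' @export
#' @examples
#' hill_rate(3, 1, 1, 2)  # 9/10
hill_rate <- function(c, kon, k_half, n) {
  if (any(c < 0)) stop("'c' must be >= 0")
  if (k_half <= 0) stop("'k_half' must be > 0")
  if (n < 1) stop("'n' must be >= 1")
  cn <- (c / k_half)^n
  kon * cn / (1 + cn)
}

#' Mitochondrial membrane potential under photosensitized-ThT load
#'
#' Linear coupling of the photosensitized mitochondrial ThT pool to the
#' potential: \eqn{\Delta\Psi_m = \delta\,[ThT_{mphoto}] + \Delta\Psi_{m,0}}.
#' With `delta > 0`, accumulation of the photosensitized pool moves the
#' potential toward 0 (depolarization). No clamping is applied.
#'
#' @param tht_mphoto Photosensitized mitochondrial ThT, uM.
#' @param delta Scaling, mV uM^-1 (>= 0).
#' @param dpsi_m0 Basal potential, mV.
#'
#' @return Potential in mV.
#' @export
mito_potential <- function(tht_mphoto, delta, dpsi_m0) {
  if (delta < 0) stop("'delta' must be >= 0")
  delta * tht_mphoto + dpsi_m0
}
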