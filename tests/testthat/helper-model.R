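# thermal voltage RT/F in mV at the default 37 C
thermal_voltage_mV <- function(pc = physical_constants()) {
  1000 * pc$gas_constant * pc$temperature / pc$faraday
}

# default parameters with both dyes in the bath
bath_params <- function(tht = 5, tmrm = 0.025, ...) {
  model_parameters(tht_ext = tht, tmrm_ext = tmrm, ...)
}

# parameters with all transport and reactions switched off
inert_params <- function(...) {
  model_parameters(
    Konc = 0, Konm = 0, Koffc = 0, Koffm = 0,
    tht = dye_spec("ThT", 1L, 0, 0, TRUE),
    tmrm = dye_spec("TMRM", 1L, 0, 0, FALSE),
    ...)
}

# independent Mann-Whitney oracle: enumerate every assignment of the
# pooled observations to group A and count greater/tied pairs directly
# (no ranks), two-sided tail by deviation from the mean
brute_force_u_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n1 <- length(a)
  mu <- n1 * (n - n1) / 2
  count_u <- function(ga, gb) {
    sum(vapply(ga, function(x) sum(x > gb) + 0.5 * sum(x == gb),
               numeric(1)))
  }
  u_obs <- count_u(a, b)
  picks <- utils::combn(n, n1)
  u_all <- apply(picks, 2L, function(ix) count_u(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
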