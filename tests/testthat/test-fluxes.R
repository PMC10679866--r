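test_that("GHK flux reduces to Fick's law at zero potential", {
  pc <- physical_constants()
  expect_identical(ghk_flux(1, 1, 0, 1, 1, pc), 0)
  expect_equal(ghk_flux(1, 1, 0, 2, 1, pc), 1)
  expect_equal(ghk_flux(3, 1, 0, 5, 2, pc), 9)
})

test_that("GHK flux vanishes exactly at the Nernst ratio", {
  pc <- physical_constants()
  vt <- thermal_voltage_mV(pc)
  for (dpsi in c(-61.54, -150, -30, 25)) {
    c_out <- 2
    c_in <- c_out * exp(-dpsi / vt)
    expect_lt(abs(ghk_flux(1, 1, dpsi, c_in, c_out, pc)), 1e-9 * c_out)
  }
  # ratio 10 at ~ -61.5 mV is the classic one-decade potential
  dpsi10 <- -vt * log(10)
  expect_lt(abs(ghk_flux(1, 1, dpsi10, 10, 1, pc)), 1e-9)
})

test_that("series branch agrees with the direct formula at the switch", {
  # f(x) = x / (1 - e^{-x}): series for |x| < 1e-5, direct beyond; the
  # two expressions agree to 1e-9 relative at the boundary
  for (x in c(-1e-5, 1e-5)) {
    f_series <- 1 + x / 2 + x^2 / 12
    f_direct <- x / (-expm1(-x))
    expect_lt(abs(f_series / f_direct - 1), 1e-9)
  }
})

test_that("the flux converges linearly to the Fickian limit", {
  pc <- physical_constants()
  # deviation from P*(c_in - c_out) shrinks proportionally to |dpsi| and
  # is below 1e-6 relative by |dpsi| = 1e-5 mV
  dev <- vapply(c(1e-3, 1e-4, 1e-5),
                function(d) abs(ghk_flux(1, 1, d, 2, 1, pc) - 1),
                numeric(1))
  expect_lt(dev[3], 1e-6)
  expect_equal(dev[1] / dev[2], 10, tolerance = 0.01)
  expect_equal(dev[2] / dev[3], 10, tolerance = 0.01)
})

test_that("GHK flux is monotone in the driving force and rejects bad input", {
  pc <- physical_constants()
  dpsis <- seq(-200, 200, by = 10)
  j <- vapply(dpsis, function(d) ghk_flux(1, 1, d, 1, 1, pc), numeric(1))
  expect_true(all(diff(j) > 0))  # more positive potential pushes cation out
  expect_error(ghk_flux(1, 1, NaN, 1, 1, pc), "finite")
  expect_error(ghk_flux(1, 1, 0, -1, 1, pc), ">= 0")
  expect_error(ghk_flux(-1, 1, 0, 1, 1, pc), "permeability")
})

test_that("Hill rate matches its defining values and bounds", {
  expect_identical(hill_rate(0, 1, 1, 2), 0)
  expect_equal(hill_rate(1, 1, 1, 4), 0.5)      # half saturation
  expect_equal(hill_rate(3, 1, 1, 2), 0.9)      # 9/(1+9)
  cs <- seq(0, 50, by = 0.5)
  r <- hill_rate(cs, 2, 5, 4)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= 2))
  expect_error(hill_rate(-1, 1, 1, 1), ">= 0")
  expect_error(hill_rate(1, 1, 0, 1), "> 0")
  expect_error(hill_rate(1, 1, 1, 0.5), ">= 1")
})

test_that("mitochondrial potential responds linearly to the photo pool", {
  expect_equal(mito_potential(0, 15, -150), -150)
  expect_equal(mito_potential(7, 0, -150), -150)
  expect_equal(mito_potential(1, 10, -150), -140)
  expect_error(mito_potential(1, -1, -150), ">= 0")
})
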