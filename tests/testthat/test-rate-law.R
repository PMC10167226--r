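test_that("derived coefficients satisfy the algebraic identities", {
  p <- kinetic_params_lk(lambda = 4e-5, kappa = 1.2e-3)
  co <- kinetic_coeffs(p)
  expect_equal(co$C_minus, -co$C_plus)
  expect_equal(co$C_plus, p$lambda^2 / (2 * p$kappa^2))
  # k_inf_bar^2 - k_inf^2 = lambda^4 / kappa^2 (since 4 C+ C- k^2 = -l^4/k^2)
  expect_equal(co$k_inf_bar^2 - co$k_inf^2, p$lambda^4 / p$kappa^2)
  expect_equal(co$B_plus * co$B_minus, co$C_plus * co$C_minus,
               tolerance = 1e-12)
  expect_equal(co$B_plus + co$B_minus, co$k_inf / p$kappa)

  # primary-nucleation-free limit: C+- = 0, k_inf_bar = k_inf, B- = 0
  p0 <- kinetic_params(k_n = 0, k_plus = 1e6, k_2 = 1e4)
  co0 <- kinetic_coeffs(p0)
  expect_equal(co0$C_plus, 0)
  expect_equal(co0$k_inf_bar, co0$k_inf)
  expect_equal(co0$B_minus, 0)

  expect_error(kinetic_coeffs(kinetic_params(1, 1, 0)), "kappa = 0")
})

test_that("coefficients match a high-precision independent evaluation", {
  # frozen from an mpmath 50-digit evaluation of the defining formulas at
  # lambda = 4e-5, kappa = 1.2e-3, n_C = n_2 = 2
  p <- kinetic_params_lk(lambda = 4e-5, kappa = 1.2e-3)
  co <- kinetic_coeffs(p)
  expect_equal(co$C_plus, 0.00055555555555555556, tolerance = 1e-12)
  expect_equal(co$k_inf, 0.0006939740629158989, tolerance = 1e-12)
  expect_equal(co$k_inf_bar, 0.00069397534378231175, tolerance = 1e-12)
  expect_equal(co$B_plus, 0.5783122527909211, tolerance = 1e-12)
  expect_equal(co$B_minus, -5.3369433868838708e-7, tolerance = 1e-10)
})

test_that("the closed form obeys its boundary identities and stays in [0,1]", {
  set.seed(13)
  for (i in 1:50) {
    ka <- 10^runif(1, -4, -2)
    la <- ka * 10^runif(1, -2, 0)
    p <- kinetic_params_lk(la, ka)
    tt <- c(0, 10^seq(1, 7, length.out = 40))
    m <- simulate_mass_fraction(p, tt)
    expect_equal(m[1], 0)
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(diff(m) >= -1e-12))
    expect_equal(m[length(m)], 1, tolerance = 1e-6)
  }
  # unseeded, no primary nucleation: no fibril mass ever forms
  p0 <- kinetic_params(k_n = 0, k_plus = 1e6, k_2 = 1e4)
  expect_equal(simulate_mass_fraction(p0, c(0, 1e4, 1e8)), c(0, 0, 0))
  expect_error(simulate_mass_fraction(p0, -1), ">= 0")
})

test_that("log-space evaluation equals direct evaluation where that is safe", {
  p <- kinetic_params_lk(lambda = 5e-4, kappa = 5e-4)
  co <- kinetic_coeffs(p)
  tt <- seq(0, 2e4, by = 500)  # kappa*t <= 10: exp() cannot overflow
  direct <- 1 -
    ((co$B_plus + co$C_plus) / (co$B_plus + co$C_plus * exp(co$kappa * tt)) *
     (co$B_minus + co$C_plus * exp(co$kappa * tt)) / (co$B_minus + co$C_plus)
    )^(co$k_inf^2 / (co$kappa * co$k_inf_bar)) * exp(-co$k_inf * tt)
  expect_equal(simulate_mass_fraction(p, tt), direct, tolerance = 1e-12)
  # naive evaluation overflows out here; the log-space path must not
  big <- simulate_mass_fraction(p, 1e7)
  expect_true(is.finite(big) && big == 1)
})

test_that("half-times respond monotonically to each rate constant", {
  base <- list(k_n = 90, k_plus = 1e6, k_2 = 3e10 / 1e6)
  t50 <- function(kn, kp, k2) {
    mass_fraction_halftime(kinetic_params(kn, kp, k2))
  }
  ref <- t50(base$k_n, base$k_plus, base$k_2)
  for (f in c(2, 5, 10)) {
    expect_lt(t50(base$k_n * f, base$k_plus, base$k_2), ref)
    expect_lt(t50(base$k_n, base$k_plus * f, base$k_2), ref)
    expect_lt(t50(base$k_n, base$k_plus, base$k_2 * f), ref)
  }
})

test_that("closed form agrees with the moment-ODE oracle where secondary nucleation dominates", {
  skip_if_not_installed("deSolve")
  p <- kinetic_params_lk(lambda = 4e-5, kappa = 1 / 3600)  # 1/kappa = 1 h
  t50 <- mass_fraction_halftime(p)
  tt <- seq(0, 4 * t50, length.out = 500)
  t50_ode <- approx(ode_mass_fraction(p, tt), tt, 0.5, ties = "ordered")$y
  expect_equal(t50, t50_ode, tolerance = 0.05)
})

test_that("the kappa = 0 branch is the continuous limit of the closed form", {
  pk0 <- kinetic_params(k_n = 1e-1, k_plus = 1e6, k_2 = 0)
  pk_eps <- kinetic_params(k_n = 1e-1, k_plus = 1e6, k_2 = 1e-6)
  tt <- seq(0, 5000, by = 50)
  expect_equal(simulate_mass_fraction(pk0, tt),
               simulate_mass_fraction(pk_eps, tt), tolerance = 1e-3)
  # early-time quadratic growth law M/m0 ~ (lambda t)^2 / 2
  t_small <- c(5, 10, 20, 40)
  expect_equal(simulate_mass_fraction(pk0, t_small),
               pk0$lambda^2 * t_small^2 / 2, tolerance = 0.05)
})
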