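test_that("kernel parameter pairs interconvert and validate", {
  k <- ref_kernel()
  expect_equal(k$nu_eps, 1300 / 1301, tolerance = 1e-12)
  ## round trip sigma -> eps -> sigma
  k2 <- fractional_kernel(0.35, tau_eps = k$tau_eps, nu_eps = k$nu_eps)
  expect_equal(k2$nu_sigma, k$nu_sigma, tolerance = 1e-12)
  expect_equal(k2$tau_sigma, k$tau_sigma, tolerance = 1e-12)
  expect_error(fractional_kernel(0.35, tau_sigma = 550, nu_sigma = -1),
               "nu_sigma")
  expect_error(fractional_kernel(0.35, tau_eps = 550, nu_eps = 1.2),
               "nu_eps")
  expect_error(fractional_kernel(1.5, tau_sigma = 550, nu_sigma = 1),
               "gamma")
  expect_error(fractional_kernel(0.35), "supply either")
})

test_that("kernel value matches the exponential at gamma = 1 and a
           high-precision series oracle at reference parameters", {
  tt <- c(0.5, 3, 40, 250)
  expect_equal(rabotnov(tt, 1, 550), exp(-tt / 550) / 550,
               tolerance = 1e-15)
  ## frozen 60-digit summation of the alternating series
  expect_equal(rabotnov(1, 0.35, 550), 0.035065495078306012,
               tolerance = 1e-10)
  expect_equal(rabotnov(300, 0.35, 550), 3.0648659053765190e-4,
               tolerance = 1e-10)
  expect_error(rabotnov(0, 0.35, 550), "positive")
  ## monotone decreasing over the loading window
  v <- rabotnov(seq(1, 300, length.out = 400), 0.35, 550)
  expect_true(all(diff(v) < 0))
})

test_that("series and large-argument evaluations join smoothly", {
  for (g in c(0.3, 0.5, 0.8)) {
    tau <- 2
    ## across the series/spectral switch at u = 1
    t_lo <- tau * 0.999^(1 / g); t_hi <- tau * 1.001^(1 / g)
    expect_equal(rabotnov(t_lo, g, tau), rabotnov(t_hi, g, tau),
                 tolerance = 1e-2)
    ## across the spectral/asymptotic switch at u = 30
    t_lo <- tau * 29.99^(1 / g); t_hi <- tau * 30.01^(1 / g)
    expect_equal(rabotnov(t_lo, g, tau), rabotnov(t_hi, g, tau),
                 tolerance = 1e-2)
    ## I0 saturates at unit kernel mass (power-law tail ~ u^-1/Gamma(1-g))
    u <- 1e14
    expect_equal(pdlvisco:::kernel_I0(u^(1 / g) * tau, g, tau),
                 1 - 1 / (u * gamma(1 - g)), tolerance = 1e-6)
  }
})

test_that("creep factor starts at 1 and reproduces reported growth", {
  k <- ref_kernel()
  expect_equal(creep_factor(0, k), 1)
  expect_equal(creep_factor(0, k, form = "resolvent"), 1)
  cv <- creep_factor(c(1, 10, 300), k)
  ## frozen high-precision values of the calibrated series
  expect_equal(cv, c(46.585143601798, 81.547446327701, 120.529770309684),
               tolerance = 1e-10)
  expect_equal(cv[2] / cv[1], 1.75, tolerance = 0.05)
  expect_equal(cv[3] / cv[1], 2.55, tolerance = 0.05)
  ## elastic limit: amplitude -> 0 gives a flat factor
  k0 <- fractional_kernel(0.35, tau_sigma = 550, nu_sigma = 1e-12)
  expect_equal(creep_factor(c(1, 300), k0), c(1, 1), tolerance = 1e-10)
})

test_that("creep factor is nondecreasing across the parameter sweep", {
  tt <- seq(0, 300, length.out = 301)
  for (g in c(0.25, 0.5, 0.9)) for (nus in c(1.3e3, 1.8e3))
    for (tau in c(350, 550)) {
      k <- fractional_kernel(g, tau_sigma = tau, nu_sigma = nus)
      ## the resolvent (governing-equation) creep is monotone always
      expect_true(all(diff(creep_factor(tt, k, "resolvent")) >= 0),
                  label = sprintf("monotone c(t), gamma=%g nu=%g tau=%g",
                                  g, nus, tau))
    }
  ## the calibrated closed-form series is monotone over the fitted
  ## window t/tau <= 300/550 but peaks near t ~ tau and then decays --
  ## a symptom of it not solving the governing equation (see vignette)
  for (g in c(0.25, 0.5, 0.9)) for (nus in c(1.3e3, 1.8e3)) {
    k <- fractional_kernel(g, tau_sigma = 550, nu_sigma = nus)
    expect_true(all(diff(creep_factor(tt, k, "calibrated")) >= 0))
  }
  k350 <- fractional_kernel(0.5, tau_sigma = 350, nu_sigma = 1.3e3)
  expect_lt(min(diff(creep_factor(tt, k350, "calibrated"))), 0)
})

test_that("matched parameter pairs give consistent long-time maxima", {
  ## pairs calibrated to the same maximum displacement
  pars <- list(c(0.25, 1850), c(0.30, 1520), c(0.35, 1300))
  c300 <- vapply(pars, function(p)
    creep_factor(300, fractional_kernel(p[1], tau_sigma = 550,
                                        nu_sigma = p[2])), numeric(1))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(c300[i], c300[j], tolerance = 0.05)
})

test_that("truncation order tracks the tolerance and the fractional order", {
  n25 <- truncation_order(0.25, t_max = 300, tau = 550, tol = 1e-3)
  n50 <- truncation_order(0.5, t_max = 300, tau = 550, tol = 1e-3)
  n75 <- truncation_order(0.75, t_max = 300, tau = 550, tol = 1e-3)
  expect_true(n25 > n50 && n50 > n75)
  ## truncating at the reported order reproduces the converged value
  for (g in c(0.25, 0.5, 0.75)) {
    n <- truncation_order(g, tol = 1e-3)
    u <- (300 / 550)^g
    terms <- vapply(0:(n + 400), function(m)
      (-1)^m * u^(m + 1) / gamma(g * (m + 1)), numeric(1))
    full <- 1 + 1300 * sum(terms)
    part <- 1 + 1300 * sum(terms[seq_len(n)])
    expect_lt(abs(part - full) / full, 1e-3)
  }
})
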