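test_that("vertical creep starts at the elastic value and fully
           compresses the ligament near 300 s under 2 N", {
  k <- ref_kernel(); g <- ref_geom()
  a22 <- published_coeffs["a22"]
  h <- vertical_creep(-2, a22, k, t = c(0, 1, 300))
  expect_equal(h$u0[1, "y"], -2 / a22, ignore_attr = TRUE)
  expect_equal(h$u0[1, "y"] * 1e6, -1.835, tolerance = 1e-3,
               ignore_attr = TRUE)
  ## kernel calibration: |u0y(300)| ~ delta (full-thickness compression)
  expect_equal(abs(h$u0[3, "y"]), g$delta, tolerance = 0.05,
               ignore_attr = TRUE)
  ## vanishing creep amplitude leaves the elastic solution
  k0 <- fractional_kernel(0.35, tau_sigma = 550, nu_sigma = 1e-12)
  h0 <- vertical_creep(-2, a22, k0, t = c(0, 10, 300))
  expect_equal(h0$u0[, "y"], rep(-2 / a22, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("horizontal creep through the centre of resistance is a
           consistent pure translation", {
  k <- ref_kernel(); S <- ref_stiffness()
  h <- horizontal_creep(2, S, k, t = c(0, 1, 300))
  cons <- attr(h, "consistency")
  expect_true(cons$consistent)
  expect_lt(cons$moment_residual_rel, 1e-12)
  expect_equal(h$u0[1, "x"], 2 / S$a11, ignore_attr = TRUE)
  ## normal strain at the crest meridian point stays near the reported
  ## 0.2 bound under 2 N
  g <- ref_geom()
  nx <- abs(unit_normal(crest_x(g), 0, g)["x"])
  eps <- abs(h$u0[3, "x"]) * nx / g$delta
  expect_lt(unname(eps), 0.21)
  expect_gt(unname(eps), 0.15)
  ## linear in the load
  h2 <- horizontal_creep(4, S, k, t = c(0, 1, 300))
  expect_equal(h2$u0[, "x"], 2 * h$u0[, "x"], tolerance = 1e-12)
  ## off-centre application breaks the assumption and is reported
  expect_warning(horizontal_creep(2, S, k, t = c(0, 1), y_f = 2e-3),
                 "centre of resistance")
})

test_that("required force inverts the creep solution", {
  k <- ref_kernel(); S <- ref_stiffness(); g <- ref_geom()
  ## vertical: f c(300)/a22 = delta  =>  about the 2 N scenario load
  fy <- required_force(g$delta, "y", 300, S, k)
  expect_equal(as.numeric(fy),
               g$delta * S$a22 / creep_factor(300, k), tolerance = 1e-10)
  expect_equal(as.numeric(fy), 2, tolerance = 0.05)
  expect_equal(attr(fy, "n_proj"), 1)
  ## doubling the target doubles the force
  f2 <- required_force(2 * g$delta, "y", 300, S, k)
  expect_equal(as.numeric(f2), 2 * as.numeric(fy), tolerance = 1e-12)
  ## horizontal: critical point is the crest end of the x meridian
  fx <- required_force(g$delta, "x", 300, S, k)
  expect_equal(attr(fx, "point"), c(g$a, 0), tolerance = 1e-6)
})

test_that("Volterra solver agrees with the closed-form resolvent creep", {
  k <- ref_kernel(); S <- ref_stiffness()
  tg <- creep_time_grid()
  h <- volterra_solve(S, k, load_case(c(0, -2, 0)), tg)
  u_exact <- (-2 / S$a22) * creep_factor(tg, k, form = "resolvent")
  i <- tg >= 1
  expect_lt(max(abs(h$u0[i, "y"] - u_exact[i]) / abs(u_exact[i])), 1e-3)
  ## other components stay numerically zero
  expect_lt(max(abs(h$u0[, c("x", "z")])), 1e-18)
  expect_lt(max(abs(h$theta)), 1e-12)
})

test_that("Volterra solver handles coupled loads and superposition", {
  k <- ref_kernel(); S <- ref_stiffness()
  tg <- creep_time_grid(n = 400L)
  ## x-force applied away from the centre of resistance couples u0x and
  ## theta_z; for a constant load the solution is the resolvent creep
  ## factor times the elastic solution
  ld <- load_case(c(2, 0, 0), r_f = c(0, 3e-3, 0))
  h <- volterra_solve(S, k, ld, tg)
  q_el <- solve(S$K, pdlvisco:::load_rhs(ld))
  i <- tg >= 1
  cfac <- creep_factor(tg[i], k, form = "resolvent")
  expect_equal(h$u0[i, "x"], q_el[1] * cfac, tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_equal(h$theta[i, "z"], q_el[6] * cfac, tolerance = 2e-3,
               ignore_attr = TRUE)
  ## zero load gives the zero solution
  h0 <- volterra_solve(S, k, load_case(c(0, 0, 0)), creep_time_grid(n = 50L))
  expect_equal(max(abs(h0$u0)), 0)
  ## superposition across load cases
  ld2 <- load_case(c(0, -2, 0))
  hA <- volterra_solve(S, k, ld2, tg)
  ldsum <- load_case(c(2, -2, 0), r_f = c(0, 3e-3, 0))
  hS <- volterra_solve(S, k, ldsum, tg)
  expect_equal(hS$u0, h$u0 + hA$u0, tolerance = 1e-10)
})

test_that("Volterra solver converges with at least first order", {
  k <- ref_kernel(); S <- ref_stiffness()
  err <- vapply(c(100L, 200L, 400L), function(n) {
    tg <- creep_time_grid(n = n)
    h <- volterra_solve(S, k, load_case(c(0, -2, 0)), tg)
    u_exact <- (-2 / S$a22) * creep_factor(tg, k, form = "resolvent")
    i <- tg >= 1
    max(abs(h$u0[i, "y"] - u_exact[i]) / abs(u_exact[i]))
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders > 1))
})

test_that("resolvent creep drives the governing-equation residual to
           discretisation level; the calibrated series does not", {
  k <- ref_kernel()
  r <- volterra_residual(k, c(1, 10, 100, 300), form = "resolvent")
  expect_lt(max(abs(r$residual_rel)), 1e-6)
  rc <- volterra_residual(k, c(1, 300), form = "calibrated",
                          n_grid = 2000L)
  expect_gt(min(abs(rc$residual_rel)), 0.1)
})

test_that("inertia estimate matches analytic differentiation and
           justifies the quasi-static approximation", {
  k <- ref_kernel()
  a22 <- unname(published_coeffs["a22"])
  ie <- inertia_estimate(c(1, 10, 300), -2, a22, k, M = 1e-3)
  ## against a central finite difference of the creep solution
  for (i in seq_len(nrow(ie))) {
    t0 <- ie$t[i]; dt <- t0 * 1e-4
    u <- (-2 / a22) * creep_factor(c(t0 - dt, t0, t0 + dt), k)
    fd <- (u[1] - 2 * u[2] + u[3]) / dt^2
    expect_equal(ie$accel[i], fd, tolerance = 1e-5)
  }
  ## inertial force is negligible against the elastic force
  expect_lt(max(ie$inertia_ratio), 1e-8)
  ## gamma = 1: second derivative of the exponential closed form
  k1 <- fractional_kernel(1, tau_sigma = 550, nu_sigma = 1.3e3)
  ie1 <- inertia_estimate(c(5, 50), 1, a22, k1)
  tt <- c(5, 50); tau <- 550
  dd <- (1.3e3 / a22) * exp(-tt / tau) * (tt / tau - 2) / tau^2
  expect_equal(ie1$accel, dd, tolerance = 1e-9)
})
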