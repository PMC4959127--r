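test_that("elastic limit of the constitutive law is plane-strain-like
           uniaxial response", {
  mt <- ref_material()
  eps <- 0.01
  n <- 40L
  sh <- structure(list(t = seq(0, 10, length.out = n),
                       eps = array(rep(diag(c(eps, 0, 0)), n),
                                   c(3, 3, n))),
                  class = "strain_history")
  st <- stress_tensor(sh, kernel = NULL, mt, t_eval = 10)
  C <- mt$E_inf / ((1 - 2 * mt$nu) * (1 + mt$nu))
  expect_equal(st$sigma[1, 1], C * (1 - mt$nu) * eps, tolerance = 1e-12)
  expect_equal(st$sigma[2, 2], C * mt$nu * eps, tolerance = 1e-12)
  expect_equal(st$sigma_h, sum(diag(st$sigma)) / 3, tolerance = 1e-15)
  ## zero strain gives zero stress
  sh0 <- structure(list(t = c(0, 5, 10), eps = array(0, c(3, 3, 3))),
                   class = "strain_history")
  expect_equal(stress_tensor(sh0, ref_kernel(), mt, 10)$sigma,
               matrix(0, 3, 3), tolerance = 1e-18)
})

test_that("step strain with gamma = 1 relaxes like the exponential
           standard-linear solid", {
  mt <- ref_material()
  k1 <- fractional_kernel(1, tau_eps = 20, nu_eps = 0.6)
  eps <- 5e-3
  tg <- c(0, exp(seq(log(1e-4), log(50), length.out = 900)))
  n <- length(tg)
  sh <- structure(list(t = tg, eps = array(rep(diag(c(eps, 0, 0)), n),
                                           c(3, 3, n))),
                  class = "strain_history")
  C <- mt$E_inf / ((1 - 2 * mt$nu) * (1 + mt$nu))
  for (te in c(5, 50)) {
    st <- stress_tensor(sh, k1, mt, t_eval = te)
    ## hat(eps) = eps (1 - nu_eps (1 - exp(-t/tau)))
    fac <- 1 - 0.6 * (1 - exp(-te / 20))
    expect_equal(st$sigma[1, 1], C * (1 - mt$nu) * eps * fac,
                 tolerance = 1e-6)
  }
})

test_that("hydrostatic stress extracts the mean direct stress", {
  expect_equal(hydrostatic(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)), 0)
  expect_equal(hydrostatic(5 * diag(3)), 5)
})

test_that("closed-form vertical map agrees with the constitutive route", {
  g <- ref_geom(); mt <- ref_material()
  u0y <- -1e-4
  expect_equal(hydrostatic_vertical(0, 0, u0y, g, mt),
               mt$E_inf * u0y / (3 * g$delta * (1 - 2 * mt$nu)))
  expect_equal(hydrostatic_vertical(1e-3, 0, 0, g, mt), 0)
  ## spatial ratio apex/crest is the geometric factor 1/cos(alpha)
  ratio <- hydrostatic_vertical(0, 0, u0y, g, mt) /
    hydrostatic_vertical(crest_x(g), 0, u0y, g, mt)
  expect_equal(ratio, 5.43, tolerance = 1e-2)
  ## dual path: elastic-limit Eq.-style trace at sampled points equals
  ## the closed form up to the strain-sign convention
  m <- rigid_motion(u0 = c(0, u0y, 0))
  set.seed(21)
  for (i in 1:8) {
    r <- sqrt(runif(1)); ph <- runif(1, 0, 2 * pi)
    x <- g$a * r * cos(ph); z <- g$b * r * sin(ph)
    sh <- structure(list(t = c(0, 1),
                         eps = array(rep(cartesian_strain_tensor(
                           x, z, m, g), 2), c(3, 3, 2))),
                    class = "strain_history")
    sv <- hydrostatic(stress_tensor(sh, NULL, mt, 1))
    expect_equal(-sv, hydrostatic_vertical(x, z, u0y, g, mt),
                 tolerance = 1e-8)
  }
})

test_that("horizontal-translation stress map is antisymmetric with a
           stress-free apex and crest-dominated extremes", {
  k <- ref_kernel(); S <- ref_stiffness()
  ld <- load_case(c(2, 0, 0),
                  r_f = c(0, unname(center_of_resistance(S)["y1"]), 0))
  fld <- surface_map(ld, 300, S, k, n_r = 24L, n_phi = 48L)
  ## pair each node with its x-mirror (phi -> pi - phi symmetry of grid)
  key <- function(x) round(x, 12)
  i <- order(key(fld$z), key(fld$y), key(fld$x))
  j <- order(key(fld$z), key(fld$y), key(-fld$x))
  expect_equal(fld$sigma_h[i], -fld$sigma_h[j], tolerance = 1e-10)
  ## apex: sigma_h -> 0 (innermost ring, meridian x = 0 exactly zero)
  on_axis <- abs(fld$x) < 1e-15
  expect_true(all(abs(fld$sigma_h[on_axis]) < 1e-8 * max(abs(fld$sigma_h))))
  ## compression on the loaded side, tension behind
  expect_lt(fld$sigma_h[which.max(fld$x)], 0)
  expect_gt(fld$sigma_h[which.min(fld$x)], 0)
  ## magnitudes peak near the alveolar crest
  expect_gt(fld$y[which.max(abs(fld$sigma_h))], 0.9 * ref_geom()$h)
  ## time scaling: map at 300 s is the 1 s map times c(300)/c(1)
  fld1 <- surface_map(ld, 1, S, k, n_r = 24L, n_phi = 48L)
  cr <- creep_factor(300, k) / creep_factor(1, k)
  expect_equal(fld$sigma_h, cr * fld1$sigma_h, tolerance = 1e-10)
})

test_that("peak-stress growth factors equal the creep-factor ratios", {
  k <- ref_kernel(); S <- ref_stiffness()
  gf <- growth_factors(load_case(c(0, -2, 0)), times = c(1, 10, 300),
                       S, k)
  cv <- creep_factor(c(1, 10, 300), k)
  expect_equal(gf$growth, cv / cv[1], tolerance = 1e-10)
  expect_equal(gf$growth[1], 1)
  expect_equal(gf$growth[2], 1.75, tolerance = 0.05)
  expect_equal(gf$growth[3], 2.55, tolerance = 0.05)
})

test_that("strain history construction matches pointwise tensors", {
  g <- ref_geom(); k <- ref_kernel()
  h <- vertical_creep(-2, 1.09e6, k, t = c(0, 1, 10))
  sh <- pdl_strain_history(1e-3, 5e-4, h, g)
  m2 <- rigid_motion(u0 = h$u0[2, ])
  expect_equal(sh$eps[, , 2], cartesian_strain_tensor(1e-3, 5e-4, m2, g),
               ignore_attr = TRUE)
})
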