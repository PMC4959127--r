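#' External load on the tooth
#'
#' A concentrated force applied at a point of the tooth (crown or root
#' axis), plus an optional external couple.
#'
#' @param f force 3-vector [N].
#' @param r_f application point \code{(x_f, y_f, z_f)} [m].
#' @param m_ext external moment 3-vector [N m].
#' @return object of class \code{"load_case"}.
#' @export
load_case <- function(f, r_f = c(0, 0, 0), m_ext = c(0, 0, 0)) {
  stopifnot(is.numeric(f), length(f) == 3L, all(is.finite(f)),
            is.numeric(r_f), length(r_f) == 3L, all(is.finite(r_f)),
            is.numeric(m_ext), length(m_ext) == 3L, all(is.finite(m_ext)))
  structure(list(f = as.numeric(f), r_f = as.numeric(r_f),
                 m_ext = as.numeric(m_ext)), class = "load_case")
}

## generalized RHS (force, moment about origin) of the rigid-root system
load_rhs <- function(load) {
  m <- c(load$r_f[2] * load$f[3] - load$r_f[3] * load$f[2],
         load$r_f[3] * load$f[1] - load$r_f[1] * load$f[3],
         load$r_f[1] * load$f[2] - load$r_f[2] * load$f[1]) + load$m_ext
  c(load$f, m)
}

#' Time history of rigid-root motion
#'
#' Container for translations and rotations of the root as functions of
#' time.
#'
#' @param t strictly increasing times [s], first value \eqn{\ge 0}.
#' @param u0 n-by-3 matrix of translations [m].
#' @param theta n-by-3 matrix of rotations [rad].
#' @return object of class \code{"displacement_history"}.
#' @export
displacement_history <- function(t, u0, theta = NULL) {
  t <- as.numeric(t)
  stopifnot(all(diff(t) > 0), t[1] >= 0)
  u0 <- matrix(u0, ncol = 3L)
  if (is.null(theta)) theta <- matrix(0, nrow(u0), 3L)
  theta <- matrix(theta, ncol = 3L)
  stopifnot(nrow(u0) == length(t), nrow(theta) == length(t),
            all(is.finite(u0)), all(is.finite(theta)))
  colnames(u0) <- c("x", "y", "z"); colnames(theta) <- c("x", "y", "z")
  structure(list(t = t, u0 = u0, theta = theta),
            class = "displacement_history")
}

#' @export
print.displacement_history <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("Rigid-root displacement history: %d times in [%g, %g] s\n",
              n, x$t[1], x$t[n]))
  cat(sprintf("  final |u0| = %.4g mm, |theta| = %.4g mrad\n",
              1e3 * sqrt(sum(x$u0[n, ]^2)),
              1e3 * sqrt(sum(x$theta[n, ]^2))))
  invisible(x)
}

#' Default time grid for creep computations
#'
#' Geometric spacing resolving the weakly singular kernel near
#' \eqn{t = 0}; includes \eqn{t = 0} as the first node.
#'
#' @param t_min first positive node [s].
#' @param t_max final time [s].
#' @param n number of positive nodes.
#' @return numeric vector \code{c(0, geometric nodes)}.
#' @export
creep_time_grid <- function(t_min = 1e-5, t_max = 300, n = 800L) {
  stopifnot(t_min > 0, t_max > t_min, n >= 2L)
  c(0, exp(seq(log(t_min), log(t_max), length.out = n)))
}

#' Vertical (intrusive/extrusive) creep of the tooth root
#'
#' Closed-form creep solution for a constant vertical load: the root
#' translates along y only, with
#' \eqn{u_{0y}(t) = (f_y/a_{22})\, c(t)} where \eqn{c} is the
#' \code{\link{creep_factor}}.  The initial (elastic) displacement is
#' \eqn{f_y/a_{22}}.
#'
#' @param f_y vertical force [N] (negative = intrusion).
#' @param a22 vertical stiffness coefficient [N/m].
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param t evaluation times [s].
#' @param form creep-factor form (see \code{\link{creep_factor}}).
#' @return a \code{\link{displacement_history}} with only \code{u0y}
#'   nonzero.
#' @export
vertical_creep <- function(f_y, a22, kernel, t = creep_time_grid(),
                           form = c("calibrated", "resolvent")) {
  stopifnot(a22 > 0)
  form <- match.arg(form)
  u <- (f_y / a22) * creep_factor(t, kernel, form)
  displacement_history(t, cbind(0, u, 0))
}

#' Horizontal creep of the tooth root through the centre of resistance
#'
#' Pure x-translation under a horizontal force whose line of action
#' passes through the centre of resistance \eqn{(0, y_1, 0)}:
#' \eqn{u_{0x}(t) = (f_x/a_{11})\, c(t)}.  The returned object carries a
#' consistency report: the pure-translation assumption requires the
#' moment equation \eqn{a_{61}\,(f_x/a_{11}) = -y_f f_x} to hold, which
#' it does identically when \eqn{y_f = y_1 = -a_{61}/a_{11}}.  For any
#' other application height the relative moment residual is reported and
#' \code{consistent} is FALSE.
#'
#' @param f_x horizontal force [N].
#' @param S a \code{\link{assemble_stiffness}} result.
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param t evaluation times [s].
#' @param y_f application height of the load [m]; defaults to the
#'   centre of resistance.
#' @param form creep-factor form.
#' @return a \code{\link{displacement_history}} (u0x only) with
#'   attribute \code{"consistency"}: list(y1, y_f, moment_residual_rel,
#'   consistent).
#' @export
horizontal_creep <- function(f_x, S, kernel, t = creep_time_grid(),
                             y_f = NULL,
                             form = c("calibrated", "resolvent")) {
  stopifnot(inherits(S, "stiffness_matrix"))
  form <- match.arg(form)
  y1 <- unname(center_of_resistance(S)["y1"])
  if (is.null(y_f)) y_f <- y1
  ## moment-about-z equation with u0x the only motion:
  ## a61 * (f_x/a11) + y_f * f_x = 0  <=>  y_f = y1
  resid <- abs(S$a61 * (f_x / S$a11) + y_f * f_x) /
    max(abs(y_f * f_x), abs(S$a61 * f_x / S$a11), .Machine$double.xmin)
  consistent <- resid < 1e-10
  if (!consistent)
    warning(sprintf(paste0(
      "load applied at y_f = %.4g mm, not at the centre of resistance ",
      "(y1 = %.4g mm): pure-translation assumption violated ",
      "(relative moment residual %.3g)"), 1e3 * y_f, 1e3 * y1, resid))
  u <- (f_x / S$a11) * creep_factor(t, kernel, form)
  out <- displacement_history(t, cbind(u, 0, 0))
  attr(out, "consistency") <- list(y1 = y1, y_f = y_f,
                                   moment_residual_rel = resid,
                                   consistent = consistent)
  out
}

## largest |n_axis| over the surface: where the root translation is most
## nearly normal to the PDL.  For y it is the apex (n_y = 1); for x/z it
## is the crest end of the corresponding principal meridian.
max_normal_projection <- function(geom, direction = c("x", "y", "z")) {
  direction <- match.arg(direction)
  if (direction == "y") return(list(value = 1, point = c(0, 0)))
  ## n_x (n_z) is monotone along the meridian z = 0 (x = 0); confirm on
  ## a fine boundary + meridian sweep
  nd <- surface_quadrature(geom, 128L, 256L)
  comp <- if (direction == "x") abs(nd$nx) else abs(nd$nz)
  i <- which.max(comp)
  crest <- if (direction == "x") c(geom$a, 0) else c(0, geom$b)
  ncr <- unit_normal(crest[1], crest[2], geom)
  vcr <- abs(if (direction == "x") ncr[1] else ncr[3])
  if (vcr >= comp[i]) list(value = vcr, point = crest)
  else list(value = comp[i], point = c(nd$x[i], nd$z[i]))
}

#' Force required for a target normal compression of the PDL
#'
#' Inverts the translational creep solution: finds the force magnitude
#' along a coordinate axis such that the maximum normal penetration of
#' the root surface into the PDL, \eqn{\max_F |u\cdot n|}, equals
#' \code{target_un} at time \code{t_eval}.  With \code{target_un} equal
#' to the PDL thickness this is the load that fully compresses the
#' ligament at its most exposed point (the apex for vertical loads, the
#' crest end of the meridian for horizontal ones).
#'
#' @param target_un target normal displacement [m].
#' @param direction one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param t_eval evaluation time [s].
#' @param S a \code{\link{assemble_stiffness}} result.
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param geom a \code{\link{root_geometry}} (defaults to the one in
#'   \code{S}).
#' @param form creep-factor form.
#' @return force magnitude [N], with attributes \code{"point"} (x, z of
#'   the critical surface point) and \code{"n_proj"} (|n| projection
#'   there).
#' @export
required_force <- function(target_un, direction = c("x", "y", "z"),
                           t_eval, S, kernel, geom = S$geometry,
                           form = c("calibrated", "resolvent")) {
  direction <- match.arg(direction)
  form <- match.arg(form)
  stopifnot(target_un > 0, t_eval >= 0)
  a_dir <- switch(direction, x = S$a11, y = S$a22, z = S$a33)
  mp <- max_normal_projection(geom, direction)
  cval <- creep_factor(t_eval, kernel, form)
  f <- target_un * a_dir / (cval * mp$value)
  attr(f, "point") <- mp$point
  attr(f, "n_proj") <- mp$value
  f
}

#' Solve the coupled rigid-root Volterra system
#'
#' Numerically integrates the quasi-static system of equations of
#' motion: for generalized coordinates
#' \eqn{q = (u_{0x}, u_{0y}, u_{0z}, \theta_x, \theta_y, \theta_z)},
#' \deqn{K\left(q(t) - \nu_\varepsilon \int_0^t
#'   \mathcal{E}_\gamma(-s/\tau_\varepsilon)\, q(t-s)\, ds\right) = F(t),}
#' with \eqn{K} the stiffness matrix and \eqn{F} the generalized load.
#' Because the Volterra operator acts identically on every component,
#' the system reduces to six scalar equations with right-hand side
#' \eqn{g(t) = K^{-1} F(t)}.  The weakly singular convolution is
#' discretised by product integration: the solution is taken piecewise
#' linear on the grid and the kernel moments
#' \eqn{\int \mathcal{E}\,ds}, \eqn{\int s\,\mathcal{E}\,ds} are
#' evaluated exactly (series plus spectral representation, tabulated on
#' a log grid and splined), so the scheme handles the
#' \eqn{t^{\gamma-1}} singularity without loss of order.
#'
#' An optional inertia term \eqn{M\ddot u_0}, \eqn{J\ddot\theta} can be
#' included explicitly (lagged finite-difference acceleration); it is
#' off by default, matching the quasi-static analysis.
#'
#' @param S a \code{\link{assemble_stiffness}} result.
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param load a \code{\link{load_case}} (constant in time) or a
#'   function(t) returning one.
#' @param t time grid [s], first node 0, strictly increasing.
#' @param inertia NULL (default, quasi-static) or
#'   \code{list(M = mass [kg], J = c(Jx, Jy, Jz) [kg m^2])}.
#' @return a \code{\link{displacement_history}}.
#' @export
volterra_solve <- function(S, kernel, load, t = creep_time_grid(),
                           inertia = NULL) {
  stopifnot(inherits(S, "stiffness_matrix"),
            inherits(kernel, "fractional_kernel"))
  t <- as.numeric(t)
  if (t[1] != 0) stop("time grid must start at 0")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  N <- length(t)
  loadfun <- if (is.function(load)) load else function(ti) load
  G <- t(vapply(t, function(ti) solve(S$K, load_rhs(loadfun(ti))),
                numeric(6)))
  ne <- kernel$nu_eps; ge <- kernel$gamma; te <- kernel$tau_eps

  ## tabulate kernel moments I0, I1 on a log grid spanning all the
  ## pairwise time differences, then spline in log-time
  tabs <- kernel_moment_tables(ge, te, min(diff(t)) / 10, t[N])
  I0 <- tabs$I0; I1 <- tabs$I1

  Q <- matrix(0, N, 6L)
  Q[1, ] <- G[1, ]
  if (!is.null(inertia)) {
    Mvec <- c(rep(inertia$M, 3L), inertia$J)
    Kdiag_inv <- solve(S$K)
  }
  for (i in 2:N) {
    ti <- t[i]
    j <- 1:(i - 1L)                  # intervals [t_j, t_j+1]
    U1 <- ti - t[j]; U0 <- ti - t[j + 1L]
    d0 <- I0(U1) - I0(U0)
    m1 <- U1 * d0 - (I1(U1) - I1(U0))
    h <- t[j + 1L] - t[j]
    wlin <- m1 / h                   # weight multiplying (q_{j+1} - q_j)
    ## sum over known part: q_j d0 + (q_{j+1}-q_j) wlin, with q_i unknown
    ## in the last interval
    cj <- d0 - wlin                  # coefficient of q_j
    ck <- wlin                       # coefficient of q_{j+1}
    known <- colSums(Q[j, , drop = FALSE] * cj) +
      colSums(Q[j + 1L, , drop = FALSE] * c(ck[-(i - 1L)], 0))
    gi <- G[i, ]
    if (!is.null(inertia) && i > 2L) {
      ## lagged acceleration estimate on the last three known nodes
      h1 <- t[i - 1L] - t[i - 2L]
      h2 <- if (i > 3L) t[i - 2L] - t[i - 3L] else h1
      qa <- Q[i - 1L, ]; qb <- Q[i - 2L, ]
      qc <- if (i > 3L) Q[i - 3L, ] else Q[i - 2L, ]
      acc <- 2 * (qc / (h2 * (h1 + h2)) - qb / (h1 * h2) +
                    qa / (h1 * (h1 + h2)))
      gi <- gi - drop(Kdiag_inv %*% (Mvec * acc))
    }
    Q[i, ] <- (gi + ne * known) / (1 - ne * ck[i - 1L])
  }
  displacement_history(t, Q[, 1:3, drop = FALSE], Q[, 4:6, drop = FALSE])
}

#' Residual of the governing Volterra equation for a creep solution
#'
#' Substitutes a scalar creep solution \eqn{u(t) = g\,c(t)} back into
#' the governing equation
#' \eqn{u(t) - \nu_\varepsilon \int_0^t
#' \mathcal{E}_\gamma(-s/\tau_\varepsilon) u(t-s) ds = g}
#' and returns the residual relative to \eqn{g}, evaluating the
#' convolution with the same exact-moment product integration used by
#' \code{\link{volterra_solve}}.  For the \code{"resolvent"} creep form
#' the residual is at discretisation level (\eqn{< 10^{-6}} on a
#' reasonable grid); the \code{"calibrated"} form leaves an order-one
#' residual, quantifying how far the calibrated closed form is from
#' solving the governing equation (see the methods vignette).
#'
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param t_eval times at which to report the residual [s] (> 0).
#' @param form creep-factor form being substituted.
#' @param n_grid nodes of the internal convolution grid.
#' @return data.frame with columns \code{t} and \code{residual_rel}.
#' @export
volterra_residual <- function(kernel, t_eval = c(1, 3, 10, 30, 100, 300),
                              form = c("resolvent", "calibrated"),
                              n_grid = 12000L) {
  form <- match.arg(form)
  stopifnot(all(t_eval > 0))
  ne <- kernel$nu_eps; ge <- kernel$gamma; te <- kernel$tau_eps
  ## moments are evaluated directly (series / spectral / asymptotic by
  ## argument), not splined: the residual is a near-cancellation and
  ## needs the moments at full precision
  res <- vapply(t_eval, function(Tv) {
    tg <- c(0, exp(seq(log(Tv * 1e-8), log(Tv), length.out = n_grid)))
    ## pin the endpoint: roundoff in exp(log(Tv)) would otherwise leave
    ## a spurious ~1e-14 final lag, which for a stiff kernel (tiny
    ## tau_eps) still carries finite kernel mass
    tg[length(tg)] <- Tv
    cv <- creep_factor(tg, kernel, form)
    j <- 1:(length(tg) - 1L)
    U1 <- Tv - tg[j]; U0 <- pmax(Tv - tg[j + 1L], 0)
    d0 <- kernel_I0(U1, ge, te) - kernel_I0(U0, ge, te)
    m1 <- U1 * d0 - (kernel_I1(U1, ge, te) - kernel_I1(U0, ge, te))
    h <- tg[j + 1L] - tg[j]
    conv <- sum(cv[j] * (d0 - m1 / h) + cv[j + 1L] * (m1 / h))
    (cv[length(tg)] - ne * conv) - 1
  }, numeric(1))
  data.frame(t = t_eval, residual_rel = res)
}

#' Inertia of the tooth root
#'
#' @param M root mass [kg].
#' @param J axial moments of inertia \code{(Jx, Jy, Jz)} [kg m^2].
#' @return object of class \code{"inertia_props"}.
#' @export
inertia_props <- function(M = 1e-3, J = c(0, 0, 0)) {
  stopifnot(M > 0, length(J) == 3L, all(J >= 0))
  structure(list(M = M, J = as.numeric(J)), class = "inertia_props")
}

#' Analytic inertia assessment for translational creep
#'
#' Differentiates the creep solution \eqn{u(t) = (f/a)\,c(t)} twice,
#' term by term in the kernel series, and compares the inertial force
#' \eqn{M \ddot u} with the elastic force \eqn{a\, u}.  The second
#' derivative of \eqn{t^{\gamma(n+1)}} is singular at \eqn{t = 0} for
#' \eqn{\gamma < 1}, so evaluation is restricted to \eqn{t \ge} the
#' first grid time (use times \eqn{\ge 1} s for the quasi-static
#' argument).
#'
#' @param t evaluation times [s], strictly positive.
#' @param f constant force [N].
#' @param a stiffness coefficient [N/m].
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param M root mass [kg].
#' @param form creep-factor form.
#' @return data.frame with columns \code{t}, \code{u} [m],
#'   \code{accel} [m/s^2], \code{inertial_force} [N] and
#'   \code{inertia_ratio} (\eqn{M|\ddot u| / (a |u|)}).
#' @export
inertia_estimate <- function(t, f, a, kernel, M = 1e-3,
                             form = c("calibrated", "resolvent")) {
  form <- match.arg(form)
  stopifnot(all(t > 0), a > 0, M > 0)
  g <- kernel$gamma; tau <- kernel$tau_sigma; nus <- kernel$nu_sigma
  n <- 0:(max(kernel$n_max, 300L))
  p <- g * (n + 1)
  lden <- if (form == "calibrated") lgamma(p) else lgamma(p + 1)
  sgn <- (-1)^n * sign(p - 1)
  ## terms in log space: t^(p-2) overflows for gamma near 1 at long times
  ddc <- vapply(t, function(ti) {
    lmag <- log(p) + log(abs(p - 1) + (p == 1)) +
      (p - 2) * log(ti) - p * log(tau) - lden
    nus * sum(sgn * (p != 1) * exp(lmag))
  }, numeric(1))
  u <- (f / a) * creep_factor(t, kernel, form)
  accel <- (f / a) * ddc
  data.frame(t = t, u = u, accel = accel,
             inertial_force = M * accel,
             inertia_ratio = abs(M * accel) / pmax(a * abs(u),
                                                   .Machine$double.xmin))
}
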