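#' Strain history of the PDL at a surface point
#'
#' Builds the Cartesian strain-tensor history at a root-surface point
#' from a rigid-root \code{\link{displacement_history}}.
#'
#' @param x,z horizontal coordinates of the surface point [m].
#' @param history a \code{\link{displacement_history}}.
#' @param geom a \code{\link{root_geometry}}.
#' @return list of class \code{"strain_history"} with \code{t} and a
#'   3-by-3-by-n array \code{eps}.
#' @export
pdl_strain_history <- function(x, z, history, geom) {
  stopifnot(inherits(history, "displacement_history"))
  n <- length(history$t)
  eps <- array(0, c(3L, 3L, n))
  for (i in seq_len(n)) {
    m <- rigid_motion(history$u0[i, ], history$theta[i, ])
    eps[, , i] <- cartesian_strain_tensor(x, z, m, geom)
  }
  structure(list(t = history$t, eps = eps), class = "strain_history")
}

#' Viscoelastic stress tensor of the PDL
#'
#' Evaluates the fractional-exponential constitutive law
#' \deqn{\sigma_{ij}(t) = \frac{E_\infty}{(1-2\nu)(1+\nu)}
#'   \left\{(1-2\nu)\,\hat\varepsilon_{ij}
#'   + \nu\,\delta_{ij}\sum_k \hat\varepsilon_{kk}\right\},\qquad
#'   \hat\varepsilon = \varepsilon(t) - \nu_\varepsilon \int_0^t
#'   \mathcal{E}_\gamma(-s/\tau_\varepsilon)\,\varepsilon(t-s)\,ds,}
#' at time \code{t_eval}, given a strain-tensor history sampled on a
#' grid covering \eqn{[0, t_{eval}]}.  The weakly singular convolution
#' uses the same exact-moment product integration as
#' \code{\link{volterra_solve}}.  With \code{kernel = NULL} the elastic
#' (no-relaxation) limit \eqn{\hat\varepsilon = \varepsilon(t)} is used.
#'
#' @param strain a \code{\link{pdl_strain_history}} (fields \code{t},
#'   \code{eps}).
#' @param kernel a \code{\link{fractional_kernel}}, or NULL for the
#'   elastic limit.
#' @param material a \code{\link{pdl_material}}.
#' @param t_eval evaluation time [s]; must lie within the sampled grid.
#' @return object of class \code{"stress_state"}: list with the 3-by-3
#'   tensor \code{sigma} [Pa] and \code{sigma_h} = trace/3 [Pa].
#' @export
stress_tensor <- function(strain, kernel, material, t_eval) {
  stopifnot(inherits(strain, "strain_history"),
            inherits(material, "pdl_material"))
  tg <- strain$t
  if (t_eval < tg[1] || t_eval > tg[length(tg)] + 1e-12 * t_eval)
    stop("strain history does not cover 't_eval'")
  i_end <- max(which(tg <= t_eval * (1 + 1e-12)))
  eps_arr <- strain$eps
  if (tg[i_end] < t_eval * (1 - 1e-12)) {
    ## t_eval falls between samples: append a linearly interpolated node
    w <- (t_eval - tg[i_end]) / (tg[i_end + 1L] - tg[i_end])
    eps_t <- (1 - w) * eps_arr[, , i_end] + w * eps_arr[, , i_end + 1L]
    eps_arr <- array(c(eps_arr[, , 1:i_end], eps_t), c(3L, 3L, i_end + 1L))
    tg <- c(tg[1:i_end], t_eval)
    i_end <- i_end + 1L
  }
  eps_now <- eps_arr[, , i_end]
  if (is.null(kernel)) {
    eps_hat <- eps_now
  } else {
    ne <- kernel$nu_eps
    tt <- tg[1:i_end]
    if (i_end < 3L) stop("strain history grid too coarse before 't_eval'")
    tabs <- kernel_moment_tables(kernel$gamma, kernel$tau_eps,
                                 min(diff(tt)) / 10, t_eval)
    j <- 1:(i_end - 1L)
    U1 <- t_eval - tt[j]; U0 <- t_eval - tt[j + 1L]
    d0 <- tabs$I0(U1) - tabs$I0(U0)
    m1 <- U1 * d0 - (tabs$I1(U1) - tabs$I1(U0))
    h <- tt[j + 1L] - tt[j]
    cj <- d0 - m1 / h; ck <- m1 / h
    conv <- matrix(0, 3L, 3L)
    for (a in 1:3) for (b in 1:3)
      conv[a, b] <- sum(cj * eps_arr[a, b, j] +
                          ck * eps_arr[a, b, j + 1L])
    eps_hat <- eps_now - ne * conv
  }
  nu <- material$nu
  C <- material$E_inf / ((1 - 2 * nu) * (1 + nu))
  sig <- C * ((1 - 2 * nu) * eps_hat +
                nu * sum(diag(eps_hat)) * diag(3))
  structure(list(sigma = sig, sigma_h = sum(diag(sig)) / 3),
            class = "stress_state")
}

#' Hydrostatic (mean) stress
#'
#' @param S a \code{\link{stress_tensor}} result or a 3-by-3 stress
#'   tensor.
#' @return \eqn{(\sigma_{xx}+\sigma_{yy}+\sigma_{zz})/3} [Pa].
#' @export
hydrostatic <- function(S) {
  if (inherits(S, "stress_state")) return(S$sigma_h)
  stopifnot(is.matrix(S), all(dim(S) == c(3L, 3L)))
  sum(diag(S)) / 3
}

#' Closed-form hydrostatic stress under vertical translation
#'
#' For a vertical root translation \eqn{u_{0y}} the hydrostatic stress
#' in the PDL at a surface point is
#' \deqn{\sigma_h = \frac{E_\infty\, u_{0y} \cos\alpha}{3\delta(1-2\nu)},}
#' with \eqn{\cos\alpha = n_y} the vertical component of the surface
#' normal: largest in magnitude at the apex (\eqn{\cos\alpha = 1}),
#' smallest at the alveolar crest.  Intrusion (\eqn{u_{0y} < 0}) gives
#' compressive (negative) \eqn{\sigma_h}.  The spatial pattern is
#' time-invariant; time enters only through \eqn{u_{0y}(t)}.
#'
#' @param x,z horizontal coordinates of the surface point [m]
#'   (vectorised).
#' @param u0y vertical translation of the root at the evaluation time
#'   [m].
#' @param geom a \code{\link{root_geometry}}.
#' @param material a \code{\link{pdl_material}}.
#' @return hydrostatic stress [Pa].
#' @export
hydrostatic_vertical <- function(x, z, u0y, geom, material) {
  stopifnot(inherits(geom, "root_geometry"),
            inherits(material, "pdl_material"))
  ca <- 1 / surface_delta_factor(x, z, geom)
  material$E_inf * u0y * ca / (3 * geom$delta * (1 - 2 * material$nu))
}

#' Hydrostatic stress map over the root surface
#'
#' Samples the quasi-elastic hydrostatic stress
#' \eqn{\sigma_h = E_\infty (u\cdot n)/(3\delta(1-2\nu))} over the root
#' surface at time \code{t_eval} for a constant load, where
#' \eqn{u = u_0(t) + \theta(t) \times r} is the rigid displacement
#' resolved from the stiffness system,
#' \eqn{q(t) = c(t)\,K^{-1}F}, and \eqn{n} is the inward surface
#' normal.  For a vertical translation the map coincides with
#' \code{\link{hydrostatic_vertical}}; for a horizontal translation it
#' is antisymmetric in the load direction (compression ahead of the
#' root, tension behind) and vanishes on the perpendicular meridian,
#' including the apex.
#'
#' @param load a \code{\link{load_case}} (constant in time).
#' @param t_eval evaluation time [s].
#' @param S a \code{\link{assemble_stiffness}} result.
#' @param kernel a \code{\link{fractional_kernel}}.
#' @param geom,material geometry and material (default from \code{S}).
#' @param n_r,n_phi surface sampling resolution.
#' @param form creep-factor form.
#' @return data.frame of class \code{"surface_field"} with columns
#'   \code{x}, \code{z}, \code{y} [m] and \code{sigma_h} [Pa];
#'   attributes \code{time}, \code{motion} (the resolved generalized
#'   displacement).
#' @export
surface_map <- function(load, t_eval, S, kernel, geom = S$geometry,
                        material = S$material, n_r = 90L, n_phi = 180L,
                        form = c("calibrated", "resolvent")) {
  stopifnot(inherits(load, "load_case"), inherits(S, "stiffness_matrix"))
  form <- match.arg(form)
  q <- drop(solve(S$K, load_rhs(load))) * creep_factor(t_eval, kernel, form)
  nd <- surface_quadrature(geom, n_r, n_phi)
  m <- rigid_motion(q[1:3], q[4:6])
  u <- rigid_displacement(cbind(nd$x, nd$y, nd$z), m)
  un <- u[, 1] * nd$nx + u[, 2] * nd$ny + u[, 3] * nd$nz
  sh <- material$E_inf * un / (3 * geom$delta * (1 - 2 * material$nu))
  out <- data.frame(x = nd$x, z = nd$z, y = nd$y, sigma_h = sh)
  class(out) <- c("surface_field", "data.frame")
  attr(out, "time") <- t_eval
  attr(out, "motion") <- q
  out
}

#' Growth factors of the peak hydrostatic stress
#'
#' Maximum-over-surface \eqn{|\sigma_h|} at each requested time,
#' divided by its value at the reference time.  By linearity of the
#' quasi-elastic stress map in the displacement, these ratios equal the
#' creep-factor ratios \eqn{c(t)/c(t_{ref})}; they are nevertheless
#' computed from actual surface maps to exercise the full pipeline.
#'
#' @param load a \code{\link{load_case}}.
#' @param times evaluation times [s].
#' @param S,kernel stiffness and kernel objects.
#' @param reference reference time [s] (default: first of \code{times}).
#' @param n_r,n_phi surface sampling resolution.
#' @param form creep-factor form.
#' @return data.frame with columns \code{t}, \code{max_abs_sigma_h}
#'   [Pa] and \code{growth} (dimensionless, 1 at the reference time).
#' @export
growth_factors <- function(load, times, S, kernel,
                           reference = times[1], n_r = 48L, n_phi = 96L,
                           form = c("calibrated", "resolvent")) {
  form <- match.arg(form)
  stopifnot(length(times) >= 1L)
  all_t <- unique(c(reference, times))
  mx <- vapply(all_t, function(tv)
    max(abs(surface_map(load, tv, S, kernel, n_r = n_r, n_phi = n_phi,
                        form = form)$sigma_h)), numeric(1))
  ref <- mx[1]
  keep <- match(times, all_t)
  data.frame(t = times, max_abs_sigma_h = mx[keep],
             growth = mx[keep] / ref)
}
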