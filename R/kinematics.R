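#' Rigid motion of the tooth root
#'
#' Small rigid-body motion of the root: a translation vector \code{u0}
#' and a rotation vector \code{theta} (linearised, components in rad).
#' The linearised theory assumes small rotations; a warning is issued
#' above 0.1 rad.
#'
#' @param u0 translation 3-vector [m].
#' @param theta rotation 3-vector [rad].
#' @return object of class \code{"rigid_motion"}.
#' @export
rigid_motion <- function(u0 = c(0, 0, 0), theta = c(0, 0, 0)) {
  stopifnot(is.numeric(u0), length(u0) == 3L,
            is.numeric(theta), length(theta) == 3L,
            all(is.finite(u0)), all(is.finite(theta)))
  if (any(abs(theta) > 0.1))
    warning("rotation angles exceed 0.1 rad; linearised kinematics suspect")
  structure(list(u0 = as.numeric(u0), theta = as.numeric(theta)),
            class = "rigid_motion")
}

#' Displacement of a material point under rigid root motion
#'
#' Linearised rigid-body displacement field
#' \deqn{u_x = u_{0x} + z\theta_y - y\theta_z,\quad
#'       u_y = u_{0y} - z\theta_x + x\theta_z,\quad
#'       u_z = u_{0z} + y\theta_x - x\theta_y,}
#' i.e. \eqn{u = u_0 + \theta \times r}.
#'
#' @param point 3-vector \code{(x, y, z)} [m] or an n-by-3 matrix.
#' @param motion a \code{\link{rigid_motion}}.
#' @return displacement 3-vector (or n-by-3 matrix) [m].
#' @export
rigid_displacement <- function(point, motion) {
  stopifnot(inherits(motion, "rigid_motion"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  u0 <- motion$u0; th <- motion$theta
  u <- cbind(u0[1] + p[, 3] * th[2] - p[, 2] * th[3],
             u0[2] - p[, 3] * th[1] + p[, 1] * th[3],
             u0[3] + p[, 2] * th[1] - p[, 1] * th[2])
  if (!is.matrix(point)) drop(u) else u
}

#' PDL strain components in the local surface frame
#'
#' For a nearly incompressible PDL of normal thickness \code{delta}, the
#' displacement of the root surface is accommodated across the layer,
#' giving the constrained strain state
#' \deqn{\varepsilon_{nn} = -u_n/\delta,\quad
#'       \gamma_{nt} = -u_t/\delta,\quad
#'       \gamma_{n\theta} = -u_\theta/\delta,}
#' with all in-plane strains zero.  \eqn{u_n, u_t, u_\theta} are the
#' projections of the rigid displacement on the local frame (inward
#' normal, generatrix tangent, circumferential tangent).  The sign
#' convention makes compression of the PDL (root moving toward the
#' socket wall) positive.  The shears are engineering shears; the tensor
#' components are half of them.
#'
#' @param x,z horizontal coordinates of the surface point [m].
#' @param motion a \code{\link{rigid_motion}}.
#' @param geom a \code{\link{root_geometry}}.
#' @return list of class \code{"strain_components"} with fields
#'   \code{eps_nn}, \code{gamma_nt}, \code{gamma_ntheta} (dimensionless)
#'   and the zero in-plane components \code{eps_tt}, \code{eps_thth},
#'   \code{gamma_ttheta}.
#' @export
strain_components <- function(x, z, motion, geom) {
  fr <- local_frame(x, z, geom)
  p <- c(x, elevation(x, z, geom), z)
  u <- rigid_displacement(p, motion)
  structure(list(
    eps_nn = -sum(u * fr$n) / geom$delta,
    gamma_nt = -sum(u * fr$t) / geom$delta,
    gamma_ntheta = -sum(u * fr$theta) / geom$delta,
    eps_tt = 0, eps_thth = 0, gamma_ttheta = 0),
    class = "strain_components")
}

#' Cartesian strain tensor of the PDL at a surface point
#'
#' Rotates the constrained local strain state (normal strain plus two
#' normal-plane shears, tensor shears = engineering/2) into the global
#' x, y, z axes.
#'
#' @inheritParams strain_components
#' @return symmetric 3-by-3 strain tensor (tensor shear convention).
#' @export
cartesian_strain_tensor <- function(x, z, motion, geom) {
  fr <- local_frame(x, z, geom)
  sc <- strain_components(x, z, motion, geom)
  ## local tensor in (n, t, theta) coordinates
  el <- matrix(c(sc$eps_nn,        sc$gamma_nt / 2,  sc$gamma_ntheta / 2,
                 sc$gamma_nt / 2,  0,                0,
                 sc$gamma_ntheta / 2, 0,             0), 3L, 3L)
  Q <- cbind(fr$n, fr$t, fr$theta)  # columns: local basis in global coords
  E <- Q %*% el %*% t(Q)
  dimnames(E) <- list(c("x", "y", "z"), c("x", "y", "z"))
  (E + t(E)) / 2
}
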