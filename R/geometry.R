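#' Elliptic-paraboloid tooth-root geometry
#'
#' Constructs the geometry of a tooth root modelled as an elliptic
#' paraboloid \eqn{y/h = ((1-e^2) x^2 + z^2)/b^2}, \eqn{0 \le y \le h},
#' together with the periodontal ligament (PDL) that surrounds it as a
#' layer of constant thickness \code{delta} measured along the surface
#' normal.  The apex of the root is at the origin; the alveolar crest is
#' the ellipse at elevation \code{h} with minor semi-axis \code{b} (along
#' z) and major semi-axis \eqn{a = b/\sqrt{1-e^2}} (along x).
#'
#' @param h root height [m].
#' @param b minor semi-axis of the crest ellipse [m].
#' @param e eccentricity of the crest ellipse, \eqn{0 \le e < 1}.
#' @param delta PDL thickness along the normal [m].
#'
#' @return An object of class \code{"root_geometry"}: a list with fields
#'   \code{h}, \code{b}, \code{e}, \code{delta} and the derived major
#'   semi-axis \code{a}.
#' @examples
#' geom <- root_geometry(h = 13.0e-3, b = 3.9e-3, e = 0.6, delta = 0.229e-3)
#' geom$a  # major semi-axis, m
#' @export
root_geometry <- function(h, b, e, delta) {
  stopifnot(is.numeric(h), is.numeric(b), is.numeric(e), is.numeric(delta),
            length(h) == 1L, length(b) == 1L, length(e) == 1L,
            length(delta) == 1L)
  if (!(h > 0)) stop("root height 'h' must be positive")
  if (!(b > 0)) stop("semi-axis 'b' must be positive")
  if (e < 0 || e >= 1) stop("eccentricity 'e' must satisfy 0 <= e < 1")
  if (!(delta > 0)) stop("PDL thickness 'delta' must be positive")
  structure(list(h = h, b = b, e = e, delta = delta,
                 a = b / sqrt(1 - e^2)),
            class = "root_geometry")
}

#' @export
print.root_geometry <- function(x, ...) {
  cat("Elliptic-paraboloid tooth root\n")
  cat(sprintf("  height h        : %.4g mm\n", 1e3 * x$h))
  cat(sprintf("  semi-axes a, b  : %.4g, %.4g mm (e = %.3g)\n",
              1e3 * x$a, 1e3 * x$b, x$e))
  cat(sprintf("  PDL thickness   : %.4g mm\n", 1e3 * x$delta))
  invisible(x)
}

#' Elevation of the root surface
#'
#' Height \eqn{y} of the root surface above the apex at horizontal
#' coordinates \eqn{(x, z)}.  The point must project inside the crest
#' ellipse so that \eqn{0 \le y \le h}.
#'
#' @param x,z horizontal coordinates [m]; vectorised.
#' @param geom a \code{\link{root_geometry}}.
#' @return elevation \eqn{y = h((1-e^2)x^2 + z^2)/b^2} [m].
#' @export
elevation <- function(x, z, geom) {
  stopifnot(inherits(geom, "root_geometry"))
  q <- (1 - geom$e^2) * x^2 + z^2
  if (any(q > geom$b^2 * (1 + 1e-12)))
    stop("point projects outside the crest ellipse")
  geom$h * q / geom$b^2
}

## rho = sqrt((1-e^2)^2 x^2 + z^2); Delta = sqrt(b^4 + 4 h^2 rho^2)/b^2.
## Delta equals the true-area stretch factor sqrt(1 + (dy/dx)^2 + (dy/dz)^2),
## and cos(alpha) = n_y = 1/Delta.
surface_rho <- function(x, z, geom) sqrt((1 - geom$e^2)^2 * x^2 + z^2)

surface_delta_factor <- function(x, z, geom) {
  sqrt(geom$b^4 + 4 * geom$h^2 * surface_rho(x, z, geom)^2) / geom$b^2
}

#' Inward unit normal of the root surface
#'
#' Unit normal at a surface point, pointing into the root (positive
#' y-component).  The PDL lies on the opposite side.
#'
#' @inheritParams elevation
#' @return numeric 3-vector \code{(n_x, n_y, n_z)} for scalar input, or a
#'   3-column matrix for vector input.
#' @export
unit_normal <- function(x, z, geom) {
  stopifnot(inherits(geom, "root_geometry"))
  D <- surface_delta_factor(x, z, geom)
  n <- cbind(-2 * (1 - geom$e^2) * geom$h * x / (geom$b^2 * D),
             1 / D,
             -2 * geom$h * z / (geom$b^2 * D))
  colnames(n) <- c("x", "y", "z")
  if (length(x) == 1L && length(z) == 1L) drop(n) else n
}

#' Local orthonormal frame on the root surface
#'
#' Right-handed frame at a surface point: the inward unit normal
#' \code{n}, the unit tangent \code{t} along the generatrix (meridian,
#' increasing y), and the circumferential unit tangent \code{theta}.
#' Also returns \code{cos_alpha = n_y}, \code{sin_alpha}, and the
#' direction cosines \code{H}, \code{G} of the in-plane (horizontal)
#' component of the normal: \eqn{n_x = -H \sin\alpha},
#' \eqn{n_z = -G \sin\alpha}, \eqn{H^2 + G^2 = 1}.
#'
#' At the apex the horizontal direction of the meridian is undefined; by
#' convention the frame degenerates to the coordinate axes
#' (\code{t = x}-axis, \code{theta = z}-axis) with \code{H = 1, G = 0}.
#'
#' @inheritParams elevation
#' @return a list of class \code{"local_frame"} with fields \code{n},
#'   \code{t}, \code{theta} (unit 3-vectors), \code{cos_alpha},
#'   \code{sin_alpha}, \code{H}, \code{G}.
#' @export
local_frame <- function(x, z, geom) {
  stopifnot(inherits(geom, "root_geometry"), length(x) == 1L,
            length(z) == 1L)
  n <- unname(unit_normal(x, z, geom))
  rho <- surface_rho(x, z, geom)
  if (rho == 0) {
    H <- 1; G <- 0
    tv <- c(1, 0, 0); th <- c(0, 0, 1)
  } else {
    H <- x * (1 - geom$e^2) / rho
    G <- z / rho
    ## meridian tangent: horizontal direction (H, 0, G) tilted up the slope
    ca <- n[2]; sa <- sqrt(max(0, 1 - ca^2))
    tv <- c(H * ca, sa, G * ca)
    tv <- tv / sqrt(sum(tv^2))
    th <- c(n[2] * tv[3] - n[3] * tv[2],
            n[3] * tv[1] - n[1] * tv[3],
            n[1] * tv[2] - n[2] * tv[1])  # theta = n x t
    th <- th / sqrt(sum(th^2))
  }
  structure(list(n = n, t = tv, theta = th,
                 cos_alpha = n[2],
                 sin_alpha = sqrt(max(0, 1 - n[2]^2)),
                 H = H, G = G),
            class = "local_frame")
}

#' Partner point on the outer PDL surface
#'
#' Maps a root-surface point to its partner on the outer wall of the
#' PDL, a distance \code{delta} away along the surface normal on the PDL
#' side (i.e. shifted opposite to the inward normal).  The resulting
#' surface satisfies the offset-paraboloid equation
#' \eqn{F_1(x,y,z) = (y + n_y\delta)/h - ((1-e^2)(x + n_x\delta)^2 +
#' (z + n_z\delta)^2)/b^2 = 0} exactly.
#'
#' @inheritParams elevation
#' @param delta offset distance [m]; defaults to the PDL thickness of
#'   \code{geom}.
#' @return numeric 3-vector \code{(x, y, z)} of the offset point.
#' @export
offset_point <- function(x, z, geom, delta = geom$delta) {
  stopifnot(inherits(geom, "root_geometry"), length(x) == 1L,
            length(z) == 1L)
  p <- c(x, elevation(x, z, geom), z)
  n <- unit_normal(x, z, geom)
  unname(p - delta * n[c(1, 2, 3)])
}

#' Quadrature rule on the lateral root surface
#'
#' Tensor-product quadrature over the root surface parameterised by
#' \eqn{x = a\, r\cos\varphi,\; z = b\, r\sin\varphi,\; y = h r^2} with
#' \eqn{r \in (0, 1]}, \eqn{\varphi \in [0, 2\pi)}: Gauss--Legendre in
#' \eqn{r} crossed with the trapezoid rule in the periodic angle.  The
#' apex \eqn{r = 0} is never a node.  Weights include the parameter-space
#' Jacobian \eqn{a b r}; the column \code{dS} additionally carries the
#' true-area stretch factor \eqn{\Delta} so that
#' \code{sum(w * dS * f)} approximates \eqn{\iint f\, dF} over the true
#' surface and \code{sum(w * f)} the projected (\eqn{dx\,dz}) integral.
#'
#' @param geom a \code{\link{root_geometry}}.
#' @param n_r,n_phi numbers of radial / angular nodes.
#' @return a data.frame with columns \code{x}, \code{z}, \code{y},
#'   \code{r}, \code{phi}, \code{w} (projected-element weight, m^2),
#'   \code{dS} (true/projected area ratio \eqn{\Delta}), plus frame
#'   columns \code{nx}, \code{ny}, \code{nz}, \code{cos_alpha},
#'   \code{sin_alpha}, \code{H}, \code{G}.
#' @export
surface_quadrature <- function(geom, n_r = 256L, n_phi = 256L) {
  stopifnot(inherits(geom, "root_geometry"), n_r >= 2L, n_phi >= 4L)
  gl <- pracma::gaussLegendre(n_r, 0, 1)
  phi <- (seq_len(n_phi) - 1L) * 2 * pi / n_phi
  wphi <- 2 * pi / n_phi
  r <- rep(gl$x, times = n_phi)
  ph <- rep(phi, each = n_r)
  wr <- rep(gl$w, times = n_phi)
  x <- geom$a * r * cos(ph)
  z <- geom$b * r * sin(ph)
  y <- geom$h * r^2
  rho <- surface_rho(x, z, geom)
  D <- surface_delta_factor(x, z, geom)
  out <- data.frame(
    x = x, z = z, y = y, r = r, phi = ph,
    w = wr * wphi * geom$a * geom$b * r,
    dS = D,
    nx = -2 * (1 - geom$e^2) * geom$h * x / (geom$b^2 * D),
    ny = 1 / D,
    nz = -2 * geom$h * z / (geom$b^2 * D),
    cos_alpha = 1 / D,
    H = x * (1 - geom$e^2) / rho,
    G = z / rho)
  out$sin_alpha <- sqrt(pmax(0, 1 - out$cos_alpha^2))
  out
}

#' Integrate a scalar field over the root surface
#'
#' Approximates \eqn{\iint_F f\, dF} over the lateral paraboloid surface
#' (\eqn{0 \le y \le h}).  The field is a function of the quadrature
#' node table (see \code{\link{surface_quadrature}}) returning one value
#' per node, so it can use the coordinates, the normal components or the
#' direction cosines.  A Richardson-style check doubles the resolution
#' and warns if the two estimates disagree beyond \code{tol}.
#'
#' @param f function(nodes) -> numeric vector, one value per node.
#' @param geom a \code{\link{root_geometry}}.
#' @param n_r,n_phi base quadrature resolution.
#' @param dF area-element convention: \code{"true"} (default) uses the
#'   actual surface element \eqn{\Delta\, dx\, dz}; \code{"projected"}
#'   uses \eqn{dx\, dz}.
#' @param check if TRUE (default), re-evaluate at doubled resolution and
#'   warn when the relative change exceeds \code{tol}; the refined value
#'   is returned.
#' @param tol relative convergence tolerance for the doubling check.
#' @return scalar value of the integral.
#' @examples
#' geom <- root_geometry(13e-3, 3.9e-3, 0.6, 0.229e-3)
#' # projected-area identity: integral of cos(alpha) over the true surface
#' surface_integrate(function(nd) nd$cos_alpha, geom)  # == pi * a * b
#' @export
surface_integrate <- function(f, geom, n_r = 256L, n_phi = 256L,
                              dF = c("true", "projected"),
                              check = TRUE, tol = 1e-8) {
  dF <- match.arg(dF)
  one <- function(nr, np) {
    nd <- surface_quadrature(geom, nr, np)
    w <- if (dF == "true") nd$w * nd$dS else nd$w
    sum(w * f(nd))
  }
  v1 <- one(n_r, n_phi)
  if (!check) return(v1)
  v2 <- one(2L * n_r, 2L * n_phi)
  ref <- max(abs(v1), abs(v2))
  if (ref > 0 && abs(v2 - v1) / ref > tol)
    warning(sprintf(
      "surface integral not converged to %g on doubling (rel. change %g)",
      tol, abs(v2 - v1) / ref))
  v2
}
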