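#' Spherical to Cartesian coordinates (left-handed, Y-up convention)
#'
#' Converts a spherical coordinate to Cartesian axes under the left-handed,
#' Y-up convention used throughout the model: positive X is right, positive
#' Y is up, positive Z is forward.  \code{theta} is the angle from the
#' X-axis towards the Z-axis and \code{phi} the angle from the Y-axis
#' towards the Z-axis, both in degrees:
#' \deqn{x = \rho\cos\theta\sin\phi,\quad y = \rho\cos\phi,\quad
#'       z = \rho\sin\theta\sin\phi.}
#'
#' @param rho Radial length (millimetres, or dimensionless for directions);
#'   must be non-negative.
#' @param theta Angle from the X-axis to the Z-axis, degrees.
#' @param phi Angle from the Y-axis to the Z-axis, degrees.
#' @return Numeric vector \code{c(x, y, z)}.  Vectorised over its
#'   arguments: with inputs of length n, a n x 3 matrix.
#' @examples
#' spherical_to_cartesian(1, 0, 90)   # unit X
#' spherical_to_cartesian(2, 90, 90)  # 2 along Z
#' @export
spherical_to_cartesian <- function(rho, theta, phi) {
  stopifnot(is.numeric(rho), is.numeric(theta), is.numeric(phi),
            all(is.finite(rho)), all(rho >= 0))
  th <- theta * pi / 180
  ph <- phi * pi / 180
  out <- cbind(x = rho * cos(th) * sin(ph),
               y = rho * cos(ph),
               z = rho * sin(th) * sin(ph))
  if (nrow(out) == 1L) drop(out) else out
}

## --- small linear-algebra helpers (3-vectors, 3x3 rotations) -------------

vec3 <- function(x, y, z) c(x = x, y = y, z = z)

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  stopifnot(n > 0)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by \code{angle_deg} degrees about the (not
#' necessarily unit) 3-vector \code{axis}.
#'
#' @param axis length-3 numeric, the rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle_deg) {
  u <- vunit(axis)
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Rotation taking unit vector `a` onto unit vector `b`; for the antiparallel
# case a deterministic perpendicular axis is chosen so results are
# reproducible.
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  c_ <- sum(a * b)
  v <- vcross(a, b)
  s <- vnorm(v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- vcross(a, c(1, 0, 0))
    if (vnorm(p) < 1e-6) p <- vcross(a, c(0, 1, 0))
    return(rotation_about(p, 180))
  }
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# wrap an angle in degrees to [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360
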