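# Low-level vector geometry shared by all analysis modules.
# All angles are in degrees; coordinates in Angstrom.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex b between points a and c
#'
#' @param a,b,c numeric 3-vectors (Angstrom).
#' @return Angle in degrees in \[0, 180\].
#' @export
vec_angle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  n1 <- vnorm(v1)
  n2 <- vnorm(v2)
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("degenerate angle: coincident points", call. = FALSE)
  ct <- sum(v1 * v2) / (n1 * n2)
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

#' Signed dihedral angle of four points
#'
#' Standard right-hand (IUPAC) convention: a cis arrangement gives 0 degrees,
#' trans gives 180 degrees. The result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return Dihedral in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("undefined dihedral: consecutive points coincide", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined dihedral: three consecutive points are collinear",
         call. = FALSE)
  m1 <- cross3(n1, unit(b2))
  ang <- -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

# Wrap an angle (degrees) into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[!is.na(y) & y == -180] <- 180
  y
}

#' Circular mean of angles in degrees
#'
#' Angles are averaged as unit vectors so values straddling the +/-180
#' discontinuity are handled correctly. NA values are dropped.
#'
#' @param x numeric vector of angles, degrees.
#' @return Mean angle in (-180, 180], or NA if no finite values.
#' @export
circular_mean <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  r <- deg2rad(x)
  wrap180(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Circular standard deviation of angles in degrees
#'
#' Mardia's circular SD, sqrt(-2 log R), mapped to degrees.
#'
#' @param x numeric vector of angles, degrees.
#' @return Circular SD (degrees), 0 for a single value, NA if empty.
#' @export
circular_sd <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  r <- deg2rad(x)
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  if (R >= 1 - 1e-12) return(0)
  rad2deg(sqrt(-2 * log(R)))
}

# Circular difference a - b wrapped into (-180, 180]
circular_diff <- function(a, b) wrap180(a - b)

# Rotation matrix for angle theta (degrees) about unit axis (Rodrigues)
rotation_matrix <- function(axis, theta) {
  u <- unit(axis)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# NeRF placement: position of atom D given A-B-C, bond |C-D|, angle B-C-D,
# torsion A-B-C-D (degrees). Used by the internal-coordinate builder.
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- cross3(b - a, bc)
  if (vnorm(n) < 1e-9)
    stop("cannot place atom: reference frame is collinear", call. = FALSE)
  n <- unit(n)
  m <- cross3(n, bc)
  th <- deg2rad(180 - angle)
  ph <- deg2rad(torsion)
  d_local <- bond * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}
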