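#' Wrap angles into [-180, 180)
#'
#' The canonical representative of the periodic boundary keeps -180 and maps
#' +180 to -180. Idempotent.
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in degrees.
#' @export
#' @examples
#' wrapAngle(c(180, -180, 360, 190))
wrapAngle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Circular distance between two angles
#'
#' Distance on the circle: |a - b| if below 180 degrees, otherwise
#' 360 - |a - b|; always in [0, 180]. Inputs are wrapped first, so any
#' finite angle is accepted.
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return numeric vector of distances in [0, 180] degrees.
#' @export
#' @examples
#' circularDelta(170, -170)  # 20
circularDelta <- function(a, b) {
  d <- abs(wrapAngle(a) - wrapAngle(b))
  ifelse(d < 180, d, 360 - d)
}

#' Torsion angle of four points
#'
#' IUPAC-signed dihedral of the p1-p2-p3-p4 chain (clockwise positive when
#' viewed from p2 towards p3): the eclipsed (cis) arrangement gives 0 and
#' the antiperiplanar (trans) arrangement gives -180 after wrapping into
#' [-180, 180).
#'
#' @param p1,p2,p3,p4 numeric xyz coordinates (length 3), Angstrom.
#' @return angle in degrees in [-180, 180).
#' @export
#' @examples
#' computeDihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 1))
computeDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("zero-length bond vector in dihedral computation")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("collinear points in dihedral computation")
  b2hat <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2hat), sum(n1 * n2)) * 180 / pi
  wrapAngle(ang)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
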