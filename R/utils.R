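#' Wrap angles into (-180, 180]
#'
#' Torsion angles and torsion differences are reported on the IUPAC branch
#' (-180, 180] throughout the package; this is the single wrapping rule.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped into (-180, 180].
#' @export
wrapAngle <- function(x) {
  w <- x - 360 * round(x / 360)
  # round() sends exactly -180 to -180; move it to the +180 branch end
  w[!is.na(w) & w <= -180] <- w[!is.na(w) & w <= -180] + 360
  w
}

# Rodrigues rotation matrix for a unit axis and angle in degrees
.rotationMatrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single finite positive number", name))
  invisible(x)
}

.assertScalarNonNegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single finite non-negative number", name))
  invisible(x)
}
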