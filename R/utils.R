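#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle_deg`
#' degrees about `axis`.
#'
#' @param axis numeric length-3 axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis has zero length")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice; deterministic, no RNG.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Unwrap an angle series (degrees)
#'
#' Removes +-360 degree branch jumps so that consecutive differences are
#' within (-180, 180]; required before averaging azimuth series.
#'
#' @param x angle series in degrees.
#' @return unwrapped series, same length.
#' @keywords internal
unwrap_degrees <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jump <- round(d / 360)
  x - c(0, cumsum(jump)) * 360
}

#' Trapezoidal integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Run an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
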