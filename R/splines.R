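# B-spline bases evaluated by the Cox-de Boor recursion. The df = 3 basis
# used in the differential expression designs mirrors the classic intercept-
# free cubic basis with no interior knots on [0, 96]; the P-spline basis used
# in trajectory clustering is a richer cubic basis with equally spaced
# interior knots plus a second-difference coefficient penalty.

#' Evaluate a B-spline basis by the Cox-de Boor recursion
#'
#' @param x evaluation points; must lie within the boundary knots.
#' @param knots full (clamped) knot vector, non-decreasing, with the boundary
#'   knots repeated `degree + 1` times.
#' @param degree spline degree (3 = cubic).
#' @return matrix, `length(x)` x (number of basis functions).
#' @export
bsplineDesign <- function(x, knots, degree = 3L) {
  nb0 <- length(knots) - 1L
  m <- length(knots) - degree - 1L
  if (m < 1L) stop("knot vector too short for the requested degree")
  lo <- knots[degree + 1L]
  hi <- knots[length(knots) - degree]
  if (any(x < lo - 1e-12 | x > hi + 1e-12))
    stop(sprintf("evaluation points must lie in [%g, %g]", lo, hi))
  # order-1 (degree-0) indicators; the rightmost non-empty interval is closed
  B <- matrix(0, length(x), nb0)
  last <- max(which(knots < hi))           # index of last non-empty interval
  for (j in seq_len(nb0)) {
    if (knots[j + 1L] > knots[j]) {
      inb <- x >= knots[j] & x < knots[j + 1L]
      if (j == last) inb <- inb | (x >= hi)
      B[inb, j] <- 1
    }
  }
  for (d in seq_len(degree)) {
    nb <- ncol(B) - 1L
    Bn <- matrix(0, length(x), nb)
    for (j in seq_len(nb)) {
      d1 <- knots[j + d] - knots[j]
      d2 <- knots[j + d + 1L] - knots[j + 1L]
      a <- if (d1 > 0) (x - knots[j]) / d1 else 0
      b <- if (d2 > 0) (knots[j + d + 1L] - x) / d2 else 0
      Bn[, j] <- a * B[, j] + b * B[, j + 1L]
    }
    B <- Bn
  }
  B
}

#' Cubic spline design for time-course differential expression
#'
#' Three-column cubic B-spline basis (df = 3, no interior knots, boundary
#' knots at 0 and 96 h, intercept column excluded) evaluated at the sample
#' times, with controls coded as time 0. At the left boundary every column is
#' 0; at the right boundary the basis is (0, 0, 1).
#'
#' @param times sample times in hours, within `boundary`.
#' @param boundary boundary knots (default `c(0, 96)`).
#' @return list with `basis` (times x 3 matrix), `knots`, `boundary`, `times`
#'   and `df`.
#' @export
buildSplineBasis <- function(times, boundary = c(0, 96)) {
  if (any(times < boundary[1L] | times > boundary[2L]))
    stop(sprintf("times must lie within [%g, %g]", boundary[1L], boundary[2L]))
  knots <- c(rep(boundary[1L], 4L), rep(boundary[2L], 4L))
  B <- bsplineDesign(times, knots, 3L)[, -1L, drop = FALSE]  # drop intercept
  colnames(B) <- paste0("bs", 1:3)
  list(basis = B, knots = knots, boundary = boundary, times = times, df = 3L)
}

#' Rich cubic B-spline basis for P-spline trajectory fits
#'
#' @param times evaluation times.
#' @param nInterior number of equally spaced interior knots (default 5).
#' @param boundary boundary knots (default the range of `times`).
#' @return list with `basis` (including the intercept span), `knots` and the
#'   second-difference penalty matrix `penalty`.
#' @export
psplineBasis <- function(times, nInterior = 5L, boundary = range(times)) {
  interior <- seq(boundary[1L], boundary[2L],
                  length.out = nInterior + 2L)[-c(1L, nInterior + 2L)]
  knots <- c(rep(boundary[1L], 4L), interior, rep(boundary[2L], 4L))
  B <- bsplineDesign(times, knots, 3L)
  m <- ncol(B)
  D <- diff(diag(m), differences = 2L)
  list(basis = B, knots = knots, penalty = crossprod(D))
}
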