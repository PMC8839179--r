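#' Implicit conic coefficients of an ellipse
#'
#' Coefficients `(a, b, c, d, e, f)` of
#' `a u^2 + b v^2 + c uv + d u + e v + f = 0`, stored normalized to unit
#' Euclidean norm with `a >= 0` (or `b > 0` when `a = 0`) so the scale
#' ambiguity of implicit conics is fixed.  The discriminant `c^2 - 4ab`
#' must be negative (a genuine ellipse).
#'
#' @param coeffs numeric vector of length 6, `(a, b, c, d, e, f)`.
#' @return an object of class `"ellipse_coefficients"` (a named numeric
#'   vector).
#' @export
ellipse_coefficients <- function(coeffs) {
  stopifnot(length(coeffs) == 6, all(is.finite(coeffs)))
  v <- as.numeric(coeffs)
  if (v[3]^2 - 4 * v[1] * v[2] >= 0) stop("degenerate conic: not an ellipse")
  v <- v / sqrt(sum(v^2))
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  names(v) <- c("a", "b", "c", "d", "e", "f")
  structure(v, class = "ellipse_coefficients")
}

#' @export
print.ellipse_coefficients <- function(x, ...) {
  cat("<ellipse_coefficients> a u^2 + b v^2 + c uv + d u + e v + f = 0\n")
  print(round(unclass(x), 8))
  invisible(x)
}

## Evaluate the implicit conic at points (rows of m).
conic_eval <- function(co, m) {
  co[1] * m[, 1]^2 + co[2] * m[, 2]^2 + co[3] * m[, 1] * m[, 2] +
    co[4] * m[, 1] + co[5] * m[, 2] + co[6]
}

#' Direct least-squares ellipse fit
#'
#' Fits the implicit conic to edge points by the ellipse-specific direct
#' least-squares method (the numerically stable partitioned eigen-variant):
#' the algebraic error is minimized subject to the ellipse constraint
#' `4ab - c^2 = 1`, so the result is guaranteed to be an ellipse.  Points
#' are centred and scaled internally for conditioning.
#'
#' @param points an [image_points()] set (or N x 2 matrix), N >= 5 and not
#'   collinear.
#' @return an [ellipse_coefficients()] vector.
#' @examples
#' th <- 2 * pi * (0:7) / 8
#' fit_ellipse(cbind(2 * cos(th), 2 * sin(th)))  # u^2 + v^2 - 4 = 0
#' @export
fit_ellipse <- function(points) {
  m <- as.matrix(points)
  if (nrow(m) < 5) stop("underdetermined: at least 5 points are required")
  mu <- colMeans(m)
  sc <- mean(sqrt(rowSums(sweep(m, 2, mu)^2)))
  if (sc < .Machine$double.eps) stop("degenerate conic: coincident points")
  x <- (m[, 1] - mu[1]) / sc
  y <- (m[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("underdetermined: points are collinear"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)   # apply inv(C1)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  ok <- which(4 * vec[1, ] * vec[3, ] - vec[2, ]^2 > 0)
  if (length(ok) == 0) stop("degenerate conic: best fit is not an ellipse")
  a1 <- vec[, ok[1]]
  co <- c(a1, as.vector(Tm %*% a1))   # A x^2 + B xy + C y^2 + D x + E y + F
  ## undo the normalization x = (u - mu1)/sc, y = (v - mu2)/sc
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  a <- A / sc^2
  b <- C / sc^2
  cc <- B / sc^2
  d <- (-2 * A * mu[1] - B * mu[2]) / sc^2 + D / sc
  e <- (-2 * C * mu[2] - B * mu[1]) / sc^2 + E / sc
  f <- (A * mu[1]^2 + B * mu[1] * mu[2] + C * mu[2]^2) / sc^2 -
    (D * mu[1] + E * mu[2]) / sc + F
  ellipse_coefficients(c(a, b, cc, d, e, f))
}

#' Convert implicit conic coefficients to geometric ellipse parameters
#'
#' @param coeffs an [ellipse_coefficients()] vector.
#' @return an object of class `"ellipse_geometric"`: list with `center`
#'   (2-vector, mm), `semi_major`, `semi_minor` (mm) and `tilt` (radians in
#'   `[0, pi)`, angle of the major axis).
#' @export
ellipse_to_geometric <- function(coeffs) {
  co <- unclass(ellipse_coefficients(coeffs))
  A2 <- matrix(c(co[1], co[3] / 2, co[3] / 2, co[2]), 2, 2)
  center <- as.vector(solve(2 * A2, -co[4:5]))
  mu <- conic_eval(co, matrix(center, 1, 2))
  ev <- eigen(A2, symmetric = TRUE)   # eigenvalues descending
  ax2 <- -mu / ev$values
  if (any(ax2 <= 0)) stop("degenerate conic: not a real ellipse")
  ## smaller eigenvalue -> longer axis
  semi <- sqrt(ax2)
  major_vec <- ev$vectors[, which.min(ev$values)]
  tilt <- atan2(major_vec[2], major_vec[1]) %% pi
  structure(list(center = center,
                 semi_major = max(semi), semi_minor = min(semi),
                 tilt = tilt),
            class = "ellipse_geometric")
}

#' @export
print.ellipse_geometric <- function(x, ...) {
  cat(sprintf("<ellipse_geometric> center (%.5f, %.5f) mm, axes (%.5f, %.5f) mm, tilt %.5f rad\n",
              x$center[1], x$center[2], x$semi_major, x$semi_minor, x$tilt))
  invisible(x)
}

#' @rdname ellipse_to_geometric
#' @param geom an `"ellipse_geometric"` object (list with `center`,
#'   `semi_major`, `semi_minor`, `tilt`).
#' @export
geometric_to_coeffs <- function(geom) {
  stopifnot(geom$semi_major >= geom$semi_minor, geom$semi_minor > 0)
  ct <- cos(geom$tilt); st <- sin(geom$tilt)
  ia2 <- 1 / geom$semi_major^2; ib2 <- 1 / geom$semi_minor^2
  a <- ia2 * ct^2 + ib2 * st^2
  b <- ia2 * st^2 + ib2 * ct^2
  cc <- 2 * ct * st * (ia2 - ib2)
  cx <- geom$center[1]; cy <- geom$center[2]
  d <- -2 * a * cx - cc * cy
  e <- -2 * b * cy - cc * cx
  f <- a * cx^2 + b * cy^2 + cc * cx * cy - 1
  ellipse_coefficients(c(a, b, cc, d, e, f))
}

#' Sample an ellipse at equal parametric angles
#'
#' Returns the `N` points at parameter angles `2 pi k / N` (k = 0 ... N-1)
#' of the ellipse's parametric form (parametric angle, not polar angle
#' about the centre).
#'
#' @param geom an `"ellipse_geometric"` object.
#' @param n number of samples (>= 4, the solver validity bound).
#' @return an [image_points()] set, in parameter order.
#' @export
sample_equal_angle <- function(geom, n) {
  if (n < 4) stop("at least 4 points are required for a valid solve")
  th <- 2 * pi * (seq_len(n) - 1L) / n
  ct <- cos(geom$tilt); st <- sin(geom$tilt)
  xa <- geom$semi_major * cos(th)
  yb <- geom$semi_minor * sin(th)
  image_points(cbind(geom$center[1] + ct * xa - st * yb,
                     geom$center[2] + st * xa + ct * yb))
}
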