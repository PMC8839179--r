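# Shared fixtures and independent oracles, built in code.

unitv <- function(v) v / sqrt(sum(v^2))

cross_prod <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])

rand_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## A random circle comfortably in front of the camera, facing roughly
## toward it.
rand_scene <- function(f0 = 16, radius = NULL) {
  radius <- radius %||% runif(1, 3, 12)
  z <- runif(1, 150, 500)
  center <- c(runif(2, -60, 60), z)
  normal <- unitv(unitv(-center / z) * 3 + rnorm(3, 0, 0.5))
  if (normal[3] > 0) normal <- -normal
  list(circle = circle3d(center, normal, radius), camera = camera(f0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent oracle: radius of the circle cut from the standardized cone
## l1 x^2 + l2 y^2 - |l3| z^2 = 0 by the unit-offset tilted section plane
## z = m x + 1 with m = sqrt((l1 - l2) / (l2 + |l3|)).  The intersection is
## sampled densely, a circle centre is recovered by linear least squares
## (points equidistant from the centre), and the radius is the mean
## distance; circularity is asserted as a side effect.
section_radius_oracle <- function(lambda, n = 10000) {
  l1 <- abs(lambda[1]); l2 <- abs(lambda[2]); l3 <- abs(lambda[3])
  m <- sqrt((l1 - l2) / (l2 + l3))
  qa <- l1 - l3 * m^2
  ## feasible x range: qa x^2 - 2 l3 m x - l3 <= 0
  disc <- sqrt((2 * l3 * m)^2 + 4 * qa * l3)
  xr <- sort(c((2 * l3 * m - disc) / (2 * qa), (2 * l3 * m + disc) / (2 * qa)))
  x <- seq(xr[1] + 1e-9 * diff(xr), xr[2] - 1e-9 * diff(xr), length.out = n %/% 2)
  z <- m * x + 1
  y2 <- (l3 * z^2 - l1 * x^2) / l2
  y2[y2 < 0] <- 0
  pts <- rbind(cbind(x, sqrt(y2), z), cbind(rev(x), -sqrt(rev(y2)), rev(z)))
  ## flatten onto the best-fit plane (the centre is only determined within
  ## it), then the standard linear circle fit in 2D
  c0 <- colMeans(pts)
  ctr <- sweep(pts, 2, c0)
  V <- svd(ctr)$v
  xy <- ctr %*% V[, 1:2]
  A <- cbind(2 * xy, -1)
  sol <- qr.solve(A, rowSums(xy^2))
  d <- sqrt(rowSums(sweep(xy, 2, sol[1:2])^2))
  stopifnot(max(d) - min(d) < 1e-6 * mean(d))   # the section really is a circle
  mean(d)
}

## Independent line-plane intersection via a generic linear solve:
## point = o + t d on plane {x : n . x = n . p0}.
line_plane_oracle <- function(o, d, p0, n) {
  t <- sum(n * (p0 - o)) / sum(n * d)
  list(point = o + t * d, t = t)
}

## Reference values printed in the benchmark table of mean errors
## (traditional closed form vs proposed fit), used by the acceptance suite.
ref_means <- list(
  snr = c(100, 90, 80, 70, 60, 50, 40),
  closed_center = c(0.020479419, 0.05156101, 0.1989628, 0.53597785,
                    1.49148405, 7.1802945, 37.409125),
  closed_normal = c(0.03141138, 0.07179895, 0.2374018, 0.6931265,
                    2.7898965, 9.6292235, 24.113495),
  fit_center = c(0.020932095, 0.056576385, 0.2159454, 0.52002465,
                 1.5883833, 6.296056, 22.92037),
  fit_normal = c(0.031870895, 0.076987605, 0.2661669, 0.7130258,
                 2.783796, 8.1799965, 18.808205))
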