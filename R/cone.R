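#' Build the back-projection cone of an image ellipse
#'
#' Substituting the pinhole relation `u = f0 x / z`, `v = f0 y / z` into the
#' image conic `a u^2 + b v^2 + c uv + d u + e v + f = 0` gives the quadric
#' cone `A x^2 + B y^2 + C xy + D xz + E yz + F z^2 = 0` with
#' `A = a f0^2, B = b f0^2, C = c f0^2, D = d f0, E = e f0, F = f`.  The
#' cone has its apex at the optical centre and contains every space circle
#' consistent with the image.  Coefficients must be expressed in
#' principal-point-centred image coordinates.
#'
#' @param coeffs an [ellipse_coefficients()] vector.
#' @param camera a [camera()].
#' @return an object of class `"cone_quadric"`: list with the six
#'   coefficients `A...F` and the symmetric matrix `Q`.
#' @export
build_cone <- function(coeffs, camera) {
  co <- unclass(ellipse_coefficients(coeffs))
  stopifnot(inherits(camera, "camera"))
  f0 <- camera$focal_length_mm
  A <- co[1] * f0^2; B <- co[2] * f0^2; C <- co[3] * f0^2
  D <- co[4] * f0; E <- co[5] * f0; F <- co[6]
  Q <- matrix(c(A, C / 2, D / 2,
                C / 2, B, E / 2,
                D / 2, E / 2, F), 3, 3)
  structure(list(A = unname(A), B = unname(B), C = unname(C),
                 D = unname(D), E = unname(E), F = unname(F), Q = unname(Q)),
            class = "cone_quadric")
}

#' @export
print.cone_quadric <- function(x, ...) {
  cat("<cone_quadric> Q =\n"); print(round(x$Q, 8)); invisible(x)
}

#' Standardize the cone quadratic form
#'
#' Eigendecomposition of `Q` into the rotated frame in which the cone is
#' axis-aligned: `lambda1 x'^2 + lambda2 y'^2 + lambda3 z'^2 = 0`.  `Q` is
#' sign-normalized so that two eigenvalues are positive; columns are
#' ordered so `lambda1 >= lambda2 > 0 > lambda3`, `e3` (the cone axis) has
#' positive z-component so the cone opens into the camera's forward
#' half-space, and `e1 = e2 x e3` forces `det(P) = +1`.
#'
#' @param cone a `"cone_quadric"`.
#' @return an object of class `"cone_frame"`: list with `lambda`
#'   (`c(lambda1, lambda2, lambda3)`), the rotation `P_matrix` (columns
#'   `e1, e2, e3`) and `axis_scales` `(kx, ky, kz)` (with the free constant
#'   rho fixed to 1; only eigenvalue ratios matter downstream).
#' @export
standardize_cone <- function(cone) {
  stopifnot(inherits(cone, "cone_quadric"))
  Q <- cone$Q
  nq <- max(abs(Q))
  ev <- eigen(Q, symmetric = TRUE)
  if (any(abs(ev$values) < 1e-12 * nq) ||
      length(unique(sign(ev$values))) == 1)
    stop("not a real cone: eigenvalues do not have mixed signature")
  if (sum(ev$values > 0) == 1) {          # conic scale sign: flip Q
    ev$values <- -ev$values
  }
  pos <- which(ev$values > 0)
  neg <- which(ev$values < 0)
  pos <- pos[order(-ev$values[pos])]       # lambda1 >= lambda2
  l <- c(ev$values[pos], ev$values[neg])
  e3 <- ev$vectors[, neg]
  if (e3[3] < 0 || (e3[3] == 0 && e3[1] < 0)) e3 <- -e3
  e2 <- ev$vectors[, pos[2]]
  i <- which.max(abs(e2))
  if (e2[i] < 0) e2 <- -e2                 # deterministic sign
  e1 <- cross3(e2, e3)
  structure(list(lambda = unname(l),
                 P_matrix = unname(cbind(e1, e2, e3)),
                 axis_scales = unname(sqrt(1 / abs(l)))),
            class = "cone_frame")
}

#' @export
print.cone_frame <- function(x, ...) {
  cat("<cone_frame> lambda =", signif(x$lambda, 8), "\n")
  cat("P =\n"); print(round(x$P_matrix, 6)); invisible(x)
}

#' Radius of the unit-offset circular section of the cone
#'
#' The plane tilted so as to cut the standardized cone in a circle, and
#' translated to unit offset along the cone axis, intersects it in a circle
#' of radius
#' `r = (1/|l2|) sqrt(|l1| |l3| (|l2| + |l3|) / (|l1| + |l3|))`.
#' The expression is 0-homogeneous in the eigenvalues.
#'
#' @param frame a `"cone_frame"`.
#' @return the section radius `r` (same units as the offset, i.e. mm per
#'   unit offset).
#' @export
small_circle_radius <- function(frame) {
  stopifnot(inherits(frame, "cone_frame"))
  al <- abs(frame$lambda)
  (1 / al[2]) * sqrt(al[1] * al[3] * (al[2] + al[3]) / (al[1] + al[3]))
}

#' Closed-form circle pose from the image conic
#'
#' The classical two-fold solution: standardize the back-projection cone,
#' compute the unit-offset section radius `r`, scale by `S = R / r`, and
#' map the two admissible section planes back to the camera frame.  Both
#' solutions are returned, normals folded to the camera-facing hemisphere
#' (negative z-component), with the reprojection RMS of each (Sampson
#' distance of reprojected edge samples to the input conic).
#'
#' When the two largest eigenvalues coincide to relative `1e-10` (a
#' fronto-parallel circle) the square-root gap terms are clamped to zero
#' and the two solutions merge.
#'
#' @param coeffs an [ellipse_coefficients()] vector
#'   (principal-point-centred coordinates).
#' @param camera a [camera()].
#' @param radius circle radius `R` in mm.
#' @return an object of class `"circle_pair"`: list with `solutions` (two
#'   [circle3d()]s), `small_radius_r`, `scale_S`, `reprojection_rms`
#'   (per solution), and the `frame` used.
#' @examples
#' cam <- camera(16)
#' ci <- circle3d(c(0, 0, 100), c(0, 0, -1), 10)
#' co <- fit_ellipse(project_circle(ci, cam, 16))
#' solve_closed_form(co, cam, 10)
#' @export
solve_closed_form <- function(coeffs, camera, radius) {
  stopifnot(radius > 0)
  co <- ellipse_coefficients(coeffs)
  frame <- standardize_cone(build_cone(co, camera))
  al <- abs(frame$lambda)
  r <- small_circle_radius(frame)
  gap <- if ((al[1] - al[2]) / al[1] < 1e-10) 0 else al[1] - al[2]
  xo <- r * sqrt(al[3] * gap / (al[1] * (al[1] + al[3])))
  zo <- r * sqrt(al[1] * (al[2] + al[3]) / (al[3] * (al[1] + al[3])))
  vx <- sqrt(gap / (al[1] + al[3]))
  vz <- -sqrt((al[2] + al[3]) / (al[1] + al[3]))
  S <- radius / r
  P <- frame$P_matrix
  sols <- lapply(c(1, -1), function(s) {
    center <- S * as.vector(P %*% c(s * xo, 0, zo))
    normal <- as.vector(P %*% c(s * vx, 0, vz))
    flipped <- normal[3] > 0
    circle3d(center, if (flipped) -normal else normal, radius,
             canonical_facing = flipped)
  })
  rms <- vapply(sols, function(s) reprojection_rms(s, camera, co), numeric(1))
  structure(list(solutions = sols, small_radius_r = r, scale_S = S,
                 reprojection_rms = rms, frame = frame),
            class = "circle_pair")
}

#' @export
print.circle_pair <- function(x, ...) {
  cat("<circle_pair> two-fold closed-form solution, r =",
      signif(x$small_radius_r, 8), " S =", signif(x$scale_S, 8), "\n")
  for (i in 1:2) {
    cat(sprintf(" [%d] reprojection RMS %.3g mm\n", i, x$reprojection_rms[i]))
    print(x$solutions[[i]])
  }
  invisible(x)
}

#' Reprojection residual of an estimated circle against an image conic
#'
#' Samples the circle, projects it, and measures the RMS Sampson distance
#' (algebraic conic residual divided by its gradient norm) to the conic.
#'
#' @param circle a [circle3d()].
#' @param camera a [camera()].
#' @param coeffs an [ellipse_coefficients()] vector.
#' @param n number of samples on the circle.
#' @return RMS distance in mm.
#' @export
reprojection_rms <- function(circle, camera, coeffs, n = 64L) {
  co <- unclass(ellipse_coefficients(coeffs))
  m <- as.matrix(project_circle(circle, camera, n))
  ## shift into principal-point-centred coordinates (conic convention)
  m <- sweep(m, 2, camera$principal_point_mm)
  g <- conic_eval(co, m)
  gu <- 2 * co[1] * m[, 1] + co[3] * m[, 2] + co[4]
  gv <- 2 * co[2] * m[, 2] + co[3] * m[, 1] + co[5]
  sqrt(mean((g / sqrt(gu^2 + gv^2))^2))
}
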