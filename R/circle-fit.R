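#' Intersect a viewing ray with the target plane
#'
#' The back-projection of an edge point onto the candidate circle plane:
#' `p_k = O + t_k i_k` with scale factor `t_k = (n . OP) / (n . i_k)`.
#'
#' @param ray a `"ray"` (from [pixel_to_ray()]) or a unit 3-vector
#'   direction.
#' @param center_P 3-vector, candidate circle centre (mm).
#' @param normal_n 3-vector, candidate plane normal (normalized
#'   internally).
#' @return list with the intersection `point` (3-vector, mm) and the scale
#'   factor `t` (mm); `t <= 0` means the plane lies behind the camera for
#'   this ray (flagged via attribute `behind`).
#' @export
backproject_point <- function(ray, center_P, normal_n) {
  d <- if (inherits(ray, "ray")) ray$direction else unit_vector(ray)
  n <- unit_vector(normal_n)
  den <- sum(n * d)
  if (abs(den) < 1e-12) stop("grazing ray: ray is parallel to the target plane")
  t <- sum(n * center_P) / den
  out <- list(point = t * d, t = t)
  attr(out, "behind") <- t <= 0
  out
}

#' Residual vector of the space-circle fit
#'
#' For candidate parameters `(P, n)` the edge rays are intersected with the
#' plane through `P` with normal `n`, giving derived space points `p_k`.
#' The first `N` residuals are the radius errors `||p_k - P|| - R` (mm);
#' residuals `N+1 ... 2N-2` are coplanarity errors: scalar triple products
#' of consecutive centre-to-edge vectors.  With
#' `coplanarity = "normalized"` (default) the three vectors are
#' unit-normalized before the determinant (a dimensionless sine measure)
#' and scaled by `R` so both blocks share the mm scale; `"raw"` uses the
#' literal mm^3 triple products.
#'
#' @param params list with `center` (3-vector) and `normal` (3-vector), or
#'   a numeric 6-vector `(P, n)`.
#' @param rays N x 3 matrix of unit ray directions (N >= 4), e.g. from
#'   [rays_from_points()].
#' @param radius circle radius `R` (mm).
#' @param coplanarity `"normalized"` or `"raw"` (see above).
#' @return numeric vector of length `2N - 2` with attributes `J` (sum of
#'   squares), `t` (the N scale factors) and `points` (the N derived space
#'   points).
#' @export
circle_residuals <- function(params, rays, radius,
                             coplanarity = c("normalized", "raw")) {
  coplanarity <- match.arg(coplanarity)
  if (is.numeric(params) && length(params) == 6)
    params <- list(center = params[1:3], normal = params[4:6])
  rays <- as.matrix(rays)
  N <- nrow(rays)
  if (N < 4) stop("at least 4 rays are required for a valid solve")
  P <- params$center
  n <- unit_vector(params$normal)
  den <- as.vector(rays %*% n)
  grazing <- which(abs(den) < 1e-12)
  if (length(grazing) > 0)
    stop("grazing ray at index ", grazing[1], ": ray parallel to target plane")
  t <- sum(n * P) / den
  pk <- rays * t
  u <- sweep(pk, 2, P)
  dist <- sqrt(rowSums(u^2))
  e_rad <- dist - radius
  if (coplanarity == "normalized") {
    w <- u / dist
    scale <- radius
  } else {
    w <- u
    scale <- 1
  }
  e_cop <- vapply(seq_len(N - 2), function(j)
    det(rbind(w[j, ], w[j + 1, ], w[j + 2, ])) * scale, numeric(1))
  res <- c(e_rad, e_cop)
  attr(res, "J") <- sum(res^2)
  attr(res, "t") <- t
  attr(res, "points") <- pk
  res
}

## Algorithm self-consistency score: unit normals from consecutive
## centre-to-edge cross products, compared with the fitted normal
## (antipodal-folded).  Near 0 for a good fit.
selfcheck_normal <- function(center, normal, rays, radius) {
  r <- circle_residuals(list(center = center, normal = normal), rays, radius)
  pk <- attr(r, "points")
  u <- sweep(pk, 2, center)
  N <- nrow(u)
  e <- vapply(2:N, function(k) {
    V <- cross3(u[k, ], u[k - 1, ])
    nv <- sqrt(sum(V^2))
    if (nv < .Machine$double.eps) return(NA_real_)
    V <- V / nv
    min(sqrt(sum((V - normal)^2)), sqrt(sum((V + normal)^2)))
  }, numeric(1))
  mean(e, na.rm = TRUE)
}

#' Least-squares fit of a space circle to edge rays
#'
#' Minimizes the sum of squared radius and coplanarity residuals
#' ([circle_residuals()]) over the six parameters `(P, n)` by
#' Levenberg-Marquardt trust-region least squares.  The normal is
#' normalized inside the residual (the objective is invariant to its scale
#' and sign) and a gauge-fixing entry `||n|| - 1` is appended so the
#' Jacobian keeps full rank; a 5-parameter spherical-angle
#' parametrization of the normal is available for conditioning
#' comparisons.
#'
#' By default both branches of the closed-form two-fold solution are used
#' as warm starts and both polished optima are returned ranked by the
#' objective `J` (ties broken toward the camera-facing normal); no
#' selection against ground truth happens here.  `init = "random"`
#' reproduces a seeded random initial normal with the centre placed at the
#' apparent depth `f0 R / r_img` along the mean ray.
#'
#' @param rays N x 3 matrix of unit ray directions, or an
#'   [image_points()] set (then `camera` is required).
#' @param radius circle radius `R` (mm), > 0.
#' @param camera a [camera()]; required when `rays` are image points or
#'   when `init = "cone"`.
#' @param init `"cone"` (closed-form warm start, default), `"random"`, or
#'   a list/`"circle_pair"` of explicit starting circles.
#' @param seed RNG seed for `init = "random"`.
#' @param parametrization `"full"` (6-vector, default) or `"spherical"`
#'   (5 parameters, normal as two angles).
#' @param coplanarity passed to [circle_residuals()].
#' @param max_iter,tol optimizer limits (maximum iterations; step and
#'   function tolerance).
#' @return an object of class `"circle_fit"`: list with `solutions` (each
#'   a list with `circle` ([circle3d()], camera-facing normal), `J`,
#'   `converged`, `iterations`, `selfcheck_E`), ranked by `J`, plus
#'   `n_points`.
#' @examples
#' cam <- camera(16)
#' truth <- circle3d(c(-30, -99, 310), c(-0.2, 0.1, -0.97), 6.5)
#' pts <- project_circle(truth, cam, 16)
#' fit <- solve_circle(pts, 6.5, camera = cam)
#' fit$solutions[[1]]$circle
#' @export
solve_circle <- function(rays, radius, camera = NULL,
                         init = c("cone", "random"),
                         seed = NULL,
                         parametrization = c("full", "spherical"),
                         coplanarity = c("normalized", "raw"),
                         max_iter = 200L, tol = 1e-12) {
  stopifnot(radius > 0)
  parametrization <- match.arg(parametrization)
  coplanarity <- match.arg(coplanarity)
  pts <- NULL
  if (inherits(rays, "image_points") ||
      (is.matrix(rays) && ncol(rays) == 2)) {
    if (is.null(camera)) stop("camera is required to back-project image points")
    pts <- image_points(rays)
    rays <- rays_from_points(pts, camera)
  }
  rays <- as.matrix(rays)
  N <- nrow(rays)
  if (N < 4) stop("at least 4 rays are required for a valid solve")

  starts <- resolve_init(init, rays, radius, camera, pts, seed)

  resfun <- function(par) {
    if (parametrization == "spherical") {
      n <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
      circle_residuals(list(center = par[1:3], normal = n), rays, radius,
                       coplanarity)
    } else {
      r <- circle_residuals(list(center = par[1:3], normal = par[4:6]),
                            rays, radius, coplanarity)
      c(r, sqrt(sum(par[4:6]^2)) - 1)   # gauge-fixing entry
    }
  }

  sols <- lapply(starts, function(s0) {
    par0 <- if (parametrization == "spherical") {
      n0 <- unit_vector(s0$normal)
      c(s0$center, acos(min(1, max(-1, n0[3]))), atan2(n0[2], n0[1]))
    } else c(s0$center, unit_vector(s0$normal))
    fit <- minpack.lm::nls.lm(par = par0, fn = resfun,
                              control = minpack.lm::nls.lm.control(
                                maxiter = max_iter, ftol = tol, ptol = tol))
    P <- fit$par[1:3]
    n <- if (parametrization == "spherical") {
      th <- fit$par[4]; ph <- fit$par[5]
      c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    } else unit_vector(fit$par[4:6])
    flipped <- n[3] > 0
    if (flipped) n <- -n
    J <- sum(circle_residuals(list(center = P, normal = n), rays, radius,
                              coplanarity)^2)
    list(circle = circle3d(P, n, radius, canonical_facing = flipped),
         J = J,
         converged = fit$info %in% 1:4,
         iterations = fit$niter,
         selfcheck_E = selfcheck_normal(P, n, rays, radius))
  })
  ## rank by J; ties toward camera-facing canonical orientation
  ord <- order(vapply(sols, `[[`, numeric(1), "J"),
               vapply(sols, function(s) s$circle$canonical_facing, logical(1)))
  structure(list(solutions = sols[ord], n_points = N), class = "circle_fit")
}

resolve_init <- function(init, rays, radius, camera, pts, seed) {
  if (inherits(init, "circle_pair"))
    return(lapply(init$solutions, function(s)
      list(center = s$center, normal = s$normal)))
  if (is.list(init) && !is.null(init$center))
    return(list(init))
  if (is.list(init))
    return(init)
  init <- match.arg(init, c("cone", "random"))
  if (init == "cone") {
    if (is.null(camera)) stop("camera is required for the closed-form warm start")
    if (is.null(pts)) {
      ## reconstruct image points from the rays
      f0 <- camera$focal_length_mm
      pts <- image_points(cbind(f0 * rays[, 1] / rays[, 3] + camera$principal_point_mm[1],
                                f0 * rays[, 2] / rays[, 3] + camera$principal_point_mm[2]))
    }
    if (nrow(pts) >= 5) {
      ctr <- sweep(as.matrix(pts), 2, camera$principal_point_mm)
      pair <- solve_closed_form(fit_ellipse(ctr), camera, radius)
      return(lapply(pair$solutions, function(s)
        list(center = s$center, normal = s$normal)))
    }
    ## the conic is underdetermined at N = 4: deterministic heuristic
    ## starts facing the camera along the mean ray, one upright and one
    ## tilted to give the optimizer a reach into either ambiguity branch
    mean_ray <- unit_vector(colMeans(rays))
    m <- as.matrix(pts)
    r_img <- mean(sqrt(rowSums(sweep(m, 2, colMeans(m))^2)))
    depth <- camera$focal_length_mm * radius / r_img
    P0 <- depth * mean_ray
    tilt <- rotation_about(unit_vector(cross3(mean_ray, c(0, 1, 0))), 0.35)
    return(list(list(center = P0, normal = -mean_ray),
                list(center = P0, normal = as.vector(tilt %*% -mean_ray))))
  }
  ## random mode: seeded normal, centre at the apparent depth along the mean ray
  if (!is.null(seed)) set.seed(seed)
  n0 <- unit_vector(rnorm(3))
  if (n0[3] > 0) n0 <- -n0
  mean_ray <- unit_vector(colMeans(rays))
  if (!is.null(camera) && !is.null(pts)) {
    m <- as.matrix(pts)
    r_img <- mean(sqrt(rowSums(sweep(m, 2, colMeans(m))^2)))
    depth <- camera$focal_length_mm * radius / r_img
  } else {
    ## ray spread proxy for the apparent radius
    spread <- mean(sqrt(rowSums(sweep(rays, 2, colMeans(rays))^2)))
    depth <- radius / spread
  }
  list(list(center = depth * mean_ray, normal = n0))
}

#' @export
print.circle_fit <- function(x, ...) {
  cat("<circle_fit>", x$n_points, "edge rays,", length(x$solutions),
      "polished solution(s)\n")
  for (i in seq_along(x$solutions)) {
    s <- x$solutions[[i]]
    cat(sprintf(" [%d] J = %.3e, converged = %s, iter = %d, selfcheck E = %.3e\n",
                i, s$J, s$converged, s$iterations, s$selfcheck_E))
    print(s$circle)
  }
  invisible(x)
}
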