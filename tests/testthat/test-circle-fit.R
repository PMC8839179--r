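test_that("ray-plane back-projection matches a generic linear solver", {
  b <- backproject_point(c(0, 0, 1), c(0, 0, 100), c(0, 0, -1))
  expect_equal(b$point, c(0, 0, 100))
  expect_equal(b$t, 100)
  b2 <- backproject_point(c(3, 4, 12) / 13, c(5, 5, 12), c(0, 0, 1))
  expect_equal(b2$point, c(3, 4, 12), tolerance = 1e-12)
  expect_equal(b2$t, 13, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    d <- unitv(rnorm(3)); n <- unitv(rnorm(3)); p0 <- rnorm(3, 0, 50)
    if (abs(sum(n * d)) < 1e-3) next
    got <- backproject_point(d, p0, n)
    want <- line_plane_oracle(c(0, 0, 0), d, p0, n)
    expect_equal(got$point, want$point, tolerance = 1e-9)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_lt(abs(sum((got$point - p0) * n)), 1e-9 * sqrt(sum(p0^2)))
  }
  expect_error(backproject_point(c(1, 0, 0), c(0, 0, 100), c(0, 0, 1)),
               "grazing ray")
})

test_that("residuals vanish at the generating parameters", {
  set.seed(42)
  sc <- rand_scene()
  rays <- rays_from_points(project_circle(sc$circle, sc$camera, 16), sc$camera)
  r <- circle_residuals(list(center = sc$circle$center,
                             normal = sc$circle$normal),
                        rays, sc$circle$radius)
  expect_length(r, 2 * 16 - 2)
  expect_lt(max(abs(r)), 1e-9)
  expect_lt(attr(r, "J"), 1e-18)
})

test_that("displacing the centre along the normal scales the section uniformly", {
  ## the derived points move with the displaced plane: every radius
  ## residual equals s*R - R with s = (n.P + 1)/(n.P); coplanarity stays 0
  cam <- camera(16)
  ci <- circle3d(c(0, 0, 100), c(0, 0, -1), 10)
  rays <- rays_from_points(project_circle(ci, cam, 8), cam)
  r <- circle_residuals(list(center = ci$center + ci$normal,
                             normal = ci$normal), rays, 10)
  s <- (sum(ci$normal * (ci$center + ci$normal))) / sum(ci$normal * ci$center)
  expect_equal(unname(r[1:8]), rep(s * 10 - 10, 8), tolerance = 1e-12)
  expect_equal(unname(r[1:8]), rep(-0.1, 8), tolerance = 1e-12)
  expect_lt(max(abs(r[9:14])), 1e-12)
})

test_that("coplanarity entries match a hand-built determinant oracle", {
  set.seed(43)
  sc <- rand_scene()
  rays <- rays_from_points(project_circle(sc$circle, sc$camera, 6), sc$camera)
  P <- sc$circle$center + c(0.5, -0.3, 0.2)
  n <- unitv(sc$circle$normal + c(0.05, -0.02, 0))
  r <- circle_residuals(list(center = P, normal = n), rays, sc$circle$radius)
  pk <- attr(r, "points")
  for (j in 1:4) {
    u <- t(apply(pk[j:(j + 2), ], 1, function(p) unitv(p - P)))
    expect_equal(unname(r[6 + j]), det(u) * sc$circle$radius,
                 tolerance = 1e-12)
  }
})

test_that("solver recovers exact scenes from the closed-form warm start", {
  set.seed(44)
  for (i in 1:4) {
    sc <- rand_scene()
    pts <- project_circle(sc$circle, sc$camera, 16)
    fit <- solve_circle(pts, sc$circle$radius, camera = sc$camera)
    best <- fit$solutions[[which.min(vapply(fit$solutions, function(s)
      sqrt(sum((s$circle$center - sc$circle$center)^2)), numeric(1)))]]
    expect_lt(best$J, 1e-16 * 16 * sc$circle$radius^2)
    expect_lt(sqrt(sum((best$circle$center - sc$circle$center)^2)) /
                sqrt(sum(sc$circle$center^2)), 1e-6)
    expect_lt(angle_between_deg(best$circle$normal, sc$circle$normal), 1e-4)
    expect_true(best$converged)
    expect_lt(best$selfcheck_E, 1e-6)
  }
})

test_that("minimal N = 4 solves are exact but non-unique", {
  ## four rays under-constrain the circle: a plane has 3 dof while
  ## concyclicity at radius R imposes only 2 constraints, so a
  ## one-parameter family of radius-R circles threads 4 exact rays.
  ## Every converged solution must be an exact root, the generating
  ## circle must be a fixed point, and N = 5 restores identifiability.
  set.seed(49)
  sc <- rand_scene()
  pts <- project_circle(sc$circle, sc$camera, 4)
  fit <- solve_circle(pts, sc$circle$radius, camera = sc$camera)
  for (s in fit$solutions)
    expect_lt(s$J, 1e-16 * sc$circle$radius^2)
  at_truth <- solve_circle(pts, sc$circle$radius, camera = sc$camera,
                           init = list(center = sc$circle$center,
                                       normal = sc$circle$normal))
  expect_lt(sqrt(sum((at_truth$solutions[[1]]$circle$center -
                        sc$circle$center)^2)) /
              sqrt(sum(sc$circle$center^2)), 1e-6)
  ## with 5 rays the perturbed init falls back into the truth basin
  pts5 <- project_circle(sc$circle, sc$camera, 5)
  near5 <- solve_circle(pts5, sc$circle$radius, camera = sc$camera,
                        init = list(center = sc$circle$center + c(0.5, -0.5, 1),
                                    normal = unitv(sc$circle$normal +
                                                     c(0.02, 0, -0.01))))
  best <- near5$solutions[[1]]
  expect_lt(sqrt(sum((best$circle$center - sc$circle$center)^2)) /
              sqrt(sum(sc$circle$center^2)), 1e-6)
  expect_lt(angle_between_deg(best$circle$normal, sc$circle$normal), 1e-4)
})

test_that("objective is gauge-invariant in the normal", {
  set.seed(45)
  sc <- rand_scene()
  rays <- rays_from_points(project_circle(sc$circle, sc$camera, 12), sc$camera)
  P <- sc$circle$center + c(1, 0, -0.5)
  n <- unitv(sc$circle$normal + c(0.1, 0, 0))
  J <- function(nn) attr(circle_residuals(list(center = P, normal = nn),
                                          rays, sc$circle$radius), "J")
  expect_equal(J(n), J(-n), tolerance = 1e-12)
  expect_equal(J(n), J(3.7 * n), tolerance = 1e-12)
})

test_that("reported optimum satisfies the first-order condition", {
  set.seed(46)
  sc <- rand_scene()
  pts <- add_noise(project_circle(sc$circle, sc$camera, 16), noise_config(60))
  rays <- rays_from_points(pts, sc$camera)
  fit <- solve_circle(pts, sc$circle$radius, camera = sc$camera)
  s <- fit$solutions[[1]]
  par <- c(s$circle$center, s$circle$normal)
  Jf <- function(p) attr(circle_residuals(list(center = p[1:3],
                                               normal = p[4:6]),
                                          rays, sc$circle$radius), "J")
  J0 <- Jf(par)
  g <- vapply(1:6, function(i) {
    h <- 1e-6 * max(1, abs(par[i]))
    pp <- par; pm <- par
    pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    (Jf(pp) - Jf(pm)) / (2 * h)
  }, numeric(1))
  ## gradient scale: compare to J curvature scale
  expect_lt(max(abs(g)), 1e-4 * max(1, J0) + 1e-6)
  expect_gt(J0, 0)
})

test_that("spherical parametrization agrees with the full one", {
  set.seed(47)
  sc <- rand_scene()
  pts <- add_noise(project_circle(sc$circle, sc$camera, 16), noise_config(70))
  f1 <- solve_circle(pts, sc$circle$radius, camera = sc$camera)
  f2 <- solve_circle(pts, sc$circle$radius, camera = sc$camera,
                     parametrization = "spherical")
  expect_equal(f1$solutions[[1]]$circle$center,
               f2$solutions[[1]]$circle$center, tolerance = 1e-5)
})

test_that("random initialization is reproducible and reaches a solution", {
  set.seed(48)
  sc <- rand_scene()
  pts <- project_circle(sc$circle, sc$camera, 16)
  f1 <- solve_circle(pts, sc$circle$radius, camera = sc$camera,
                     init = "random", seed = 7)
  f2 <- solve_circle(pts, sc$circle$radius, camera = sc$camera,
                     init = "random", seed = 7)
  expect_equal(f1$solutions[[1]]$circle$center,
               f2$solutions[[1]]$circle$center)
  expect_lt(f1$solutions[[1]]$J, 1e-12)
})

test_that("noise degrades the fit monotonically between SNR 80 and 50", {
  sc <- make_reference_scene()
  errs <- sapply(c(80, 50), function(snr) {
    vapply(1:10, function(i) {
      pts <- add_noise(sc$points, noise_config(snr, seed = 500 + i))
      fit <- solve_circle(pts, sc$circle$radius, camera = sc$camera)
      min(vapply(fit$solutions, function(s)
        sqrt(sum((s$circle$center - sc$circle$center)^2)), numeric(1)))
    }, numeric(1))
  })
  expect_lt(median(errs[, 1]), median(errs[, 2]))
})

test_that("fit stays comparable to the closed form under noise and lowers J", {
  ## the least-squares polish starts at the closed-form solution and can
  ## only decrease the geometric objective; on truth-closeness the two are
  ## statistically indistinguishable at this noise level
  sc <- make_reference_scene()
  ratio <- vapply(1:10, function(i) {
    pts <- add_noise(sc$points, noise_config(60, seed = 600 + i))
    ctr <- as.matrix(pts)
    pair <- solve_closed_form(fit_ellipse(ctr), sc$camera, sc$circle$radius)
    fit <- solve_circle(pts, sc$circle$radius, camera = sc$camera)
    rays <- rays_from_points(pts, sc$camera)
    J0 <- min(vapply(pair$solutions, function(s)
      attr(circle_residuals(list(center = s$center, normal = s$normal),
                            rays, sc$circle$radius), "J"), numeric(1)))
    expect_lte(fit$solutions[[1]]$J, J0 + 1e-18)
    ec <- min(vapply(pair$solutions, function(s)
      sqrt(sum((s$center - sc$circle$center)^2)), numeric(1)))
    ef <- min(vapply(fit$solutions, function(s)
      sqrt(sum((s$circle$center - sc$circle$center)^2)), numeric(1)))
    ef / ec
  }, numeric(1))
  expect_lt(median(ratio), 1.5)
})
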