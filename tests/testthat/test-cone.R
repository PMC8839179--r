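test_that("cone coefficients scale with the focal length as required", {
  co <- ellipse_coefficients(c(1, 1, 0, 0, 0, -1))
  q1 <- build_cone(co, camera(1))$Q
  expect_equal(q1 / q1[1, 1], diag(c(1, 1, -1)), tolerance = 1e-12)
  co4 <- ellipse_coefficients(c(1, 1, 0, 0, 0, -4))
  q2 <- build_cone(co4, camera(2))$Q
  expect_equal(q2 / q2[1, 1], diag(c(1, 1, -1)), tolerance = 1e-12)
  ## general pattern A = a f0^2 ... F = f on unnormalized coefficients
  set.seed(31)
  raw <- unclass(ellipse_coefficients(c(2, 3, 0.5, 0.3, -0.2, -9)))
  q <- build_cone(ellipse_coefficients(raw), camera(5))
  expect_equal(c(q$A, q$B, q$C, q$D, q$E, q$F),
               unname(raw * c(25, 25, 25, 5, 5, 1)), tolerance = 1e-12)
})

test_that("standardization orders eigenvalues and yields a proper rotation", {
  f <- standardize_cone(structure(list(Q = diag(c(1, 1, -1))),
                                  class = "cone_quadric"))
  expect_equal(f$lambda, c(1, 1, -1))
  expect_equal(abs(det(f$P_matrix)), 1, tolerance = 1e-12)
  f2 <- standardize_cone(structure(list(Q = diag(c(4, 1, -2))),
                                   class = "cone_quadric"))
  expect_equal(f2$lambda, c(4, 1, -2))
  ## conjugation invariance: rotated cones keep eigenvalues, P diagonalizes
  set.seed(32)
  for (i in 1:8) {
    Rm <- rand_rotation()
    Q <- Rm %*% diag(c(4, 1, -2)) %*% t(Rm)
    fr <- standardize_cone(structure(list(Q = Q), class = "cone_quadric"))
    expect_equal(fr$lambda, c(4, 1, -2), tolerance = 1e-9)
    D <- t(fr$P_matrix) %*% Q %*% fr$P_matrix
    expect_equal(D, diag(fr$lambda), tolerance = 1e-9)
    expect_equal(det(fr$P_matrix), 1, tolerance = 1e-9)
    expect_gt(fr$P_matrix[3, 3] * sign(fr$P_matrix[3, 3]), 0)
  }
  expect_error(standardize_cone(structure(list(Q = diag(c(1, 2, 3))),
                                          class = "cone_quadric")),
               "not a real cone")
})

test_that("section radius formula matches the brute-force sectioning oracle", {
  ## right circular 45-degree cone: unit-offset section is the unit circle
  f45 <- structure(list(lambda = c(1, 1, -1), P_matrix = diag(3),
                        axis_scales = c(1, 1, 1)), class = "cone_frame")
  expect_equal(small_circle_radius(f45), 1, tolerance = 1e-12)
  mk <- function(l) structure(list(lambda = l, P_matrix = diag(3),
                                   axis_scales = sqrt(1 / abs(l))),
                              class = "cone_frame")
  expect_equal(small_circle_radius(mk(c(4, 1, -2))),
               section_radius_oracle(c(4, 1, -2)), tolerance = 1e-6)
  set.seed(33)
  for (i in 1:10) {
    l <- c(sort(runif(2, 0.5, 6), decreasing = TRUE), -runif(1, 0.5, 6))
    expect_equal(small_circle_radius(mk(l)), section_radius_oracle(l),
                 tolerance = 1e-6)
    ## 0-homogeneous in the eigenvalues
    rho <- runif(1, 0.1, 9)
    expect_equal(small_circle_radius(mk(rho * l)), small_circle_radius(mk(l)),
                 tolerance = 1e-12)
  }
})

test_that("closed form recovers exact synthetic scenes (one branch)", {
  set.seed(34)
  for (i in 1:8) {
    sc <- rand_scene()
    pts <- project_circle(sc$circle, sc$camera, 16)
    pair <- solve_closed_form(fit_ellipse(pts), sc$camera, sc$circle$radius)
    errs <- vapply(pair$solutions, function(s)
      sqrt(sum((s$center - sc$circle$center)^2)), numeric(1))
    expect_lt(min(errs) / sqrt(sum(sc$circle$center^2)), 1e-6)
    best <- pair$solutions[[which.min(errs)]]
    expect_lt(abs(sum(best$normal * sc$circle$normal)) - 1, 1e-9)
    expect_lt(max(pair$reprojection_rms), 1e-9)
  }
})

test_that("both closed-form planes cut the cone in circles of radius R", {
  set.seed(35)
  sc <- rand_scene(radius = 7)
  pts <- project_circle(sc$circle, sc$camera, 16)
  co <- fit_ellipse(pts)
  pair <- solve_closed_form(co, sc$camera, 7)
  for (s in pair$solutions) {
    ## sample each solution circle; its projection must land on the conic
    expect_equal(s$radius, 7)
    expect_lt(reprojection_rms(s, sc$camera, co, 128), 1e-9)
  }
})

test_that("fronto-parallel circles give one merged solution along the axis", {
  cam <- camera(16)
  ci <- circle3d(c(0, 0, 100), c(0, 0, -1), 10)
  pair <- solve_closed_form(fit_ellipse(project_circle(ci, cam, 16)), cam, 10)
  for (s in pair$solutions) {
    expect_equal(s$center, c(0, 0, 100), tolerance = 1e-8)
    expect_equal(s$normal, c(0, 0, -1), tolerance = 1e-8)
  }
})

test_that("solutions scale linearly with radius and rotate equivariantly", {
  set.seed(36)
  sc <- rand_scene(radius = 5)
  pts <- project_circle(sc$circle, sc$camera, 16)
  co <- fit_ellipse(pts)
  p1 <- solve_closed_form(co, sc$camera, 5)
  p3 <- solve_closed_form(co, sc$camera, 15)
  for (i in 1:2) {
    expect_equal(p3$solutions[[i]]$center, 3 * p1$solutions[[i]]$center,
                 tolerance = 1e-9)
    expect_equal(p3$solutions[[i]]$normal, p1$solutions[[i]]$normal,
                 tolerance = 1e-12)
  }
  ## equivariance: a modest rotation of the scene about the optical centre
  th <- 0.15
  Rm <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  rot <- circle3d(as.vector(Rm %*% sc$circle$center),
                  as.vector(Rm %*% sc$circle$normal), 5)
  pr <- solve_closed_form(fit_ellipse(project_circle(rot, sc$camera, 16)),
                          sc$camera, 5)
  cen <- lapply(p1$solutions, function(s) as.vector(Rm %*% s$center))
  got <- lapply(pr$solutions, `[[`, "center")
  d11 <- sqrt(sum((cen[[1]] - got[[1]])^2)) + sqrt(sum((cen[[2]] - got[[2]])^2))
  d12 <- sqrt(sum((cen[[1]] - got[[2]])^2)) + sqrt(sum((cen[[2]] - got[[1]])^2))
  expect_lt(min(d11, d12), 1e-7)
})
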