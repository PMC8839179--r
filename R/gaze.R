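#' Screen plane geometry
#'
#' A flat display in the camera frame: `origin` is the screen point mapped
#' to screen coordinate `(0, 0)`, `x_axis`/`y_axis` are unit in-plane
#' directions (mm per screen unit), and `width`/`height` bound the visible
#' area.  The default places a 340 x 270 mm screen in the camera plane
#' `z = 0`, centred on the optical axis, with screen y running downward in
#' camera y.
#'
#' @param origin 3-vector, mm.
#' @param x_axis,y_axis in-plane direction vectors (normalized).
#' @param width,height screen extent in mm.
#' @return an object of class `"screen_plane"` with the plane `normal`
#'   attached.
#' @export
make_screen <- function(origin = c(-170, 135, 0),
                        x_axis = c(1, 0, 0), y_axis = c(0, -1, 0),
                        width = 340, height = 270) {
  x_axis <- unit_vector(x_axis); y_axis <- unit_vector(y_axis)
  if (abs(sum(x_axis * y_axis)) > 1e-9) stop("screen axes must be orthogonal")
  structure(list(origin = as.numeric(origin), x_axis = x_axis, y_axis = y_axis,
                 width = width, height = height,
                 normal = cross3(x_axis, y_axis)),
            class = "screen_plane")
}

#' Map screen coordinates to the camera frame
#'
#' @param screen a [make_screen()] plane.
#' @param xy 2-vector or k x 2 matrix of screen coordinates (mm).
#' @return 3-vector or k x 3 matrix of camera-frame points.
#' @export
screen_to_world <- function(screen, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, 1, 2)
  out <- t(apply(xy, 1, function(p)
    screen$origin + p[1] * screen$x_axis + p[2] * screen$y_axis))
  if (nrow(out) == 1) as.vector(out) else out
}

## --- kappa geometry -------------------------------------------------------
## Per-fixation eye frame built deterministically from the optical-axis
## direction d (unit, pointing out of the eye toward the scene): z_e = d,
## y_e = camera-frame y projected off d, x_e = y_e x z_e.
eye_frame <- function(d) {
  z <- unit_vector(d)
  y_ref <- if (abs(z[2]) > 0.99) c(1, 0, 0) else c(0, 1, 0)
  y <- unit_vector(y_ref - sum(y_ref * z) * z)
  cbind(cross3(y, z), y, z)
}

## Visual direction from optical direction: in the eye frame the visual
## axis is (sin kh, sin kv, sqrt(1 - sin^2 kh - sin^2 kv)).
kappa_apply <- function(d, kappa_h_deg, kappa_v_deg) {
  sh <- sin(kappa_h_deg * pi / 180); sv <- sin(kappa_v_deg * pi / 180)
  cz <- 1 - sh^2 - sv^2
  if (cz <= 0) stop("kappa angles too large")
  as.vector(eye_frame(d) %*% c(sh, sv, sqrt(cz)))
}

## Horizontal/vertical kappa angles implied by an (optical, visual) pair.
kappa_extract <- function(d, w) {
  we <- as.vector(t(eye_frame(d)) %*% unit_vector(w))
  c(h = asin(min(1, max(-1, we[1]))) * 180 / pi,
    v = asin(min(1, max(-1, we[2]))) * 180 / pi)
}

kappa_magnitude <- function(kappa_h_deg, kappa_v_deg) {
  s <- sqrt(sin(kappa_h_deg * pi / 180)^2 + sin(kappa_v_deg * pi / 180)^2)
  asin(min(1, s)) * 180 / pi
}

## Invert kappa_apply: the optical direction whose visual direction is w.
## Fixed-point iteration; kappa is a few degrees so convergence is fast.
kappa_invert <- function(w, kappa_h_deg, kappa_v_deg, tol = 1e-14) {
  d <- unit_vector(w)
  sh <- sin(kappa_h_deg * pi / 180); sv <- sin(kappa_v_deg * pi / 180)
  k_hat <- c(sh, sv, sqrt(1 - sh^2 - sv^2))
  for (i in 1:100) {
    F <- eye_frame(d)
    ## rotation taking z to k_hat within the current frame, inverted
    ax <- cross3(c(0, 0, 1), k_hat)
    na <- sqrt(sum(ax^2))
    Rk <- if (na < 1e-15) diag(3) else
      rotation_about(ax / na, asin(min(1, na)))
    d_new <- unit_vector(as.vector(F %*% (t(Rk) %*% (t(F) %*% w))))
    if (sum((d_new - d)^2) < tol^2) return(d_new)
    d <- d_new
  }
  d
}

#' Synthetic gaze session
#'
#' Generates per-fixation iris edge observations for an eye of known
#' geometry watching known screen targets.  The eye rotates about a fixed
#' eyeball centre; for each target the optical-axis direction is solved so
#' that the visual axis (optical axis rotated by the kappa angles in the
#' per-fixation eye frame) passes from the iris centre through the target.
#' The iris is a space circle centred on the optical axis at distance
#' `sqrt(eyeball_radius^2 - iris_radius^2)` from the eyeball centre;
#' its projected edge points (optionally noised) form the observation.
#'
#' @param targets_screen k x 2 matrix of screen coordinates (mm), e.g.
#'   [calibration_targets()] or [test_targets()].
#' @param camera a [camera()].
#' @param screen a [make_screen()] plane.
#' @param eyeball_center 3-vector, mm (the default sits ~450 mm from the
#'   camera, inside the usual viewing range).
#' @param eyeball_radius eyeball radius, mm (nominal 12).
#' @param iris_radius true iris radius, mm (normal range 5-6.8).
#' @param kappa_h_deg,kappa_v_deg true kappa angles, degrees.
#' @param n_edge iris edge samples per fixation.
#' @param snr_db edge-noise SNR in dB (`Inf` = noise-free).
#' @param seed RNG seed for the noise draws.
#' @return an object of class `"gaze_session"`: list with `camera`,
#'   `screen`, `fixations` (each: `target_screen`, `target_mm`, `points`).
#'   The generating truth (kappa, radii, eyeball centre, per-fixation iris
#'   centre and axis) is attached as attribute `"truth"` for validation.
#' @export
make_gaze_session <- function(targets_screen,
                              camera = circlepose::camera(16),
                              screen = make_screen(),
                              eyeball_center = c(30, -20, 450),
                              eyeball_radius = 12,
                              iris_radius = 5.8,
                              kappa_h_deg = 5, kappa_v_deg = 0,
                              n_edge = 16L, snr_db = Inf, seed = NULL) {
  stopifnot(iris_radius > 0, iris_radius < eyeball_radius)
  if (is.null(dim(targets_screen))) targets_screen <- matrix(targets_screen, 1, 2)
  offset <- sqrt(eyeball_radius^2 - iris_radius^2)
  if (!is.null(seed)) set.seed(seed)
  cfg <- noise_config(snr_db)
  fixations <- list(); truth_fix <- list()
  for (i in seq_len(nrow(targets_screen))) {
    target <- screen_to_world(screen, targets_screen[i, ])
    ## iris centre sits on the optical axis: I = E + offset * d, and the
    ## visual axis from I must hit the target -> joint fixed point in d.
    d <- unit_vector(target - eyeball_center)
    for (it in 1:100) {
      I <- eyeball_center + offset * d
      w <- unit_vector(target - I)
      d_new <- kappa_invert(w, kappa_h_deg, kappa_v_deg)
      if (sum((d_new - d)^2) < 1e-28) { d <- d_new; break }
      d <- d_new
    }
    I <- eyeball_center + offset * d
    iris <- circle3d(I, d, iris_radius)
    pts <- add_noise(project_circle(iris, camera, n_edge), cfg)
    fixations[[i]] <- list(target_screen = targets_screen[i, ],
                           target_mm = target, points = pts)
    truth_fix[[i]] <- list(iris_center = I, axis = d)
  }
  structure(list(camera = camera, screen = screen, fixations = fixations),
            class = "gaze_session",
            truth = list(eyeball_center = eyeball_center,
                         eyeball_radius = eyeball_radius,
                         iris_radius = iris_radius,
                         kappa_h_deg = kappa_h_deg, kappa_v_deg = kappa_v_deg,
                         kappa_deg = kappa_magnitude(kappa_h_deg, kappa_v_deg),
                         fixations = truth_fix))
}

#' @export
print.gaze_session <- function(x, ...) {
  cat("<gaze_session>", length(x$fixations), "fixations,",
      nrow(x$fixations[[1]]$points), "iris edge points each\n")
  invisible(x)
}

#' Default calibration and test target layouts
#'
#' Five calibration points (centre plus four at 20/80 % of the screen) and
#' a 3 x 3 test grid at 15/50/85 %.
#'
#' @param screen a [make_screen()] plane.
#' @return k x 2 matrix of screen coordinates (mm).
#' @export
calibration_targets <- function(screen = make_screen()) {
  fr <- rbind(c(0.5, 0.5), c(0.2, 0.2), c(0.8, 0.2), c(0.2, 0.8), c(0.8, 0.8))
  cbind(fr[, 1] * screen$width, fr[, 2] * screen$height)
}

#' @rdname calibration_targets
#' @export
test_targets <- function(screen = make_screen()) {
  fr <- as.matrix(expand.grid(c(0.15, 0.5, 0.85), c(0.15, 0.5, 0.85)))
  cbind(fr[, 1] * screen$width, fr[, 2] * screen$height)
}

#' Reconstruct the eyeball optical axis from iris edge points
#'
#' Runs the selected circle solver on the iris edge observation; the
#' optical axis is the line through the estimated iris centre along the
#' estimated normal, oriented out of the eye toward the scene (the
#' camera-facing hemisphere).  Both ambiguity branches are returned; the
#' calibration stage disambiguates them by fixation consistency.
#'
#' @param iris_edges an [image_points()] set (>= 4 points).
#' @param camera a [camera()].
#' @param iris_radius assumed iris radius, mm.
#' @param method `"circle_fit"` (default) or `"closed_form"`.
#' @return list of two candidate axes, each a list with `point` (the iris
#'   centre, mm) and unit `direction`.
#' @export
reconstruct_optical_axis <- function(iris_edges, camera, iris_radius,
                                     method = c("circle_fit", "closed_form")) {
  method <- match.arg(method)
  stopifnot(iris_radius > 0)
  circles <- if (method == "closed_form") {
    ctr <- sweep(as.matrix(iris_edges), 2, camera$principal_point_mm)
    solve_closed_form(fit_ellipse(ctr), camera, iris_radius)$solutions
  } else {
    lapply(solve_circle(iris_edges, iris_radius, camera = camera)$solutions,
           `[[`, "circle")
  }
  lapply(circles, function(ci)
    list(point = ci$center, direction = ci$normal))
}

## Implied eyeball centres for all fixations/branches at assumed radius r,
## given unit-radius solutions (centres scale linearly with the assumed
## radius; normals are radius-free).
implied_eye_centers <- function(unit_centers, dirs, r, r_ref, eyeball_radius) {
  offset <- sqrt(eyeball_radius^2 - r^2)
  lapply(seq_along(unit_centers), function(k)
    lapply(seq_along(unit_centers[[k]]), function(b)
      unit_centers[[k]][[b]] * (r / r_ref) - offset * dirs[[k]][[b]]))
}

## Best branch combination: minimal total spread of implied eyeball
## centres.  Exhaustive for <= 2^10 combinations, greedy otherwise.
best_branch_combo <- function(E) {
  K <- length(E)
  spread <- function(combo) {
    M <- t(vapply(seq_len(K), function(k) E[[k]][[combo[k]]], numeric(3)))
    sum(sweep(M, 2, colMeans(M))^2)
  }
  nb <- vapply(E, length, integer(1))
  if (prod(nb) <= 1024) {
    combos <- as.matrix(expand.grid(lapply(nb, seq_len)))
    sc <- apply(combos, 1, spread)
    i <- which.min(sc)
    list(combo = as.integer(combos[i, ]), spread = sc[i])
  } else {
    combo <- rep(1L, K)
    for (pass in 1:3) for (k in seq_len(K)) {
      sc <- vapply(seq_len(nb[k]), function(b) {
        cb <- combo; cb[k] <- b; spread(cb)
      }, numeric(1))
      combo[k] <- which.min(sc)
    }
    list(combo = combo, spread = spread(combo))
  }
}

#' Calibrate per-user eye parameters from known fixation targets
#'
#' Two-step user calibration.  (1) The iris radius is found by a 1-D
#' search: candidate radii rescale the reconstructed iris centres
#' (solutions are linear in the assumed radius), and the radius minimizing
#' the spread of implied eyeball centres (iris centre minus
#' `sqrt(eyeball_radius^2 - r^2)` along the optical axis) across fixations
#' is selected — a rigid single-eye consistency criterion; the
#' two-fold ambiguity branch per fixation is chosen jointly to minimize
#' the same spread.  (2) The kappa angles are the per-fixation angles
#' between the reconstructed optical axis and the true visual axis (iris
#' centre to target), expressed in the per-fixation eye frame and averaged.
#'
#' @param session a [make_gaze_session()] (or equivalent) session with
#'   >= 2 fixations spanning distinct gaze directions.
#' @param method solver for the iris circle, see
#'   [reconstruct_optical_axis()].
#' @param eyeball_radius assumed eyeball radius, mm.
#' @param radius_range search interval for the iris radius, mm.
#' @return an object of class `"eye_model"`: `iris_radius` (mm),
#'   `kappa_h_deg`, `kappa_v_deg`, `kappa_deg` (magnitude),
#'   `eyeball_center` (mm), `eyeball_radius`, `branch_spread_mm2`,
#'   `method`.  A warning is raised when the iris radius falls outside the
#'   physiological 5-6.8 mm band.
#' @export
calibrate_user <- function(session, method = c("circle_fit", "closed_form"),
                           eyeball_radius = 12, radius_range = c(3, 9)) {
  method <- match.arg(method)
  K <- length(session$fixations)
  if (K < 2) stop("kappa unidentifiable: at least 2 fixations are required")
  r_ref <- 5.9   # nominal solve radius; solutions rescale linearly
  axes_ref <- lapply(session$fixations, function(fx)
    reconstruct_optical_axis(fx$points, session$camera, r_ref, method))
  unit_centers <- lapply(axes_ref, function(a) lapply(a, `[[`, "point"))
  dirs <- lapply(axes_ref, function(a) lapply(a, `[[`, "direction"))

  dmat <- t(vapply(dirs, function(d) d[[1]], numeric(3)))
  if (sum(sweep(dmat, 2, colMeans(dmat))^2) < 1e-12)
    stop("kappa unidentifiable: fixations do not span distinct gaze directions")

  hi <- min(radius_range[2], eyeball_radius - 0.05)
  obj <- function(r)
    best_branch_combo(implied_eye_centers(unit_centers, dirs, r, r_ref,
                                          eyeball_radius))$spread
  opt <- optimize(obj, c(radius_range[1], hi), tol = 1e-9)
  r_hat <- opt$minimum

  ## re-solve at the calibrated radius and re-select branches
  axes <- lapply(session$fixations, function(fx)
    reconstruct_optical_axis(fx$points, session$camera, r_hat, method))
  uc <- lapply(axes, function(a) lapply(a, `[[`, "point"))
  dd <- lapply(axes, function(a) lapply(a, `[[`, "direction"))
  Ecand <- implied_eye_centers(uc, dd, r_hat, r_hat, eyeball_radius)
  sel <- best_branch_combo(Ecand)
  Emat <- t(vapply(seq_len(K), function(k)
    Ecand[[k]][[sel$combo[k]]], numeric(3)))
  eye_center <- colMeans(Emat)

  kap <- t(vapply(seq_len(K), function(k) {
    ax <- axes[[k]][[sel$combo[k]]]
    w <- unit_vector(session$fixations[[k]]$target_mm - ax$point)
    kappa_extract(ax$direction, w)
  }, numeric(2)))
  kh <- mean(kap[, 1]); kv <- mean(kap[, 2])

  if (r_hat < 5 || r_hat > 6.8)
    warning(sprintf("calibrated iris radius %.3f mm outside physiological 5-6.8 mm band",
                    r_hat))
  structure(list(iris_radius = r_hat,
                 kappa_h_deg = kh, kappa_v_deg = kv,
                 kappa_deg = kappa_magnitude(kh, kv),
                 eyeball_center = eye_center,
                 eyeball_radius = eyeball_radius,
                 branch_spread_mm2 = sel$spread,
                 method = method),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model> iris radius %.4f mm, kappa %.4f deg (h %.4f, v %.4f)\n",
              x$iris_radius, x$kappa_deg, x$kappa_h_deg, x$kappa_v_deg))
  cat(sprintf("  eyeball center (%.2f, %.2f, %.2f) mm, R_eye %.1f mm, solver: %s\n",
              x$eyeball_center[1], x$eyeball_center[2], x$eyeball_center[3],
              x$eyeball_radius, x$method))
  invisible(x)
}

#' Intersect the visual axis with the screen
#'
#' Applies the calibrated kappa rotation to the optical axis about the
#' iris centre and intersects the resulting visual axis with the screen
#' plane.
#'
#' @param axis list with `point` (iris centre, mm) and unit `direction`
#'   (optical axis, toward the scene).
#' @param model an [calibrate_user()] `"eye_model"` (only the kappa angles
#'   are used).
#' @param screen a [make_screen()] plane.
#' @return list with `screen_xy` (2-vector, screen coordinates mm),
#'   `point_mm` (3-vector) and `behind` (TRUE when the intersection lies
#'   opposite the gaze direction).
#' @export
point_of_regard <- function(axis, model, screen) {
  w <- kappa_apply(axis$direction, model$kappa_h_deg, model$kappa_v_deg)
  den <- sum(w * screen$normal)
  if (abs(den) < 1e-12) stop("no intersection: visual axis parallel to screen")
  s <- sum((screen$origin - axis$point) * screen$normal) / den
  q <- axis$point + s * w
  rel <- q - screen$origin
  list(screen_xy = c(sum(rel * screen$x_axis), sum(rel * screen$y_axis)),
       point_mm = q, behind = s < 0)
}

#' Evaluate point-of-regard accuracy on a test session
#'
#' For each fixation the optical axis is reconstructed at the calibrated
#' iris radius (ambiguity branch chosen by closeness of the implied
#' eyeball centre to the calibrated one), converted to the visual axis and
#' intersected with the screen; errors against the known targets are
#' reported per screen axis, in mm and as visual angles.
#'
#' @param session a test [make_gaze_session()].
#' @param model an `"eye_model"` from [calibrate_user()].
#' @param method solver, see [reconstruct_optical_axis()].
#' @return data.frame with one row per fixation (target and estimated
#'   screen coordinates, per-axis errors in mm and degrees) with an
#'   `"rmse"` attribute: named vector
#'   `c(x_mm, y_mm, x_deg, y_deg)`.
#' @export
evaluate_gaze <- function(session, model,
                          method = c("circle_fit", "closed_form")) {
  method <- match.arg(method)
  offset <- sqrt(model$eyeball_radius^2 - model$iris_radius^2)
  rows <- lapply(session$fixations, function(fx) {
    cand <- reconstruct_optical_axis(fx$points, session$camera,
                                     model$iris_radius, method)
    dE <- vapply(cand, function(a)
      sum((a$point - offset * a$direction - model$eyeball_center)^2),
      numeric(1))
    ax <- cand[[which.min(dE)]]
    por <- point_of_regard(ax, model, session$screen)
    dxy <- por$screen_xy - fx$target_screen
    dist <- sqrt(sum((fx$target_mm - ax$point)^2))
    data.frame(target_x = fx$target_screen[1], target_y = fx$target_screen[2],
               est_x = por$screen_xy[1], est_y = por$screen_xy[2],
               err_x_mm = dxy[1], err_y_mm = dxy[2],
               eps_x_deg = atan(dxy[1] / dist) * 180 / pi,
               eps_y_deg = atan(dxy[2] / dist) * 180 / pi)
  })
  out <- do.call(rbind, rows)
  attr(out, "rmse") <- c(x_mm = sqrt(mean(out$err_x_mm^2)),
                         y_mm = sqrt(mean(out$err_y_mm^2)),
                         x_deg = sqrt(mean(out$eps_x_deg^2)),
                         y_deg = sqrt(mean(out$eps_y_deg^2)))
  out
}
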