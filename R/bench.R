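#' Reference simulation scene
#'
#' The benchmark configuration: a 16 mm camera observing a circular target
#' of radius 6.5726701 mm at centre
#' `(-30.7587037, -99.5438179, 310.8944607)` mm with unit normal parallel
#' to `(-0.1806, 0.1086, -0.9775)`, sampled at `n_points` uniform edge
#' angles and projected to the image plane.
#'
#' @param n_points number of edge samples (default 16).
#' @return list with `circle` ([circle3d()]), `camera` ([camera()]) and
#'   `points` ([image_points()]).
#' @export
make_reference_scene <- function(n_points = 16L) {
  circle <- circle3d(center = c(-30.7587037, -99.5438179, 310.8944607),
                     normal = c(-0.1806, 0.1086, -0.9775),
                     radius = 6.5726701)
  cam <- camera(16)
  list(circle = circle, camera = cam,
       points = project_circle(circle, cam, n_points))
}

#' Gaussian edge-noise configuration
#'
#' Noise level is set by a signal-to-noise ratio in dB.  Signal power is,
#' by default, the mean squared distance of the edge points from the image
#' origin (`definition = "point_power"`): the per-coordinate noise standard
#' deviation is `sigma = sqrt(mean(u^2 + v^2) * 10^(-snr/10))`.  The
#' alternative `"centroid_power"` references the mean squared deviation
#' from the point-set centroid split over the two coordinates, making the
#' noise scale with the apparent ellipse size instead of its position.
#' `snr_db = Inf` is the no-noise sentinel.
#'
#' @param snr_db signal-to-noise ratio in dB (e.g. 100 down to 40), or
#'   `Inf` for no noise.
#' @param seed optional RNG seed for reproducible draws.
#' @param definition `"point_power"` (default) or `"centroid_power"`.
#' @return an object of class `"noise_config"`.
#' @export
noise_config <- function(snr_db, seed = NULL,
                         definition = c("point_power", "centroid_power")) {
  stopifnot(is.numeric(snr_db), length(snr_db) == 1, !is.na(snr_db))
  definition <- match.arg(definition)
  structure(list(snr_db = snr_db, seed = seed, definition = definition),
            class = "noise_config")
}

#' Per-coordinate noise standard deviation implied by an SNR
#'
#' @param points an [image_points()] set (or N x 2 matrix).
#' @param config a [noise_config()].
#' @return scalar sigma in mm (0 for the `Inf` sentinel).
#' @export
noise_sigma <- function(points, config) {
  stopifnot(inherits(config, "noise_config"))
  if (is.infinite(config$snr_db)) return(0)
  m <- as.matrix(points)
  p_signal <- switch(config$definition,
    point_power    = mean(rowSums(m^2)),
    centroid_power = mean(rowSums(sweep(m, 2, colMeans(m))^2)) / 2)
  sqrt(p_signal * 10^(-config$snr_db / 10))
}

#' Add SNR-controlled Gaussian noise to edge points
#'
#' i.i.d. zero-mean Gaussian offsets with standard deviation
#' [noise_sigma()] are added to each coordinate.  With a `seed` in the
#' config the draw is reproducible; without one the current RNG stream is
#' used (so a caller can seed once for a whole sweep).
#'
#' @param points an [image_points()] set.
#' @param config a [noise_config()].
#' @return a noisy [image_points()] set of the same size.
#' @export
add_noise <- function(points, config) {
  m <- as.matrix(points)
  sg <- noise_sigma(m, config)
  if (sg == 0) return(image_points(m))
  if (!is.null(config$seed)) set.seed(config$seed)
  image_points(m + matrix(rnorm(length(m), 0, sg), nrow(m), 2))
}

#' Pose error metrics
#'
#' Euclidean distance between centres (mm) and angle between unit normals
#' (degrees, folded over the antipodal ambiguity so it lies in 0-90).
#'
#' @param estimate,truth [circle3d()] objects.
#' @return named numeric vector `c(center_error_mm, normal_error_deg)`.
#' @export
error_metrics <- function(estimate, truth) {
  c(center_error_mm = sqrt(sum((estimate$center - truth$center)^2)),
    normal_error_deg = angle_between_deg(estimate$normal, truth$normal))
}

## Bench-only: of the two ambiguity branches, pick the one closest to the
## ground truth (combined, unit-free closeness: centre error in radii plus
## chord distance between unit normals).
select_closest <- function(circles, truth) {
  score <- vapply(circles, function(ci) {
    e <- error_metrics(ci, truth)
    e[1] / truth$radius + 2 * sin(e[2] * pi / 360)
  }, numeric(1))
  circles[[which.min(score)]]
}

#' Monte Carlo noise sweep over both estimators
#'
#' For each SNR level and replicate, Gaussian noise is added to the scene's
#' projected edge points and the same noisy points are handed to both
#' estimators: the closed-form method refits the conic to the noisy points
#' and back-projects it; the least-squares fit consumes the noisy points
#' directly (closed-form warm start).  Per method the ambiguity branch
#' closer to ground truth is selected (a bench-only operation) and the
#' centre / normal errors recorded.
#'
#' @param snr_list SNR levels in dB (default 100 down to 40 by 10).
#' @param replicates noise replicates per level (default 20).
#' @param base_seed single RNG seed for the entire sweep.
#' @param scene a scene list from [make_reference_scene()] (default).
#' @param methods subset of `c("closed_form", "circle_fit")`.
#' @param definition noise-power definition, see [noise_config()].
#' @return an object of class `"sweep_result"`: list with `replicates`
#'   (data.frame: snr, method, replicate, center_error_mm,
#'   normal_error_deg), `means` (per snr x method averages over successful
#'   replicates), `failures` (data.frame of failed cells with reasons) and
#'   `meta` (seed, noise definition, scene size).
#' @export
run_sweep <- function(snr_list = seq(100, 40, by = -10), replicates = 20L,
                      base_seed = 1L, scene = make_reference_scene(),
                      methods = c("closed_form", "circle_fit"),
                      definition = "point_power") {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 1)
  set.seed(base_seed)
  pts <- scene$points
  truth <- scene$circle
  cam <- scene$camera
  rows <- list(); fails <- list()
  for (snr in snr_list) {
    cfg <- noise_config(snr, definition = definition)
    for (rep in seq_len(replicates)) {
      noisy <- add_noise(pts, cfg)
      for (method in methods) {
        est <- tryCatch({
          if (method == "closed_form") {
            pair <- solve_closed_form(fit_ellipse(noisy), cam, truth$radius)
            select_closest(pair$solutions, truth)
          } else {
            fit <- solve_circle(noisy, truth$radius, camera = cam)
            select_closest(lapply(fit$solutions, `[[`, "circle"), truth)
          }
        }, error = function(e) e)
        if (inherits(est, "error")) {
          fails[[length(fails) + 1L]] <-
            data.frame(snr = snr, method = method, replicate = rep,
                       reason = conditionMessage(est))
        } else {
          e <- error_metrics(est, truth)
          rows[[length(rows) + 1L]] <-
            data.frame(snr = snr, method = method, replicate = rep,
                       center_error_mm = e[1], normal_error_deg = e[2],
                       row.names = NULL)
        }
      }
    }
  }
  reps <- do.call(rbind, rows)
  means <- aggregate_sweep(reps)
  structure(list(replicates = reps, means = means,
                 failures = if (length(fails)) do.call(rbind, fails) else NULL,
                 meta = list(base_seed = base_seed, definition = definition,
                             n_points = nrow(pts), replicates = replicates)),
            class = "sweep_result")
}

#' Aggregate a per-replicate sweep table into per-level means
#'
#' @param replicates a data.frame with columns snr, method, replicate,
#'   center_error_mm, normal_error_deg (e.g. `sweep$replicates` or a
#'   re-read [read_sweep_csv()] table).
#' @return data.frame with one row per (snr, method) and mean errors.
#' @export
aggregate_sweep <- function(replicates) {
  out <- stats::aggregate(
    replicates[, c("center_error_mm", "normal_error_deg")],
    by = list(snr = replicates$snr, method = replicates$method), mean)
  out[order(out$method, -out$snr), , drop = FALSE]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> seed", x$meta$base_seed, "-", x$meta$replicates,
      "replicates/level, noise definition:", x$meta$definition, "\n")
  print(x$means, row.names = FALSE)
  if (!is.null(x$failures))
    cat(nrow(x$failures), "failed replicate cells (excluded from means)\n")
  invisible(x)
}

#' Plot mean sweep errors against SNR
#'
#' Base-graphics line plot of mean centre (or normal) error per method,
#' mirroring the usual robustness comparison figures.
#'
#' @param sweep a `"sweep_result"`.
#' @param metric `"center_error_mm"` or `"normal_error_deg"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_sweep <- function(sweep, metric = c("center_error_mm", "normal_error_deg"),
                       ...) {
  metric <- match.arg(metric)
  m <- sweep$means
  methods <- unique(m$method)
  snrs <- sort(unique(m$snr), decreasing = TRUE)
  y <- sapply(methods, function(mm)
    m[m$method == mm, ][match(snrs, m$snr[m$method == mm]), metric])
  graphics::matplot(snrs, y, type = "b", pch = 19, lty = 1, log = "y",
                    xlim = rev(range(snrs)), xlab = "SNR (dB)",
                    ylab = metric, ...)
  graphics::legend("topleft", legend = methods, col = seq_along(methods),
                   lty = 1, pch = 19, bty = "n")
  invisible(y)
}
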