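#' Read an edge-point set from CSV
#'
#' Accepts metric input with header `u,v` (mm on the image plane) or pixel
#' input with header `u_px,v_px`; the latter requires a camera with
#' `pixel_pitch_mm` and is converted to mm once on read.  Mixed headers or
#' malformed rows are rejected with the offending line number.
#'
#' @param path CSV file path.
#' @param camera a [camera()]; needed only for pixel-unit input.
#' @return an [image_points()] set (mm).
#' @export
read_points_csv <- function(path, camera = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  if (identical(nm, c("u", "v"))) {
    scale <- 1
  } else if (identical(nm, c("u_px", "v_px"))) {
    if (is.null(camera) || is.null(camera$pixel_pitch_mm))
      stop("pixel-unit input requires a camera with pixel_pitch_mm")
    scale <- camera$pixel_pitch_mm
  } else if (any(c("u", "v") %in% nm) && any(c("u_px", "v_px") %in% nm)) {
    stop("mixed-unit headers: use either u,v or u_px,v_px")
  } else {
    stop("expected CSV header 'u,v' or 'u_px,v_px', got: ",
         paste(nm, collapse = ","))
  }
  num <- suppressWarnings(vapply(df, function(col) as.numeric(as.character(col)),
                                 numeric(nrow(df))))
  num <- matrix(num, ncol = 2)
  bad <- which(!stats::complete.cases(num))
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  image_points(num * scale)
}

#' @rdname read_points_csv
#' @param points an [image_points()] set to write (mm, header `u,v`).
#' @export
write_points_csv <- function(points, path) {
  m <- as.matrix(points)
  colnames(m) <- c("u", "v")
  write.csv(as.data.frame(m), path, row.names = FALSE)
}

#' Read a camera specification from JSON or YAML
#'
#' Expected fields: `focal_length_mm` (required), `principal_point_mm`
#' (optional 2-vector) and `pixel_pitch_mm` (optional scalar).
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a [camera()].
#' @export
read_camera_config <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(spec$focal_length_mm)) stop("camera config lacks focal_length_mm")
  camera(spec$focal_length_mm,
         principal_point_mm = spec$principal_point_mm %||% c(0, 0),
         pixel_pitch_mm = spec$pixel_pitch_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a solution pair to JSON
#'
#' Serializes the two (centre, normal) solutions of either solver, with
#' the objective/reprojection diagnostics, under a versioned schema.
#'
#' @param x a `"circle_pair"` ([solve_closed_form()]) or `"circle_fit"`
#'   ([solve_circle()]).
#' @param path output JSON path.
#' @export
write_solution_json <- function(x, path) {
  sols <- if (inherits(x, "circle_pair")) {
    lapply(seq_along(x$solutions), function(i) {
      s <- x$solutions[[i]]
      list(center_mm = s$center, normal = s$normal, radius_mm = s$radius,
           reprojection_rms_mm = x$reprojection_rms[i])
    })
  } else if (inherits(x, "circle_fit")) {
    lapply(x$solutions, function(s)
      list(center_mm = s$circle$center, normal = s$circle$normal,
           radius_mm = s$circle$radius, J = s$J,
           converged = s$converged, selfcheck_E = s$selfcheck_E))
  } else stop("unsupported solution object")
  payload <- list(schema = "circlepose/solution/1", solutions = sols)
  if (inherits(x, "circle_pair"))
    payload <- c(payload, list(small_radius_r_mm = x$small_radius_r,
                               scale_S = x$scale_S))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read per-replicate sweep tables
#'
#' Column order is fixed: snr, method, replicate, center_error_mm,
#' normal_error_deg.  The run metadata (seed, noise definition) is written
#' alongside as a `#`-prefixed comment header.
#'
#' @param sweep a `"sweep_result"` from [run_sweep()].
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# base_seed=%d definition=%s n_points=%d replicates=%d",
                     sweep$meta$base_seed, sweep$meta$definition,
                     sweep$meta$n_points, sweep$meta$replicates), con)
  cols <- c("snr", "method", "replicate", "center_error_mm", "normal_error_deg")
  utils::write.table(sweep$replicates[, cols], con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a gaze session as JSON
#'
#' @param session a [make_gaze_session()] session (truth attribute is not
#'   serialized).
#' @param path JSON path.
#' @export
write_gaze_session <- function(session, path) {
  payload <- list(
    schema = "circlepose/gaze-session/1",
    camera = list(focal_length_mm = session$camera$focal_length_mm,
                  principal_point_mm = session$camera$principal_point_mm),
    screen = session$screen[c("origin", "x_axis", "y_axis", "width", "height")],
    fixations = lapply(session$fixations, function(fx)
      list(target_screen = fx$target_screen, target_mm = fx$target_mm,
           points = unclass(fx$points))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gaze_session
#' @export
read_gaze_session <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  scr <- make_screen(p$screen$origin, p$screen$x_axis, p$screen$y_axis,
                     p$screen$width, p$screen$height)
  cam <- camera(p$camera$focal_length_mm, p$camera$principal_point_mm)
  fixations <- if (is.data.frame(p$fixations)) {
    lapply(seq_len(nrow(p$fixations)), function(i)
      list(target_screen = unlist(p$fixations$target_screen[i]),
           target_mm = unlist(p$fixations$target_mm[i]),
           points = image_points(p$fixations$points[[i]])))
  } else {
    lapply(p$fixations, function(fx)
      list(target_screen = unlist(fx$target_screen),
           target_mm = unlist(fx$target_mm),
           points = image_points(fx$points)))
  }
  structure(list(camera = cam, screen = scr, fixations = fixations),
            class = "gaze_session")
}
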