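#' Pinhole camera model
#'
#' The camera sits at the origin of its own frame, looking along +z; the
#' image plane is `z = f0` and image coordinates `(u, v)` are metric
#' (millimetres) on that plane, measured from the principal point.  Inputs
#' in pixel units are converted once at the I/O boundary via
#' `pixel_pitch_mm` (see [read_points_csv()]); all internal math is metric.
#'
#' @param focal_length_mm focal length `f0` in mm; must be positive.
#' @param principal_point_mm 2-vector, principal point on the image plane
#'   (mm).  Defaults to `(0, 0)`.
#' @param pixel_pitch_mm optional scalar, physical size of one pixel (mm);
#'   used only when reading pixel-unit point sets.
#' @return an object of class `"camera"`.
#' @examples
#' cam <- camera(16)
#' pixel_to_ray(c(16, 0), cam)$direction  # 45 degree ray
#' @export
camera <- function(focal_length_mm, principal_point_mm = c(0, 0),
                   pixel_pitch_mm = NULL) {
  stopifnot(is.numeric(focal_length_mm), length(focal_length_mm) == 1,
            is.finite(focal_length_mm), focal_length_mm > 0,
            length(principal_point_mm) == 2, all(is.finite(principal_point_mm)))
  if (!is.null(pixel_pitch_mm))
    stopifnot(is.numeric(pixel_pitch_mm), pixel_pitch_mm > 0)
  structure(list(focal_length_mm = focal_length_mm,
                 principal_point_mm = as.numeric(principal_point_mm),
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  cat("<camera> f0 =", x$focal_length_mm, "mm, principal point (",
      x$principal_point_mm[1], ",", x$principal_point_mm[2], ") mm\n")
  invisible(x)
}

#' A circle in 3D space
#'
#' A planar circle given by its centre (mm), unit normal and radius (mm).
#' The two antipodal normals describe the same circle; the stored normal is
#' whichever the caller supplies, and `canonical_facing = TRUE` records that
#' it was flipped to the camera-facing hemisphere (negative z-component).
#'
#' @param center 3-vector, mm.
#' @param normal 3-vector; normalized on construction.
#' @param radius scalar, mm; must be positive.
#' @param canonical_facing logical flag recording whether `normal` was
#'   folded to the camera-facing hemisphere.
#' @return an object of class `"circle3d"`.
#' @export
circle3d <- function(center, normal, radius, canonical_facing = FALSE) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            length(normal) == 3, all(is.finite(normal)),
            is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(center = as.numeric(center),
                 normal = unit_vector(as.numeric(normal)),
                 radius = as.numeric(radius),
                 canonical_facing = isTRUE(canonical_facing)),
            class = "circle3d")
}

#' @export
print.circle3d <- function(x, ...) {
  cat(sprintf("<circle3d> center (%.4f, %.4f, %.4f) mm, normal (%.5f, %.5f, %.5f), R = %.4f mm\n",
              x$center[1], x$center[2], x$center[3],
              x$normal[1], x$normal[2], x$normal[3], x$radius))
  invisible(x)
}

#' An image point set
#'
#' An ordered set of `(u, v)` edge points (mm) on the image plane.
#'
#' @param points numeric matrix (or coercible) with two columns `u`, `v`.
#' @return an object of class `"image_points"`: an N x 2 matrix with
#'   columns `u`, `v`.
#' @export
image_points <- function(points) {
  m <- as.matrix(points)
  stopifnot(ncol(m) == 2, nrow(m) >= 1, all(is.finite(m)))
  colnames(m) <- c("u", "v")
  structure(m, class = c("image_points", "matrix", "array"))
}

#' @export
print.image_points <- function(x, ...) {
  cat("<image_points>", nrow(x), "edge points (mm)\n")
  print(head(unclass(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Sample a 3D circle and project it through the camera
#'
#' Edge points are sampled at uniform angle on the space circle (angle
#' measured from a deterministic in-plane basis) and each is mapped by the
#' pinhole projection `(u, v) = (f0 x/z, f0 y/z)` plus the principal point.
#'
#' @param circle a [circle3d()].
#' @param camera a [camera()].
#' @param n_points number of edge samples (>= 4).
#' @return an [image_points()] set, ordered by the angular parameter.
#' @examples
#' cam <- camera(16)
#' ci <- circle3d(c(0, 0, 100), c(0, 0, -1), 10)
#' project_circle(ci, cam, 4)  # points at +-1.6 mm
#' @export
project_circle <- function(circle, camera, n_points = 16L) {
  stopifnot(inherits(circle, "circle3d"), inherits(camera, "camera"),
            n_points >= 4)
  ## canonicalize the normal so the sampled edge ordering (and hence the
  ## output) is invariant to the antipodal ambiguity of the normal
  nrm <- circle$normal
  if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
  b <- plane_basis(nrm)
  th <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  edge <- t(vapply(th, function(t)
    circle$center + circle$radius * (cos(t) * b$u + sin(t) * b$v),
    numeric(3)))
  if (any(edge[, 3] <= 0)) stop("circle not fully in front of camera")
  f0 <- camera$focal_length_mm
  image_points(cbind(f0 * edge[, 1] / edge[, 3] + camera$principal_point_mm[1],
                     f0 * edge[, 2] / edge[, 3] + camera$principal_point_mm[2]))
}

#' Back-project an image point to a viewing ray
#'
#' Returns the unit direction from the optical centre (the origin) through
#' the image point `(u, v, f0)`.
#'
#' @param point 2-vector `(u, v)` in mm.
#' @param camera a [camera()].
#' @return a list of class `"ray"` with `origin` (the optical centre) and
#'   unit `direction` (positive z-component).
#' @examples
#' pixel_to_ray(c(3, 4), camera(12))$direction  # (3, 4, 12) / 13
#' @export
pixel_to_ray <- function(point, camera) {
  stopifnot(length(point) == 2, all(is.finite(point)), inherits(camera, "camera"))
  d <- unit_vector(c(point - camera$principal_point_mm, camera$focal_length_mm))
  structure(list(origin = c(0, 0, 0), direction = d), class = "ray")
}

#' Viewing rays for a whole point set
#'
#' @param points an [image_points()] set.
#' @param camera a [camera()].
#' @return an N x 3 matrix of unit ray directions (origin is the optical
#'   centre for all of them).
#' @export
rays_from_points <- function(points, camera) {
  stopifnot(inherits(camera, "camera"))
  m <- as.matrix(points)
  t(apply(m, 1L, function(p) pixel_to_ray(p, camera)$direction))
}
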