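## Small 3D geometry helpers shared by every solver.  All internal.

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / nv
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Deterministic in-plane orthonormal basis for the plane with normal `n`:
## Gram-Schmidt of the coordinate axis least aligned with `n`.  Used for
## circle edge parametrization, so reproducibility matters more than the
## particular basis chosen.
plane_basis <- function(n) {
  n <- unit_vector(n)
  ax <- diag(3)[, which.min(abs(n))]
  u <- unit_vector(ax - sum(ax * n) * n)
  list(u = u, v = cross3(n, u))
}

## Rotation by `angle` radians about unit `axis` (Rodrigues).
rotation_about <- function(axis, angle) {
  a <- unit_vector(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Angle between two directions folded over the antipodal ambiguity, degrees.
angle_between_deg <- function(a, b, fold = TRUE) {
  ca <- sum(unit_vector(a) * unit_vector(b))
  if (fold) ca <- abs(ca)
  acos(min(1, max(-1, ca))) * 180 / pi
}
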