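# Rigid-body geometry of stem migration.
#
# Euler convention used throughout: intrinsic x -> y -> z rotations, i.e.
# R = Rx(rx) %*% Ry(ry) %*% Rz(rz), angles in degrees. The convention is a
# package constant (EULER_SEQUENCE) because RSA platforms do not agree on a
# sequence; at clinical migration magnitudes (< ~6 degrees) the sequences
# differ only in the third decimal.

#' @rdname dof6
#' @export
EULER_SEQUENCE <- "xyz"

.deg2rad <- pi / 180

#' Six-degree-of-freedom migration value
#'
#' Constructs a validated 6-DOF migration vector: translations in mm along
#' x/y/z and rotations in degrees about x/y/z. Rotations are restricted to
#' (-90, 90) degrees, a plausibility guard for the small-rotation regime of
#' implant migration (it also keeps the Euler decomposition away from its
#' gimbal singularity).
#'
#' @param tx,ty,tz Translations in mm.
#' @param rx,ry,rz Rotations in degrees.
#' @return Named numeric vector of class `dof6` ordered as [RSA_AXES].
#' @examples
#' dof6(1, 2, 2, 0, 0, 0)
#' @export
dof6 <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  d <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  if (!all(is.finite(d))) stop("dof6: all six components must be finite")
  if (any(abs(d[c("rx", "ry", "rz")]) >= 90)) {
    stop("dof6: rotations must lie strictly within (-90, 90) degrees")
  }
  class(d) <- "dof6"
  d
}

#' @export
print.dof6 <- function(x, ...) {
  cat("6-DOF migration (mm / deg):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

as_dof6 <- function(x) {
  if (inherits(x, "dof6")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6) stop("expected 6 components (tx, ty, tz, rx, ry, rz)")
  dof6(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' Rigid transform (pose)
#'
#' A rotation matrix plus translation vector describing the pose of the stem
#' rigid body in the laboratory frame, acting as `x -> R x + t`.
#'
#' @param R 3x3 rotation matrix; must be orthonormal with determinant +1
#'   (tolerance 1e-9).
#' @param t Numeric translation 3-vector (mm).
#' @return Object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  if (!all(dim(R) == c(3, 3)) || length(t) != 3) {
    stop("rigid_transform: R must be 3x3 and t a 3-vector")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop("rigid_transform: R is not a proper rotation (orthonormal, det +1)")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  R:\n")
  print(round(x$R, 6))
  cat("  t (mm):", round(x$t, 6), "\n")
  invisible(x)
}

#' Labeled 3D marker set
#'
#' Tantalum-bead marker positions (mm) used as the rigid-body reference.
#'
#' @param points Numeric n x 3 matrix of coordinates (mm), n >= 3.
#' @param labels Optional character labels; defaults to `m1..mn`.
#' @return Object of class `marker_set`: the coordinate matrix with rownames.
#' @export
marker_set <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 3) {
    stop("marker_set: need an n x 3 coordinate matrix with n >= 3")
  }
  if (is.null(labels)) labels <- rownames(points)
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(points)))
  if (anyDuplicated(labels)) stop("marker_set: duplicated marker labels")
  dimnames(points) <- list(labels, c("x", "y", "z"))
  storage.mode(points) <- "double"
  class(points) <- c("marker_set", "matrix")
  points
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Convert a 6-DOF migration to the corresponding rigid transform
#'
#' Inverse of [dof6_from_transforms()] for the relative motion: builds
#' `R = Rx(rx) Ry(ry) Rz(rz)` (intrinsic x->y->z) and pairs it with the
#' translation triple.
#'
#' @param d A [dof6()] value.
#' @return A [rigid_transform()].
#' @export
dof6_to_transform <- function(d) {
  d <- as_dof6(d)
  R <- rot_x(d["rx"] * .deg2rad) %*% rot_y(d["ry"] * .deg2rad) %*%
    rot_z(d["rz"] * .deg2rad)
  rigid_transform(R, unclass(d)[1:3])
}

#' Decompose relative stem motion into six degrees of freedom
#'
#' Computes the relative motion `followup o baseline^-1` and decomposes it
#' into translations (mm) and Euler angles (degrees, intrinsic x->y->z).
#' This is the migration of the stem between the baseline and follow-up
#' examinations, expressed in the baseline laboratory frame.
#'
#' @param baseline,followup [rigid_transform()] poses of the stem.
#' @return A [dof6()] migration value.
#' @export
dof6_from_transforms <- function(baseline, followup) {
  stopifnot(inherits(baseline, "rigid_transform"),
            inherits(followup, "rigid_transform"))
  R <- followup$R %*% t(baseline$R)
  t <- followup$t - R %*% baseline$t
  ry <- asin(max(-1, min(1, R[1, 3])))
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  dof6(t[1], t[2], t[3],
       rx / .deg2rad, ry / .deg2rad, rz / .deg2rad)
}

#' Total translation and total rotation
#'
#' Surrogate scalar measures of implant motion: the Euclidean norm of the
#' translation triple (mm) and of the rotation triple (degrees). Both are
#' invariant under a common rotation of the coordinate frame
#' (see [rotate_dof6()]).
#'
#' @param d A [dof6()] value.
#' @return Non-negative scalar (mm or degrees).
#' @export
total_translation <- function(d) {
  d <- as_dof6(d)
  sqrt(sum(unclass(d)[1:3]^2))
}

#' @rdname total_translation
#' @export
total_rotation <- function(d) {
  d <- as_dof6(d)
  sqrt(sum(unclass(d)[4:6]^2))
}

#' Maximum total point motion (MTPM)
#'
#' The largest displacement among the points of the implant surface model
#' under a rigid motion: `max_p || R p + t - p ||`. Equals the translation
#' norm exactly for a pure translation, and grows with the lever arm of the
#' model points for rotations.
#'
#' @param motion A [rigid_transform()] (the relative stem motion).
#' @param model_points A [marker_set()] or n x 3 matrix of stem-model points
#'   (mm); must be non-empty.
#' @return MTPM in mm.
#' @export
mtpm <- function(motion, model_points) {
  stopifnot(inherits(motion, "rigid_transform"))
  P <- as.matrix(unclass(model_points))
  if (nrow(P) == 0) stop("mtpm: empty point set")
  if (ncol(P) != 3) stop("mtpm: points must be n x 3")
  disp <- P %*% t(motion$R) - P
  disp <- sweep(disp, 2, motion$t, `+`)
  sqrt(max(rowSums(disp^2)))
}

#' Synthetic femoral stem point cloud for MTPM
#'
#' A deterministic point set spanning a 160 mm stem silhouette (distal tip at
#' y = -160, head centre near the origin), used as the default implant model
#' for MTPM when no CAD surface model is available. Clearly synthetic: a
#' tapered eight-point ring sampled every 20 mm plus tip and head points.
#'
#' @param length_mm Stem length (default 160).
#' @return A [marker_set()].
#' @export
stem_model_points <- function(length_mm = 160) {
  ys <- seq(0, -length_mm, by = -20)
  pts <- do.call(rbind, lapply(ys, function(y) {
    r <- 2 + 10 * (1 + y / length_mm) # taper: 12 mm proximal -> 2 mm distal
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(r * cos(ang), y, r * sin(ang))
  }))
  pts <- rbind(pts, c(0, -length_mm, 0), c(0, 8, 0))
  marker_set(pts, labels = paste0("p", seq_len(nrow(pts))))
}

#' Rodrigues rotation matrix
#'
#' Rotation by `theta_deg` degrees about the unit axis `u`.
#'
#' @param u Unit 3-vector.
#' @param theta_deg Angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(u, theta_deg) {
  u <- as.numeric(u)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-8) stop("axis must be a unit vector")
  th <- theta_deg * .deg2rad
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate a migration value about an axis in the x-z plane
#'
#' Applies the same 3x3 rotation (angle `theta_deg` about `axis_u`, Rodrigues
#' form) to the translation triple and to the rotation triple of `d`
#' (block-diagonal action on the 6-vector, treating the small Euler triple as
#' a rotation vector). Used by the power study to tilt the simulated group
#' difference away from the y-axis; preserves [total_translation()] and
#' [total_rotation()].
#'
#' @param d A [dof6()] value, or an n x 6 matrix of migration rows.
#' @param axis_u Unit 3-vector orthogonal to the y-axis (i.e. in the x-z
#'   plane), e.g. from [random_xz_unit()].
#' @param theta_deg Rotation angle in degrees.
#' @return Same shape as `d`.
#' @export
rotate_dof6 <- function(d, axis_u, theta_deg) {
  axis_u <- as.numeric(axis_u)
  if (abs(sqrt(sum(axis_u^2)) - 1) > 1e-8) {
    stop("rotate_dof6: axis_u must be a unit vector")
  }
  if (abs(axis_u[2]) > 1e-12) {
    stop("rotate_dof6: axis_u must lie in the x-z plane (zero y-component)")
  }
  R <- rotation_about_axis(axis_u, theta_deg)
  if (is.matrix(d)) {
    stopifnot(ncol(d) == 6)
    out <- cbind(d[, 1:3, drop = FALSE] %*% t(R),
                 d[, 4:6, drop = FALSE] %*% t(R))
    colnames(out) <- colnames(d)
    return(out)
  }
  d <- as_dof6(d)
  v <- unclass(d)
  tr <- R %*% v[1:3]
  ro <- R %*% v[4:6]
  dof6(tr[1], tr[2], tr[3], ro[1], ro[2], ro[3])
}

#' Random unit vector in the x-z plane
#'
#' Draws `(cos(phi), 0, sin(phi))` with `phi` uniform on `[0, 2*pi)`, the
#' random rotation axis of the offset-angle simulation. Uses the current R
#' RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @return Unit 3-vector with exact zero y-component.
#' @export
random_xz_unit <- function() {
  phi <- stats::runif(1, 0, 2 * pi)
  c(cos(phi), 0, sin(phi))
}
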