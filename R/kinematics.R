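#' Rotation matrix from a rotation vector (exponential map)
#'
#' The rigid-body moves of the optimizer are parameterized by rotation
#' vectors `v = angle * axis` (radians) rather than Euler angles, so that the
#' parameter space has no gimbal singularity. Euler angles are used only for
#' *measuring* orientations (see [measure_orientation()]).
#'
#' @param v numeric length-3 rotation vector, radians; `|v|` is the rotation
#'   angle and `v/|v|` the axis. The zero vector gives the identity.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
#' @examples
#' rotation_from_vector(c(pi, 0, 0))  # 180 degrees about x
rotation_from_vector <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  theta <- sqrt(sum(v * v))
  K <- skew3(v)
  if (theta < 1e-12) {
    # second-order series keeps the map smooth through the origin
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  a <- sin(theta) / theta
  b <- (1 - cos(theta)) / (theta * theta)
  diag(3) + a * K + b * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Partial derivatives of the exponential map
#'
#' Returns `dR/dv_k` for `k = 1..3` using the closed form of Gallego & Yezzi
#' (J Math Imaging Vis, 2015); the limit at `v = 0` is the generator
#' `[e_k]_x`. These feed the chain rule that converts per-atom energy
#' gradients into gradients with respect to rigid parameters.
#'
#' @param v rotation vector (radians).
#' @param R optional precomputed `rotation_from_vector(v)`.
#' @return list of three 3x3 matrices.
#' @keywords internal
drotation_dvector <- function(v, R = rotation_from_vector(v)) {
  theta2 <- sum(v * v)
  out <- vector("list", 3L)
  if (theta2 < 1e-16) {
    for (k in 1:3) {
      e <- numeric(3); e[k] <- 1
      out[[k]] <- skew3(e)
    }
    return(out)
  }
  ImR <- diag(3) - R
  for (k in 1:3) {
    e <- numeric(3); e[k] <- 1
    w <- crossprod3(v, ImR %*% e)
    out[[k]] <- ((v[k] * skew3(v) + skew3(w)) %*% R) / theta2
  }
  out
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a rigid pose
#'
#' A pose is a rotation vector plus a translation, applied about a center of
#' rotation `c`: `x' = R (x - c) + c + t`. The translation is either a free
#' 3-vector (`mode = "vector3"`) or a scalar displacement along a fixed axis
#' (`mode = "axis1"`), matching the two translation modes the mobile-unit
#' operators expose.
#'
#' @param rotation length-3 rotation vector, radians.
#' @param translation length-3 vector (Angstrom), or a scalar when
#'   `mode = "axis1"`.
#' @param mode `"vector3"` or `"axis1"`.
#' @param axis unit axis for `"axis1"` mode.
#' @return object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                       mode = c("vector3", "axis1"), axis = NULL) {
  mode <- match.arg(mode)
  if (mode == "axis1") {
    stopifnot(length(translation) == 1L, length(axis) == 3L)
    axis <- axis / sqrt(sum(axis^2))
  } else {
    stopifnot(length(translation) == 3L)
  }
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 mode = mode, axis = axis),
            class = "rigid_pose")
}

pose_translation_vec <- function(pose) {
  if (pose$mode == "axis1") pose$translation * pose$axis else pose$translation
}

#' Apply a rigid pose to coordinates
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param pose a [rigid_pose()].
#' @param center length-3 center of rotation (Angstrom).
#' @return transformed n x 3 matrix; internal distances are preserved.
#' @export
apply_rigid_pose <- function(coords, pose, center) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, length(center) == 3L)
  R <- rotation_from_vector(pose$rotation)
  t <- pose_translation_vec(pose)
  shifted <- sweep(coords, 2L, center)
  out <- shifted %*% t(R)
  sweep(out, 2L, center + t, "+")
}

#' Inverse of a rigid pose
#' @param pose a [rigid_pose()] with `mode = "vector3"`.
#' @return the pose undoing `pose` about the same center.
#' @export
invert_rigid_pose <- function(pose) {
  R <- rotation_from_vector(pose$rotation)
  t <- pose_translation_vec(pose)
  rigid_pose(rotation = -pose$rotation, translation = as.numeric(-t(R) %*% t))
}

#' Flat-bottom harmonic distance restraint
#'
#' Penalizes displacement of a mobile anchor point beyond a threshold:
#' zero for `d <= threshold`, `0.5 k (d - threshold)^2` beyond it. The
#' gradient is continuous at the threshold. Used to keep the mobile units
#' from drifting unrealistically far (default thresholds 7.5 Angstrom for
#' Vbeta and 13.0 Angstrom for pMHC).
#'
#' @param reference_point,threshold,force_constant restraint definition;
#'   threshold in Angstrom, force constant in kcal/mol/A^2.
#' @return object of class `restraint_spec`.
#' @export
restraint_spec <- function(reference_point, threshold, force_constant = 10) {
  stopifnot(length(reference_point) == 3L, threshold > 0, force_constant >= 0)
  structure(list(reference_point = as.numeric(reference_point),
                 threshold = threshold, force_constant = force_constant),
            class = "restraint_spec")
}

#' Evaluate a flat-bottom restraint
#'
#' @param mobile_point length-3 current anchor position.
#' @param spec a [restraint_spec()].
#' @return list with `energy` (kcal/mol) and `gradient` (length 3, with
#'   respect to the mobile point).
#' @export
restraint_energy <- function(mobile_point, spec) {
  d_vec <- as.numeric(mobile_point) - spec$reference_point
  d <- sqrt(sum(d_vec^2))
  if (d <= spec$threshold || spec$force_constant == 0) {
    return(list(energy = 0, gradient = c(0, 0, 0)))
  }
  excess <- d - spec$threshold
  list(energy = 0.5 * spec$force_constant * excess^2,
       gradient = spec$force_constant * excess * d_vec / d)
}
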