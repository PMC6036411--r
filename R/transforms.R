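# All coordinates are DICOM LPS millimetres: +x patient left, +y posterior,
# +z superior. Angles are degrees at every interface, radians internally.

.deg2rad <- function(deg) deg * pi / 180
.rad2deg <- function(rad) rad * 180 / pi

.check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
    stop(sprintf("%s must be 3 finite numbers", what), call. = FALSE)
  as.numeric(v)
}

.rotation_defect <- function(r) {
  max(abs(r %*% t(r) - diag(3)))
}

.check_rotation <- function(r, tol = 1e-9, warn_tol = 1e-3) {
  if (!is.matrix(r) || !identical(dim(r), c(3L, 3L)) || any(!is.finite(r)))
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  defect <- .rotation_defect(r)
  det_defect <- abs(det(r) - 1)
  if (defect > warn_tol || det_defect > warn_tol)
    stop(sprintf("matrix is not a rotation (orthonormality defect %.2g, det defect %.2g)",
                 defect, det_defect), call. = FALSE)
  if (defect > tol || det_defect > tol)
    warning(sprintf("rotation block deviates from orthonormality by %.2g (file rounding?)",
                    max(defect, det_defect)), call. = FALSE)
  r
}

# ---- patient shifts ---------------------------------------------------------

.DIRECTION_AXIS <- c(Lt = 1L, Rt = 1L, Ant = 2L, Post = 2L, Sup = 3L, `Inf` = 3L)
.DIRECTION_SIGN <- c(Lt = 1, Rt = -1, Ant = -1, Post = 1, Sup = 1, `Inf` = -1)

#' Patient-direction shift specification
#'
#' Describes a known couch/phantom shift in patient-direction vocabulary
#' (Lt/Rt toward patient left/right, Ant/Post anterior/posterior, Sup/Inf
#' superior/inferior), together with which dataset of the registered pair was
#' physically shifted. Commissioning datasets state their ground truth this
#' way; [patient_shift_to_dicom()] and [expected_translation()] convert it to
#' the DICOM LPS vectors the registration object reports.
#'
#' @param magnitudes numeric vector of three signed shift magnitudes in mm.
#' @param directions character vector of three labels from
#'   `c("Lt","Rt","Ant","Post","Sup","Inf")`; together the labels must cover
#'   the three patient axes exactly once.
#' @param shifted one of `"stationary"` or `"moving"`: which dataset of the
#'   registered pair was shifted by these amounts.
#' @return an object of class `patient_shift`.
#' @examples
#' patient_shift(c(10, 5, 15), c("Lt", "Ant", "Sup"), shifted = "stationary")
#' @export
patient_shift <- function(magnitudes, directions,
                          shifted = c("stationary", "moving", "unspecified")) {
  shifted <- match.arg(shifted)
  magnitudes <- .check_vec3(magnitudes, "shift magnitudes")
  directions <- as.character(directions)
  if (length(directions) != 3L || !all(directions %in% names(.DIRECTION_AXIS)))
    stop("directions must be three labels from Lt/Rt/Ant/Post/Sup/Inf",
         call. = FALSE)
  axes <- .DIRECTION_AXIS[directions]
  if (!setequal(axes, 1:3))
    stop("shift directions must cover the three patient axes exactly once (got ",
         paste(directions, collapse = ", "), ")", call. = FALSE)
  structure(list(magnitudes = magnitudes, directions = directions,
                 shifted = shifted),
            class = "patient_shift")
}

#' @export
print.patient_shift <- function(x, ...) {
  cat("Patient shift:",
      paste(sprintf("%g mm %s", x$magnitudes, x$directions), collapse = ", "),
      sprintf("(%s dataset shifted)\n", x$shifted))
  invisible(x)
}

#' Convert a patient-direction shift to a DICOM LPS displacement
#'
#' Maps each labelled shift onto the DICOM patient coordinate axes:
#' left is +x, posterior is +y, superior is +z (right, anterior and inferior
#' negate). The result is the physical displacement of the shifted dataset,
#' irrespective of registration direction.
#'
#' @param shift a [patient_shift()].
#' @return numeric length-3 LPS displacement in mm, named `x`, `y`, `z`.
#' @export
patient_shift_to_dicom <- function(shift) {
  stopifnot(inherits(shift, "patient_shift"))
  out <- numeric(3)
  axes <- .DIRECTION_AXIS[shift$directions]
  out[axes] <- shift$magnitudes * .DIRECTION_SIGN[shift$directions]
  names(out) <- c("x", "y", "z")
  out
}

#' Expected translation vector of the registration object
#'
#' The 4x4 matrix stored in a DICOM spatial registration object maps the
#' stationary (target) frame to the moving frame -- the opposite of the
#' registration direction. For a pure translation case the expected vector T
#' is therefore the negated LPS shift when the stationary dataset is the one
#' that was shifted, and the un-negated shift when the moving dataset was.
#'
#' @param shift a [patient_shift()] with `shifted` set to `"stationary"` or
#'   `"moving"`.
#' @return numeric length-3 expected T (mm, LPS, target-to-moving direction).
#' @export
expected_translation <- function(shift) {
  stopifnot(inherits(shift, "patient_shift"))
  if (shift$shifted == "unspecified")
    stop("shifted role must be 'stationary' or 'moving' to orient T",
         call. = FALSE)
  d <- patient_shift_to_dicom(shift)
  if (shift$shifted == "stationary") -d else d
}

# ---- rotations --------------------------------------------------------------

#' Single-axis rotation matrix
#'
#' Builds the elementary rotation matrix about a cardinal patient axis. The
#' element layout follows the convention used for commissioning worked
#' examples: Rx and Rz are the usual right-handed forms, while Ry places
#' \eqn{-\sin\theta} at row 1, column 3 (the transpose of the more common
#' layout). The composite in [compose_rotations()] is validated against the
#' worked rotation case, so the layouts must be used together as printed.
#'
#' @param axis one of `"x"`, `"y"`, `"z"` (case-insensitive).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- tolower(as.character(axis))
  if (!axis %in% c("x", "y", "z")) stop("axis must be 'x', 'y' or 'z'", call. = FALSE)
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle))
    stop("angle must be a single finite number (degrees)", call. = FALSE)
  t <- .deg2rad(angle)
  c_ <- cos(t); s_ <- sin(t)
  switch(axis,
    x = matrix(c(1, 0, 0,
                 0, c_, -s_,
                 0, s_, c_), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, -s_,
                 0, 1, 0,
                 s_, 0, c_), 3, 3, byrow = TRUE),
    z = matrix(c(c_, -s_, 0,
                 s_, c_, 0,
                 0, 0, 1), 3, 3, byrow = TRUE))
}

#' Rotation specification in per-axis degrees
#'
#' @param x,y,z rotation angles about the patient X, Y and Z axes, degrees,
#'   each in (-180, 180].
#' @return an object of class `rotation_spec`.
#' @export
rotation_spec <- function(x = 0, y = 0, z = 0) {
  angles <- c(x = x, y = y, z = z)
  if (any(!is.finite(angles)) || any(angles <= -180) || any(angles > 180))
    stop("angles must be finite degrees in (-180, 180]", call. = FALSE)
  structure(list(angles = angles), class = "rotation_spec")
}

#' @export
print.rotation_spec <- function(x, ...) {
  cat(sprintf("Rotations: %g deg X, %g deg Y, %g deg Z\n",
              x$angles[1], x$angles[2], x$angles[3]))
  invisible(x)
}

#' Compose per-axis rotations into one rotation matrix
#'
#' Multiplies the elementary matrices of [rotation_about_axis()]. The default
#' order applies the Z rotation first, then Y, then X -- i.e. the matrix
#' product \eqn{R_z R_y R_x} read right to left -- which is the order that
#' reproduces the published worked example for the rotation commissioning
#' case. Other orders are available for software that composes differently.
#'
#' @param spec a [rotation_spec()].
#' @param order three-letter string naming the matrix product left to right;
#'   default `"zyx"` means \eqn{R_z \cdot R_y \cdot R_x}.
#' @return a 3x3 orthonormal rotation matrix.
#' @export
compose_rotations <- function(spec, order = "zyx") {
  stopifnot(inherits(spec, "rotation_spec"))
  letters3 <- strsplit(tolower(order), "")[[1]]
  if (length(letters3) != 3L || !setequal(letters3, c("x", "y", "z")))
    stop("order must be a permutation of 'xyz'", call. = FALSE)
  mats <- lapply(letters3, function(a) rotation_about_axis(a, spec$angles[a]))
  Reduce(`%*%`, mats)
}

# ---- homogeneous transforms -------------------------------------------------

#' Rigid homogeneous transform
#'
#' A 4x4 homogeneous transformation: a 3x3 rotation block, a translation
#' column in mm, and an implied bottom row (0,0,0,1). The `direction` tag
#' records which way the transform maps points: DICOM spatial registration
#' objects store the target-to-moving direction, while ground-truth transforms
#' are naturally constructed moving-to-stationary.
#'
#' @param rotation 3x3 rotation matrix (checked orthonormal; deviations above
#'   `warn_tol` are an error, between `1e-9` and `warn_tol` a warning, to
#'   accommodate matrices re-read from rounded files).
#' @param translation length-3 translation in mm.
#' @param direction one of `"moving_to_stationary"`, `"target_to_moving"`,
#'   `"unspecified"`.
#' @param warn_tol orthonormality tolerance above which construction fails.
#' @return an object of class `homogeneous_transform`.
#' @examples
#' t <- homogeneous_transform(diag(3), c(10, -5, 15))
#' transform_point(t, c(0, 0, 0))
#' @export
homogeneous_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                  direction = c("unspecified",
                                                "moving_to_stationary",
                                                "target_to_moving"),
                                  warn_tol = 1e-3) {
  direction <- match.arg(direction)
  rotation <- .check_rotation(rotation, warn_tol = warn_tol)
  translation <- .check_vec3(translation, "translation")
  m <- rbind(cbind(rotation, translation), c(0, 0, 0, 1))
  dimnames(m) <- NULL
  structure(list(matrix = m, direction = direction),
            class = "homogeneous_transform")
}

#' @export
print.homogeneous_transform <- function(x, digits = 4, ...) {
  cat(sprintf("Rigid homogeneous transform (%s)\n", x$direction))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Rotation block of a homogeneous transform
#' @param t a [homogeneous_transform()].
#' @return 3x3 rotation matrix.
#' @export
transform_rotation <- function(t) {
  stopifnot(inherits(t, "homogeneous_transform"))
  t$matrix[1:3, 1:3]
}

#' Translation column of a homogeneous transform
#' @param t a [homogeneous_transform()].
#' @return length-3 translation (mm), named `x`, `y`, `z`.
#' @export
transform_translation <- function(t) {
  stopifnot(inherits(t, "homogeneous_transform"))
  stats::setNames(t$matrix[1:3, 4], c("x", "y", "z"))
}

#' Flatten / rebuild the 16-value row-major representation
#'
#' DICOM spatial registration objects serialize the 4x4 matrix row by row as
#' 16 values ending 0/0/0/1. These helpers round-trip losslessly.
#'
#' @param t a [homogeneous_transform()].
#' @return for `transform_to_flat`, a numeric vector of 16 values.
#' @export
transform_to_flat <- function(t) {
  stopifnot(inherits(t, "homogeneous_transform"))
  as.numeric(t(t$matrix))
}

#' @rdname transform_to_flat
#' @param flat numeric vector of 16 row-major values; the last four must be
#'   exactly 0, 0, 0, 1.
#' @param direction,warn_tol passed to [homogeneous_transform()].
#' @export
transform_from_flat <- function(flat, direction = "unspecified",
                                warn_tol = 1e-3) {
  if (length(flat) != 16L)
    stop(sprintf("expected 16 matrix values, got %d", length(flat)), call. = FALSE)
  if (!identical(as.numeric(flat[13:16]), c(0, 0, 0, 1)))
    stop("last row of the flattened matrix must be exactly 0/0/0/1", call. = FALSE)
  m <- matrix(as.numeric(flat), 4, 4, byrow = TRUE)
  homogeneous_transform(m[1:3, 1:3], m[1:3, 4], direction = direction,
                        warn_tol = warn_tol)
}

#' Build the nominal ground-truth transform for a rigid test case
#'
#' Constructs the direct moving-to-stationary matrix for a known shift and
#' rotation: rotations are applied first (composed per [compose_rotations()]),
#' followed by the translation, whose column is the LPS displacement of the
#' shifted dataset. Invert with [invert_transform()] to obtain the
#' target-to-moving matrix comparable with a registration object.
#'
#' @param spec a [rotation_spec()].
#' @param shift a [patient_shift()].
#' @param order rotation composition order, see [compose_rotations()].
#' @return a `homogeneous_transform` tagged `moving_to_stationary`.
#' @examples
#' nominal <- build_nominal_transform(
#'   rotation_spec(x = -5, y = 8, z = 10),
#'   patient_shift(c(5, 15, 20), c("Lt", "Ant", "Sup"), "stationary"))
#' transform_translation(invert_transform(nominal))
#' @export
build_nominal_transform <- function(spec, shift, order = "zyx") {
  homogeneous_transform(compose_rotations(spec, order = order),
                        patient_shift_to_dicom(shift),
                        direction = "moving_to_stationary")
}

#' Invert a rigid transform
#'
#' For an orthonormal rotation block the exact inverse is
#' \eqn{(R^\top, -R^\top T)}; for slightly non-orthonormal matrices read from
#' rounded files the full 4x4 inverse is used. The direction tag is flipped.
#'
#' @param t a [homogeneous_transform()].
#' @return the inverse `homogeneous_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "homogeneous_transform"))
  r <- transform_rotation(t)
  tr <- t$matrix[1:3, 4]
  if (.rotation_defect(r) <= 1e-9) {
    rinv <- t(r)
    tinv <- -rinv %*% tr
  } else {
    mi <- tryCatch(solve(t$matrix),
                   error = function(e) stop("transform matrix is singular", call. = FALSE))
    rinv <- mi[1:3, 1:3]
    tinv <- mi[1:3, 4]
  }
  flipped <- switch(t$direction,
                    moving_to_stationary = "target_to_moving",
                    target_to_moving = "moving_to_stationary",
                    "unspecified")
  homogeneous_transform(rinv, tinv, direction = flipped)
}

#' Apply a rigid transform to points
#'
#' @param t a [homogeneous_transform()].
#' @param p a length-3 point or an n x 3 matrix of points (mm).
#' @return mapped point(s), same shape as `p`.
#' @export
transform_point <- function(t, p) {
  stopifnot(inherits(t, "homogeneous_transform"))
  r <- transform_rotation(t)
  tr <- t$matrix[1:3, 4]
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    sweep(p %*% t(r), 2, tr, `+`)
  } else {
    as.numeric(r %*% .check_vec3(p, "point") + tr)
  }
}

#' Per-axis translation errors of a reported registration
#'
#' The registration error along each cardinal axis is the difference between
#' the translation column reported by the software and the known nominal
#' vector, both expressed in the target-to-moving direction. These per-axis
#' errors are what the half-voxel criterion compares against.
#'
#' @param reported a `homogeneous_transform` read from the registration
#'   object (direction `target_to_moving` or `unspecified`).
#' @param known numeric length-3 nominal T (mm), e.g. from
#'   [expected_translation()] or `transform_translation(invert_transform(...))`.
#' @return numeric length-3 per-axis errors (mm), named `x`, `y`, `z`.
#' @export
translation_errors <- function(reported, known) {
  stopifnot(inherits(reported, "homogeneous_transform"))
  if (reported$direction == "moving_to_stationary")
    stop("reported transform must be in the target-to-moving direction; ",
         "invert it first", call. = FALSE)
  known <- .check_vec3(known, "known translation")
  stats::setNames(transform_translation(reported) - known, c("x", "y", "z"))
}

# ---- rotation axis analysis -------------------------------------------------

#' Axis of a composite rotation
#'
#' A 3x3 rotation matrix has one real eigenvector (eigenvalue +1): the axis
#' about which the composite rotation takes place, the only line left
#' unchanged. Comparing the nominal and reported axes quantifies overall
#' angular misalignment without a (degenerate) per-axis decomposition.
#'
#' The sign of an eigenvector is solver-dependent; the result is canonicalized
#' so that its largest-magnitude component is positive. Compare axes with
#' [axis_misalignment()], which is sign-invariant. For the identity (rotation
#' angle 0) the axis is undefined: the result is `NA` with attribute
#' `degenerate = TRUE`.
#'
#' @param r a 3x3 rotation matrix (approximately orthonormal; file-read
#'   rounding is tolerated).
#' @return unit length-3 axis vector, or `NA`s flagged `degenerate` for a
#'   (numerically) zero rotation angle.
#' @examples
#' rotation_axis(rotation_about_axis("z", 10))  # (0, 0, 1)
#' @export
rotation_axis <- function(r) {
  r <- .check_rotation(r, warn_tol = 1e-2)
  # rotation angle from the trace; undefined axis at angle ~ 0
  ctheta <- (sum(diag(r)) - 1) / 2
  theta <- acos(min(1, max(-1, ctheta)))
  if (theta < 1e-9)
    return(structure(rep(NA_real_, 3), degenerate = TRUE))
  e <- eigen(r)
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Angle between two rotation axes
#'
#' Misalignment between the expected and achieved rotation axes, from the dot
#' product of the unit eigenvectors. The absolute value of the cosine is used
#' so the solver-dependent eigenvector sign cannot flip the answer; the result
#' lies in [0, 90] degrees. A degenerate axis (flagged by [rotation_axis()]
#' for a zero rotation) compares as 0 degrees with a warning, so an identity
#' registration does not fail QA.
#'
#' @param u,v unit length-3 axis vectors (or degenerate-flagged results).
#' @return misalignment angle in degrees.
#' @export
axis_misalignment <- function(u, v) {
  if (isTRUE(attr(u, "degenerate")) || isTRUE(attr(v, "degenerate"))) {
    warning("degenerate rotation axis (zero rotation angle); misalignment reported as 0",
            call. = FALSE)
    return(0)
  }
  u <- .check_vec3(u, "axis u"); v <- .check_vec3(v, "axis v")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("rotation axis has zero length", call. = FALSE)
  cang <- abs(sum(u * v)) / (nu * nv)
  .rad2deg(acos(min(1, cang)))
}

#' Half-voxel tolerance check for per-axis translation errors
#'
#' The commissioning tolerance for rigid registration: the error along each
#' cardinal axis should not exceed half the image voxel dimension along that
#' axis. The boundary is inclusive -- an error exactly equal to half a voxel
#' passes.
#'
#' @param errors numeric length-3 per-axis errors (mm), e.g. from
#'   [translation_errors()].
#' @param voxel numeric length-3 voxel dimensions (mm), all positive.
#' @return named logical vector (`x`, `y`, `z`), `TRUE` = pass.
#' @export
half_voxel_check <- function(errors, voxel) {
  errors <- .check_vec3(errors, "errors")
  voxel <- .check_vec3(voxel, "voxel dimensions")
  if (any(voxel <= 0)) stop("voxel dimensions must be positive", call. = FALSE)
  stats::setNames(abs(errors) <= voxel / 2, c("x", "y", "z"))
}

# Rodrigues axis-angle rotation; used by the fixture generator to inject
# rotation errors with an exactly known axis tilt.
.rotation_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  t <- .deg2rad(angle_deg)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}
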