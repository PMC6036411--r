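# Seeded synthetic fixtures with exact ground truth. These stand in for the
# commissioning phantom datasets: every bundle records, in a manifest, the
# values the QA pipeline is expected to recover, so the fixture suite is
# self-verifying and needs no external data.

.bundle <- function(kind, seed, dir, files, manifest) {
  manifest$kind <- kind
  manifest$seed <- seed
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(kind = kind, seed = seed, dir = dir,
                 files = files, manifest = manifest),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("Fixture bundle '%s' (seed %d) in %s\n", x$kind, x$seed, x$dir))
  cat("  files:", paste(basename(unlist(x$files)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a rigid registration test fixture
#'
#' Emulates one rigid commissioning case: a phantom shifted (and optionally
#' rotated) by known amounts, registered by software that reports a
#' target-to-moving transform. The bundle contains the nominal
#' moving-to-stationary transform, a "reported" registration file equal to
#' the inverted nominal composed with an injected error (zero by default),
#' and a manifest of the values QA should recover: the expected T, the
#' injected per-axis translation errors, and the injected axis tilt.
#'
#' The rotation error is injected by tilting the nominal rotation axis by
#' exactly `injected_axis_tilt_deg` (rotating the axis about a perpendicular
#' direction), so [axis_misalignment()] must recover that angle exactly.
#'
#' @param seed integer seed (recorded in the manifest).
#' @param shift a [patient_shift()].
#' @param spec a [rotation_spec()] (default: no rotation).
#' @param injected_translation_error length-3 per-axis error (mm) added to
#'   the reported translation.
#' @param injected_axis_tilt_deg rotation-axis tilt (degrees) applied to the
#'   reported rotation; requires a non-zero nominal rotation.
#' @param dir output directory (created; default a fresh tempdir).
#' @return a `fixture_bundle` with `$files$nominal`, `$files$reported` and
#'   `$manifest`.
#' @export
gen_rigid_case <- function(seed, shift, spec = rotation_spec(),
                           injected_translation_error = c(0, 0, 0),
                           injected_axis_tilt_deg = 0,
                           dir = tempfile("rigid_case_")) {
  stopifnot(inherits(shift, "patient_shift"), inherits(spec, "rotation_spec"))
  err_t <- .check_vec3(injected_translation_error, "injected translation error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  nominal <- build_nominal_transform(spec, shift)
  truth <- invert_transform(nominal)            # target -> moving, as reported
  expected_T <- transform_translation(truth)

  rep_rot <- transform_rotation(truth)
  axis_nominal <- rotation_axis(rep_rot)
  if (injected_axis_tilt_deg != 0) {
    if (isTRUE(attr(axis_nominal, "degenerate")))
      stop("cannot tilt the rotation axis of an identity rotation", call. = FALSE)
    # tilt the axis by exactly the requested angle about a random
    # perpendicular direction, preserving the rotation angle
    u <- axis_nominal
    r <- stats::rnorm(3)
    perp <- r - sum(r * u) * u
    perp <- perp / sqrt(sum(perp^2))
    tilt <- .rotation_from_axis_angle(perp, injected_axis_tilt_deg)
    theta <- .rad2deg(acos(min(1, max(-1, (sum(diag(rep_rot)) - 1) / 2))))
    # preserve the sign of the rotation about the axis
    skew <- c(rep_rot[3, 2] - rep_rot[2, 3],
              rep_rot[1, 3] - rep_rot[3, 1],
              rep_rot[2, 1] - rep_rot[1, 2])
    if (sum(skew * u) < 0) theta <- -theta
    rep_rot <- .rotation_from_axis_angle(as.numeric(tilt %*% u), theta)
  }
  reported <- homogeneous_transform(rep_rot, expected_T + err_t,
                                    direction = "target_to_moving")

  f_nom <- file.path(dir, "nominal_reg.txt")
  f_rep <- file.path(dir, "reported_reg.txt")
  write_rigid_reg(nominal, f_nom, frame_of_reference = "regqa-synthetic-nominal")
  write_rigid_reg(reported, f_rep, frame_of_reference = "regqa-synthetic-reported")

  manifest <- list(
    shift = list(magnitudes = shift$magnitudes, directions = shift$directions,
                 shifted = shift$shifted),
    rotations_deg = as.list(spec$angles),
    expected_T = as.numeric(expected_T),
    expected_translation_errors = err_t,
    expected_axis_misalignment_deg = injected_axis_tilt_deg,
    nominal_file = basename(f_nom), reported_file = basename(f_rep))
  .bundle("rigid", seed, dir, list(nominal = f_nom, reported = f_rep), manifest)
}

# analytic displacement fields ------------------------------------------------

.field_fun <- function(field, params) {
  switch(field,
    zero = list(
      fun = function(p) matrix(0, nrow(p), 3),
      bound = function(spacing) 0),
    affine = list(
      # d(p) = A p + b, componentwise linear: trilinear reproduces it exactly
      fun = function(p) sweep(p %*% t(params$A), 2, params$b, `+`),
      bound = function(spacing) 0),
    gaussian_bump = list(
      # d_c(p) = amp_c * exp(-|p - center|^2 / (2 sigma^2))
      fun = function(p) {
        r2 <- rowSums(sweep(p, 2, params$center, `-`)^2)
        outer(exp(-r2 / (2 * params$sigma^2)), params$amp)
      },
      # conservative trilinear error bound: per component
      # |f - interp| <= (1/8) sum_i h_i^2 max|d2f/dx_i^2|, and for a Gaussian
      # max|d2/dx2| <= amp / sigma^2 (attained at the center)
      bound = function(spacing) {
        per_comp <- abs(params$amp) * sum(spacing^2) / (8 * params$sigma^2)
        sqrt(sum(per_comp^2))
      }),
    sinusoid = list(
      # d_c(p) = amp_c * sin(2 pi p . k_c / wavelength)
      fun = function(p) {
        phase <- 2 * pi * (p %*% t(params$k)) / params$wavelength
        sweep(sin(phase), 2, params$amp, `*`)
      },
      bound = function(spacing) {
        w2 <- (2 * pi / params$wavelength)^2
        per_comp <- vapply(seq_len(3), function(c_) {
          abs(params$amp[c_]) * w2 * sum(params$k[c_, ]^2 * spacing^2) / 8
        }, numeric(1))
        sqrt(sum(per_comp^2))
      }),
    stop("unknown field family: ", field, call. = FALSE))
}

#' Generate a deformable (DVF + landmarks) test fixture
#'
#' Builds a DVF by sampling an analytic displacement field at voxel centers,
#' draws seeded landmarks strictly inside the grid hull, and records their
#' exact analytically-mapped positions plus a conservative trilinear
#' interpolation-error bound in the manifest. For the `affine` family the
#' bound is zero (trilinear interpolation reproduces componentwise-linear
#' fields exactly), so TRE against the manifest positions must vanish to
#' numerical precision.
#'
#' @param seed integer seed.
#' @param field one of `"zero"`, `"affine"`, `"gaussian_bump"`, `"sinusoid"`.
#' @param params field parameters: for `affine`, `A` (3x3) and `b`
#'   (length 3, mm); for `gaussian_bump`, `amp` (length 3, mm), `center`
#'   (mm) and `sigma` (mm); for `sinusoid`, `amp` (mm), `k` (3x3 integer
#'   direction matrix, rows per component) and `wavelength` (mm). Defaults
#'   give mild, realistic deformations.
#' @param origin,spacing,dims DVF grid geometry.
#' @param n_landmarks number of landmark pairs.
#' @param dir output directory.
#' @return a `fixture_bundle` with a DVF file, fixed/moving landmark files
#'   and a manifest carrying the interpolation bound.
#' @export
gen_dvf_case <- function(seed, field = c("affine", "gaussian_bump", "sinusoid", "zero"),
                         params = NULL,
                         origin = c(-100, -100, -75), spacing = c(2, 2, 2.5),
                         dims = c(101L, 101L, 61L), n_landmarks = 100L,
                         dir = tempfile("dvf_case_")) {
  field <- match.arg(field)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  if (is.null(params)) {
    params <- switch(field,
      zero = list(),
      affine = list(A = matrix(stats::runif(9, -0.02, 0.02), 3),
                    b = stats::runif(3, -5, 5)),
      gaussian_bump = list(amp = c(0, 0, 8), sigma = 30,
                           center = origin + (dims - 1) * spacing / 2),
      sinusoid = list(amp = c(2, 2, 4), k = diag(3), wavelength = 150))
  }
  ff <- .field_fun(field, params)

  centers <- dvf_voxel_centers(dvf_grid(origin, spacing, dims,
                                        matrix(0, prod(dims), 3)))
  g <- dvf_grid(origin, spacing, dims, ff$fun(centers))

  # landmarks strictly inside the hull (margin of one voxel)
  lo <- origin + spacing
  hi <- origin + (dims - 2) * spacing
  fixed <- cbind(stats::runif(n_landmarks, lo[1], hi[1]),
                 stats::runif(n_landmarks, lo[2], hi[2]),
                 stats::runif(n_landmarks, lo[3], hi[3]))
  moving <- fixed + ff$fun(fixed)

  f_dvf <- file.path(dir, "dvf_reg.bin")
  f_fix <- file.path(dir, "landmarks_fixed.txt")
  f_mov <- file.path(dir, "landmarks_moving.txt")
  write_deformable_reg(deformable_reg_record(g), f_dvf)
  write_landmarks(fixed, f_fix)
  write_landmarks(moving, f_mov)

  manifest <- list(
    field = field,
    interpolation_bound_mm = ff$bound(spacing),
    # float32 serialization adds relative rounding of 2^-24 on displacements
    serialization_eps_mm = max(abs(g$displacements)) * 2^-23,
    n_landmarks = n_landmarks,
    grid = list(origin = origin, spacing = spacing, dims = dims),
    dvf_file = basename(f_dvf), fixed_file = basename(f_fix),
    moving_file = basename(f_mov))
  .bundle("dvf", seed, dir,
          list(dvf = f_dvf, fixed = f_fix, moving = f_mov), manifest)
}

# mask rasterization -----------------------------------------------------------

.rasterize <- function(origin, spacing, dims, inside_fun, name) {
  centers <- dvf_voxel_centers(dvf_grid(origin, spacing, dims,
                                        matrix(0, prod(dims), 3)))
  occ <- array(inside_fun(centers), dim = dims)
  mask_volume(occ, origin, spacing, name = name)
}

#' Rasterize a sphere into a mask volume
#'
#' Voxel-center-inside occupancy rule: a voxel belongs to the structure iff
#' its center lies inside the analytic surface.
#'
#' @param center,radius sphere geometry (mm).
#' @param origin,spacing,dims grid geometry.
#' @param name structure name.
#' @return a [mask_volume()].
#' @export
rasterize_sphere <- function(center, radius, origin, spacing, dims,
                             name = "sphere") {
  center <- .check_vec3(center, "center")
  .rasterize(origin, spacing, dims,
             function(p) rowSums(sweep(p, 2, center, `-`)^2) < radius^2, name)
}

#' Rasterize an axis-aligned box into a mask volume
#' @param lower,upper opposite box corners (mm).
#' @param origin,spacing,dims grid geometry.
#' @param name structure name.
#' @return a [mask_volume()].
#' @export
rasterize_box <- function(lower, upper, origin, spacing, dims, name = "box") {
  lower <- .check_vec3(lower, "lower"); upper <- .check_vec3(upper, "upper")
  .rasterize(origin, spacing, dims, function(p) {
    p[, 1] >= lower[1] & p[, 1] < upper[1] &
    p[, 2] >= lower[2] & p[, 2] < upper[2] &
    p[, 3] >= lower[3] & p[, 3] < upper[3]
  }, name)
}

# closed-form sphere-sphere intersection (lens) volume
.lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

#' Generate a mask-pair fixture with closed-form overlap
#'
#' Emulates a contour-comparison case: two structures rasterized on one
#' common grid, with the analytic volumes, overlap and Dice coefficient in
#' the manifest. Boxes with corners commensurate with the voxel lattice
#' rasterize exactly; spheres carry a voxelization tolerance of order one
#' voxel of surface shell.
#'
#' @param seed integer seed (recorded; shapes are deterministic given the
#'   geometry parameters).
#' @param shapes `"spheres"` or `"boxes"`.
#' @param params for spheres: `center1`, `center2`, `r1`, `r2` (mm); for
#'   boxes: `lower1`, `upper1`, `lower2`, `upper2` (mm).
#' @param voxel scalar or length-3 voxel size (mm).
#' @param margin padding around the shapes (mm).
#' @param dir output directory.
#' @return a `fixture_bundle` with two NRRD mask files and a manifest holding
#'   `dsc_analytic` and the voxelization tolerance.
#' @export
gen_mask_pair <- function(seed, shapes = c("spheres", "boxes"), params = NULL,
                          voxel = 0.05, margin = NULL,
                          dir = tempfile("mask_case_")) {
  shapes <- match.arg(shapes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  voxel <- if (length(voxel) == 1L) rep(voxel, 3) else .check_vec3(voxel, "voxel")
  if (is.null(params)) {
    params <- if (shapes == "spheres")
      list(center1 = c(0, 0, 0), center2 = c(1, 0, 0), r1 = 1, r2 = 1)
    else
      list(lower1 = c(0, 0, 0), upper1 = c(1, 1, 1),
           lower2 = c(0.5, 0, 0), upper2 = c(1.5, 1, 1))
  }
  if (is.null(margin)) margin <- 2 * max(voxel)

  if (shapes == "spheres") {
    lo <- pmin(params$center1 - params$r1, params$center2 - params$r2) - margin
    hi <- pmax(params$center1 + params$r1, params$center2 + params$r2) + margin
    dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
    origin <- lo
    m1 <- rasterize_sphere(params$center1, params$r1, origin, voxel, dims, "sphere1")
    m2 <- rasterize_sphere(params$center2, params$r2, origin, voxel, dims, "sphere2")
    v1 <- 4 / 3 * pi * params$r1^3 / 1000
    v2 <- 4 / 3 * pi * params$r2^3 / 1000
    d <- sqrt(sum((params$center2 - params$center1)^2))
    vab <- .lens_volume(params$r1, params$r2, d) / 1000
    # surface-shell voxelization tolerance: one voxel-diagonal shell around
    # each sphere surface, relative to the sphere volume
    tol <- 4 * pi * max(params$r1, params$r2)^2 * sqrt(sum(voxel^2)) / 1000 /
      max(v1, v2)
  } else {
    lo <- pmin(params$lower1, params$lower2) - margin
    hi <- pmax(params$upper1, params$upper2) + margin
    # snap the origin onto the corner lattice so commensurate boxes are exact:
    # place voxel centers at corner + (n + 1/2) * voxel
    origin <- params$lower1 - voxel * (ceiling((params$lower1 - lo) / voxel) - 0.5)
    dims <- as.integer(ceiling((hi - origin) / voxel)) + 1L
    m1 <- rasterize_box(params$lower1, params$upper1, origin, voxel, dims, "box1")
    m2 <- rasterize_box(params$lower2, params$upper2, origin, voxel, dims, "box2")
    v1 <- prod(params$upper1 - params$lower1) / 1000
    v2 <- prod(params$upper2 - params$lower2) / 1000
    ov <- pmax(pmin(params$upper1, params$upper2) -
               pmax(params$lower1, params$lower2), 0)
    vab <- prod(ov) / 1000
    tol <- 0
  }
  dsc <- if (v1 + v2 > 0) 2 * vab / (v1 + v2) else NA_real_

  f1 <- file.path(dir, "mask_deformed.nrrd")
  f2 <- file.path(dir, "mask_target.nrrd")
  write_mask(m1, f1)
  write_mask(m2, f2)
  manifest <- list(
    shapes = shapes, voxel = voxel,
    volume1_cc = v1, volume2_cc = v2, overlap_cc = vab,
    dsc_analytic = dsc, dsc_tolerance = tol,
    deformed_file = basename(f1), target_file = basename(f2))
  .bundle("mask", seed, dir, list(deformed = f1, target = f2), manifest)
}
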