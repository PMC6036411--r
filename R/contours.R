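# Contour-propagation scoring: structure volumes and the Dice similarity
# coefficient DSC = 2|A n B| / (|A| + |B|) on binary masks sharing one grid.

#' Binary structure mask on a regular grid
#'
#' @param occupancy 3-D logical (or 0/1) array of voxel occupancy.
#' @param origin length-3 position of the first voxel center (LPS mm).
#' @param spacing length-3 positive voxel spacing (mm).
#' @param name structure name.
#' @return an object of class `mask_volume`.
#' @export
mask_volume <- function(occupancy, origin, spacing, name = "structure") {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3-D array", call. = FALSE)
  if (anyNA(occupancy)) stop("occupancy must not contain NA", call. = FALSE)
  storage.mode(occupancy) <- "logical"
  origin <- .check_vec3(origin, "origin")
  spacing <- .check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(occupancy = occupancy, origin = origin, spacing = spacing,
                 name = as.character(name)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("Mask '%s': grid %s, spacing (%s) mm, volume %.3f cc\n",
              x$name, paste(dim(x$occupancy), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), volume(x)))
  invisible(x)
}

#' Structure volume in cubic centimetres
#'
#' Occupied-voxel count times the voxel volume, converted from cubic mm to
#' cc.
#'
#' @param m a [mask_volume()].
#' @param ... unused.
#' @return volume in cc.
#' @export
volume <- function(m, ...) UseMethod("volume")

#' @export
volume.mask_volume <- function(m, ...) {
  sum(m$occupancy) * prod(m$spacing) / 1000
}

#' Dice similarity coefficient from three volumes
#'
#' `DSC = 2 V_AB / (V_A + V_B)` where `V_A`, `V_B` are the volumes of the
#' deformed and target structures and `V_AB` their overlap. This is the form
#' a physicist can evaluate from the volume read-outs of any planning system,
#' without voxel access.
#'
#' @param va,vb structure volumes (cc), non-negative.
#' @param vab overlap volume (cc), at most `min(va, vb)` (a relative slack of
#'   1e-9 absorbs floating-point jitter).
#' @return the Dice coefficient in [0, 1].
#' @examples
#' dice_from_volumes(34.2, 33.2, 31.3)  # 0.929
#' @export
dice_from_volumes <- function(va, vb, vab) {
  if (any(!is.finite(c(va, vb, vab))) || va < 0 || vb < 0 || vab < 0)
    stop("volumes must be finite and non-negative", call. = FALSE)
  if (va + vb == 0)
    stop("DSC undefined: both volumes are zero", call. = FALSE)
  if (vab > min(va, vb) * (1 + 1e-9) + 1e-12)
    stop(sprintf("inconsistent volumes: overlap %.6g exceeds min(%.6g, %.6g)",
                 vab, va, vb), call. = FALSE)
  2 * vab / (va + vb)
}

#' Compare two structure masks
#'
#' Computes the deformed and target volumes, their voxelwise overlap volume,
#' and the Dice coefficient. The two masks must live on the identical grid:
#' no implicit resampling is performed, because a resampling policy would
#' silently change the DSC.
#'
#' @param deformed a [mask_volume()]: the structure propagated from the
#'   moving dataset.
#' @param target a [mask_volume()]: the structure drawn on the target
#'   dataset.
#' @param name comparison label (default: the deformed mask's name).
#' @return a one-row data.frame of class `structure_comparison` with columns
#'   `name`, `dsc`, `volume_deformed_cc`, `volume_target_cc`,
#'   `common_volume_cc`.
#' @export
dice_from_masks <- function(deformed, target, name = NULL) {
  stopifnot(inherits(deformed, "mask_volume"), inherits(target, "mask_volume"))
  same_geom <- identical(dim(deformed$occupancy), dim(target$occupancy)) &&
    max(abs(deformed$origin - target$origin)) <= 1e-9 &&
    max(abs(deformed$spacing - target$spacing)) <= 1e-9
  if (!same_geom)
    stop("mask grids differ (dims/origin/spacing); masks must be produced ",
         "on a common grid upstream", call. = FALSE)
  va <- volume(deformed)
  vb <- volume(target)
  vab <- sum(deformed$occupancy & target$occupancy) * prod(deformed$spacing) / 1000
  out <- data.frame(name = if (is.null(name)) deformed$name else name,
                    dsc = dice_from_volumes(va, vb, vab),
                    volume_deformed_cc = va, volume_target_cc = vb,
                    common_volume_cc = vab, stringsAsFactors = FALSE)
  class(out) <- c("structure_comparison", "data.frame")
  out
}

#' Direction-consistency of contour propagation
#'
#' A well-behaved deformable registration should score similarly when run
#' source-to-target and target-to-source. Given per-structure comparisons for
#' the two directions, reports the per-structure DSC difference
#' (forward minus backward) and the largest absolute difference.
#'
#' @param fwd,bwd `structure_comparison` rows (or data.frames with columns
#'   `name` and `dsc`) for the forward and reverse registrations. Structures
#'   are matched by name; unmatched names are excluded with a warning.
#' @return a list of class `direction_consistency`: data.frame `deltas`
#'   (`name`, `dsc_fwd`, `dsc_bwd`, `delta`) and `max_abs_delta`.
#' @export
direction_consistency <- function(fwd, bwd) {
  fwd <- as.data.frame(fwd); bwd <- as.data.frame(bwd)
  stopifnot(all(c("name", "dsc") %in% names(fwd)),
            all(c("name", "dsc") %in% names(bwd)))
  common <- intersect(fwd$name, bwd$name)
  missing <- union(setdiff(fwd$name, bwd$name), setdiff(bwd$name, fwd$name))
  if (length(missing) > 0)
    warning("structures without a match in both directions excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
  if (length(common) == 0) stop("no matched structure names", call. = FALSE)
  df <- data.frame(name = common,
                   dsc_fwd = fwd$dsc[match(common, fwd$name)],
                   dsc_bwd = bwd$dsc[match(common, bwd$name)],
                   stringsAsFactors = FALSE)
  df$delta <- df$dsc_fwd - df$dsc_bwd
  structure(list(deltas = df, max_abs_delta = max(abs(df$delta))),
            class = "direction_consistency")
}

#' @export
print.direction_consistency <- function(x, ...) {
  cat("Direction consistency (DSC forward - backward):\n")
  print(transform(x$deltas, delta = round(delta, 3)), row.names = FALSE)
  cat(sprintf("  max |delta| = %.3f\n", x$max_abs_delta))
  invisible(x)
}

#' Band a Dice coefficient against the commissioning tolerance
#'
#' The accepted range for contour-propagation DSC is 0.8 to 0.9: values
#' below the lower edge fail, values within the band are acceptable, values
#' above it are good.
#'
#' @param dsc Dice coefficient in [0, 1] (vectorized).
#' @param bands length-2 increasing band edges (default `c(0.8, 0.9)`).
#' @return character vector of `"fail"`, `"acceptable"`, `"good"`.
#' @export
dsc_tolerance_check <- function(dsc, bands = c(0.8, 0.9)) {
  if (length(bands) != 2L || bands[1] >= bands[2] || any(bands <= 0))
    stop("bands must be two increasing positive edges", call. = FALSE)
  if (any(!is.finite(dsc)) || any(dsc < 0) || any(dsc > 1))
    stop("dsc must lie in [0, 1]", call. = FALSE)
  ifelse(dsc < bands[1], "fail", ifelse(dsc <= bands[2], "acceptable", "good"))
}
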