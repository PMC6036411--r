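# QA report assembly: declarative configs in, structured pass/fail reports
# out. Every verdict in a report can be recomputed from the metrics stored
# alongside it.

#' Tolerance specification for a QA run
#'
#' Defaults are the commissioning-report values: per-axis rigid error within
#' half a voxel, mean TRE below 2 mm and maximum below 5 mm, Dice bands at
#' 0.8 and 0.9. All thresholds are overridable per run and are recorded in
#' the report.
#'
#' @param half_voxel optional length-3 voxel dimensions (mm) for the
#'   half-voxel criterion.
#' @param tre_mean_max,tre_max mean / maximum TRE thresholds (mm).
#' @param dsc_bands length-2 increasing Dice band edges.
#' @return an object of class `tolerance_spec`.
#' @export
tolerance_spec <- function(half_voxel = NULL, tre_mean_max = 2, tre_max = 5,
                           dsc_bands = c(0.8, 0.9)) {
  if (!is.null(half_voxel)) {
    half_voxel <- .check_vec3(half_voxel, "half_voxel")
    if (any(half_voxel <= 0)) stop("voxel dimensions must be positive", call. = FALSE)
  }
  if (tre_mean_max <= 0 || tre_max <= 0) stop("TRE thresholds must be positive", call. = FALSE)
  if (length(dsc_bands) != 2L || dsc_bands[1] >= dsc_bands[2])
    stop("dsc_bands must be two increasing edges", call. = FALSE)
  structure(list(half_voxel = half_voxel, tre_mean_max = tre_mean_max,
                 tre_max = tre_max, dsc_bands = dsc_bands),
            class = "tolerance_spec")
}

.qa_report <- function(test_id, check, inputs, metrics, verdicts, tolerances) {
  structure(list(test_id = test_id, check = check, inputs = inputs,
                 metrics = metrics, verdicts = verdicts,
                 tolerances = tolerances,
                 tool_version = as.character(utils::packageVersion("regqa"))),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("QA report [%s] case %s (regqa %s)\n", x$check,
              x$test_id, x$tool_version))
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    if (is.numeric(v) && length(v) <= 3)
      cat(sprintf("  %-28s %s\n", nm, paste(round(v, 4), collapse = ", ")))
  }
  for (nm in names(x$verdicts)) {
    v <- x$verdicts[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.logical(v)) paste(ifelse(v, "pass", "FAIL"), collapse = ", ")
                else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a QA report
#'
#' @param report a `qa_report`.
#' @param file output path; format from extension (`.json` or `.csv`) unless
#'   given explicitly.
#' @param format `"json"` (full structure) or `"csv"` (flat metric/verdict
#'   table).
#' @return `file`, invisibly.
#' @export
write_qa_report <- function(report, file, format = NULL) {
  stopifnot(inherits(report, "qa_report"))
  if (is.null(format))
    format <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    flat <- c(report$metrics, report$verdicts)
    keep <- vapply(flat, function(v) is.atomic(v) && length(v) <= 3, logical(1))
    flat <- flat[keep]
    rows <- do.call(rbind, lapply(names(flat), function(nm) {
      data.frame(test_id = report$test_id, check = report$check, quantity = nm,
                 value = paste(format(flat[[nm]]), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, file, row.names = FALSE)
  }
  invisible(file)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a list or a YAML/JSON file path", call. = FALSE)
}

.shift_from_config <- function(cfg) {
  patient_shift(as.numeric(cfg$magnitudes), as.character(cfg$directions),
                shifted = if (is.null(cfg$shifted)) "stationary" else cfg$shifted)
}

.rotation_from_config <- function(cfg) {
  if (is.null(cfg)) rotation_spec()
  else rotation_spec(x = if (is.null(cfg$x)) 0 else cfg$x,
                     y = if (is.null(cfg$y)) 0 else cfg$y,
                     z = if (is.null(cfg$z)) 0 else cfg$z)
}

#' Run a rigid registration QA check
#'
#' End-to-end rigid check: read the reported registration object, build the
#' nominal transform from the known shift/rotations, invert it into the
#' reported (target-to-moving) direction, difference the translations, apply
#' the half-voxel criterion, and -- when rotations are present -- measure the
#' rotation-axis misalignment in degrees.
#'
#' @param config a list or YAML/JSON path with fields: `reg_file` (path),
#'   `shift` (list with `magnitudes`, `directions`, optional `shifted`),
#'   optional `rotations` (list with `x`, `y`, `z` degrees), optional `voxel`
#'   (length-3 mm, enables the half-voxel verdict), optional `case_id`.
#' @param tolerances a [tolerance_spec()]; its `half_voxel` is used when the
#'   config has no `voxel`.
#' @return a `qa_report` with known T, reported T, per-axis errors, half-voxel
#'   verdicts and axis misalignment.
#' @export
run_rigid_check <- function(config, tolerances = tolerance_spec()) {
  cfg <- .load_config(config)
  stopifnot(!is.null(cfg$reg_file), !is.null(cfg$shift))
  shift <- .shift_from_config(cfg$shift)
  spec <- .rotation_from_config(cfg$rotations)
  rec <- read_rigid_reg(cfg$reg_file)

  nominal <- build_nominal_transform(spec, shift)
  truth <- invert_transform(nominal)
  known_T <- transform_translation(truth)
  reported_T <- transform_translation(rec$transform)
  errors <- translation_errors(rec$transform, known_T)

  has_rotation <- any(spec$angles != 0)
  misalign <- NA_real_
  if (has_rotation) {
    axis_known <- rotation_axis(transform_rotation(truth))
    axis_rep <- rotation_axis(transform_rotation(rec$transform))
    misalign <- axis_misalignment(axis_known, axis_rep)
  }

  voxel <- if (!is.null(cfg$voxel)) as.numeric(cfg$voxel) else tolerances$half_voxel
  verdicts <- list()
  if (!is.null(voxel)) {
    hv <- half_voxel_check(errors, voxel)
    verdicts$half_voxel_pass <- as.logical(hv)
    verdicts$all_axes_pass <- all(hv)
  }
  .qa_report(
    test_id = if (is.null(cfg$case_id)) "rigid" else cfg$case_id,
    check = "rigid-check",
    inputs = list(reg_file = cfg$reg_file, parse_mode = rec$parse_mode,
                  shift = cfg$shift, rotations = cfg$rotations, voxel = voxel),
    metrics = list(known_T_mm = as.numeric(known_T),
                   reported_T_mm = as.numeric(reported_T),
                   translation_errors_mm = as.numeric(errors),
                   axis_misalignment_deg = misalign),
    verdicts = verdicts,
    tolerances = unclass(tolerances))
}

#' Run a landmark TRE QA check
#'
#' Reads a registration (rigid or deformable) and two landmark files, maps
#' the fixed-frame landmarks through the registration, and scores the TRE
#' statistics against the mean/max tolerances.
#'
#' @param config a list or YAML/JSON path with fields: `reg_file`, `reg_type`
#'   (`"rigid"` or `"deformable"`), `landmarks_fixed`, `landmarks_moving`,
#'   `dialect` (`"mm"` or `"index"`; index needs `origin`, `spacing` and
#'   optionally `index_base`), optional `case_id`, optional
#'   `omit_unmappable`.
#' @param tolerances a [tolerance_spec()].
#' @return a `qa_report`; `$metrics$per_point` holds the per-point table.
#' @export
run_tre <- function(config, tolerances = tolerance_spec()) {
  cfg <- .load_config(config)
  stopifnot(!is.null(cfg$reg_file), !is.null(cfg$landmarks_fixed),
            !is.null(cfg$landmarks_moving))
  reg_type <- if (is.null(cfg$reg_type)) "deformable" else cfg$reg_type
  mapping <- if (reg_type == "rigid") read_rigid_reg(cfg$reg_file)
             else read_deformable_reg(cfg$reg_file)
  dialect <- if (is.null(cfg$dialect)) "mm" else cfg$dialect
  lm_args <- list(dialect = dialect)
  if (dialect == "index") {
    lm_args$origin <- as.numeric(cfg$origin)
    lm_args$spacing <- as.numeric(cfg$spacing)
    lm_args$index_base <- if (is.null(cfg$index_base)) 0 else cfg$index_base
  }
  fixed <- do.call(read_landmarks, c(list(cfg$landmarks_fixed), lm_args))
  moving <- do.call(read_landmarks, c(list(cfg$landmarks_moving), lm_args))
  f <- fiducial_set(fixed, moving)
  stats <- compute_tre(f, mapping,
                       omit_unmappable = isTRUE(cfg$omit_unmappable))
  check <- tre_tolerance_check(stats, mean_tol = tolerances$tre_mean_max,
                               max_tol = tolerances$tre_max)
  .qa_report(
    test_id = if (is.null(cfg$case_id)) "tre" else cfg$case_id,
    check = "tre",
    inputs = list(reg_file = cfg$reg_file, reg_type = reg_type,
                  landmarks_fixed = cfg$landmarks_fixed,
                  landmarks_moving = cfg$landmarks_moving, dialect = dialect),
    metrics = list(n = stats$n, mean_tre_mm = stats$mean, sd_tre_mm = stats$sd,
                   max_tre_mm = stats$max,
                   axis_mean_delta_mm = as.numeric(stats$axis_means),
                   per_point = as.data.frame(stats)),
    verdicts = list(mean_pass = check$mean_pass, max_pass = check$max_pass,
                    pass = check$pass),
    tolerances = unclass(tolerances))
}

#' Run a contour Dice QA check
#'
#' Reads target and deformed structure masks (same grid), computes volumes,
#' overlap and Dice, and bands the Dice value against the tolerance.
#'
#' @param config a list or YAML/JSON path with fields: `target_mask`,
#'   `deformed_mask` (NRRD paths) or `pairs` (list of lists with `name`,
#'   `target_mask`, `deformed_mask`), optional `case_id`.
#' @param tolerances a [tolerance_spec()].
#' @return a `qa_report`; `$metrics$structures` is the per-structure table
#'   with the same columns as a commissioning contour-comparison table.
#' @export
run_dice <- function(config, tolerances = tolerance_spec()) {
  cfg <- .load_config(config)
  pairs <- if (!is.null(cfg$pairs)) cfg$pairs
           else list(list(name = NULL, target_mask = cfg$target_mask,
                          deformed_mask = cfg$deformed_mask))
  rows <- lapply(pairs, function(pr) {
    stopifnot(!is.null(pr$target_mask), !is.null(pr$deformed_mask))
    dice_from_masks(read_mask(pr$deformed_mask), read_mask(pr$target_mask),
                    name = pr$name)
  })
  tbl <- do.call(rbind, lapply(rows, as.data.frame))
  bands <- dsc_tolerance_check(tbl$dsc, bands = tolerances$dsc_bands)
  .qa_report(
    test_id = if (is.null(cfg$case_id)) "dice" else cfg$case_id,
    check = "dice",
    inputs = list(pairs = lapply(pairs, function(pr)
      list(name = pr$name, target_mask = pr$target_mask,
           deformed_mask = pr$deformed_mask))),
    metrics = list(structures = tbl,
                   dsc = tbl$dsc,
                   mean_dsc = mean(tbl$dsc)),
    verdicts = list(dsc_band = bands,
                    all_acceptable = all(bands != "fail")),
    tolerances = unclass(tolerances))
}
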