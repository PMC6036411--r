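# Target registration error: Euclidean distances between landmarks mapped
# from the target frame and their known positions in the moving frame.

#' Paired landmark (fiducial) set
#'
#' @param fixed n x 3 matrix of landmark positions in the target (stationary)
#'   frame, LPS mm.
#' @param moving n x 3 matrix of the corresponding known positions in the
#'   moving frame, LPS mm.
#' @param ids optional unique landmark identifiers (default `1..n`).
#' @return an object of class `fiducial_set`.
#' @export
fiducial_set <- function(fixed, moving, ids = NULL) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (ncol(fixed) != 3L || ncol(moving) != 3L)
    stop("landmark matrices must have 3 columns", call. = FALSE)
  if (nrow(fixed) != nrow(moving))
    stop("fixed and moving landmark sets must have equal length", call. = FALSE)
  if (any(!is.finite(fixed)) || any(!is.finite(moving)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(nrow(fixed))
  if (anyDuplicated(ids)) stop("landmark ids must be unique", call. = FALSE)
  if (length(ids) != nrow(fixed))
    stop("ids length must match the number of landmarks", call. = FALSE)
  colnames(fixed) <- colnames(moving) <- c("x", "y", "z")
  structure(list(ids = ids, fixed = fixed, moving = moving),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("Fiducial set: %d paired landmarks\n", nrow(x$fixed)))
  invisible(x)
}

.map_points <- function(mapping, p, ...) {
  if (inherits(mapping, "homogeneous_transform")) transform_point(mapping, p)
  else if (inherits(mapping, "deformable_reg_record") ||
           inherits(mapping, "dvf_grid")) apply_deformable(mapping, p, ...)
  else if (inherits(mapping, "rigid_reg_record"))
    transform_point(mapping$transform, p)
  else if (is.function(mapping)) {
    q <- mapping(p)
    if (!is.matrix(q)) q <- matrix(q, ncol = 3)
    q
  }
  else stop("mapping must be a rigid transform, a deformable record, ",
            "a DVF grid, or a function", call. = FALSE)
}

#' Target registration error statistics
#'
#' Maps each fixed-frame landmark through the registration and compares it to
#' its known moving-frame position. Per-point TRE is the Euclidean distance;
#' the summary reports mean, standard deviation, maximum, and the signed
#' per-axis mean deltas (mapped minus known), which expose systematic
#' directional bias.
#'
#' @param f a [fiducial_set()].
#' @param mapping a [homogeneous_transform()], [deformable_reg_record()],
#'   [dvf_grid()], `rigid_reg_record`, or a function mapping an n x 3 matrix
#'   of points to an n x 3 matrix.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param omit_unmappable with a deformable mapping, landmarks outside the
#'   DVF hull are a hard error by default; set `TRUE` to exclude them with a
#'   warning listing their ids.
#' @return an object of class `tre_stats`: `n`, `ids`, `distances` (mm),
#'   `mean`, `sd`, `max`, `axis_means` (named length-3), `excluded_ids`.
#' @examples
#' f <- fiducial_set(fixed = diag(3), moving = diag(3) + 1)
#' compute_tre(f, function(p) p + 1)  # perfect mapping: mean TRE 0
#' @export
compute_tre <- function(f, mapping, sd_type = c("sample", "population"),
                        omit_unmappable = FALSE) {
  stopifnot(inherits(f, "fiducial_set"))
  sd_type <- match.arg(sd_type)
  fixed <- f$fixed; moving <- f$moving; ids <- f$ids
  excluded <- NULL
  deformable <- inherits(mapping, "deformable_reg_record") ||
    inherits(mapping, "dvf_grid")
  if (deformable && omit_unmappable) {
    g <- if (inherits(mapping, "dvf_grid")) mapping else mapping$dvf
    pm <- fixed
    pre <- if (inherits(mapping, "deformable_reg_record")) mapping$pre_rigid else NULL
    if (!is.null(pre)) pm <- transform_point(pre, pm)
    u <- sweep(sweep(pm, 2, g$origin, `-`), 2, g$spacing, `/`) + 1
    inside <- apply(u >= 1 - 1e-9 &
                    u <= matrix(rep(g$dims, each = nrow(u)), ncol = 3) + 1e-9,
                    1, all)
    if (!all(inside)) {
      excluded <- ids[!inside]
      warning("excluded landmarks outside the DVF hull: ",
              paste(utils::head(excluded, 10), collapse = ", "),
              if (length(excluded) > 10) " ..." else "", call. = FALSE)
      fixed <- fixed[inside, , drop = FALSE]
      moving <- moving[inside, , drop = FALSE]
      ids <- ids[inside]
    }
  }
  if (nrow(fixed) == 0L) stop("no evaluable landmarks", call. = FALSE)
  mapped <- .map_points(mapping, fixed)
  deltas <- mapped - moving
  d <- sqrt(rowSums(deltas^2))
  sdv <- if (length(d) < 2) 0
         else if (sd_type == "sample") stats::sd(d)
         else sqrt(mean((d - mean(d))^2))
  structure(list(n = length(d), ids = ids, distances = as.numeric(d),
                 mean = mean(d), sd = sdv, max = max(d),
                 axis_means = stats::setNames(colMeans(deltas), c("x", "y", "z")),
                 sd_type = sd_type, excluded_ids = excluded),
            class = "tre_stats")
}

#' @export
print.tre_stats <- function(x, digits = 2, ...) {
  cat(sprintf("TRE over %d landmarks: mean %.*f +/- %.*f mm (%s SD), max %.*f mm\n",
              x$n, digits, x$mean, digits, x$sd, x$sd_type, digits, x$max))
  cat(sprintf("  mean (dx, dy, dz): (%.*f, %.*f, %.*f) mm\n",
              digits, x$axis_means[1], digits, x$axis_means[2],
              digits, x$axis_means[3]))
  if (!is.null(x$excluded_ids))
    cat(sprintf("  excluded (outside DVF hull): %d\n", length(x$excluded_ids)))
  invisible(x)
}

#' Per-point TRE table
#' @param x a `tre_stats` object.
#' @param ... unused.
#' @return data.frame with columns `id` and `tre_mm`.
#' @export
as.data.frame.tre_stats <- function(x, ...) {
  data.frame(id = x$ids, tre_mm = x$distances)
}

#' TRE tolerance check
#'
#' Compares TRE statistics with the commissioning recommendation for
#' deformable registration: mean TRE below 2 mm and maximum below 5 mm.
#' Inequalities are strict, matching the stated wording; both thresholds are
#' configurable.
#'
#' @param s a `tre_stats` object from [compute_tre()].
#' @param mean_tol mean-TRE threshold in mm (default 2).
#' @param max_tol max-TRE threshold in mm (default 5).
#' @return a list of class `tre_check`: logical `pass`, `mean_pass`,
#'   `max_pass`, and the thresholds used.
#' @export
tre_tolerance_check <- function(s, mean_tol = 2, max_tol = 5) {
  stopifnot(inherits(s, "tre_stats"))
  if (mean_tol <= 0 || max_tol <= 0) stop("thresholds must be positive", call. = FALSE)
  mean_pass <- s$mean < mean_tol
  max_pass <- s$max < max_tol
  structure(list(pass = mean_pass && max_pass, mean_pass = mean_pass,
                 max_pass = max_pass, mean_tol = mean_tol, max_tol = max_tol,
                 mean = s$mean, max = s$max),
            class = "tre_check")
}

#' @export
print.tre_check <- function(x, ...) {
  cat(sprintf("TRE check: mean %.2f mm %s %g mm [%s], max %.2f mm %s %g mm [%s] -> %s\n",
              x$mean, if (x$mean_pass) "<" else ">=", x$mean_tol,
              if (x$mean_pass) "pass" else "FAIL",
              x$max, if (x$max_pass) "<" else ">=", x$max_tol,
              if (x$max_pass) "pass" else "FAIL",
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
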