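# Deformation vector fields on regular grids. A DVF maps points expressed in
# the target (stationary) frame to the moving frame: q = p + d(p), optionally
# wrapped by pre/post rigid transforms.

#' Deformation vector field grid
#'
#' A regular 3-D grid of displacement vectors, one per voxel center. Voxel
#' center (i, j, k) (1-based) sits at `origin + (c(i,j,k) - 1) * spacing` in
#' LPS mm. The stored vector is the displacement of that point from the
#' target frame into the moving frame.
#'
#' @param origin length-3 position of the first voxel center (mm).
#' @param spacing length-3 positive voxel spacing (mm).
#' @param dims length-3 positive integer grid dimensions (i, j, k).
#' @param displacements either an `prod(dims) x 3` matrix (voxel order: i
#'   fastest, then j, then k -- R array order) or a 4-D array
#'   `[i, j, k, component]`; mm, finite.
#' @return an object of class `dvf_grid`. `$displacements` is stored as the
#'   n x 3 matrix form; `$array` retrieves the 4-D array view.
#' @export
dvf_grid <- function(origin, spacing, dims, displacements) {
  origin <- .check_vec3(origin, "origin")
  spacing <- .check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three positive integers", call. = FALSE)
  if (is.array(displacements) && length(dim(displacements)) == 4L) {
    if (!identical(dim(displacements)[1:3], dims) || dim(displacements)[4] != 3L)
      stop("displacement array must be dims x 3", call. = FALSE)
    displacements <- matrix(displacements, ncol = 3L)
  }
  if (!is.matrix(displacements) || ncol(displacements) != 3L ||
      nrow(displacements) != prod(dims))
    stop(sprintf("displacements must be %d x 3 (got %s)", prod(dims),
                 paste(dim(displacements), collapse = "x")), call. = FALSE)
  if (any(!is.finite(displacements)))
    stop("displacements must be finite", call. = FALSE)
  storage.mode(displacements) <- "double"
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 displacements = displacements),
            class = "dvf_grid")
}

#' @export
print.dvf_grid <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf("DVF grid %s, spacing (%s) mm, origin (%s) mm\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  |d|: mean %.3f mm, max %.3f mm\n", mean(mag), max(mag)))
  invisible(x)
}

#' Voxel-center coordinates of a DVF grid
#' @param g a [dvf_grid()].
#' @return `prod(dims) x 3` matrix of LPS mm positions, i fastest.
#' @export
dvf_voxel_centers <- function(g) {
  stopifnot(inherits(g, "dvf_grid"))
  idx <- as.matrix(expand.grid(i = seq_len(g$dims[1]),
                               j = seq_len(g$dims[2]),
                               k = seq_len(g$dims[3])))
  sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

#' Sample a DVF at arbitrary points
#'
#' Interpolates each displacement component at the query points. Trilinear
#' interpolation is the default (exact at voxel centers, and exact everywhere
#' for componentwise-affine fields); nearest-neighbour is available for
#' sensitivity checks. The interpolable hull is the box spanned by the voxel
#' centers.
#'
#' @param g a [dvf_grid()].
#' @param p length-3 point or n x 3 matrix (LPS mm).
#' @param policy `"strict"` errors on points outside the hull; `"clamp"`
#'   clamps them to the hull edge and counts them in the `clamped` attribute.
#' @param method `"trilinear"` or `"nearest"`.
#' @return displacement(s), same shape as `p`; with policy `"clamp"` the
#'   result carries an attribute `clamped` giving the number of clamped
#'   points.
#' @export
sample_dvf <- function(g, p, policy = c("strict", "clamp"),
                       method = c("trilinear", "nearest")) {
  stopifnot(inherits(g, "dvf_grid"))
  policy <- match.arg(policy)
  method <- match.arg(method)
  single <- !is.matrix(p)
  pm <- if (single) matrix(.check_vec3(p, "point"), 1) else p
  stopifnot(ncol(pm) == 3L)

  # continuous 1-based voxel index of each query point
  u <- sweep(sweep(pm, 2, g$origin, `-`), 2, g$spacing, `/`) + 1
  tol <- 1e-9
  lo <- 1 - tol
  hi <- matrix(rep(g$dims, each = nrow(u)), ncol = 3) + tol
  outside <- u < lo | u > hi
  n_out <- sum(apply(outside, 1, any))
  if (n_out > 0) {
    if (policy == "strict") {
      bad <- which(apply(outside, 1, any))
      stop(sprintf("%d point(s) outside the DVF grid hull (rows %s)",
                   n_out, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
    warning(sprintf("%d point(s) clamped to the DVF grid edge", n_out),
            call. = FALSE)
  }
  for (c_ in 1:3) u[, c_] <- pmin(pmax(u[, c_], 1), g$dims[c_])

  darr <- array(g$displacements, dim = c(g$dims, 3L))
  out <- matrix(0, nrow(u), 3)
  if (method == "nearest") {
    idx <- round(u)
    for (c_ in 1:3) idx[, c_] <- pmin(pmax(idx[, c_], 1), g$dims[c_])
    flat <- idx[, 1] + (idx[, 2] - 1) * g$dims[1] +
      (idx[, 3] - 1) * g$dims[1] * g$dims[2]
    out <- g$displacements[flat, , drop = FALSE]
  } else {
    i0 <- floor(u)
    for (c_ in 1:3) i0[, c_] <- pmin(pmax(i0[, c_], 1), max(g$dims[c_] - 1, 1))
    fr <- u - i0
    # collapse degenerate axes (dims == 1): weight 0 on the upper corner
    for (c_ in 1:3) if (g$dims[c_] == 1L) fr[, c_] <- 0
    d1 <- g$dims[1]; d12 <- g$dims[1] * g$dims[2]
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      ii <- pmin(i0[, 1] + di, g$dims[1])
      jj <- pmin(i0[, 2] + dj, g$dims[2])
      kk <- pmin(i0[, 3] + dk, g$dims[3])
      w <- (if (di == 1) fr[, 1] else 1 - fr[, 1]) *
           (if (dj == 1) fr[, 2] else 1 - fr[, 2]) *
           (if (dk == 1) fr[, 3] else 1 - fr[, 3])
      flat <- ii + (jj - 1) * d1 + (kk - 1) * d12
      out <- out + w * g$displacements[flat, , drop = FALSE]
    }
  }
  colnames(out) <- c("x", "y", "z")
  if (policy == "clamp") attr(out, "clamped") <- n_out
  if (single) {
    res <- out[1, ]
    if (policy == "clamp") attr(res, "clamped") <- n_out
    res
  } else out
}

#' Map points through a deformable registration
#'
#' Applies the full chain of a deformable spatial registration object:
#' optional pre-displacement rigid transform, then the displacement field
#' sampled at the pre-transformed position, then the optional
#' post-displacement rigid transform:
#' `q = post(pre(p) + d(pre(p)))`. Missing pre/post transforms are the
#' identity.
#'
#' @param rec a [deformable_reg_record()] (or a bare [dvf_grid()]).
#' @param p length-3 point or n x 3 matrix (LPS mm, target frame).
#' @param policy,method passed to [sample_dvf()].
#' @return mapped point(s) in the moving frame, same shape as `p`.
#' @export
apply_deformable <- function(rec, p, policy = c("strict", "clamp"),
                             method = c("trilinear", "nearest")) {
  if (inherits(rec, "dvf_grid")) rec <- deformable_reg_record(rec)
  stopifnot(inherits(rec, "deformable_reg_record"))
  single <- !is.matrix(p)
  pm <- if (single) matrix(.check_vec3(p, "point"), 1) else p
  if (!is.null(rec$pre_rigid)) pm <- transform_point(rec$pre_rigid, pm)
  d <- sample_dvf(rec$dvf, pm, policy = policy, method = method)
  q <- pm + d
  if (!is.null(rec$post_rigid)) q <- transform_point(rec$post_rigid, q)
  colnames(q) <- c("x", "y", "z")
  if (single) q[1, ] else q
}
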