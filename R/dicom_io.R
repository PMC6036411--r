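# File I/O for spatial registration objects, deformable registration records,
# landmark lists and mask volumes. All geometry is DICOM LPS mm,
# point = origin + index * spacing (axis-aligned grids only).

# Numbers are serialized with 17 significant digits so that
# as.numeric(format(x)) == x exactly (IEEE double round-trip).
.fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, digits = 17, format = "g")
    gsub(" ", "", s)
  }, character(1))
}

.flat_to_string <- function(flat) paste(.fmt_num(flat), collapse = "/")

.MATRIX_RUN_RE <- "(-?[0-9]+(\\.[0-9]+)?([eE][-+]?[0-9]+)?/){15}-?[0-9]+(\\.[0-9]+)?([eE][-+]?[0-9]+)?"

# ---- rigid spatial registration ---------------------------------------------

#' Write a rigid spatial registration file
#'
#' Emits a minimal plain-text spatial registration object holding the 4x4
#' matrix as the standard 16-value row-major slash-separated string ending
#' "0/0/0/1" -- the same string visible inside a DICOM REG object. Values are
#' serialized at full double precision so the matrix re-reads bit-exact.
#'
#' @param t a [homogeneous_transform()].
#' @param file output path.
#' @param frame_of_reference free-text frame-of-reference descriptor.
#' @return `file`, invisibly.
#' @export
write_rigid_reg <- function(t, file, frame_of_reference = "regqa-fixture") {
  stopifnot(inherits(t, "homogeneous_transform"))
  lines <- c(
    "# regqa spatial registration v1",
    "SOPClassName: SpatialRegistrationStorage",
    paste0("FrameOfReferenceUID: ", frame_of_reference),
    paste0("Direction: ", t$direction),
    "MatrixType: RIGID",
    paste0("Matrix: ", .flat_to_string(transform_to_flat(t))))
  writeLines(lines, file)
  invisible(file)
}

#' Read a rigid spatial registration file
#'
#' Two parse modes, mirroring how physicists actually extract the matrix:
#' \describe{
#'   \item{tag_based}{the file is a recognised registration object; the matrix
#'     is taken from its Matrix field. Authoritative.}
#'   \item{raw_scan}{for any other file (including binary DICOM), the raw
#'     bytes are scanned for a run of 16 slash-separated ASCII numbers ending
#'     "0/0/0/1" -- the text-editor extraction trick. Recorded in provenance.}
#' }
#' The rotation block is checked for orthonormality; deviations above `1e-3`
#' are an error, smaller ones (file rounding) a warning.
#'
#' @param file path to a registration file.
#' @param select when a raw scan finds several candidate matrix runs, the
#'   1-based index of the one to use; by default multiple candidates are an
#'   error listing them all.
#' @param direction direction tag to attach when the file does not declare
#'   one; files written by [write_rigid_reg()] carry their own tag.
#' @return a list of class `rigid_reg_record` with elements `transform`
#'   ([homogeneous_transform()]), `source` (file path and frame-of-reference
#'   text) and `parse_mode`.
#' @export
read_rigid_reg <- function(file, select = NULL, direction = "target_to_moving") {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  raw <- readBin(file, "raw", n = file.info(file)$size)
  txt <- rawToChar(raw[raw != as.raw(0)])
  Encoding(txt) <- "latin1"
  lines <- strsplit(txt, "\r?\n")[[1]]

  tag_based <- any(grepl("^# regqa spatial registration", lines))
  frame <- sub("^FrameOfReferenceUID:\\s*", "",
               grep("^FrameOfReferenceUID:", lines, value = TRUE)[1])
  if (tag_based) {
    mline <- grep("^Matrix:\\s*", lines, value = TRUE)
    if (length(mline) != 1L)
      stop("malformed registration file: expected exactly one Matrix field",
           call. = FALSE)
    run <- sub("^Matrix:\\s*", "", mline)
    dline <- grep("^Direction:\\s*", lines, value = TRUE)
    if (length(dline) == 1L) direction <- sub("^Direction:\\s*", "", dline)
    mode <- "tag_based"
  } else {
    m <- gregexpr(.MATRIX_RUN_RE, txt)[[1]]
    runs <- if (m[1] == -1) character(0) else regmatches(txt, gregexpr(.MATRIX_RUN_RE, txt))[[1]]
    runs <- runs[vapply(runs, function(r) {
      v <- as.numeric(strsplit(r, "/")[[1]])
      identical(v[13:16], c(0, 0, 0, 1))
    }, logical(1))]
    if (length(runs) == 0L)
      stop("no 16-value slash-separated matrix run ending 0/0/0/1 found in ",
           file, call. = FALSE)
    if (length(runs) > 1L && is.null(select))
      stop("multiple candidate matrix runs found; pass select = <index>:\n",
           paste(sprintf("  [%d] %s", seq_along(runs), runs), collapse = "\n"),
           call. = FALSE)
    run <- runs[[if (is.null(select)) 1L else select]]
    mode <- "raw_scan"
  }

  flat <- as.numeric(strsplit(run, "/")[[1]])
  transform <- transform_from_flat(flat, direction = direction)
  structure(list(transform = transform,
                 source = list(file = file, frame_of_reference = frame),
                 parse_mode = mode),
            class = "rigid_reg_record")
}

#' @export
print.rigid_reg_record <- function(x, ...) {
  cat(sprintf("Rigid registration record (%s parse) from %s\n",
              x$parse_mode, x$source$file))
  print(x$transform)
  invisible(x)
}

# ---- deformable spatial registration ----------------------------------------

#' Deformable registration record
#'
#' Bundles a deformation vector field grid with the optional pre- and
#' post-displacement rigid transforms a deformable spatial registration
#' object may carry. See [apply_deformable()] for the mapping semantics.
#'
#' @param dvf a [dvf_grid()].
#' @param pre_rigid,post_rigid optional [homogeneous_transform()]s applied
#'   before / after the displacement step.
#' @return an object of class `deformable_reg_record`.
#' @export
deformable_reg_record <- function(dvf, pre_rigid = NULL, post_rigid = NULL) {
  stopifnot(inherits(dvf, "dvf_grid"))
  if (!is.null(pre_rigid)) stopifnot(inherits(pre_rigid, "homogeneous_transform"))
  if (!is.null(post_rigid)) stopifnot(inherits(post_rigid, "homogeneous_transform"))
  structure(list(dvf = dvf, pre_rigid = pre_rigid, post_rigid = post_rigid),
            class = "deformable_reg_record")
}

#' @export
print.deformable_reg_record <- function(x, ...) {
  cat("Deformable registration record\n")
  print(x$dvf)
  cat(sprintf("  pre-rigid: %s, post-rigid: %s\n",
              if (is.null(x$pre_rigid)) "none" else "present",
              if (is.null(x$post_rigid)) "none" else "present"))
  invisible(x)
}

#' Write a deformable registration record
#'
#' Emits a text header (grid geometry plus optional pre/post rigid matrices
#' as 16-value strings) followed by the displacement stream as little-endian
#' 32-bit floats, interleaved (dx, dy, dz) per voxel with the first grid index
#' varying fastest -- the layout of the Vector Grid Data in a deformable
#' spatial registration object. Round-trips at float32 precision.
#'
#' @param rec a [deformable_reg_record()] (a bare [dvf_grid()] is wrapped).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_deformable_reg <- function(rec, file) {
  if (inherits(rec, "dvf_grid")) rec <- deformable_reg_record(rec)
  stopifnot(inherits(rec, "deformable_reg_record"))
  g <- rec$dvf
  hdr <- c("REGQA-DVF v1",
           paste("dims:", paste(g$dims, collapse = " ")),
           paste("origin:", paste(.fmt_num(g$origin), collapse = " ")),
           paste("spacing:", paste(.fmt_num(g$spacing), collapse = " ")),
           paste("pre:", if (is.null(rec$pre_rigid)) "none" else
                 .flat_to_string(transform_to_flat(rec$pre_rigid))),
           paste("post:", if (is.null(rec$post_rigid)) "none" else
                 .flat_to_string(transform_to_flat(rec$post_rigid))),
           "data: float32 little-endian dx/dy/dz interleaved, i fastest",
           "end_header")
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  # interleave components per voxel: row t(disp) streams (dx,dy,dz) tuples
  writeBin(as.vector(t(g$displacements)), con, size = 4L, endian = "little")
  invisible(file)
}

.parse_pre_post <- function(s, direction) {
  if (identical(s, "none")) return(NULL)
  transform_from_flat(as.numeric(strsplit(s, "/")[[1]]), direction = direction)
}

#' Read a deformable registration record
#'
#' Inverts [write_deformable_reg()]: recovers grid origin, spacing and
#' dimensions, the per-voxel displacement triplets (mm, LPS) and any pre/post
#' rigid matrices. A mismatch between the declared dimensions and the length
#' of the data stream is an error.
#'
#' @param file path written by [write_deformable_reg()].
#' @return a [deformable_reg_record()].
#' @export
read_deformable_reg <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed DVF file: no end_header", call. = FALSE)
    if (ln == "end_header") break
    hdr <- c(hdr, ln)
  }
  if (!any(grepl("^REGQA-DVF", hdr)))
    stop("not a regqa DVF file: ", file, call. = FALSE)
  field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1L) stop("missing DVF header field: ", key, call. = FALSE)
    sub(paste0("^", key, ":\\s*"), "", ln)
  }
  dims <- as.integer(strsplit(field("dims"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(field("origin"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(field("spacing"), "\\s+")[[1]])
  n <- prod(dims) * 3L
  vals <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
  if (length(vals) != n)
    stop(sprintf("DVF data length %d does not match declared dims (%s -> %d values)",
                 length(vals), paste(dims, collapse = "x"), n), call. = FALSE)
  disp <- matrix(vals, ncol = 3L, byrow = TRUE)
  deformable_reg_record(
    dvf_grid(origin = origin, spacing = spacing, dims = dims,
             displacements = disp),
    pre_rigid = .parse_pre_post(field("pre"), "target_to_moving"),
    post_rigid = .parse_pre_post(field("post"), "target_to_moving"))
}

# ---- landmark lists ---------------------------------------------------------

#' Read a landmark (fiducial) list
#'
#' Reads a delimited text file of 3-D landmark coordinates: three numeric
#' columns separated by whitespace, comma, semicolon or tab, with an optional
#' single header line. Two dialects exist in the wild and silent unit errors
#' are the central hazard, so the dialect must be declared -- it is never
#' auto-detected:
#' \describe{
#'   \item{mm}{coordinates are physical LPS mm and returned as-is.}
#'   \item{index}{coordinates are voxel indices; they are converted to mm via
#'     `origin + (index - index_base) * spacing`, so the grid geometry and the
#'     index base (0 or 1) are required.}
#' }
#'
#' @param file path to the landmark file.
#' @param dialect `"mm"` or `"index"`.
#' @param origin,spacing grid geometry (length-3, mm), required for the index
#'   dialect.
#' @param index_base 0 or 1: value of the index that sits at `origin`.
#' @return n x 3 numeric matrix of LPS mm coordinates (columns x, y, z).
#' @export
read_landmarks <- function(file, dialect = c("mm", "index"),
                           origin = NULL, spacing = NULL, index_base = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty landmark file: ", file, call. = FALSE)
  parse_row <- function(ln) {
    toks <- strsplit(trimws(ln), "[,;[:space:]]+")[[1]]
    suppressWarnings(as.numeric(toks))
  }
  first <- parse_row(lines[1])
  start <- 1L
  if (any(is.na(first))) start <- 2L  # header line
  if (start > length(lines)) stop("no data rows in landmark file", call. = FALSE)
  rows <- lapply(seq(start, length(lines)), function(i) {
    v <- parse_row(lines[i])
    if (length(v) != 3L || any(is.na(v)))
      stop(sprintf("non-numeric or malformed landmark row at line %d of %s",
                   i, file), call. = FALSE)
    v
  })
  pts <- do.call(rbind, rows)
  colnames(pts) <- c("x", "y", "z")
  if (dialect == "index") {
    if (is.null(origin) || is.null(spacing))
      stop("index-dialect landmarks require origin and spacing", call. = FALSE)
    if (!index_base %in% c(0, 1))
      stop("index_base must be 0 or 1", call. = FALSE)
    origin <- .check_vec3(origin, "origin")
    spacing <- .check_vec3(spacing, "spacing")
    pts <- sweep(sweep(pts, 2, index_base, `-`) %*% diag(spacing), 2, origin, `+`)
    colnames(pts) <- c("x", "y", "z")
  }
  pts
}

#' Write a landmark list (mm dialect)
#' @param points n x 3 matrix of LPS mm coordinates.
#' @param file output path.
#' @param header write a column-name header line.
#' @return `file`, invisibly.
#' @export
write_landmarks <- function(points, file, header = TRUE) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  lines <- apply(points, 1, function(p) paste(.fmt_num(p), collapse = " "))
  if (header) lines <- c("x y z", lines)
  writeLines(lines, file)
  invisible(file)
}

# ---- NRRD masks -------------------------------------------------------------

#' Read / write a binary mask volume as NRRD
#'
#' Minimal NRRD support for axis-aligned binary label volumes: type uint8,
#' 3-D, raw or text encoding, geometry carried by `space origin` and diagonal
#' `space directions` in LPS mm. Direction cosines beyond axis-aligned are a
#' declared limitation. Round-trips are lossless.
#'
#' @param file path to a `.nrrd` file.
#' @return for `read_mask`, a [mask_volume()].
#' @export
read_mask <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", file, call. = FALSE)
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated NRRD header", call. = FALSE)
    if (!nzchar(ln)) break
    hdr <- c(hdr, ln)
  }
  field <- function(key, required = TRUE) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE, ignore.case = TRUE)
    if (length(ln) == 0L) {
      if (required) stop("NRRD header missing required field: ", key, call. = FALSE)
      return(NULL)
    }
    trimws(sub(paste0("^", key, ":=?\\s*"), "", ln[1], ignore.case = TRUE))
  }
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD masks are supported", call. = FALSE)
  enc <- tolower(field("encoding"))
  typ <- tolower(field("type"))
  if (!typ %in% c("uint8", "uchar", "unsigned char"))
    stop("only uint8 NRRD masks are supported, got type: ", typ, call. = FALSE)
  parse_triples <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(m, function(t) as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]]))
  }
  sd_raw <- field("space directions")
  or_raw <- field("space origin")
  dirs <- parse_triples(sd_raw)
  if (length(dirs) != 3L) stop("NRRD space directions must have 3 vectors", call. = FALSE)
  spacing <- vapply(seq_len(3), function(i) {
    v <- dirs[[i]]
    off <- v[-i]
    if (any(abs(off) > 1e-9))
      stop("only axis-aligned NRRD space directions are supported", call. = FALSE)
    v[i]
  }, numeric(1))
  origin <- as.numeric(strsplit(gsub("[()]", "", or_raw), ",")[[1]])
  n <- prod(sizes)
  vals <- switch(enc,
    raw = as.integer(readBin(con, "raw", n = n + 1L)),
    text = , txt = , ascii = {
      rest <- readLines(con, warn = FALSE)
      toks <- strsplit(paste(rest, collapse = " "), "\\s+")[[1]]
      as.integer(toks[nzchar(toks)])
    },
    stop("unsupported NRRD encoding: ", enc, call. = FALSE))
  if (length(vals) != n)
    stop(sprintf("NRRD data length %d does not match declared sizes (%s)",
                 length(vals), paste(sizes, collapse = "x")), call. = FALSE)
  occ <- array(vals != 0L, dim = sizes)
  nm <- field("content", required = FALSE)
  mask_volume(occ, origin = origin, spacing = spacing,
              name = if (is.null(nm)) tools::file_path_sans_ext(basename(file)) else nm)
}

#' @rdname read_mask
#' @param mask a [mask_volume()].
#' @param encoding `"raw"` (binary stream) or `"text"` (ASCII 0/1, suitable
#'   for version-controlled fixtures).
#' @export
write_mask <- function(mask, file, encoding = c("raw", "text")) {
  stopifnot(inherits(mask, "mask_volume"))
  encoding <- match.arg(encoding)
  dirs <- sprintf("(%s,0,0) (0,%s,0) (0,0,%s)",
                  .fmt_num(mask$spacing[1]), .fmt_num(mask$spacing[2]),
                  .fmt_num(mask$spacing[3]))
  hdr <- c("NRRD0004",
           "type: uint8",
           "dimension: 3",
           paste("sizes:", paste(dim(mask$occupancy), collapse = " ")),
           "space: left-posterior-superior",
           paste("space directions:", dirs),
           sprintf("space origin: (%s,%s,%s)",
                   .fmt_num(mask$origin[1]), .fmt_num(mask$origin[2]),
                   .fmt_num(mask$origin[3])),
           paste("content:", mask$name),
           "endian: little",
           paste("encoding:", if (encoding == "raw") "raw" else "text"),
           "")
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vals <- as.integer(mask$occupancy)
  if (encoding == "raw") {
    writeBin(as.raw(vals), con)
  } else {
    writeLines(paste(vals, collapse = " "), con)
  }
  invisible(file)
}
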