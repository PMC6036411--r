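test_that("rigid registration files round-trip bit-exact", {
  inv <- invert_transform(build_nominal_transform(case10_spec(), case10_shift()))
  f <- withr::local_tempfile()
  write_rigid_reg(inv, f)
  rec <- read_rigid_reg(f)
  expect_identical(rec$transform$matrix, inv$matrix)
  expect_identical(rec$parse_mode, "tag_based")
  expect_identical(rec$transform$direction, "target_to_moving")
  set.seed(1)
  for (i in 1:100) {
    t1 <- random_transform()
    write_rigid_reg(t1, f)
    expect_identical(read_rigid_reg(f)$transform$matrix, t1$matrix)
  }
})

test_that("raw scan locates the slash-separated matrix run in foreign files", {
  f <- withr::local_tempfile()
  writeLines("some binary-ish junk 1/0/0/10/0/1/0/-5/0/0/1/15/0/0/0/1 trailer", f)
  rec <- read_rigid_reg(f)
  expect_identical(rec$parse_mode, "raw_scan")
  expect_equal(unname(transform_translation(rec$transform)), c(10, -5, 15))
  expect_equal(transform_rotation(rec$transform), diag(3))
  # raw bytes with embedded NULs, as in a genuine binary object
  fb <- withr::local_tempfile()
  con <- file(fb, "wb")
  writeBin(c(as.raw(c(0, 1, 2)), charToRaw("1/0/0/3/0/1/0/4/0/0/1/5/0/0/0/1"),
             as.raw(0)), con)
  close(con)
  expect_equal(unname(transform_translation(read_rigid_reg(fb)$transform)),
               c(3, 4, 5))
})

test_that("raw scan and tag parse of the same matrix agree", {
  set.seed(2)
  t1 <- random_transform()
  f_tag <- withr::local_tempfile()
  write_rigid_reg(t1, f_tag)
  tagged <- read_rigid_reg(f_tag)
  f_raw <- withr::local_tempfile()
  flat <- readLines(f_tag)
  writeLines(paste("noise", sub("^Matrix: ", "", grep("^Matrix:", flat, value = TRUE))),
             f_raw)
  raw <- read_rigid_reg(f_raw)
  expect_identical(raw$parse_mode, "raw_scan")
  expect_identical(tagged$transform$matrix, raw$transform$matrix)
})

test_that("malformed matrix streams are rejected informatively", {
  f <- withr::local_tempfile()
  writeLines("1/0/0/10/0/1/0/-5/0/0/1/15/0/0/0", f)  # 15 values
  expect_error(read_rigid_reg(f), "no 16-value")
  writeLines("no numbers here", f)
  expect_error(read_rigid_reg(f), "no 16-value")
  # two candidate runs: error unless one is selected
  writeLines(c("1/0/0/1/0/1/0/2/0/0/1/3/0/0/0/1",
               "1/0/0/7/0/1/0/8/0/0/1/9/0/0/0/1"), f)
  expect_error(read_rigid_reg(f), "multiple")
  rec <- read_rigid_reg(f, select = 2)
  expect_equal(unname(transform_translation(rec$transform)), c(7, 8, 9))
})

test_that("deformable records round-trip at float32 precision", {
  f <- withr::local_tempfile()
  zero <- dvf_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4), matrix(0, 64, 3))
  write_deformable_reg(zero, f)
  back <- read_deformable_reg(f)
  expect_true(all(back$dvf$displacements == 0))
  expect_equal(back$dvf$dims, c(4L, 4L, 4L))
  expect_null(back$pre_rigid)

  set.seed(4)
  for (i in 1:20) {
    dims <- sample(2:6, 3, replace = TRUE)
    disp <- matrix(stats::runif(prod(dims) * 3, -20, 20), ncol = 3)
    g <- dvf_grid(stats::runif(3, -100, 0), stats::runif(3, 0.5, 5), dims, disp)
    rec <- deformable_reg_record(g, pre_rigid = random_transform(),
                                 post_rigid = random_transform())
    write_deformable_reg(rec, f)
    back <- read_deformable_reg(f)
    expect_equal(back$dvf$displacements, disp, tolerance = 1e-6)
    expect_lt(max(abs(back$dvf$displacements - disp)),
              max(abs(disp)) * 2^-22)
    expect_identical(back$pre_rigid$matrix, rec$pre_rigid$matrix)
    expect_identical(back$post_rigid$matrix, rec$post_rigid$matrix)
    expect_equal(back$dvf$origin, g$origin)
    expect_equal(back$dvf$spacing, g$spacing)
  }
  # single-voxel edge case
  g1 <- dvf_grid(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), matrix(1:3, 1))
  write_deformable_reg(g1, f)
  expect_equal(as.numeric(read_deformable_reg(f)$dvf$displacements), 1:3)
})

test_that("truncated DVF streams raise a size-mismatch error", {
  f <- withr::local_tempfile()
  g <- dvf_grid(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3),
                matrix(stats::runif(81), ncol = 3))
  write_deformable_reg(g, f)
  sz <- file.info(f)$size
  raw <- readBin(f, "raw", sz)
  f2 <- withr::local_tempfile()
  writeBin(raw[1:(sz - 8)], f2)
  expect_error(read_deformable_reg(f2), "does not match declared dims")
})

test_that("landmark dialects convert indices through the grid geometry", {
  f <- withr::local_tempfile()
  writeLines("0 0 0", f)
  expect_equal(unname(read_landmarks(f, "mm")[1, ]), c(0, 0, 0))
  writeLines(c("i j k", "1,1,1"), f)
  expect_equal(unname(read_landmarks(f, "index", origin = c(-100, -100, -50),
                                     spacing = c(2, 2, 5), index_base = 0)[1, ]),
               c(-98, -98, -45))
  expect_equal(unname(read_landmarks(f, "index", origin = c(-100, -100, -50),
                                     spacing = c(2, 2, 5), index_base = 1)[1, ]),
               c(-100, -100, -50))
  expect_error(read_landmarks(f, "index"), "origin and spacing")
  writeLines(c("1 2 3", "4 five 6"), f)
  expect_error(read_landmarks(f, "mm"), "line 2")
  # mm round trip with mixed delimiters and header
  pts <- matrix(stats::runif(30, -100, 100), ncol = 3)
  write_landmarks(pts, f)
  expect_equal(unname(read_landmarks(f, "mm")), unname(pts))
})

test_that("NRRD masks round-trip in raw and text encodings", {
  set.seed(6)
  f <- withr::local_tempfile(fileext = ".nrrd")
  for (enc in c("raw", "text")) {
    for (i in 1:10) {
      dims <- sample(3:8, 3, replace = TRUE)
      m <- mask_volume(array(stats::runif(prod(dims)) > 0.5, dims),
                       origin = stats::runif(3, -50, 0),
                       spacing = stats::runif(3, 0.5, 3), name = "fixture")
      write_mask(m, f, encoding = enc)
      back <- read_mask(f)
      expect_identical(back$occupancy, m$occupancy)
      expect_equal(back$origin, m$origin)
      expect_equal(back$spacing, m$spacing)
      expect_identical(back$name, "fixture")
    }
  }
  # empty mask round trip
  m0 <- mask_volume(array(FALSE, c(3, 3, 3)), c(0, 0, 0), c(1, 1, 1))
  write_mask(m0, f)
  expect_equal(volume(read_mask(f)), 0)
})

test_that("NRRD reader enforces geometry metadata and size consistency", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  m <- mask_volume(array(TRUE, c(2, 2, 2)), c(0, 0, 0), c(1, 1, 1))
  write_mask(m, f, encoding = "text")
  lines <- readLines(f, warn = FALSE)
  writeLines(lines[!grepl("^space origin", lines)], f)
  expect_error(read_mask(f), "space origin")
  write_mask(m, f, encoding = "text")
  lines <- readLines(f, warn = FALSE)
  lines[grepl("^sizes", lines)] <- "sizes: 2 2 3"
  writeLines(lines, f)
  expect_error(read_mask(f), "does not match")
})
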