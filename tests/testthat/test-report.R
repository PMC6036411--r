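rigid_config <- function(bundle, voxel = NULL, case_id = "case-10") {
  cfg <- list(reg_file = bundle$files$reported,
              shift = bundle$manifest$shift,
              rotations = bundle$manifest$rotations_deg,
              case_id = case_id)
  cfg$voxel <- voxel
  cfg
}

test_that("rigid check passes a perfect registration end to end", {
  b <- gen_rigid_case(61, case10_shift(), case10_spec())
  rep <- run_rigid_check(rigid_config(b, voxel = c(0.7, 0.7, 3.0)))
  expect_true(rep$verdicts$all_axes_pass)
  expect_true(all(rep$verdicts$half_voxel_pass))
  expect_equal(rep$metrics$translation_errors_mm, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(rep$metrics$axis_misalignment_deg, 1e-6)
  expect_identical(rep$test_id, "case-10")
  expect_identical(rep$inputs$parse_mode, "tag_based")
})

test_that("rigid check fails the axis carrying an injected 1.3 mm error", {
  b <- gen_rigid_case(62, case10_shift(), case10_spec(),
                      injected_translation_error = c(1.3, 0, 0))
  rep <- run_rigid_check(rigid_config(b, voxel = c(0.7, 0.7, 3.0)))
  expect_identical(rep$verdicts$half_voxel_pass, c(FALSE, TRUE, TRUE))
  expect_false(rep$verdicts$all_axes_pass)
  expect_equal(rep$metrics$translation_errors_mm[1], 1.3, tolerance = 1e-9)
})

test_that("rigid check config loads from YAML and JSON files", {
  b <- gen_rigid_case(63, case10_shift(), case10_spec())
  cfg <- rigid_config(b, voxel = c(0.7, 0.7, 3.0))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  rep_y <- run_rigid_check(fy)
  expect_true(rep_y$verdicts$all_axes_pass)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  rep_j <- run_rigid_check(fj)
  expect_equal(rep_j$metrics, rep_y$metrics)
})

test_that("tre runner scores a deformable fixture against tolerances", {
  b <- gen_dvf_case(64, "affine", origin = c(-20, -20, -20),
                    spacing = c(2, 2, 2), dims = c(21, 21, 21),
                    n_landmarks = 60)
  rep <- run_tre(list(reg_file = b$files$dvf, reg_type = "deformable",
                      landmarks_fixed = b$files$fixed,
                      landmarks_moving = b$files$moving, case_id = "case-16"))
  expect_true(rep$verdicts$pass)
  expect_lt(rep$metrics$mean_tre_mm, 1e-5)
  expect_equal(nrow(rep$metrics$per_point), 60)
  # per-point table reproduces the summary
  expect_equal(mean(rep$metrics$per_point$tre_mm), rep$metrics$mean_tre_mm)
  expect_equal(max(rep$metrics$per_point$tre_mm), rep$metrics$max_tre_mm)
})

test_that("tre runner flags a registration violating the recommendations", {
  # zero DVF but landmarks displaced by 6 mm: mean TRE 6 > 2
  g <- dvf_grid(c(-20, -20, -20), c(2, 2, 2), c(21, 21, 21),
                matrix(0, 21^3, 3))
  fdvf <- withr::local_tempfile()
  write_deformable_reg(g, fdvf)
  set.seed(65)
  fixed <- matrix(stats::runif(60, -10, 10), ncol = 3)
  moving <- fixed + matrix(rep(c(6, 0, 0), each = 20), ncol = 3)
  ffix <- withr::local_tempfile(); fmov <- withr::local_tempfile()
  write_landmarks(fixed, ffix); write_landmarks(moving, fmov)
  rep <- run_tre(list(reg_file = fdvf, landmarks_fixed = ffix,
                      landmarks_moving = fmov))
  expect_false(rep$verdicts$pass)
  expect_equal(rep$metrics$mean_tre_mm, 6, tolerance = 1e-9)
  expect_equal(rep$metrics$axis_mean_delta_mm, c(-6, 0, 0), tolerance = 1e-9)
})

test_that("dice runner reports per-structure volumes, DSC and bands", {
  b1 <- gen_mask_pair(66, "boxes", voxel = 0.1)
  b2 <- gen_mask_pair(67, "spheres",
                      params = list(center1 = c(0, 0, 0), center2 = c(0, 0, 0),
                                    r1 = 1, r2 = 1), voxel = 0.1)
  rep <- run_dice(list(pairs = list(
    list(name = "half-box", target_mask = b1$files$target,
         deformed_mask = b1$files$deformed),
    list(name = "same-sphere", target_mask = b2$files$target,
         deformed_mask = b2$files$deformed))))
  tbl <- rep$metrics$structures
  expect_equal(tbl$dsc[tbl$name == "half-box"], 0.5)
  expect_equal(tbl$dsc[tbl$name == "same-sphere"], 1.0)
  expect_identical(rep$verdicts$dsc_band, c("fail", "good"))
  expect_false(rep$verdicts$all_acceptable)
  # verdicts recomputable from the stored metrics
  expect_identical(rep$verdicts$dsc_band,
                   dsc_tolerance_check(rep$metrics$dsc,
                                       rep$tolerances$dsc_bands))
})

test_that("reports serialize to JSON and CSV and are reproducible", {
  b <- gen_rigid_case(68, case10_shift(), case10_spec())
  cfg <- rigid_config(b, voxel = c(0.7, 0.7, 3.0))
  rep <- run_rigid_check(cfg)
  fj <- withr::local_tempfile(fileext = ".json")
  write_qa_report(rep, fj)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(parsed$metrics$known_T_mm, rep$metrics$known_T_mm)
  expect_identical(parsed$check, "rigid-check")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_qa_report(rep, fc)
  tbl <- utils::read.csv(fc)
  expect_true("translation_errors_mm" %in% tbl$quantity)
  # byte-for-byte reproducibility given identical inputs
  rep2 <- run_rigid_check(cfg)
  fj2 <- withr::local_tempfile(fileext = ".json")
  write_qa_report(rep2, fj2)
  expect_identical(readLines(fj), readLines(fj2))
})

test_that("tolerance spec validates its thresholds", {
  expect_error(tolerance_spec(tre_mean_max = -1), "positive")
  expect_error(tolerance_spec(dsc_bands = c(0.9, 0.8)), "increasing")
  expect_error(tolerance_spec(half_voxel = c(1, 0, 1)), "positive")
  ts <- tolerance_spec(half_voxel = c(0.7, 0.7, 3))
  expect_equal(ts$tre_mean_max, 2)
  expect_equal(ts$tre_max, 5)
  expect_equal(ts$dsc_bands, c(0.8, 0.9))
})
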