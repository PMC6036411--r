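# Shared constants and small generators for the test suite.

# Worked rotation commissioning case: -5 deg X, 8 deg Y, 10 deg Z, shift
# 5 mm Lt / 15 mm Ant / 20 mm Sup, stationary dataset shifted.
case10_spec <- function() rotation_spec(x = -5, y = 8, z = 10)
case10_shift <- function() {
  patient_shift(c(5, 15, 20), c("Lt", "Ant", "Sup"), shifted = "stationary")
}

# Published values for that case (printed at 2-3 decimals).
CASE10_INVERSE_T <- c(-5.07, 17.29, -18.06)
CASE10_INVERSE_R <- matrix(c(0.975, 0.173, 0.139,
                             -0.161, 0.983, -0.087,
                             -0.152, 0.061, 0.987), 3, 3, byrow = TRUE)
CASE10_AXIS_MAG <- c(0.3165, 0.6251, 0.7135)

# Published contour-comparison volume triples (deformed, target, common, cc)
# and their Dice coefficients; the SV_RT row is excluded everywhere because
# its printed volumes are rounding-inconsistent with its printed DSC.
CONTOUR_TABLE <- data.frame(
  name = c("Prostate", "Bladder", "Rectum", "Femur_L", "Femur_R", "SV_LT"),
  va = c(34.2, 239.2, 182.6, 288.3, 285.4, 3.4),
  vb = c(33.2, 224.5, 166.1, 281.8, 278.3, 3.5),
  vab = c(31.3, 221.8, 165.4, 278.5, 276.4, 3.03),
  dsc = c(0.929, 0.957, 0.949, 0.977, 0.981, 0.878),
  stringsAsFactors = FALSE)

random_rotation_spec <- function() {
  rotation_spec(x = stats::runif(1, -170, 170),
                y = stats::runif(1, -170, 170),
                z = stats::runif(1, -170, 170))
}

random_transform <- function() {
  homogeneous_transform(compose_rotations(random_rotation_spec()),
                        stats::runif(3, -50, 50),
                        direction = "target_to_moving")
}
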