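flat_angles <- function(t, hip = c(12, 3, -2), knee = c(-40, 1, 2),
                        ankle = c(8, -1, 0)) {
  mk <- function(v, joint) structure(
    data.frame(t = t, flexion = rep(v[1], length(t)),
               adduction = rep(v[2], length(t)),
               rotation = rep(v[3], length(t))),
    class = c("joint_angle_series", "data.frame"), joint = joint)
  list(hip = mk(hip, "hip"), knee = mk(knee, "knee"), ankle = mk(ankle, "ankle"))
}

flat_com <- function(t, p = c(0.5, 0, 0.9)) {
  structure(data.frame(t = t, x = p[1], y = p[2], z = p[3]),
            class = c("com_trajectory", "data.frame"))
}

test_that("value_at_event picks the nearest sample, ties to the earlier one", {
  t <- seq(0, 0.1, by = 0.01)
  s <- structure(data.frame(t = t, flexion = seq(30, 40, by = 1),
                            adduction = 0 * t, rotation = 0 * t),
                 class = c("joint_angle_series", "data.frame"), joint = "hip")
  expect_equal(value_at_event(s, "flexion", 0.03), 33)      # exact sample
  expect_equal(value_at_event(s, "flexion", 0.012), 31)     # nearer first
  expect_equal(value_at_event(s, "flexion", 0.015), 31)     # tie -> earlier
  expect_error(value_at_event(s, "flexion", 0.2), "outside")
})

test_that("axis_range matches analytic extrema", {
  t <- seq(0, 2, by = 0.01)
  const <- flat_angles(t)$hip
  expect_equal(axis_range(const, "flexion", c(0, 2)), 0)
  sine <- structure(data.frame(t = t, flexion = 3.5 * sin(2 * pi * t),
                               adduction = 0 * t, rotation = 0 * t),
                    class = c("joint_angle_series", "data.frame"), joint = "hip")
  expect_equal(axis_range(sine, "flexion", c(0, 2)), 7, tolerance = 0.01)
  expect_error(axis_range(sine, "flexion", c(5, 6)), "empty window")
})

test_that("CoM dispersion follows the documented quartile rule", {
  t <- seq(0, 0.03, by = 0.01)
  com <- structure(data.frame(t = t, x = 0 * t, y = -c(0, 1, 2, 3), z = 0.9),
                   class = c("com_trajectory", "data.frame"))
  # lab -y is the body mediolateral (right) axis under the default body axes
  d <- com_dispersion(com, "mediolateral", c(0, 0.03))
  expect_equal(d$range, 3)
  expect_equal(d$iqr, 1.5)
  cc <- flat_com(t)
  d0 <- com_dispersion(cc, "sagittal", c(0, 0.03))
  expect_equal(unlist(d0), c(iqr = 0, range = 0))
})

test_that("all-constant inputs populate the twelve features exactly", {
  t <- seq(0, 1, by = 0.01)
  ev <- stride_events(0.1, 0.6, 0.9)
  fv <- extract_features(flat_angles(t), flat_com(t), ev)
  expect_named(fv, feature_names())
  expect_equal(unname(fv["dorsiflexion_range"]), 0)
  expect_equal(unname(fv["com_ml_iqr"]), 0)
  expect_equal(unname(fv["hip_flexion_at_initial_contact"]), 12)
  expect_equal(unname(fv["hip_flexion_average"]), 12)
  expect_equal(unname(fv["knee_flexion_at_push_off"]), -40)
  expect_equal(unname(fv["ankle_adduction_at_push_off_end"]), -1)
  expect_equal(unname(fv["dorsiflexion_at_push_off"]), 8)
})

test_that("features are local: a hip-adduction offset at push-off moves one field", {
  t <- seq(0, 1, by = 0.01)
  ev <- stride_events(0.1, 0.6, 0.9)
  base <- flat_angles(t)
  fv0 <- extract_features(base, flat_com(t), ev)
  mod <- base
  # add a bump covering only the push-off sample neighbourhood
  bump <- ifelse(abs(t - 0.6) < 0.004, 2.5, 0)
  mod$hip$adduction <- mod$hip$adduction + bump
  fv1 <- extract_features(mod, flat_com(t), ev)
  expect_equal(unname(fv1["hip_adduction_at_push_off"] -
                        fv0["hip_adduction_at_push_off"]), 2.5)
  same <- setdiff(feature_names(), c("hip_adduction_at_push_off"))
  expect_equal(fv1[same], fv0[same], tolerance = 1e-12)
})

test_that("constant angle shifts move instant/average features, not ranges", {
  kin <- stride_fixture()
  fv0 <- extract_features(kin$angles, kin$com, kin$events)
  shifted <- kin$angles
  shifted$hip$flexion <- shifted$hip$flexion + 7
  fv1 <- extract_features(shifted, kin$com, kin$events)
  expect_equal(unname(fv1["hip_flexion_at_initial_contact"] -
                        fv0["hip_flexion_at_initial_contact"]), 7)
  expect_equal(unname(fv1["hip_flexion_average"] -
                        fv0["hip_flexion_average"]), 7)
  expect_equal(fv1["dorsiflexion_range"], fv0["dorsiflexion_range"])
})

test_that("feature extraction is invariant to a rigid lab rotation", {
  kin <- stride_fixture()
  win <- c(kin$events$t_initial_contact, kin$events$t_push_off_end)
  ba0 <- body_axes_from_pelvis(kin$orientations$pelvis, win)
  fv0 <- extract_features(kin$angles, kin$com, kin$events, ba0)
  set.seed(81)
  Rlab <- random_rotation()
  com_rot <- structure(
    data.frame(t = kin$com$t,
               t(Rlab %*% t(cbind(kin$com$x, kin$com$y, kin$com$z)))),
    names = c("t", "x", "y", "z"),
    class = c("com_trajectory", "data.frame"))
  pelvis_rot <- orientation_series(
    kin$t, t(apply(kin$orientations$pelvis$q, 1, function(q)
      quat_multiply(matrix_to_quat(Rlab), q))))
  ba1 <- body_axes_from_pelvis(pelvis_rot, win)
  fv1 <- extract_features(kin$angles, com_rot, kin$events, ba1)
  expect_equal(fv1, fv0, tolerance = 1e-6)
})
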