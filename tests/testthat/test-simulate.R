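test_that("zero keypoints give identity orientations throughout", {
  kp <- lapply(default_keypoints(), function(j) lapply(j, function(a) a * 0))
  kin <- generate_stride(stride_params(keypoints = kp, com_sway_ml = 0,
                                       com_sway_vertical = 0, speed = 0))
  for (seg in c("thigh", "shank", "foot")) {
    errs <- vapply(seq_along(kin$t), function(i)
      deg_between(kin$orientations[[seg]]$q[i, ], c(1, 0, 0, 0)), numeric(1))
    expect_lt(max(errs), 1e-9)
  }
})

test_that("stride keypoints produce the constructed feature ground truth", {
  kin <- stride_fixture()
  fv <- extract_features(kin$angles, kin$com, kin$events)
  kp <- default_keypoints()
  # dorsiflexion keypoints span (-10, 18): range >= 28 (spline may overshoot
  # between knots, never undershoot the knot span)
  expect_gte(fv[["dorsiflexion_range"]], 28)
  expect_lt(fv[["dorsiflexion_range"]], 31)
  # instant features read the keypoints exactly (events sit on knots)
  expect_equal(fv[["hip_flexion_at_initial_contact"]],
               kp$hip$flexion[["ic"]], tolerance = 0.2)
  expect_equal(fv[["knee_flexion_at_push_off"]],
               kp$knee$flexion[["po"]], tolerance = 0.2)
  expect_equal(fv[["hip_adduction_at_push_off"]],
               kp$hip$adduction[["po"]], tolerance = 0.2)
  expect_equal(fv[["dorsiflexion_at_push_off"]],
               kp$ankle$flexion[["po"]], tolerance = 0.2)
  # CoM sway amplitude a gives range ~ 2a in each plane
  expect_equal(fv[["com_ml_range"]], 2 * 0.04, tolerance = 0.002)
  expect_equal(fv[["com_sagittal_range"]], 2 * 0.02, tolerance = 0.002)
})

test_that("forward kinematics and JCS decomposition are mutually inverse", {
  kin <- stride_fixture()
  pairs <- list(hip = c("pelvis", "thigh"), knee = c("thigh", "shank"),
                ankle = c("shank", "foot"))
  for (j in names(pairs)) {
    a <- jcs_angles(kin$orientations[[pairs[[j]][1]]],
                    kin$orientations[[pairs[[j]][2]]], j)
    for (ax in c("flexion", "adduction", "rotation"))
      expect_equal(a[[ax]], kin$angles[[j]][[ax]], tolerance = 1e-9)
  }
})

test_that("keypoints outside anatomical bounds are rejected", {
  kp <- default_keypoints()
  kp$hip$flexion["mid"] <- 150
  expect_error(stride_params(keypoints = kp), "anatomical range")
  expect_error(stride_params(calibre_deltas = c(nonexistent_feature = 1)),
               "unsupported")
})

test_that("noise-free virtual markers reproduce poses; noisy ones stay bounded", {
  kin <- stride_fixture()
  ms <- synthesize_markers(kin)
  f <- anatomical_frame(ms, "thigh", 50)
  expect_equal(f$r, quat_to_matrix(kin$orientations$thigh$q[50, ]),
               tolerance = 1e-9)
  # static pose, zero noise: template positions exactly
  kp0 <- lapply(default_keypoints(), function(j) lapply(j, function(a) a * 0))
  kin0 <- generate_stride(stride_params(keypoints = kp0, com_sway_ml = 0,
                                        com_sway_vertical = 0, speed = 0,
                                        pelvis_height = 0))
  ms0 <- synthesize_markers(kin0)
  tpl <- landmark_template()
  expect_equal(unname(ms0$markers$RASIS[1, ]), tpl$pelvis$RASIS,
               tolerance = 1e-12)
})

test_that("virtual IMU signals match their kinematic definitions", {
  # static identity pose: zero rates, specific force +g up, reference field
  n <- 51; t <- seq(0, 0.5, by = 0.01)
  qs <- orientation_series(t, matrix(rep(c(1, 0, 0, 0), n), n, byrow = TRUE))
  still <- matrix(0, n, 3)
  rec <- synthesize_imu(qs, still)
  expect_equal(max(abs(rec$gyro)), 0)
  expect_equal(rec$accel[25, ], c(0, 0, 9.81), tolerance = 1e-9)
  expect_equal(rec$mag[25, ], c(0.4, 0, -0.3), tolerance = 1e-12)
  # constant 10 deg/s yaw: gyro constant (0, 0, 10 deg/s) in the body frame
  w <- 10 * pi / 180
  qy <- orientation_series(t, t(vapply(t, function(tt)
    quat_from_axis_angle(c(0, 0, 1), w * tt), numeric(4))))
  rec2 <- synthesize_imu(qy, still)
  expect_equal(rec2$gyro[10, ], c(0, 0, w), tolerance = 1e-9)
  # saturation warning on unrealistic rates
  fast <- orientation_series(t, t(vapply(t, function(tt)
    quat_from_axis_angle(c(0, 0, 1), 40 * tt), numeric(4))))
  expect_warning(synthesize_imu(fast, still), "clipped")
})

test_that("fusing a synthesized recording recovers the source orientations", {
  kin <- stride_fixture()
  for (seg in c("pelvis", "foot")) {
    rec <- synthesize_imu(kin$orientations[[seg]], kin$origins[[seg]])
    q <- fuse_imu(rec)
    errs <- vapply(seq_along(q$t), function(i)
      deg_between(q$q[i, ], kin$orientations[[seg]]$q[i, ]), numeric(1))
    expect_lt(max(errs[-(1:10)]), 0.5)
  }
  # with a fixed origin (no linear acceleration) recovery is tighter
  still <- matrix(0, length(kin$t), 3)
  rec <- synthesize_imu(kin$orientations$foot, still)
  q <- fuse_imu(rec)
  errs <- vapply(seq_along(q$t), function(i)
    deg_between(q$q[i, ], kin$orientations$foot$q[i, ]), numeric(1))
  expect_lt(max(errs[-(1:10)]), 0.2)
})

test_that("cohorts are reproducible and encode the calibre construction", {
  c1 <- generate_cohort(seed = 10, signals = FALSE)
  c2 <- generate_cohort(seed = 10, signals = FALSE)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$experience, c2$experience)
  expect_equal(nrow(c1$features), 60)
  expect_true(all(table(c1$features$participant) == 5))
  # trials of one participant all share the participant's label
  lab_per_part <- tapply(as.character(c1$features$calibre),
                         c1$features$participant,
                         function(x) length(unique(x)))
  expect_true(all(lab_per_part == 1))
  # k-means on the drawn experience regenerates the 6/6 split
  split <- kmeans_calibre(c1$experience)
  expect_equal(as.character(split), as.character(c1$calibre),
               ignore_attr = TRUE)
  expect_equal(sum(split == "high"), 6)
  # injected deltas appear in the group feature means with the right sign
  dm <- function(f) mean(c1$features[[f]][c1$features$calibre == "high"]) -
    mean(c1$features[[f]][c1$features$calibre == "low"])
  expect_equal(dm("dorsiflexion_range"), 5, tolerance = 1.5)
  expect_equal(dm("hip_adduction_at_push_off"), -4, tolerance = 1.5)
  expect_equal(dm("knee_flexion_at_push_off"), 5, tolerance = 1.5)
  # null construction: no deltas -> group means differ only by jitter
  c0 <- generate_cohort(params = stride_params(calibre_deltas = numeric(0)),
                        seed = 10, signals = FALSE)
  dm0 <- function(f) mean(c0$features[[f]][c0$features$calibre == "high"]) -
    mean(c0$features[[f]][c0$features$calibre == "low"])
  expect_lt(abs(dm0("dorsiflexion_range")), 1.5)
})

test_that("validation error grows with sensor noise (coarse monotonicity)", {
  mk <- function(scale) {
    nm <- noise_model(0.3 * scale, 0.5 * scale, 0.05 * scale, 0.005 * scale,
                      0.001 * scale, 2 * scale)
    co <- generate_cohort(n_high = 1, n_low = 1, trials = 1, noise = nm,
                          seed = 20, signals = TRUE)
    max_participant_rms(suppressWarnings(cohort_validation(co)))
  }
  errs <- vapply(c(0, 1, 4), mk, numeric(1))
  expect_true(all(diff(errs) > 0))
})
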