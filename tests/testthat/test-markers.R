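# canonical static marker set built from the landmark template at given poses
template_markers <- function(R = diag(3), origin = c(0, 0, 0), n = 3,
                             segment = "pelvis") {
  tpl <- landmark_template()[[segment]]
  t <- seq(0, by = 0.01, length.out = n)
  markers <- lapply(tpl, function(p) {
    pos <- as.numeric(R %*% p) + origin
    matrix(rep(pos, n), n, byrow = TRUE)
  })
  marker_set(t, markers)
}

test_that("anatomical frames reproduce canonical and rigidly moved layouts", {
  for (seg in c("pelvis", "thigh", "shank", "foot")) {
    ms <- template_markers(segment = seg)
    f <- anatomical_frame(ms, seg, 1)
    expect_equal(f$r, diag(3), tolerance = 1e-12)
  }
  set.seed(51)
  for (i in 1:10) {
    R <- random_rotation(); d <- stats::rnorm(3)
    for (seg in c("pelvis", "foot")) {
      ms <- template_markers(R, d, segment = seg)
      f <- anatomical_frame(ms, seg, 1)
      expect_equal(f$r, R, tolerance = 1e-9)
      expect_silent(check_rotation(f$r, tol = 1e-9))
    }
  }
})

test_that("missing and degenerate landmarks raise named errors", {
  ms <- template_markers(segment = "pelvis")
  ms$markers$RASIS <- NULL
  expect_error(anatomical_frame(ms, "pelvis", 1), "RASIS")
  ms2 <- template_markers(segment = "pelvis")
  ms2$markers$RASIS <- ms2$markers$LASIS           # coincident ASIS markers
  expect_error(anatomical_frame(ms2, "pelvis", 1), "degenerate")
  ms3 <- template_markers(segment = "pelvis")
  ms3$markers$LPSIS[2, ] <- NA
  expect_error(anatomical_frame(ms3, "pelvis", 2), "NaN|missing")
  expect_error(anatomical_frame(template_markers(), "femur"), "unknown segment")
})

test_that("millimetre coordinates are auto-detected and converted", {
  tpl <- landmark_template()$pelvis
  t <- c(0, 0.01)
  mm <- lapply(tpl, function(p) matrix(rep(p * 1000, 2), 2, byrow = TRUE))
  expect_message(ms <- marker_set(t, mm), "millimetres")
  expect_equal(ms$markers$RASIS[1, ], tpl$RASIS, tolerance = 1e-12)
})

test_that("reference orientation stream matches ground truth and tolerates noise", {
  kin <- stride_fixture()
  ms <- synthesize_markers(kin)
  for (seg in c("pelvis", "thigh", "shank", "foot")) {
    ref <- reference_segment_orientation(ms, seg)
    errs <- vapply(seq_along(ref$t), function(i)
      deg_between(ref$q[i, ], kin$orientations[[seg]]$q[i, ]), numeric(1))
    expect_lt(max(errs), 1e-9)
  }
  # 1 mm marker noise keeps the mean orientation error below 1 deg for this
  # geometry (per-sample extremes stay within a few degrees)
  ms_noisy <- synthesize_markers(kin, noise_sigma = 0.001, seed = 52)
  for (seg in c("pelvis", "foot")) {
    ref <- reference_segment_orientation(ms_noisy, seg)
    errs <- vapply(seq_along(ref$t), function(i)
      deg_between(ref$q[i, ], kin$orientations[[seg]]$q[i, ]), numeric(1))
    expect_lt(mean(errs), 1)
    expect_lt(max(errs), 4)
  }
  # a gap inside the window is reported with its sample index
  ms$markers$TOE[100, ] <- NA
  expect_error(reference_segment_orientation(ms, "foot"), "100")
})

test_that("CoM proxy is the PSIS midpoint with affine equivariance", {
  t <- c(0, 0.01)
  base <- list(LPSIS = rbind(c(0, 1, 1), c(0, 1, 1)),
               RPSIS = rbind(c(0, -1, 1), c(0, -1, 1)))
  com <- com_proxy(marker_set(t, base))
  expect_equal(unlist(com[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 1))
  d <- c(0.3, -0.2, 0.5)
  shifted <- lapply(base, function(m) sweep(m, 2, d, "+"))
  com2 <- com_proxy(marker_set(t, shifted))
  expect_equal(as.numeric(com2[1, c("x", "y", "z")]), c(0, 0, 1) + d)
  expect_error(com_proxy(marker_set(t, base["LPSIS"])), "RPSIS")
})

test_that("the shipped JSON recipe table equals the built-in conventions", {
  path <- system.file("extdata", "segment_recipes.json", package = "skatekin")
  expect_equal(read_segment_recipes(path), segment_recipes())
})
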