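# shared fixtures and small independent oracles

# uniformly distributed random unit quaternion (Shoemake subgroup algorithm)
random_quat <- function() {
  u <- stats::runif(3)
  quat_normalize(c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
                   sqrt(1 - u[1]) * cos(2 * pi * u[2]),
                   sqrt(u[1]) * sin(2 * pi * u[3]),
                   sqrt(u[1]) * cos(2 * pi * u[3])))
}

random_rotation <- function() quat_to_matrix(random_quat())

deg_between <- function(a, b) quat_angle(a, b) * 180 / pi

# elementary rotation matrices, built independently of the package
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}

# a static imu_recording consistent with orientation R (lab-to-body columns)
static_recording <- function(R = diag(3), duration = 1, fs = 100,
                             params = fusion_params()) {
  n <- duration * fs + 1
  t <- seq(0, duration, by = 1 / fs)
  accel <- matrix(rep(crossprod(R, params$ref_gravity), n), n, byrow = TRUE)
  mag <- matrix(rep(crossprod(R, params$ref_field), n), n, byrow = TRUE)
  imu_recording(t, matrix(0, n, 3), accel, mag)
}

# noise-free default-parameter stride, reused across test files
stride_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_stride(stride_params(), fs = 100)
    cache
  }
})
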