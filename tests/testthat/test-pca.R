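test_that("segment window selection keeps whole windows inside the segment", {
  ser <- band_energy_series(sine_recording(15, duration_s = 20))
  # onset at 0: initial 5 s holds the four windows starting at 0..3
  expect_equal(select_segment_windows(ser, 0, 12, "initial"), 1:4)
  # 10 s seizure, whole mode: starts 0..8
  expect_equal(select_segment_windows(ser, 0, 10, "whole"), 1:9)
  # initial_len equal to the window length: exactly one window
  expect_equal(select_segment_windows(ser, 0, 12, "initial",
                                      initial_len_s = 2), 1)
  # offset onset: containment arithmetic shifts with it
  expect_equal(select_segment_windows(ser, 3, 11, "initial"), 4:7)
  expect_error(select_segment_windows(ser, 0, 1.5, "whole"), "shorter")
})

test_that("second-moment accumulation matches the brute-force definition", {
  v <- c(1, 2, 0, 0, 3)
  acc <- accumulate_second_moment(matrix(v, nrow = 1))
  expect_equal(acc$C, v %o% v)
  expect_equal(qr(acc$C)$rank, 1)

  u1 <- c(1, 0, 0, 0, 0); u2 <- c(0, 1, 0, 0, 0)
  acc2 <- accumulate_second_moment(rbind(u1, u2))
  expect_equal(acc2$C, (u1 %o% u1 + u2 %o% u2) / 2)
  expect_equal(sum(diag(acc2$C)), 1)

  set.seed(31)
  X <- matrix(abs(rnorm(500)), ncol = 5)
  got <- accumulate_second_moment(X)
  want <- matrix(0, 5, 5)
  for (i in seq_len(nrow(X))) want <- want + X[i, ] %o% X[i, ]
  want <- want / nrow(X)
  expect_equal(got$C, want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$n, 100)
  expect_error(accumulate_second_moment(X[0, , drop = FALSE]), "no windows")
})

test_that("dominant eigenvector solves C e = lambda e with fixed orientation", {
  f <- dominant_eigenvector(diag(c(5, 1, 1, 1, 1)))
  expect_equal(f$e, c(1, 0, 0, 0, 0))
  expect_equal(f$lambda, 5)

  v <- c(3, 4, 0, 0, 0)
  f2 <- dominant_eigenvector(v %o% v)
  expect_equal(f2$e, c(0.6, 0.8, 0, 0, 0))
  expect_equal(f2$lambda, 25)

  expect_warning(dominant_eigenvector(diag(c(2, 2, 1, 1, 1))), "tie")

  set.seed(32)
  for (i in 1:25) {
    C <- random_psd()
    f3 <- dominant_eigenvector(C)
    expect_lte(sqrt(sum((C %*% f3$e - f3$lambda * f3$e)^2)),
               1e-8 * norm(C, "2"))
    expect_gte(f3$lambda, max(diag(C)))
    oracle <- power_iteration_oracle(C)
    expect_lt(angle_deg(f3$e, oracle$e), 1e-8)
  }
})

test_that("projection is the per-window dot product", {
  ser <- band_energy_series(sine_recording(10, 6))
  e <- c(0, 0, 1, 0, 0)
  # X_n = c * e for a unit e gives u_n = c
  ser2 <- ser
  ser2$energies <- outer(1:5, e)
  expect_equal(project_feature(ser2, e)$values, 1:5)
  # orthogonal energies project to zero
  ser2$energies <- outer(1:5, c(1, 0, 0, 0, 0))
  expect_equal(project_feature(ser2, e)$values, rep(0, 5))
  # random series equals the loop oracle
  set.seed(33)
  w <- abs(rnorm(5)); w <- w / sqrt(sum(w^2))
  u <- project_feature(ser, w)$values
  expect_equal(u, apply(ser$energies, 1, function(r) sum(r * w)))
})

test_that("single-band features equal one-hot projections", {
  ser <- band_energy_series(sine_recording(20, 6))
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    one_hot <- as.numeric(eeg_bands()$name == b)
    expect_equal(subband_feature(ser, b)$values,
                 project_feature(ser, one_hot)$values)
  }
  expect_error(subband_feature(ser, "mu"), "unknown band")
})

test_that("eigenvector angles are axis angles in degrees", {
  expect_equal(eigenvector_angle(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 0)
  expect_equal(eigenvector_angle(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)), 90)
  expect_equal(eigenvector_angle(c(0.6, 0.8, 0, 0, 0), c(1, 0, 0, 0, 0)),
               acos(0.6) * 180 / pi, tolerance = 1e-10)
  # sign flips do not matter
  expect_equal(eigenvector_angle(c(0.6, 0.8, 0, 0, 0),
                                 -c(0.6, 0.8, 0, 0, 0)), 0)
  expect_error(eigenvector_angle(rep(0, 5), c(1, 0, 0, 0, 0)), "zero")
})

test_that("accumulated second moments keep the Perron sign structure", {
  set.seed(34)
  for (i in 1:20) {
    X <- matrix(stats::rlnorm(100), ncol = 5)
    f <- dominant_eigenvector(accumulate_second_moment(X))
    expect_gte(min(f$e), -1e-10)
  }
})

test_that("a planted energy direction is recovered from noisy windows", {
  set.seed(35)
  w <- c(0.1, 0.1, 0.35, 0.9, 0.1); w <- w / sqrt(sum(w^2))
  s <- stats::rlnorm(500, 3, 0.5)
  X <- outer(s, w) + matrix(rnorm(2500, sd = 0.1 * mean(s)), ncol = 5)
  f <- dominant_eigenvector(accumulate_second_moment(X))
  expect_lt(angle_deg(f$e, w), 5)
})

test_that("trained models round-trip through JSON", {
  ds <- small_dataset()
  series <- lapply(ds$seizures[1:4], function(s)
    band_energy_series(s$recording))
  anns <- lapply(ds$seizures[1:4], function(s) s$annotation)
  feat <- train_eigenfeature(series, anns, mode = "initial")
  expect_equal(feat$segment_mode, "initial_5s")
  expect_equal(sum(feat$e^2), 1, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(feat, path, config_hash = "abc")
  back <- load_model(path)
  expect_equal(back$e, feat$e, tolerance = 1e-12)
  expect_equal(back$lambda, feat$lambda, tolerance = 1e-12)
  expect_equal(back$segment_mode, "initial_5s")
})
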