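test_that("dipole Bz matches the closed-form free-space expression", {
  ## on the z-axis an x-directed dipole has no Bz
  expect_equal(dipole_bz(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0.01)), 0)
  ## off-axis closed form: mu0/4pi * y / (y^2 + d^2)^(3/2)
  y <- 0.05; d <- 0.01
  expect_equal(dipole_bz(c(1, 0, 0), c(0, 0, 0), c(0, y, d)),
               1e-7 * y / (y^2 + d^2)^1.5, tolerance = 1e-12)
  ## antisymmetry across the x-z plane
  expect_equal(dipole_bz(c(1, 0, 0), c(0, 0, 0), c(0, -y, d)),
               -dipole_bz(c(1, 0, 0), c(0, 0, 0), c(0, y, d)))
  expect_error(dipole_bz(c(1, 0, 0), c(0, 0, 0.01), c(0, 0, 0.01)),
               "coincides")
})

test_that("forward model is linear in the moment and matches the lead field", {
  set.seed(1)
  arr <- default_sensor_array()
  src <- c(0.01, -0.02, -0.05)
  lf <- leadfield_bz(arr, src)
  for (r in 1:5) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    s <- sample(64, 1)
    pos <- c(arr$x[s], arr$y[s], arr$z[s])
    b1 <- dipole_bz(p1, src, pos)
    b2 <- dipole_bz(p2, src, pos)
    expect_equal(dipole_bz(p1 + p2, src, pos), b1 + b2, tolerance = 1e-14)
    ## lead-field row reproduces the closed form
    expect_equal(as.numeric(lf[s, ] %*% p1), b1, tolerance = 1e-12)
  }
})

test_that("default sensor array has 64 distinct positions at the standoff", {
  arr <- default_sensor_array()
  expect_equal(nrow(arr), 64L)
  expect_true(all(arr$z == 0.01))
  expect_equal(anyDuplicated(round(arr[, c("x", "y")], 10)), 0L)
  expect_identical(arr, default_sensor_array())  # deterministic
})

test_that("simulated recordings have the contracted shape and metadata", {
  rec <- simulate_recording(minutes = 1, seed = 7L)
  expect_equal(dim(rec$signal), c(64L, 30000L))
  expect_equal(rec$fs, 500L)
  expect_true(all(rec$labels %in% c(0, 1)))
  expect_true(all(rec$signal[!rec$valid_channels, ] == 0))
  expect_error(simulate_recording(minutes = 0), "positive")
  expect_error(simulate_recording(rr_mean = -1), "positive")
})

test_that("a designated channel with dropout probability 1 is zeroed", {
  p <- rep(0, 64); p[12] <- 1
  rec <- simulate_recording(minutes = 0.1, missing_prob = p, seed = 3L)
  expect_true(all(rec$signal[12, ] == 0))
  expect_false(rec$valid_channels[12])
  expect_true(all(rec$valid_channels[-12]))
})

test_that("noise-free simulation agrees with an independent dipole oracle", {
  ## independent re-evaluation: Gaussian-bump moment from the wave table,
  ## evaluated per sensor through the closed-form dipole expression
  rec <- simulate_recording(minutes = 1 / 60, noise_white = 0, drift_amp = 0,
                            line_amp = 0, missing_prob = 0, rr_sd = 0,
                            rr_mean = 0.85, subject_variability = 0,
                            seed = 5L)
  arr <- rec$sensor_array
  waves <- magcardia:::mcg_wave_table()
  n <- ncol(rec$signal)
  tt <- (seq_len(n) - 1) / 500
  onset <- floor(tt / 0.85) * 0.85
  theta <- -pi + 2 * pi * (tt - onset) / 0.85
  wrap <- function(x) ((x + pi) %% (2 * pi)) - pi
  m <- matrix(0, 3, n)
  for (i in seq_len(nrow(waves))) {
    amp <- waves$a[i] * exp(-wrap(theta - waves$theta[i])^2 /
                              (2 * waves$b[i]^2))
    m <- m + outer(c(cos(waves$dir[i]), sin(waves$dir[i]), 0), amp)
  }
  expected <- matrix(0, 64, n)
  for (s in 1:64) {
    pos <- c(arr$x[s], arr$y[s], arr$z[s])
    for (t in seq(1, n, by = 25)) {  # every 50 ms across the beat
      expected[s, t] <- dipole_bz(m[, t], c(0, 0, -0.06), pos) * 1e12
    }
  }
  idx <- seq(1, n, by = 25)
  expect_equal(rec$signal[, idx], expected[, idx], tolerance = 1e-10)
})

test_that("field amplitude strictly decreases with standoff", {
  a1 <- default_sensor_array(standoff = 0.01)
  a2 <- default_sensor_array(standoff = 0.02)
  r1 <- simulate_recording(minutes = 0.05, noise_white = 0, drift_amp = 0,
                           line_amp = 0, missing_prob = 0, seed = 2L,
                           sensor_array = a1)
  r2 <- simulate_recording(minutes = 0.05, noise_white = 0, drift_amp = 0,
                           line_amp = 0, missing_prob = 0, seed = 2L,
                           sensor_array = a2)
  expect_lt(max(abs(r2$signal)), max(abs(r1$signal)))
})

test_that("class effects scale monotonically and vanish at effect size 0", {
  base_args <- list(minutes = 0.1, noise_white = 0, drift_amp = 0,
                    line_amp = 0, missing_prob = 0, seed = 9L)
  ctrl <- do.call(simulate_recording, c(base_args, class_label = "control"))
  for (cl in c("cad_lcx", "low_ef", "af_substrate")) {
    z <- do.call(simulate_recording,
                 c(base_args, class_label = cl, effect_size = 0))
    expect_equal(z$signal, ctrl$signal, tolerance = 1e-12)
    contrasts <- vapply(c(0.5, 1, 2, 4), function(e) {
      r <- do.call(simulate_recording,
                   c(base_args, class_label = cl, effect_size = e))
      mean(abs(r$signal - ctrl$signal))
    }, numeric(1))
    expect_true(all(diff(contrasts) > 0), info = cl)
  }
})

test_that("cohorts respect proportions, determinism and seed sensitivity", {
  spec <- cohort_spec(40, c(control = 0.5, cad_lcx = 0.5),
                      minutes_per_patient = 0.05, seed = 21L)
  coh <- simulate_cohort(spec)
  expect_length(coh, 40L)
  pos <- sum(vapply(coh, function(r) r$labels[["cad_multivessel"]],
                    numeric(1)))
  expect_equal(pos, 20)
  coh2 <- simulate_cohort(spec)
  expect_identical(lapply(coh, `[[`, "signal"), lapply(coh2, `[[`, "signal"))
  spec2 <- cohort_spec(40, c(control = 0.5, cad_lcx = 0.5),
                       minutes_per_patient = 0.05, seed = 22L)
  coh3 <- simulate_cohort(spec2)
  expect_false(identical(coh[[1]]$signal, coh3[[1]]$signal))
})
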