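test_that("R-peak detection recovers simulator ground truth", {
  segs <- sim_segments_one_patient()
  for (seg in segs[1:2]) {
    peaks <- detect_r_peaks(seg)
    ## beats at the very segment edge cannot be localised (their QRS is
    ## clipped), so compare over the interior
    truth <- seg$gt_r_peaks
    interior <- function(v) v[v >= 100 & v <= 4900]
    expect_equal(length(interior(peaks)), length(interior(truth)))
    ## every interior detection within +/- 20 ms (10 samples) of a true peak
    for (p in interior(peaks)) expect_lte(min(abs(truth - p)), 10)
    expect_true(all(diff(peaks) >= 100))  # 200 ms refractory
  }
})

test_that("undetectable and boundary cases are handled", {
  expect_length(detect_r_peaks(matrix(0, 64, 5000)), 0L)
  ## 72 bpm for 10 s -> 11-13 peaks (reference morphology, no subject
  ## heart-rate factor, so the count reflects the stated RR distribution)
  rec <- simulate_recording(minutes = 1 / 3, rr_mean = 60 / 72, rr_sd = 0.02,
                            subject_variability = 0, seed = 31L)
  seg <- preprocess_pipeline(rec)[[1]]
  n <- length(detect_r_peaks(seg))
  expect_gte(n, 11L)
  expect_lte(n, 13L)
})

test_that("beat matrices stack complete fixed windows only", {
  x <- matrix(rnorm(2 * 5000), 2)
  peaks <- as.integer(seq(300, 4700, length.out = 10))
  bm <- build_beat_matrix(x, peaks)
  expect_equal(dim(bm$beats), c(10L, 300L, 2L))
  ## a peak 50 samples from the start cannot host the 75-sample pre-window
  bm2 <- build_beat_matrix(x, c(50L, peaks))
  expect_equal(dim(bm2$beats)[1], 10L)
  expect_null(build_beat_matrix(x, c(10L, 4990L)))
})

test_that("noise-free identical beats align and score far above threshold", {
  rec <- simulate_recording(minutes = 0.5, noise_white = 0, drift_amp = 0,
                            line_amp = 0, missing_prob = 0, rr_sd = 0,
                            subject_variability = 0, seed = 41L)
  seg <- preprocess_pipeline(rec)[[1]]
  peaks <- detect_r_peaks(seg)
  bm <- build_beat_matrix(seg, peaks)
  ## beats well inside the window are identical (within filter tolerance;
  ## beats near the segment edges carry residual filtering edge effects)
  rows <- which(bm$r_peaks >= 1000 & bm$r_peaks <= 4000)
  m <- bm$beats[, , 5]
  interior <- m[rows, , drop = FALSE]
  expect_gte(nrow(interior), 5L)
  ## "filter tolerance": the 0.5 Hz high-pass resolves ~1% differences
  ## across beats of a 10-s window
  expect_lt(max(abs(sweep(interior, 2, interior[1, ]))),
            0.02 * max(abs(m)))
  rep_ <- svd_snr(bm, k = 1)
  expect_gt(rep_$mean_snr, 30)
  expect_true(rep_$pass)
})

test_that("an exactly rank-1 beat matrix is capped at 80 dB", {
  bm <- synthetic_beat_matrix(30, 100, 2, noise_sd = 0)
  rep_ <- svd_snr(bm, k = 1)
  expect_true(all(rep_$channel_snr == 80))
  expect_true(rep_$pass)
})

test_that("rank-k reconstruction satisfies the Eckart-Young identity", {
  set.seed(6)
  for (i in 1:10) {
    nr <- sample(3:6, 1); nc <- sample(4:8, 1)
    m <- matrix(rnorm(nr * nc), nr)
    k <- sample(seq_len(nr - 1L), 1)
    rec <- magcardia:::lowrank_approx(m, k)
    d <- svd(m)$d
    expect_equal(sqrt(sum((m - rec)^2)),
                 sqrt(sum(d[-seq_len(k)]^2)), tolerance = 1e-10)
  }
})

test_that("SNR estimates a known 10 dB signal-to-noise power ratio", {
  set.seed(7)
  est <- replicate(20, {
    bm <- synthetic_beat_matrix(200, 100, 1, noise_sd = sqrt(0.1))
    svd_snr(bm, k = 1)$mean_snr
  })
  expect_equal(mean(est), 10, tolerance = 0.5 / 10)
})

test_that("pure noise scores below the exclusion threshold", {
  set.seed(8)
  for (i in 1:5) {
    bm <- synthetic_beat_matrix(50, 100, 1, noise_sd = 1,
                                template = rep(0, 100))
    bm$beats <- array(rnorm(50 * 100), c(50, 100, 1))
    expect_lt(svd_snr(bm, k = 1)$mean_snr, 5)
  }
})

test_that("SNR is monotone in added noise and scale invariant", {
  set.seed(9)
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  snr_by_noise <- sapply(grid, function(ns) {
    mean(replicate(20, {
      bm <- synthetic_beat_matrix(60, 80, 1, noise_sd = ns)
      svd_snr(bm, k = 1)$mean_snr
    }))
  })
  expect_true(all(diff(snr_by_noise) < 0))
  ## scale invariance: power ratio is unchanged by positive scaling
  bm <- synthetic_beat_matrix(40, 80, 2, noise_sd = 0.3)
  r1 <- svd_snr(bm, k = 2)
  bm$beats <- bm$beats * 7.3
  r2 <- svd_snr(bm, k = 2)
  expect_equal(r1$channel_snr, r2$channel_snr, tolerance = 1e-10)
})

test_that("all-zero channels carry no SNR and are excluded from the mean", {
  set.seed(10)
  bm <- synthetic_beat_matrix(30, 60, 3, noise_sd = 0.2)
  bm$beats[, , 2] <- 0
  bm$valid_channels[2] <- FALSE
  rep_ <- svd_snr(bm, k = 1)
  expect_true(is.na(rep_$channel_snr[2]))
  expect_equal(rep_$mean_snr, mean(rep_$channel_snr[c(1, 3)]))
})

test_that("the exclusion rule keeps exactly-at-threshold segments", {
  set.seed(11)
  bm <- synthetic_beat_matrix(60, 80, 1, noise_sd = 0.4)
  snr <- svd_snr(bm, k = 1)$mean_snr
  ## mean SNR < threshold is excluded; equality is kept
  expect_true(svd_snr(bm, k = 1, threshold = snr)$pass)
  expect_false(svd_snr(bm, k = 1, threshold = snr + 1e-6)$pass)
})

test_that("qc_filter partitions, annotates and keeps clean simulations", {
  segs <- sim_segments_one_patient()
  res <- qc_filter(segs)
  expect_equal(length(res$kept) + length(res$rejected), length(segs))
  expect_equal(length(res$kept), length(segs))  # clean simulator passes
  expect_true(all(vapply(res$kept, function(s) is.finite(s$snr),
                         logical(1))))
  expect_equal(nrow(res$report), length(segs))
  ## a dead segment is rejected as undetectable
  dead <- fake_segment(matrix(0, 64, 5000))
  res2 <- qc_filter(list(dead))
  expect_length(res2$kept, 0L)
  expect_equal(res2$report$reason, "undetectable")
})
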