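## Synthetic 64-channel magnetocardiogram generator. One rotating current
## dipole below the array centre generates the P-QRS-T cycle as a sum of
## Gaussian bumps in beat phase (ECGSYN-style dynamics); class-conditional
## perturbations add a displaced ST-T-timed secondary dipole (coronary
## territory effects), scale/widen the QRS (reduced ejection fraction), or
## prolong/duplicate and jitter the P wave (atrial-fibrillation substrate).
## Noise: per-channel white Gaussian, slow sinusoidal baseline drift, 50 Hz
## line interference, and randomly dropped (zeroed) channels.

MCG_CLASSES <- c("control", "cad_lad", "cad_lcx", "cad_rca",
                 "low_ef", "af_substrate")

## Base wave table: amplitudes relative to R = 30, phase centres in beat
## phase (R at 0), Gaussian widths in radians, moment direction in the
## sensor plane (degrees). Overall scale 20 uA*m at the R peak gives
## ~100-200 pT fields at a 1 cm standoff, the typical MCG range.
mcg_wave_table <- function() {
  tibble::tibble(
    wave  = c("P", "Q", "R", "S", "T"),
    a     = c(1.2, -5, 30, -7.5, 3) / 30 * 20e-6,  # A*m
    theta = c(-pi / 3, -pi / 12, 0, pi / 12, pi / 2),
    b     = c(0.25, 0.1, 0.1, 0.1, 0.4),
    dir   = c(70, -30, 0, 170, 40) * pi / 180
  )
}

## Territory displacements of the secondary ST-T source (metres, array
## coordinates): anterior-septal (LAD, +y), lateral (LCX, +x),
## inferior (RCA, -y).
territory_displacement <- function(class_label) {
  switch(class_label,
         cad_lad = c(0, 0.035, 0),
         cad_lcx = c(0.045, 0, 0),
         cad_rca = c(0, -0.045, 0),
         stop("not a coronary territory class: ", class_label))
}

## Binary task labels implied by a patient class. The synthetic territory
## effect stands in for high-burden obstructive CAD, so any cad_* class is
## positive for the CAD task and for its own vessel.
task_labels <- function(class_label) {
  lab <- c(cad_multivessel = 0, lvef_reduced = 0, af_risk = 0,
           lad = 0, lcx = 0, rca = 0)
  if (startsWith(class_label, "cad_")) {
    lab["cad_multivessel"] <- 1
    lab[sub("cad_", "", class_label)] <- 1
  } else if (class_label == "low_ef") {
    lab["lvef_reduced"] <- 1
  } else if (class_label == "af_substrate") {
    lab["af_risk"] <- 1
  }
  lab
}

wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Simulate one synthetic MCG recording
#'
#' @param class_label One of `control`, `cad_lad`, `cad_lcx`, `cad_rca`,
#'   `low_ef`, `af_substrate`.
#' @param minutes Recording duration in minutes.
#' @param effect_size Non-negative strength of the class effect; 0 reproduces
#'   the control generator on the same random stream.
#' @param noise_white White-noise standard deviation per channel (pT).
#' @param drift_amp Baseline-drift amplitude (pT, ~0.1-0.3 Hz sinusoids).
#' @param line_amp 50 Hz line-interference amplitude (pT).
#' @param missing_prob Probability a channel is dropped (zeroed); scalar or a
#'   length-64 vector of per-channel probabilities.
#' @param rr_mean,rr_sd Mean and SD of RR intervals (s); jitter is Gaussian
#'   truncated at three SDs so beats stay ordered.
#' @param subject_variability Scale of per-subject morphological variability
#'   (default 1): log-normal per-wave amplitude and width multipliers,
#'   moment-direction jitter, an overall dipole-strength factor, a subject
#'   heart-rate factor and heart-position jitter. Real cohorts vary strongly
#'   between subjects; without this, simulated patients are morphological
#'   clones and patient identity is carried only by noise idiosyncrasies.
#'   Set to 0 for the deterministic reference morphology.
#' @param seed Integer seed; the whole recording is a deterministic function
#'   of its arguments.
#' @param sensor_array An `mcg_sensor_array` (default [default_sensor_array()]).
#' @param patient_id Identifier string.
#' @param source_pos Main dipole position (m); default 6 cm below the array
#'   centre at `(0, 0, -0.06)`.
#' @return An `mcg_recording`: list with `signal` (64 x N matrix, pT), `fs`
#'   (500 Hz), `sensor_array`, `patient_id`, `labels`, `valid_channels`,
#'   `r_peaks` (ground-truth R-peak sample indices, 1-based), `class_label`,
#'   `effect_size` and a `meta` list.
#' @export
simulate_recording <- function(class_label = "control", minutes = 1,
                               effect_size = 1, noise_white = 0.5,
                               drift_amp = 5, line_amp = 2,
                               missing_prob = 0.03, rr_mean = 0.85,
                               rr_sd = 0.05, subject_variability = 1,
                               seed = 1L,
                               sensor_array = default_sensor_array(),
                               patient_id = "P001",
                               source_pos = c(0, 0, -0.06)) {
  if (minutes <= 0) stop("recording duration must be positive")
  if (rr_mean <= 0) stop("rr_mean must be positive")
  class_label <- match.arg(class_label, MCG_CLASSES)
  stopifnot(effect_size >= 0, noise_white >= 0, drift_amp >= 0, line_amp >= 0,
            subject_variability >= 0)
  fs <- 500L
  n <- as.integer(round(fs * minutes * 60))
  n_ch <- nrow(sensor_array)
  set.seed(as.integer(seed))

  ## --- per-subject morphology (drawn before any class effect, with the
  ## same draw count for every class, so matched-seed contrasts stay exact)
  sv <- subject_variability
  amp_mult <- exp(stats::rnorm(5, sd = 0.15 * sv))
  width_mult <- exp(stats::rnorm(5, sd = 0.10 * sv))
  dir_jit <- stats::rnorm(5, sd = 10 * pi / 180 * sv)
  scale_all <- exp(stats::rnorm(1, sd = 0.20 * sv))
  rr_mean <- rr_mean * min(max(exp(stats::rnorm(1, sd = 0.08 * sv)),
                               0.75), 1.3)
  source_pos <- source_pos + c(stats::rnorm(2, sd = 0.010 * sv),
                               stats::rnorm(1, sd = 0.008 * sv))

  ## --- beat grid (identical draws for every class at matched seed) ---
  duration <- n / fs
  n_beats <- ceiling(duration / max(rr_mean - 3 * rr_sd, rr_mean / 2)) + 2L
  jit <- pmin(pmax(stats::rnorm(n_beats), -3), 3)
  rr <- pmax(rr_mean + rr_sd * jit, rr_mean / 4)
  onsets <- c(0, cumsum(rr))
  ## per-beat atrial jitters are always drawn to keep streams matched
  zj <- matrix(stats::rnorm(2L * n_beats), nrow = 2L)

  waves <- mcg_wave_table()
  waves$a <- waves$a * amp_mult * scale_all
  waves$b <- waves$b * width_mult
  waves$dir <- waves$dir + dir_jit
  eff <- effect_size
  ## per-beat wave parameter matrices (rows = waves, cols = beats)
  a_mat <- matrix(waves$a, nrow(waves), n_beats)
  b_mat <- matrix(waves$b, nrow(waves), n_beats)
  if (class_label == "low_ef") {
    qrs <- waves$wave %in% c("Q", "R", "S")
    a_mat[qrs, ] <- a_mat[qrs, ] * max(1 - 0.15 * eff, 0.2)
    b_mat[qrs, ] <- b_mat[qrs, ] * (1 + 0.15 * eff)
  }
  if (class_label == "af_substrate") {
    pw <- waves$wave == "P"
    a_mat[pw, ] <- a_mat[pw, ] * exp(0.08 * eff * zj[1, ])
    b_mat[pw, ] <- b_mat[pw, ] * (1 + 0.2 * eff) * exp(0.05 * eff * zj[2, ])
  }

  tt <- (seq_len(n) - 1L) / fs
  beat <- findInterval(tt, onsets, rightmost.closed = FALSE)
  beat[beat < 1L] <- 1L
  beat[beat > n_beats] <- n_beats
  theta <- -pi + 2 * pi * (tt - onsets[beat]) / rr[beat]

  ## moment time-series of the main dipole (3 x N)
  m <- matrix(0, 3, n)
  for (i in seq_len(nrow(waves))) {
    amp <- a_mat[i, beat] * exp(-wrap_phase(theta - waves$theta[i])^2 /
                                  (2 * b_mat[i, beat]^2))
    u <- c(cos(waves$dir[i]), sin(waves$dir[i]), 0)
    m <- m + outer(u, amp)
  }
  if (class_label == "af_substrate" && eff > 0) {
    ## duplicated (late) atrial component
    th_p2 <- waves$theta[waves$wave == "P"] + 0.35
    amp <- 0.4 * eff * a_mat[waves$wave == "P", beat] *
      exp(-wrap_phase(theta - th_p2)^2 / (2 * b_mat[waves$wave == "P", beat]^2))
    u <- c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
    m <- m + outer(u, amp)
  }

  pT <- 1e12
  lf_main <- leadfield_bz(sensor_array, source_pos) * pT
  signal <- lf_main %*% m

  if (startsWith(class_label, "cad_") && eff > 0) {
    ## displaced secondary dipole active in the ST-T window
    disp <- territory_displacement(class_label)
    lf_sec <- leadfield_bz(sensor_array, source_pos + disp) * pT
    ## the territory source scales with the subject's overall dipole strength
    amp <- eff * 0.6e-6 * scale_all *
      exp(-wrap_phase(theta - 1.05)^2 / (2 * 0.35^2))
    m2 <- outer(c(0, 1, 0), amp)
    signal <- signal + lf_sec %*% m2
  }

  ## --- noise (same draw counts for every class) ---
  wn <- matrix(stats::rnorm(n_ch * n), n_ch, n)
  if (noise_white > 0) signal <- signal + noise_white * wn
  damp <- drift_amp * stats::runif(n_ch, 0.5, 1)
  ph1 <- stats::runif(n_ch, 0, 2 * pi)
  ph2 <- stats::runif(n_ch, 0, 2 * pi)
  if (drift_amp > 0) {
    drift <- damp * sin(outer(rep(2 * pi * 0.12, n_ch), tt,
                              function(a, b) a * b) + ph1) +
      0.5 * damp * sin(outer(rep(2 * pi * 0.31, n_ch), tt,
                             function(a, b) a * b) + ph2)
    signal <- signal + drift
  }
  lamp <- line_amp * stats::runif(n_ch, 0.5, 1)
  phl <- stats::runif(n_ch, 0, 2 * pi)
  if (line_amp > 0) {
    signal <- signal + lamp * sin(outer(rep(2 * pi * 50, n_ch), tt,
                                        function(a, b) a * b) + phl)
  }
  pmiss <- rep_len(missing_prob, n_ch)
  dropped <- stats::runif(n_ch) < pmiss
  valid <- !dropped
  signal[dropped, ] <- 0

  r_times <- onsets[seq_len(n_beats)] + rr / 2  # theta = 0
  r_idx <- as.integer(round(r_times * fs)) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]

  structure(list(signal = signal, fs = fs, sensor_array = sensor_array,
                 patient_id = patient_id, labels = task_labels(class_label),
                 valid_channels = valid, r_peaks = r_idx,
                 class_label = class_label, effect_size = eff,
                 meta = list(seed = as.integer(seed), minutes = minutes,
                             noise_white = noise_white, drift_amp = drift_amp,
                             line_amp = line_amp, missing_prob = missing_prob,
                             rr_mean = rr_mean, rr_sd = rr_sd,
                             subject_variability = subject_variability,
                             source_pos = source_pos)),
            class = "mcg_recording")
}

#' Cohort specification for the simulator
#'
#' @param n_patients Number of patients.
#' @param class_probs Named proportions over the patient classes (must sum to
#'   1); converted to exact counts by largest remainder, so stated
#'   proportions are met exactly where divisible.
#' @param minutes_per_patient Recording length per patient (minutes).
#' @param effect_size Class-effect strength applied to every non-control
#'   patient.
#' @inheritParams simulate_recording
#' @param seed Master seed; per-patient seeds are derived deterministically.
#' @return An object of class `mcg_cohort_spec`.
#' @export
cohort_spec <- function(n_patients, class_probs = c(control = 0.5, cad_lcx = 0.5),
                        minutes_per_patient = 1, effect_size = 1,
                        noise_white = 0.5, drift_amp = 5, line_amp = 2,
                        missing_prob = 0.03, rr_mean = 0.85, rr_sd = 0.05,
                        subject_variability = 1, seed = 1L) {
  stopifnot(n_patients >= 1, all(names(class_probs) %in% MCG_CLASSES),
            all(class_probs >= 0), minutes_per_patient > 0, rr_mean > 0,
            effect_size >= 0)
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class proportions must sum to 1")
  structure(list(n_patients = as.integer(n_patients),
                 class_probs = class_probs,
                 minutes_per_patient = minutes_per_patient,
                 effect_size = effect_size, noise_white = noise_white,
                 drift_amp = drift_amp, line_amp = line_amp,
                 missing_prob = missing_prob, rr_mean = rr_mean,
                 rr_sd = rr_sd,
                 subject_variability = subject_variability,
                 seed = as.integer(seed)),
            class = "mcg_cohort_spec")
}

## Largest-remainder apportionment of n among proportions p.
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Simulate a cohort of recordings
#'
#' @param spec An `mcg_cohort_spec`.
#' @return List of `mcg_recording`, one per patient, with deterministic
#'   per-patient seeds derived from `spec$seed`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "mcg_cohort_spec"))
  counts <- apportion(spec$n_patients, spec$class_probs)
  classes <- rep(names(spec$class_probs), counts)
  arr <- default_sensor_array()
  purrr::imap(classes, function(cl, i) {
    simulate_recording(
      class_label = cl, minutes = spec$minutes_per_patient,
      effect_size = spec$effect_size, noise_white = spec$noise_white,
      drift_amp = spec$drift_amp, line_amp = spec$line_amp,
      missing_prob = spec$missing_prob, rr_mean = spec$rr_mean,
      rr_sd = spec$rr_sd,
      subject_variability = spec$subject_variability,
      seed = (spec$seed %% 100000L) * 10000L + i,
      sensor_array = arr, patient_id = sprintf("P%04d", i))
  })
}

#' @export
print.mcg_recording <- function(x, ...) {
  cat(sprintf("<mcg_recording> %s: %d ch x %d samples @ %d Hz, class %s, %d/%d channels valid\n",
              x$patient_id, nrow(x$signal), ncol(x$signal), x$fs,
              x$class_label, sum(x$valid_channels), length(x$valid_channels)))
  invisible(x)
}
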