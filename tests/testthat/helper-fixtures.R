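## Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## A fake recording wrapper around an arbitrary signal matrix.
fake_recording <- function(signal, valid = rep(TRUE, nrow(signal)),
                           labels = NULL, r_peaks = integer(0),
                           patient_id = "T001") {
  structure(list(signal = signal, fs = 500L,
                 sensor_array = default_sensor_array(),
                 patient_id = patient_id, labels = labels,
                 valid_channels = valid, r_peaks = r_peaks,
                 class_label = "control", effect_size = 0,
                 meta = list()),
            class = "mcg_recording")
}

fake_segment <- function(signal, patient_id = "T001", segment_index = 1L,
                         labels = NULL, valid = rep(TRUE, nrow(signal))) {
  structure(list(signal = signal, fs = 500L, patient_id = patient_id,
                 segment_index = segment_index, valid_channels = valid,
                 labels = labels, snr = NULL, r_peaks = NULL,
                 gt_r_peaks = NULL),
            class = "mcg_segment")
}

## Tiny encoder configuration used for mechanics tests (8 "channels",
## 200-sample "segments", double precision so oracles are exact).
tiny_cfg <- function() {
  encoder_config(in_channels = 8L, in_len = 200L, widths = c(4L, 6L),
                 kernel = 5L, embed_dim = 8L, proj_hidden = 8L,
                 proj_dim = 4L)
}

## Structured tiny "segments": mixtures of per-segment random sinusoids so
## instances have stable morphology the contrastive task can latch onto.
tiny_segments <- function(n = 24L, c_in = 8L, t_len = 200L, seed = 99L,
                          labels = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f <- runif(3, 2, 40)
    ph <- runif(3, 0, 2 * pi)
    amp <- runif(c_in, 0.5, 2)
    base <- sapply(seq_len(t_len), function(t)
      sum(sin(2 * pi * f * t / t_len + ph)))
    outer(amp, base) + matrix(rnorm(c_in * t_len, sd = 0.2), c_in)
  })
}

## One simulated, preprocessed, QC-passed patient (cached).
sim_segments_one_patient <- function() {
  cached("sim_one", {
    rec <- simulate_recording(minutes = 0.5, seed = 301L)
    qc_filter(preprocess_pipeline(rec))$kept
  })
}
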