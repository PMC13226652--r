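## Stochastic augmentations for contrastive pretraining, applied in order:
## (i) additive Gaussian noise scaled to the per-channel standard deviation,
## (ii) random channel dropout where a fraction of valid channels is
## replaced by noise drawn from their own distribution, (iii) simulated
## sensor dropout that zeroes a small random subset of valid channels, and
## (iv) per-channel temporal masking of a contiguous run (up to a maximum
## fraction of the segment) by the channel mean. Invalid (all-zero) channels
## are never noised or dropped and are unchanged by masking. Transform (iii)
## exists because recordings carry per-session dead-channel patterns that
## are otherwise a perfectly augmentation-invariant instance fingerprint:
## randomising the zero pattern between views forces the representation to
## be invariant to which sensors are missing instead of collapsing onto it.

#' Augmentation configuration
#'
#' @param noise_scale Multiplier on the per-channel standard deviation for
#'   additive Gaussian noise (default 1.0 — augmentation strengths are meant
#'   to be high, so the contrastive task requires matching under substantial
#'   corruption).
#' @param dropout_fraction Fraction of valid channels replaced (default 0.10).
#' @param missing_sim_fraction Fraction of valid channels zeroed per view to
#'   simulate missing sensors (default 0.05), so the dead-channel pattern is
#'   not a stable instance fingerprint.
#' @param mask_fraction Maximum masked fraction per channel (default 0.75).
#' @param noise_on,dropout_on,missing_on,mask_on Per-transform enable flags.
#' @param dropout_bootstrap If `TRUE`, dropped channels are refilled by
#'   resampling their own samples instead of Gaussian noise with matched
#'   moments.
#' @return An `mcg_augment_config`.
#' @export
augment_config <- function(noise_scale = 1.0, dropout_fraction = 0.10,
                           missing_sim_fraction = 0.05,
                           mask_fraction = 0.75, noise_on = TRUE,
                           dropout_on = TRUE, missing_on = TRUE,
                           mask_on = TRUE, dropout_bootstrap = FALSE) {
  stopifnot(noise_scale >= 0, dropout_fraction >= 0, dropout_fraction <= 1,
            missing_sim_fraction >= 0, missing_sim_fraction <= 1,
            mask_fraction >= 0, mask_fraction <= 1)
  structure(list(noise_scale = noise_scale,
                 dropout_fraction = dropout_fraction,
                 missing_sim_fraction = missing_sim_fraction,
                 mask_fraction = mask_fraction, noise_on = noise_on,
                 dropout_on = dropout_on, missing_on = missing_on,
                 mask_on = mask_on, dropout_bootstrap = dropout_bootstrap),
            class = "mcg_augment_config")
}

#' Simulated sensor dropout
#'
#' Zeroes `round(fraction * n_valid)` randomly selected valid channels,
#' emulating dead sensors. Between two views this randomises which channels
#' are zero, so a recording's fixed dead-channel pattern cannot serve as an
#' augmentation-invariant fingerprint during contrastive pretraining.
#'
#' @param x Channels-by-samples matrix.
#' @param fraction Fraction of valid channels to zero.
#' @return Matrix of the same shape; unselected channels bit-identical.
#' @export
simulate_missing_channels <- function(x, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(x)
  valid <- which(valid_channel_mask(x))
  n_zero <- round(fraction * length(valid))
  if (fraction > 0 && n_zero == 0L && length(valid) > 0L) n_zero <- 1L
  if (n_zero == 0L) return(x)
  x[sample(valid, n_zero), ] <- 0
  x
}

valid_channel_mask <- function(x) rowSums(x != 0) > 0

#' Additive Gaussian noise scaled per channel
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `alpha * sd(channel)` to each channel; all-zero channels have sd 0 and
#' stay untouched.
#'
#' @param x Channels-by-samples matrix.
#' @param alpha Noise scale (>= 0); 0 is the identity.
#' @return Matrix of the same shape.
#' @export
add_gaussian_noise <- function(x, alpha = 1.0) {
  stopifnot(alpha >= 0)
  if (alpha == 0) return(x)
  sds <- row_sds(x)
  ## one draw per sample; zero-sd (missing) channels scale their noise to 0
  x + matrix(stats::rnorm(length(x)), nrow(x), ncol(x)) * (alpha * sds)
}

#' Random channel dropout
#'
#' Replaces `round(fraction * n_valid)` valid channels (ties-to-even
#' rounding, at least 1 when the fraction is positive) entirely by noise
#' drawn from their own distribution: Gaussian with the channel's empirical
#' mean and standard deviation (or a bootstrap resample of the channel's own
#' samples when `bootstrap = TRUE`).
#'
#' @param x Channels-by-samples matrix.
#' @param fraction Fraction of valid channels to replace.
#' @param bootstrap Resample instead of matched-moment Gaussian.
#' @return Matrix of the same shape; unselected channels bit-identical.
#' @export
channel_dropout <- function(x, fraction = 0.10, bootstrap = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(x)
  valid <- which(valid_channel_mask(x))
  n_drop <- round(fraction * length(valid))
  if (fraction > 0 && n_drop == 0L && length(valid) > 0L) n_drop <- 1L
  if (n_drop == 0L) return(x)
  drop <- sample(valid, n_drop)
  for (c in drop) {
    if (bootstrap) {
      x[c, ] <- sample(x[c, ], ncol(x), replace = TRUE)
    } else {
      x[c, ] <- stats::rnorm(ncol(x), mean = mean(x[c, ]), sd = stats::sd(x[c, ]))
    }
  }
  x
}

#' Per-channel temporal masking
#'
#' Independently per channel, a contiguous run of length
#' `L ~ Uniform{0, ..., floor(max_fraction * T)}` starting at
#' `s ~ Uniform{0, ..., T - L}` is replaced by the channel's pre-mask mean.
#'
#' @param x Channels-by-samples matrix.
#' @param max_fraction Maximum masked fraction (default 0.75).
#' @return Matrix of the same shape; samples outside the mask bit-identical.
#' @export
temporal_mask <- function(x, max_fraction = 0.75) {
  stopifnot(max_fraction >= 0, max_fraction <= 1)
  if (max_fraction == 0) return(x)
  t_len <- ncol(x)
  l_max <- floor(max_fraction * t_len)
  for (c in seq_len(nrow(x))) {
    l <- sample.int(l_max + 1L, 1L) - 1L
    s <- sample.int(t_len - l + 1L, 1L) - 1L
    if (l > 0L) x[c, (s + 1L):(s + l)] <- mean(x[c, ])
  }
  x
}

#' Generate two augmented views of a segment
#'
#' Applies noise, channel dropout and temporal masking (in that order) with
#' independent draws per view. Deterministic for a given seed.
#'
#' @param x Channels-by-samples matrix (or `mcg_segment`).
#' @param cfg An [augment_config()].
#' @param seed Optional seed for the augmentation stream.
#' @return List `(view1, view2)` of matrices.
#' @export
make_views <- function(x, cfg = augment_config(), seed = NULL) {
  if (inherits(x, "mcg_segment")) x <- x$signal
  if (!is.null(seed)) set.seed(as.integer(seed))
  list(view1 = augment_once(x, cfg), view2 = augment_once(x, cfg))
}

augment_once <- function(x, cfg) {
  if (cfg$noise_on) x <- add_gaussian_noise(x, cfg$noise_scale)
  if (cfg$dropout_on) x <- channel_dropout(x, cfg$dropout_fraction,
                                           cfg$dropout_bootstrap)
  if (isTRUE(cfg$missing_on)) x <- simulate_missing_channels(
    x, cfg$missing_sim_fraction)
  if (cfg$mask_on) x <- temporal_mask(x, cfg$mask_fraction)
  x
}
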