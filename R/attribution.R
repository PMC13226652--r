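## Grad-CAM over the encoder's temporal feature maps, plus input-level
## gradient x input channel attribution. The Grad-CAM map lives after
## channel mixing, so per-sensor scores use the time-aggregated
## |gradient x input| at the input tensor instead; both are computed from a
## single backward pass from the head logit.

#' Grad-CAM temporal and channel attribution for one segment
#'
#' Computes (i) the Grad-CAM temporal importance profile at a target
#' convolutional block — feature maps weighted by their time-averaged logit
#' gradients, rectified, and linearly upsampled to the segment length — and
#' (ii) per-channel importance as time-summed |gradient x input| at the
#' input, which is zero for invalid (all-zero) channels.
#'
#' @param seg An `mcg_segment` or `64 x 5000` matrix.
#' @param encoder An `mcg_encoder` / `mcg_checkpoint`.
#' @param head An `mcg_probe_head` trained for the probed task.
#' @param target_block Index of the convolutional block whose feature maps
#'   are weighted (default: the last block, deepest temporal features).
#' @return An `mcg_attribution`: `temporal` (length 5000, >= 0), `channel`
#'   (length 64, >= 0), the raw `logit`, and metadata.
#' @export
grad_cam <- function(seg, encoder, head, target_block = NULL) {
  x <- if (is.matrix(seg)) seg else seg$signal
  nb <- length(encoder$params$blocks)
  if (is.null(target_block)) target_block <- nb
  if (target_block < 1L || target_block > nb) {
    stop("target block must index a convolutional block with a temporal axis")
  }
  xn <- seg_norm(x)
  fw <- encoder_forward(encoder, xn, keep_cache = TRUE)
  hf <- head_forward(head, fw$emb)
  hb <- head_backward(head, hf$cache, 1)   # d logit / d embedding
  eb <- encoder_backward(encoder, fw$cache, hb$d_emb, need_dx = TRUE,
                         capture_act = TRUE)
  act <- fw$cache$blocks[[target_block]]$a[, , 1]
  dact <- eb$d_act[[target_block]][, , 1]
  alpha <- rowMeans(dact)                  # time-averaged gradient per map
  raw <- pmax(colSums(act * alpha), 0)     # rectified weighted sum over maps
  t_in <- ncol(x)
  temporal <- stats::approx(seq_len(length(raw)), raw,
                            xout = seq(1, length(raw), length.out = t_in))$y
  channel <- rowSums(abs(eb$d_input[, , 1] * xn))
  structure(list(temporal = temporal, channel = channel,
                 logit = hf$logit, target_block = target_block,
                 patient_id = if (is.matrix(seg)) NA_character_
                              else seg$patient_id),
            class = "mcg_attribution")
}

#' Beat-aligned importance profile
#'
#' Stacks the temporal importance map in fixed windows around each R-peak
#' and averages; the profile is max-normalised to 1 when nonzero.
#'
#' @param temporal Importance vector over segment time (>= 0).
#' @param r_peaks R-peak sample indices.
#' @param pre_ms,post_ms Window around each peak (ms).
#' @param fs Sampling rate (Hz).
#' @param normalize Max-normalise the profile to 1 (default).
#' @return An `mcg_beat_profile`: `profile` (length `window` samples),
#'   `n_beats`, window metadata; `n_beats = 0` flags an empty profile.
#' @export
beat_align_importance <- function(temporal, r_peaks, pre_ms = 150,
                                  post_ms = 450, fs = 500,
                                  normalize = TRUE) {
  pre <- as.integer(round(pre_ms / 1000 * fs))
  post <- as.integer(round(post_ms / 1000 * fs))
  ok <- r_peaks[r_peaks - pre >= 1L & r_peaks + post - 1L <= length(temporal)]
  if (length(ok) == 0L) {
    return(structure(list(profile = numeric(0), n_beats = 0L, pre = pre,
                          post = post, fs = fs), class = "mcg_beat_profile"))
  }
  snip <- vapply(ok, function(r) temporal[(r - pre):(r + post - 1L)],
                 numeric(pre + post))
  prof <- rowMeans(snip)
  if (normalize && max(prof) > 0) prof <- prof / max(prof)
  structure(list(profile = prof, n_beats = length(ok), pre = pre,
                 post = post, fs = fs), class = "mcg_beat_profile")
}

#' Channel importance projected onto the sensor array
#'
#' @param seg Segment (matrix or `mcg_segment`).
#' @param encoder,head As in [grad_cam()].
#' @param sensor_array An `mcg_sensor_array` giving channel coordinates.
#' @return Tibble `channel`, `x`, `y`, `importance` (invalid channels 0).
#' @export
spatial_importance <- function(seg, encoder, head,
                               sensor_array = default_sensor_array()) {
  at <- grad_cam(seg, encoder, head)
  tibble::tibble(channel = sensor_array$channel, x = sensor_array$x,
                 y = sensor_array$y, importance = at$channel)
}

#' Importance-weighted centroid over the sensor array
#'
#' @param imp Tibble from [spatial_importance()] (or columns `x`, `y`,
#'   `importance`).
#' @return Named vector `c(x, y)`.
#' @export
importance_centroid <- function(imp) {
  w <- imp$importance / sum(imp$importance)
  c(x = sum(imp$x * w), y = sum(imp$y * w))
}

## Angular sector membership for a coronary territory (array coordinates):
## within +/- 60 degrees of the territory's displacement direction.
in_territory_sector <- function(centroid, class_label, min_radius = 0.002) {
  disp <- territory_displacement(class_label)
  r <- sqrt(sum(centroid^2))
  if (r < min_radius) return(FALSE)
  cosang <- sum(centroid * disp[1:2]) / (r * sqrt(sum(disp[1:2]^2)))
  cosang > cos(pi / 3)
}

#' Cohort-averaged attribution for a trained probe
#'
#' Runs Grad-CAM on each fold's validation segments with that fold's models,
#' averages beat-aligned temporal profiles and channel importances across the
#' validation cohort, and max-normalises.
#'
#' @param probe An `mcg_probe_result` (with per-fold models).
#' @param segments The segment list the probe was trained on.
#' @param max_segments_per_fold Cap on validation segments used per fold.
#' @return List with `beat_profile` (`mcg_beat_profile`), `channel`
#'   (per-channel mean importance), per-fold centroids, and the per-fold
#'   segment counts.
#' @export
cohort_attribution <- function(probe, segments,
                               max_segments_per_fold = 20L) {
  pid <- vapply(segments, function(s) s$patient_id, character(1))
  fold_of <- stats::setNames(probe$folds$fold, probe$folds$patient_id)
  profs <- list()
  chans <- list()
  centroids <- list()
  for (f in sort(unique(probe$folds$fold))) {
    idx <- which(fold_of[pid] == f)
    idx <- utils::head(idx, max_segments_per_fold)
    mdl <- probe$models[[f]]
    ch_acc <- 0
    for (i in idx) {
      seg <- segments[[i]]
      at <- grad_cam(seg, mdl$encoder, mdl$head)
      rp <- if (!is.null(seg$r_peaks) && length(seg$r_peaks) >= 1L) {
        seg$r_peaks
      } else {
        seg$gt_r_peaks
      }
      bp <- beat_align_importance(at$temporal, rp)
      if (bp$n_beats > 0L) profs[[length(profs) + 1L]] <- bp$profile
      ch_acc <- ch_acc + at$channel
      chans[[length(chans) + 1L]] <- at$channel
    }
    imp <- tibble::tibble(x = default_sensor_array()$x,
                          y = default_sensor_array()$y,
                          importance = ch_acc / max(length(idx), 1L))
    centroids[[as.character(f)]] <- importance_centroid(imp)
  }
  prof <- if (length(profs)) rowMeans(do.call(cbind, profs)) else numeric(0)
  if (length(prof) && max(prof) > 0) prof <- prof / max(prof)
  chan <- if (length(chans)) Reduce(`+`, chans) / length(chans) else numeric(64)
  list(beat_profile = structure(list(profile = prof,
                                     n_beats = length(profs), pre = 75L,
                                     post = 225L, fs = 500),
                                class = "mcg_beat_profile"),
       channel = chan, centroids = centroids,
       n_segments = length(chans))
}
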