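#' Pretraining configuration
#'
#' Defaults follow the standard recipe: 100 epochs, batch size 32, NT-Xent
#' temperature 0.1, AdamW with initial learning rate 1e-3 and weight decay
#' 1e-4, cosine decay to 1% of the initial rate.
#'
#' @param epochs Number of epochs.
#' @param batch_size Segments per batch (>= 2; each contributes two views).
#' @param tau NT-Xent temperature (> 0).
#' @param lr0 Initial learning rate.
#' @param weight_decay Decoupled (AdamW) weight decay.
#' @param floor_frac Final learning-rate fraction of `lr0`.
#' @param seed Master seed; data order, augmentation and weight
#'   initialisation get independent derived streams.
#' @return An `mcg_pretrain_config`.
#' @export
pretrain_config <- function(epochs = 100L, batch_size = 32L, tau = 0.1,
                            lr0 = 1e-3, weight_decay = 1e-4,
                            floor_frac = 0.01, seed = 1L) {
  stopifnot(tau > 0, batch_size >= 2L, epochs >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), tau = tau, lr0 = lr0,
                 weight_decay = weight_decay, floor_frac = floor_frac,
                 seed = as.integer(seed)),
            class = "mcg_pretrain_config")
}

## Per-segment amplitude normalisation: divide by the global standard
## deviation so the encoder never relies on absolute field amplitude.
seg_norm <- function(m) {
  s <- stats::sd(m)
  if (is.na(s) || s == 0) m else m / s
}

## One-segment-per-patient batch plan: segments are dealt in rounds (one
## per patient, patient order reshuffled each round) and rounds are chunked
## into batches, so a batch never holds two segments of one patient.
plan_patient_batches <- function(pids, batch_size) {
  by_pat <- split(seq_along(pids), pids)
  by_pat <- lapply(by_pat, function(v) v[sample.int(length(v))])
  rounds <- max(lengths(by_pat))
  batches <- list()
  for (r in seq_len(rounds)) {
    round_idx <- unlist(lapply(by_pat, function(v) {
      if (length(v) >= r) v[r] else NULL
    }), use.names = FALSE)
    round_idx <- round_idx[sample.int(length(round_idx))]
    k <- ceiling(length(round_idx) / batch_size)
    batches <- c(batches, split(round_idx, rep(seq_len(k),
                                               each = batch_size)[seq_along(round_idx)]))
  }
  batches
}

make_batch_cube <- function(sig_list) {
  array(unlist(lapply(sig_list, seg_norm), use.names = FALSE),
        c(nrow(sig_list[[1]]), ncol(sig_list[[1]]), length(sig_list)))
}

#' Contrastive pretraining of the encoder
#'
#' SimCLR-style loop: per segment two independently augmented views are
#' encoded by the shared encoder, passed through the projection head, and
#' pulled together by the NT-Xent loss against all in-batch negatives.
#' Optimised with AdamW under a cosine learning-rate schedule. Fully
#' deterministic for a given config seed.
#'
#' @param segments List of `mcg_segment` (or channels-by-samples matrices).
#' @param enc_cfg An [encoder_config()].
#' @param cfg An [pretrain_config()].
#' @param aug_cfg An [augment_config()].
#' @param patient_batching Compose every batch from segments of distinct
#'   patients (default TRUE). In large cohorts same-patient collisions
#'   within a batch are rare; with few patients and several segments each,
#'   uniform batches would make a patient's other segments frequent
#'   negatives, forcing the representation to separate them — which
#'   penalises exactly the stable morphology the objective is meant to
#'   promote. Bare matrices count as one patient each (plain shuffling).
#' @param verbose Print per-epoch losses.
#' @return An `mcg_checkpoint` (also usable wherever an `mcg_encoder` is
#'   expected): encoder config + parameters, projection head, per-epoch mean
#'   loss trace, and the seed.
#' @export
pretrain <- function(segments, enc_cfg = encoder_config_desk(),
                     cfg = pretrain_config(), aug_cfg = augment_config(),
                     patient_batching = TRUE, verbose = FALSE) {
  stopifnot(length(segments) >= 2L)
  sig <- lapply(segments, function(s) if (is.matrix(s)) s else s$signal)
  pids <- vapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (is.matrix(s) || is.null(s$patient_id)) paste0("seg", i) else s$patient_id
  }, character(1))
  set.seed(cfg$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 3L)
  enc <- encoder_init(enc_cfg, seed = streams[1])
  comb <- list(enc = enc$params, proj = enc$proj)
  opt <- adam_init(comb)
  n <- length(sig)
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- cosine_lr(ep - 1, cfg$epochs, cfg$lr0, cfg$floor_frac)
    set.seed((streams[2] + ep) %% .Machine$integer.max)
    batches <- if (patient_batching) {
      plan_patient_batches(pids, cfg$batch_size)
    } else {
      ord <- sample.int(n)
      split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    }
    set.seed((streams[3] + ep) %% .Machine$integer.max)
    losses <- c()
    for (idx in batches) {
      if (length(idx) < 2L) {
        warning("skipping batch with fewer than 2 segments")
        next
      }
      v1 <- vector("list", length(idx))
      v2 <- vector("list", length(idx))
      for (q in seq_along(idx)) {
        vw <- make_views(sig[[idx[q]]], aug_cfg)
        v1[[q]] <- vw$view1
        v2[[q]] <- vw$view2
      }
      x <- make_batch_cube(c(v1, v2))
      enc$params <- comb$enc
      enc$proj <- comb$proj
      fw <- encoder_forward(enc, x, keep_cache = TRUE, train = TRUE)
      pf <- proj_forward(enc$proj, fw$emb, keep_cache = TRUE)
      ls <- nt_xent_loss(pf$z, cfg$tau, return_grad = TRUE)
      losses <- c(losses, ls$loss)
      pb <- proj_backward(enc$proj, pf$cache, ls$grad)
      eb <- encoder_backward(enc, fw$cache, pb$d_emb)
      grads <- list(enc = eb$grads, proj = pb$grads)
      st <- adam_step(comb, grads, opt, lr,
                      weight_decay = cfg$weight_decay)
      comb <- st$params
      opt <- st$state
      enc <- bn_from_cache(enc, fw$cache)
    }
    loss_trace[ep] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f", ep, lr, loss_trace[ep]))
    }
  }
  enc$params <- comb$enc
  enc$proj <- comb$proj
  ## exact normalisation statistics over the training segments: the running
  ## (momentum) statistics lag the drifting feature distribution over short
  ## schedules, which would mis-centre inference-mode embeddings
  enc <- calibrate_bn(enc, sig, cfg$batch_size)
  structure(list(cfg = enc_cfg, params = comb$enc, proj = comb$proj,
                 bn = enc$bn, bn_blocks = enc$bn_blocks,
                 loss_trace = loss_trace, pretrain_cfg = cfg,
                 seed = cfg$seed),
            class = c("mcg_checkpoint", "mcg_encoder"))
}

#' @export
print.mcg_checkpoint <- function(x, ...) {
  cat(sprintf("<mcg_checkpoint> D=%d, %d epochs, final NT-Xent loss %.4f\n",
              x$cfg$embed_dim, length(x$loss_trace),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
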