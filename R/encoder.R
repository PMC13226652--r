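#' Temporal convolutional encoder configuration
#'
#' The encoder maps a raw `64 x 5000` magnetocardiogram segment to a
#' fixed-dimensional embedding. It stacks residual blocks of 1-D convolutions
#' over time (all 64 sensor channels enter every convolution as input feature
#' maps, so inter-channel field structure is mixed at every layer), each block
#' followed by stride-2 average pooling, then global average pooling over time
#' and a linear map to the embedding.
#'
#' @param in_channels Number of input channels (sensor count), default 64.
#' @param in_len Samples per segment, default 5000 (10 s at 500 Hz).
#' @param widths Integer vector of per-block output widths.
#' @param kernel Odd convolution kernel length(s), recycled per block.
#' @param first_stride Stride of the first convolution (1 or 2). A stride of 2
#'   halves the temporal resolution at the input, which is ample for cardiac
#'   morphology at 500 Hz and roughly halves the arithmetic cost.
#' @param embed_dim Embedding dimensionality D (>= 8).
#' @param proj_hidden,proj_dim Projection-head hidden and output widths used
#'   only by the contrastive loss (SimCLR convention); embeddings are taken
#'   before the head.
#' @param single_precision Run convolutions in single precision (faster,
#'   ~1e-6 relative rounding; used by the desk preset).
#' @return An object of class `mcg_encoder_config`.
#' @export
encoder_config <- function(in_channels = 64L, in_len = 5000L,
                           widths = c(32L, 64L, 128L, 128L), kernel = 15L,
                           first_stride = 1L, embed_dim = 128L,
                           proj_hidden = embed_dim, proj_dim = 64L,
                           single_precision = FALSE) {
  kernels <- as.integer(rep_len(kernel, length(widths)))
  stopifnot(all(kernels %% 2L == 1L), embed_dim >= 8L, length(widths) >= 1L,
            first_stride %in% c(1L, 2L))
  t_len <- in_len
  strides <- c(first_stride, rep(1L, length(widths) - 1L))
  for (b in seq_along(widths)) {
    pad <- (kernels[b] - 1L) %/% 2L
    t_len <- (t_len + 2L * pad - kernels[b]) %/% strides[b] + 1L
    t_len <- t_len %/% 2L # pooling
  }
  if (t_len < 1L) stop("encoder downsampling exhausts the segment length")
  structure(list(in_channels = as.integer(in_channels),
                 in_len = as.integer(in_len),
                 widths = as.integer(widths), kernels = kernels,
                 strides = as.integer(strides),
                 single_precision = isTRUE(single_precision),
                 embed_dim = as.integer(embed_dim),
                 proj_hidden = as.integer(proj_hidden),
                 proj_dim = as.integer(proj_dim),
                 out_len = as.integer(t_len)),
            class = "mcg_encoder_config")
}

#' Scaled-down encoder preset
#'
#' A light configuration (widths 8/16/32/64, short kernels, stride-2 first
#' convolution, 64-dimensional embedding, single-precision convolutions)
#' suitable for single-CPU experiments on synthetic cohorts. The last block
#' is kept comparatively wide: the globally pooled features are the
#' representation bottleneck, and at desk scale a wider pooled layer markedly
#' improves how reliably class structure survives random initialisation.
#'
#' @inheritParams encoder_config
#' @return An `mcg_encoder_config`.
#' @export
encoder_config_desk <- function(embed_dim = 64L) {
  encoder_config(widths = c(8L, 16L, 32L, 64L), kernel = c(5L, 9L, 9L, 9L),
                 first_stride = 2L, embed_dim = embed_dim,
                 proj_hidden = embed_dim, proj_dim = 32L,
                 single_precision = TRUE)
}

#' Initialise encoder (and projection head) parameters
#'
#' @param cfg An `mcg_encoder_config`.
#' @param seed Optional integer seed for the weight-initialisation stream.
#' @return An object of class `mcg_encoder`: list with `cfg`, `params`
#'   (convolution blocks + embedding map) and `proj` (projection head).
#' @export
encoder_init <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c_in <- cfg$in_channels
  blocks <- vector("list", length(cfg$widths))
  for (b in seq_along(cfg$widths)) {
    c_out <- cfg$widths[b]
    blocks[[b]] <- list(
      W  = he_init(c_out, c_in * cfg$kernels[b]),
      b  = rep(0, c_out),
      Wp = he_init(c_out, c_in)   # 1x1 projection for the residual skip
    )
    c_in <- c_out
  }
  params <- list(blocks = blocks,
                 emb = list(W = he_init(cfg$embed_dim, c_in),
                            b = rep(0, cfg$embed_dim)))
  proj <- list(W1 = he_init(cfg$proj_hidden, cfg$embed_dim),
               b1 = rep(0, cfg$proj_hidden),
               W2 = he_init(cfg$proj_dim, cfg$proj_hidden),
               b2 = rep(0, cfg$proj_dim))
  ## affine-free batch normalisation: per feature map after every block
  ## (over time x batch) and on the globally pooled features. Normalisation
  ## keeps activations well-scaled over the short optimisation schedules
  ## this package runs, and pooled-feature centring removes the common
  ## component of GAP'd ReLU features that would otherwise start all cosine
  ## similarities near 1.
  bn_blocks <- lapply(cfg$widths, function(w) {
    list(mu = rep(0, w), var = rep(1, w), eps = 1e-5, momentum = 0.1,
         initialized = FALSE)
  })
  bn <- list(mu = rep(0, c_in), var = rep(1, c_in), eps = 1e-5,
             momentum = 0.1, initialized = FALSE)
  structure(list(cfg = cfg, params = params, proj = proj, bn = bn,
                 bn_blocks = bn_blocks),
            class = "mcg_encoder")
}

## Forward pass. x: array c(C, T, B). Returns list(emb = D x B, cache).
## train = TRUE uses batch statistics in the normalisation layer (and the
## cache carries updated running statistics); inference uses running stats
## so embeddings are deterministic per segment.
encoder_forward <- function(enc, x, keep_cache = FALSE, train = FALSE) {
  cfg <- enc$cfg
  p <- enc$params
  x <- as_batch(x)
  stopifnot(dim(x)[1] == cfg$in_channels, dim(x)[2] == cfg$in_len)
  cache <- if (keep_cache) list(blocks = vector("list", length(p$blocks)))
  sp <- isTRUE(cfg$single_precision)
  batch_stats <- train && dim(x)[3] > 1L
  for (b in seq_along(p$blocks)) {
    s <- cfg$strides[b]
    h <- conv1d_fw(x, p$blocks[[b]]$W, p$blocks[[b]]$b, s, sp)
    pr <- conv1d_fw(x, p$blocks[[b]]$Wp, rep(0, nrow(p$blocks[[b]]$Wp)), s, sp)
    z <- h + pr
    bnb <- enc$bn_blocks[[b]]
    if (batch_stats) {
      mu_b <- rowMeans(z, dims = 1)          # over time x batch
      v_b <- rowMeans((z - mu_b)^2, dims = 1)
      mom <- if (bnb$initialized) bnb$momentum else 1
      bnb$mu <- (1 - mom) * bnb$mu + mom * mu_b
      bnb$var <- (1 - mom) * bnb$var + mom * v_b
      bnb$initialized <- TRUE
    } else {
      mu_b <- bnb$mu
      v_b <- bnb$var
    }
    inv_b <- 1 / sqrt(v_b + bnb$eps)
    zh <- (z - mu_b) * inv_b
    a <- relu(zh)
    if (keep_cache) {
      cache$blocks[[b]] <- list(x = x, z = zh, a = a, inv_sd = inv_b,
                                mu = mu_b, bn_update = bnb)
    }
    x <- avgpool2(a)
  }
  t_out <- dim(x)[2]
  emb_pre <- apply(x, c(1, 3), mean)          # C_last x B
  if (is.null(dim(emb_pre))) emb_pre <- matrix(emb_pre, ncol = dim(x)[3])
  bn <- enc$bn
  if (batch_stats) {
    mu <- rowMeans(emb_pre)
    v <- rowMeans((emb_pre - mu)^2)
    bn_update <- bn
    mom <- if (bn$initialized) bn$momentum else 1
    bn_update$mu <- (1 - mom) * bn$mu + mom * mu
    bn_update$var <- (1 - mom) * bn$var + mom * v
    bn_update$initialized <- TRUE
  } else {
    mu <- bn$mu
    v <- bn$var
    bn_update <- bn
  }
  inv_sd <- 1 / sqrt(v + bn$eps)
  xhat <- (emb_pre - mu) * inv_sd
  emb <- p$emb$W %*% xhat + p$emb$b
  if (keep_cache) {
    cache$pooled <- x
    cache$emb_pre <- emb_pre
    cache$xhat <- xhat
    cache$inv_sd <- inv_sd
    cache$train_mode <- batch_stats
    cache$bn_update <- bn_update
    cache$t_out <- t_out
  }
  list(emb = emb, cache = cache)
}

## Backward pass from d_emb (D x B). Returns list(grads, d_input, d_act)
## where d_act[[b]] is the gradient at block b's post-ReLU activation
## (needed by Grad-CAM) when capture_act is TRUE.
encoder_backward <- function(enc, cache, d_emb, need_dx = FALSE,
                             capture_act = FALSE) {
  cfg <- enc$cfg
  p <- enc$params
  nb <- length(p$blocks)
  grads <- list(blocks = vector("list", nb), emb = list())
  grads$emb$W <- d_emb %*% t(cache$xhat)
  grads$emb$b <- rowSums(d_emb)
  dxhat <- t(p$emb$W) %*% d_emb               # C_last x B
  if (cache$train_mode) {
    ## batch-norm backward (no affine parameters)
    d_pre <- cache$inv_sd *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    d_pre <- cache$inv_sd * dxhat
  }
  ## global average pool backward
  dpool <- array(0, dim(cache$pooled))
  for (s in seq_len(dim(dpool)[3])) {
    dpool[, , s] <- matrix(d_pre[, s] / cache$t_out, nrow(d_pre), cache$t_out)
  }
  d_act <- if (capture_act) vector("list", nb)
  sp <- isTRUE(cfg$single_precision)
  dy <- dpool
  for (b in rev(seq_len(nb))) {
    blk <- cache$blocks[[b]]
    da <- avgpool2_bw(dy, dim(blk$a)[2])
    if (capture_act) d_act[[b]] <- da
    dzh <- da * (blk$z > 0)
    if (cache$train_mode) {
      ## batch-norm backward per feature map over time x batch
      dz <- blk$inv_sd * (dzh - rowMeans(dzh, dims = 1) -
                            blk$z * rowMeans(dzh * blk$z, dims = 1))
    } else {
      dz <- dzh * blk$inv_sd
    }
    s <- cfg$strides[b]
    want_dx <- need_dx || b > 1L
    g <- conv1d_bw(blk$x, p$blocks[[b]]$W, dz, s, want_dx, sp)
    gp <- conv1d_bw(blk$x, p$blocks[[b]]$Wp, dz, s, want_dx, sp)
    grads$blocks[[b]] <- list(W = g$dW, b = as.numeric(g$db), Wp = gp$dW)
    dy <- if (want_dx) g$dX + gp$dX else NULL
  }
  list(grads = grads, d_input = dy, d_act = d_act)
}

## Projection head forward/backward (z used only by the contrastive loss).
proj_forward <- function(proj, emb, keep_cache = FALSE) {
  a1 <- proj$W1 %*% emb + proj$b1
  h1 <- relu(a1)
  z <- proj$W2 %*% h1 + proj$b2
  list(z = z, cache = if (keep_cache) list(emb = emb, a1 = a1, h1 = h1))
}

proj_backward <- function(proj, cache, dz) {
  dW2 <- dz %*% t(cache$h1)
  db2 <- rowSums(dz)
  dh1 <- t(proj$W2) %*% dz
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- da1 %*% t(cache$emb)
  db1 <- rowSums(da1)
  d_emb <- t(proj$W1) %*% da1
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), d_emb = d_emb)
}

## Exact calibration of all normalisation statistics (per-block and pooled)
## as empirical moments over a segment list, block by block so each layer is
## calibrated under the already-calibrated statistics of the layers below.
## Used after pretraining (running statistics lag the drifting feature
## distribution over short schedules) and for freshly initialised encoders
## before supervised training.
calibrate_bn <- function(enc, sig_list, batch_size = 32L) {
  nb <- length(enc$params$blocks)
  n <- length(sig_list)
  for (stage in seq_len(nb + 1L)) {
    s1 <- 0; s2 <- 0; cnt <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + batch_size - 1L, n)
      fw <- encoder_forward(enc, make_batch_cube(sig_list[i:j]),
                            keep_cache = TRUE)
      if (stage <= nb) {
        blk <- fw$cache$blocks[[stage]]
        z <- blk$z / blk$inv_sd + blk$mu     # undo current normalisation
        s1 <- s1 + rowSums(z, dims = 1)
        s2 <- s2 + rowSums(z^2, dims = 1)
        cnt <- cnt + prod(dim(z)[2:3])
      } else {
        ep <- fw$cache$emb_pre
        s1 <- s1 + rowSums(ep)
        s2 <- s2 + rowSums(ep^2)
        cnt <- cnt + ncol(ep)
      }
      i <- j + 1L
    }
    mu <- s1 / cnt
    v <- pmax(s2 / cnt - mu^2, 0)
    if (stage <= nb) {
      enc$bn_blocks[[stage]]$mu <- mu
      enc$bn_blocks[[stage]]$var <- v
      enc$bn_blocks[[stage]]$initialized <- TRUE
    } else {
      enc$bn$mu <- mu
      enc$bn$var <- v
      enc$bn$initialized <- TRUE
    }
  }
  enc
}

## fold running-statistic updates from a training-mode cache back into enc
bn_from_cache <- function(enc, cache) {
  for (b in seq_along(enc$bn_blocks)) {
    enc$bn_blocks[[b]] <- cache$blocks[[b]]$bn_update
  }
  enc$bn <- cache$bn_update
  enc
}

#' Encode segments into embeddings
#'
#' Deterministic inference-mode forward pass of the encoder.
#'
#' @param enc An `mcg_encoder` (e.g. from [encoder_init()] or [pretrain()]).
#' @param segments A single segment (`64 x 5000` matrix or `mcg_segment`) or a
#'   list of them.
#' @return A tibble with one row per segment: `patient_id`, `segment_index`,
#'   and an `embedding` list-column of length-D numeric vectors.
#' @export
encode <- function(enc, segments) {
  if (inherits(segments, "mcg_segment") || is.matrix(segments)) {
    segments <- list(segments)
  }
  sig <- lapply(segments, function(s) if (is.matrix(s)) s else s$signal)
  for (m in sig) {
    if (!all(dim(m) == c(enc$cfg$in_channels, enc$cfg$in_len))) {
      stop("segment shape must be ", enc$cfg$in_channels, " x ", enc$cfg$in_len)
    }
    if (!all(is.finite(m))) stop("segment contains non-finite values")
  }
  emb <- encode_batched(enc, sig)
  tibble::tibble(
    patient_id = vapply(segments, function(s)
      if (is.matrix(s)) NA_character_ else s$patient_id, character(1)),
    segment_index = vapply(segments, function(s)
      if (is.matrix(s)) NA_integer_ else s$segment_index, integer(1)),
    embedding = lapply(seq_along(segments), function(i) emb[, i])
  )
}

## Matrix of embeddings (D x n) for a list of signal matrices, batched.
encode_batched <- function(enc, sig, batch_size = 32L) {
  n <- length(sig)
  out <- matrix(0, enc$cfg$embed_dim, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    ## make_batch_cube applies the same per-segment amplitude normalisation
    ## as training, so inference sees the distribution the encoder was
    ## trained (and its normalisation statistics calibrated) on
    out[, i:j] <- encoder_forward(enc, make_batch_cube(sig[i:j]))$emb
    i <- j + 1L
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints round-trip exactly: reloading and re-encoding a probe batch
#' reproduces identical embeddings.
#'
#' @param ckpt A checkpoint list (e.g. the result of [pretrain()]).
#' @param path File path.
#' @return `read_checkpoint` returns the checkpoint; `write_checkpoint`
#'   returns `path` invisibly.
#' @export
write_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
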