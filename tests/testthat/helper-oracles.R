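## Independent oracles shared across test files.

## independent brute-force evaluation of the NT-Xent expression
brute_nt_xent <- function(z, tau) {
  n <- ncol(z)
  b <- n / 2
  u <- apply(z, 2, function(v) v / sqrt(sum(v^2)))
  partner <- function(i) if (i <= b) i + b else i - b
  total <- 0
  for (i in seq_len(n)) {
    num <- exp(sum(u[, i] * u[, partner(i)]) / tau)
    den <- 0
    for (k in seq_len(n)) {
      if (k != i) den <- den + exp(sum(u[, i] * u[, k]) / tau)
    }
    total <- total - log(num / den)
  }
  total / n
}

## construct a beat matrix object directly with known signal/noise powers
synthetic_beat_matrix <- function(n_beats, win, n_ch, noise_sd,
                                  template = NULL) {
  if (is.null(template)) template <- sin(seq(0, 2 * pi, length.out = win))
  template <- template / sqrt(mean(template^2))  # unit power
  beats <- array(0, c(n_beats, win, n_ch))
  for (c in seq_len(n_ch)) {
    beats[, , c] <- matrix(rep(template, each = n_beats), n_beats) +
      matrix(rnorm(n_beats * win, sd = noise_sd), n_beats)
  }
  structure(list(beats = beats, valid_channels = rep(TRUE, n_ch), pre = 75L,
                 post = 225L, r_peaks = seq_len(n_beats), fs = 500),
            class = "mcg_beat_matrix")
}


## A one-block, kernel-1 encoder small enough to differentiate by hand.
toy_model <- function() {
  cfg <- encoder_config(in_channels = 2L, in_len = 8L, widths = 2L,
                        kernel = 1L, embed_dim = 8L, proj_hidden = 8L,
                        proj_dim = 4L)
  enc <- encoder_init(cfg, seed = 70)
  enc$params$blocks[[1]]$W <- matrix(c(1, -0.3, 0.5, 2), 2)   # C_out x C_in
  enc$params$blocks[[1]]$b <- c(0.1, -0.2)
  enc$params$blocks[[1]]$Wp <- matrix(0, 2, 2)
  enc$params$emb$W <- matrix(seq(-0.8, 0.8, length.out = 16), 8)
  enc$params$emb$b <- rep(0.05, 8)
  head <- structure(list(W1 = matrix(seq(0.1, 1.6, 0.1), 2, 8),
                         b1 = c(0.05, -0.05), w2 = c(1.2, -0.7), b2 = 0.3),
                    class = "mcg_probe_head")
  list(enc = enc, head = head)
}

## independent hand evaluation of the toy model's forward pass, Grad-CAM map
## and gradient-x-input channel scores, written as plain matrix arithmetic
toy_oracle <- function(enc, head, x) {
  xn <- x / sd(x)
  W <- enc$params$blocks[[1]]$W
  cb <- 1 / sqrt(1 + enc$bn_blocks[[1]]$eps)     # block BN, mu 0 var 1
  z <- (W %*% xn + enc$params$blocks[[1]]$b) * cb  # 2 x 8
  a <- pmax(z, 0)
  pooled <- (a[, c(1, 3, 5, 7)] + a[, c(2, 4, 6, 8)]) / 2  # 2 x 4
  gap <- rowMeans(pooled)
  cs <- 1 / sqrt(1 + enc$bn$eps)                 # inference BN, mu 0 var 1
  xhat <- gap * cs
  emb <- enc$params$emb$W %*% xhat + enc$params$emb$b
  a1 <- head$W1 %*% emb + head$b1
  sw <- a1 * plogis(a1)
  logit <- sum(head$w2 * sw) + head$b2
  ## backward from d logit = 1
  dsw <- head$w2
  da1 <- dsw * (plogis(a1) * (1 + a1 * (1 - plogis(a1))))
  demb <- t(head$W1) %*% da1
  dxhat <- t(enc$params$emb$W) %*% demb
  dgap <- cs * dxhat
  dpooled <- matrix(rep(dgap / 4, 4), 2)         # 2 x 4
  da <- matrix(0, 2, 8)
  da[, c(1, 3, 5, 7)] <- dpooled / 2
  da[, c(2, 4, 6, 8)] <- dpooled / 2
  dz <- da * (z > 0) * cb
  dx <- t(W) %*% dz
  alpha <- rowMeans(da)
  map <- pmax(colSums(a * alpha), 0)
  list(logit = logit, map = map, channel = rowSums(abs(dx * xn)))
}

## all-pairs AUC with half credit for ties
brute_auc <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
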