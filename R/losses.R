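#' NT-Xent contrastive loss
#'
#' Normalised-temperature cross-entropy over a batch of paired projections,
#' as used for SimCLR-style pretraining. Column `i` and column `i + B` are the
#' two views of the same segment; all other in-batch columns act as negatives.
#' Projections are L2-normalised internally, so the similarity is the cosine.
#'
#' For each anchor `i` with partner `j`:
#' `loss_i = -log( exp(cos(z_i, z_j)/tau) / sum_{k != i} exp(cos(z_i, z_k)/tau) )`
#' and the reported loss is the mean over all `2B` anchors.
#'
#' @param z Numeric matrix, `P x 2B`, projections as columns.
#' @param tau Temperature (> 0), default 0.1.
#' @param return_grad If `TRUE`, also return the gradient w.r.t. `z`.
#' @return The scalar loss, or a list `(loss, grad)`.
#' @export
nt_xent_loss <- function(z, tau = 0.1, return_grad = FALSE) {
  stopifnot(is.matrix(z), tau > 0)
  n <- ncol(z)
  if (n %% 2L != 0L || n < 4L) {
    stop("need 2B columns with B >= 2 (no negatives exist otherwise)")
  }
  b <- n %/% 2L
  r <- sqrt(colSums(z^2))
  r <- pmax(r, 1e-12)
  u <- sweep(z, 2, r, "/")
  s <- crossprod(u) / tau                       # n x n cosine / tau
  partner <- c((b + 1L):n, 1L:b)
  ## stable log-sum-exp over k != i, per row
  diag(s) <- -Inf
  m <- apply(s, 1, max)
  lse <- m + log(rowSums(exp(s - m)))
  pos <- s[cbind(seq_len(n), partner)]
  loss <- mean(lse - pos)
  if (!return_grad) return(loss)
  q <- exp(s - lse)                             # softmax over k != i, diag 0
  g <- q
  g[cbind(seq_len(n), partner)] <- g[cbind(seq_len(n), partner)] - 1
  g <- g / n
  du <- u %*% (g + t(g)) / tau
  dz <- sweep(du - sweep(u, 2, colSums(u * du), "*"), 2, r, "/")
  list(loss = loss, grad = dz)
}

#' Cosine learning-rate schedule
#'
#' Decays from `lr0` at epoch 0 to `floor_frac * lr0` at `total`:
#' `lr(e) = lr_floor + 0.5 * (lr0 - lr_floor) * (1 + cos(pi * e / total))`.
#'
#' @param epoch Current epoch in `[0, total]`.
#' @param total Total epochs.
#' @param lr0 Initial learning rate.
#' @param floor_frac Final fraction of `lr0`.
#' @return Learning rate at `epoch`.
#' @export
cosine_lr <- function(epoch, total = 100, lr0 = 1e-3, floor_frac = 0.01) {
  if (epoch < 0 || epoch > total) stop("epoch out of [0, total]")
  lr_floor <- floor_frac * lr0
  lr_floor + 0.5 * (lr0 - lr_floor) * (1 + cos(pi * epoch / total))
}

#' Class-frequency-weighted binary cross-entropy
#'
#' `sum(w_i * l_i) / sum(w_i)` with `l_i = -(y log p + (1-y) log(1-p))`.
#'
#' @param prob Predicted probabilities in (0, 1).
#' @param y Binary labels.
#' @param w Per-sample weights (default all 1).
#' @return Scalar loss.
#' @export
weighted_bce <- function(prob, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(prob))
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  l <- -(y * log(p) + (1 - y) * log(1 - p))
  sum(w * l) / sum(w)
}

## Per-sample weights inversely proportional to class frequency,
## normalised to mean 1.
class_weights <- function(y) {
  f <- table(factor(y, levels = c(0, 1))) / length(y)
  w <- ifelse(y == 1, 1 / max(f[["1"]], 1e-12), 1 / max(f[["0"]], 1e-12))
  w / mean(w)
}
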