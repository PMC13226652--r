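## Adam / AdamW over nested parameter lists (decoupled weight decay).

adam_init <- function(params) {
  list(step = 0L,
       m = params_map(params, function(x) x * 0),
       v = params_map(params, function(x) x * 0))
}

## One update. weight_decay > 0 gives AdamW's decoupled decay.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$step <- state$step + 1L
  t <- state$step
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      upd <- (m2 / bc1) / (sqrt(v2 / bc2) + eps)
      p2 <- p - lr * upd
      if (weight_decay > 0) p2 <- p2 - lr * weight_decay * p
      list(p = p2, m = m2, v = v2)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
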