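## Low-level neural-network primitives shared by the encoder, the projection
## head and the probing heads. Batches of segments travel as 3-D arrays with
## dim c(channels, time, batch); per-sample vectors as columns of a matrix.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Swish activation
#'
#' `swish(x) = x * sigmoid(x)`, the activation used in the probing heads.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
swish <- function(x) x * stats::plogis(x)

swish_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

sigmoid <- function(x) stats::plogis(x)

## Average pooling over time with stride 2; a trailing odd sample is dropped.
avgpool2 <- function(x) {
  tp <- dim(x)[2] %/% 2L
  idx <- seq_len(tp) * 2L
  (x[, idx - 1L, , drop = FALSE] + x[, idx, , drop = FALSE]) / 2
}

avgpool2_bw <- function(dy, t_in) {
  d <- dim(dy)
  dx <- array(0, c(d[1], t_in, d[3]))
  idx <- seq_len(d[2]) * 2L
  dx[, idx - 1L, ] <- dy / 2
  dx[, idx, ] <- dy / 2
  dx
}

## Fan-in scaled Gaussian (He) initialisation.
he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

as_batch <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

## Walk two parallel nested lists of numeric arrays.
walk_params <- function(a, b, f) {
  stopifnot(identical(names(a), names(b)))
  for (nm in names(a)) {
    if (is.list(a[[nm]])) {
      a[[nm]] <- walk_params(a[[nm]], b[[nm]], f)
    } else {
      a[[nm]] <- f(a[[nm]], b[[nm]])
    }
  }
  a
}

params_map <- function(a, f) {
  for (nm in names(a)) {
    if (is.list(a[[nm]])) a[[nm]] <- params_map(a[[nm]], f) else a[[nm]] <- f(a[[nm]])
  }
  a
}

params_checksum <- function(p) {
  acc <- 0
  rec <- function(x) {
    for (el in x) if (is.list(el)) rec(el) else acc <<- acc + sum(el^2)
  }
  rec(p)
  acc
}

## Fast per-row standard deviation (denominator n - 1).
row_sds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(pmax(rowSums(x^2) - n * mu^2, 0) / (n - 1))
}
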