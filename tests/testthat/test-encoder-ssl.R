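enc_fw <- magcardia:::encoder_forward
enc_bw <- magcardia:::encoder_backward
prj_fw <- magcardia:::proj_forward
prj_bw <- magcardia:::proj_backward

test_that("analytic gradients match finite differences through the stack", {
  set.seed(30)
  cfg <- tiny_cfg()
  enc <- encoder_init(cfg, seed = 31)
  x <- array(rnorm(8 * 200 * 4), c(8, 200, 4))
  for (train_mode in c(FALSE, TRUE)) {
    loss_fn <- function(e) {
      fw <- enc_fw(e, x, keep_cache = TRUE, train = train_mode)
      nt_xent_loss(prj_fw(e$proj, fw$emb)$z, 0.2)
    }
    fw <- enc_fw(enc, x, keep_cache = TRUE, train = train_mode)
    pf <- prj_fw(enc$proj, fw$emb, keep_cache = TRUE)
    ls <- nt_xent_loss(pf$z, 0.2, return_grad = TRUE)
    pb <- prj_bw(enc$proj, pf$cache, ls$grad)
    eb <- enc_bw(enc, fw$cache, pb$d_emb, need_dx = TRUE)
    eps <- 1e-6
    check <- function(get, set, ana, n = 4) {
      idx <- sample(length(get(enc)), n)
      for (i in idx) {
        e2 <- enc; v <- get(e2)
        v[i] <- v[i] + eps; lp <- loss_fn(set(e2, v))
        v[i] <- v[i] - 2 * eps; lm <- loss_fn(set(e2, v))
        ## mixed tolerance: near-zero gradients are dominated by the
        ## finite-difference cancellation error
        expect_lt(abs((lp - lm) / (2 * eps) - ana[i]),
                  1e-6 + 1e-4 * abs(ana[i]))
      }
    }
    check(function(e) e$params$blocks[[1]]$W,
          function(e, v) { e$params$blocks[[1]]$W <- v; e },
          eb$grads$blocks[[1]]$W)
    check(function(e) e$params$blocks[[2]]$Wp,
          function(e, v) { e$params$blocks[[2]]$Wp <- v; e },
          eb$grads$blocks[[2]]$Wp)
    check(function(e) e$params$emb$W,
          function(e, v) { e$params$emb$W <- v; e },
          eb$grads$emb$W)
    check(function(e) e$proj$W1,
          function(e, v) { e$proj$W1 <- v; e },
          pb$grads$W1)
    ## input gradient
    for (i in sample(length(x), 3)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      f <- function(xx) nt_xent_loss(
        prj_fw(enc$proj, enc_fw(enc, xx, train = train_mode)$emb)$z, 0.2)
      expect_lt(abs((f(xp) - f(xm)) / (2 * eps) - eb$d_input[i]),
                1e-6 + 1e-4 * abs(eb$d_input[i]))
    }
  }
})

test_that("NT-Xent reproduces closed-form values and symmetries", {
  ## B = 2, all four projections identical: uniform softmax over 3
  z <- matrix(rep(c(1, 2, 3), 4), 3)
  expect_equal(nt_xent_loss(z, 0.1), log(3), tolerance = 1e-12)
  ## identical within pairs, orthogonal across, tau = 0.1
  z2 <- cbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expected <- -log(exp(10) / (exp(10) + 2 * exp(0)))
  expect_equal(nt_xent_loss(z2, 0.1), expected, tolerance = 1e-9)
  expect_equal(expected, 9.08e-5, tolerance = 1e-2)
  ## permuting the pair order leaves the loss unchanged
  set.seed(32)
  z3 <- matrix(rnorm(5 * 8), 5)
  perm <- sample(4)
  z3p <- z3[, c(perm, perm + 4)]
  expect_equal(nt_xent_loss(z3, 0.2), nt_xent_loss(z3p, 0.2),
               tolerance = 1e-12)
  expect_error(nt_xent_loss(matrix(rnorm(6), 3), 0.1), "B >= 2")
})


test_that("NT-Xent matches brute force for B in 2:4 and stays positive", {
  set.seed(33)
  for (b in 2:4) {
    for (r in 1:5) {
      z <- matrix(rnorm(6 * 2 * b), 6)
      tau <- runif(1, 0.05, 0.5)
      expect_equal(nt_xent_loss(z, tau), brute_nt_xent(z, tau),
                   tolerance = 1e-9)
      expect_gt(nt_xent_loss(z, tau), 0)
    }
  }
  ## when views disagree more than strangers (hard geometry), raising the
  ## temperature softens the penalty: loss decreases from tau 0.05 to 0.5,
  ## in agreement with the brute-force oracle at every point
  z <- cbind(c(1, 0), c(0, 1), c(-1, 0.1), c(0.1, -1))
  taus <- c(0.05, 0.1, 0.2, 0.5)
  losses <- vapply(taus, function(tt) nt_xent_loss(z, tt), numeric(1))
  oracle <- vapply(taus, function(tt) brute_nt_xent(z, tt), numeric(1))
  expect_equal(losses, oracle, tolerance = 1e-9)
  expect_true(all(diff(losses) < 0))
})

test_that("the cosine schedule hits its endpoints and midpoint", {
  expect_identical(cosine_lr(0, 100, 1e-3, 0.01), 1e-3)
  expect_equal(cosine_lr(100, 100, 1e-3, 0.01), 1e-5, tolerance = 1e-12)
  expect_equal(cosine_lr(50, 100, 1e-3, 0.01), 5.05e-4, tolerance = 1e-12)
  expect_error(cosine_lr(101, 100), "out of")
  expect_error(cosine_lr(-1, 100), "out of")
})

test_that("encode is deterministic, finite and shape-checked", {
  cfg <- tiny_cfg()
  enc <- encoder_init(cfg, seed = 34)
  z <- matrix(0, 8, 200)
  e1 <- encode(enc, z)$embedding[[1]]
  expect_true(all(is.finite(e1)))
  expect_length(e1, 8L)
  expect_identical(e1, encode(enc, z)$embedding[[1]])
  set.seed(35)
  x <- matrix(rnorm(8 * 200), 8)
  x2 <- x; x2[3, 100] <- x2[3, 100] + 0.5
  ea <- encode(enc, x)$embedding[[1]]
  eb_ <- encode(enc, x2)$embedding[[1]]
  expect_false(identical(ea, eb_))
  expect_true(all(is.finite(eb_)))
  expect_error(encode(enc, matrix(0, 4, 200)), "shape")
  expect_error(encode(enc, matrix(c(1, Inf), 8, 200)), "finite")
})

test_that("tiny pretraining reduces the loss, deterministically", {
  segs <- tiny_segments(24)
  cfg <- tiny_cfg()
  pc <- pretrain_config(epochs = 6L, batch_size = 8L, seed = 51L)
  ck <- pretrain(segs, cfg, pc)
  expect_length(ck$loss_trace, 6L)
  expect_lt(ck$loss_trace[6], ck$loss_trace[1])
  ck2 <- pretrain(segs, cfg, pc)
  expect_identical(ck$loss_trace, ck2$loss_trace)
  expect_identical(ck$params, ck2$params)
})

test_that("pretrained embeddings align views more than strangers", {
  segs <- tiny_segments(24)
  ck <- pretrain(segs, tiny_cfg(),
                 pretrain_config(epochs = 6L, batch_size = 8L, seed = 51L))
  set.seed(52)
  unit <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")
  view_sims <- cross_sims <- c()
  for (i in 1:8) {
    v <- make_views(segs[[i]], augment_config())
    e <- unit(magcardia:::encode_batched(ck, list(v$view1, v$view2,
                                                  segs[[i + 8]])))
    view_sims <- c(view_sims, sum(e[, 1] * e[, 2]))
    cross_sims <- c(cross_sims, sum(e[, 1] * e[, 3]))
  }
  expect_gt(mean(view_sims), mean(cross_sims))
})

test_that("checkpoints round-trip to identical embeddings", {
  segs <- tiny_segments(24)
  ck <- pretrain(segs, tiny_cfg(),
                 pretrain_config(epochs = 2L, batch_size = 8L, seed = 53L))
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(ck, path)
  ck2 <- read_checkpoint(path)
  probe_batch <- segs[1:4]
  expect_identical(magcardia:::encode_batched(ck, probe_batch),
                   magcardia:::encode_batched(ck2, probe_batch))
})
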