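test_that("the probing head has the contracted form", {
  expect_identical(swish(0), 0)
  expect_equal(swish(1), 1 * plogis(1), tolerance = 1e-12)
  expect_equal(swish(1), 0.7311, tolerance = 1e-4)
  head <- build_head(16, seed = 40)
  expect_equal(dim(head$W1), c(64L, 16L))
  p <- magcardia:::head_forward(head, matrix(rnorm(16 * 5), 16))$prob
  expect_true(all(p > 0 & p < 1))
})

test_that("weighted binary cross-entropy follows the stated conventions", {
  ## toy batch {(p=0.5, y=1, w=2), (p=0.5, y=0, w=1)} under weighted mean
  expect_equal(weighted_bce(c(0.5, 0.5), c(1, 0), c(2, 1)), log(2),
               tolerance = 1e-12)
  ## doubling a sample's weight doubles its loss contribution exactly
  p <- c(0.8, 0.3, 0.6); y <- c(1, 0, 1); w <- c(1, 1, 1)
  term <- function(w) weighted_bce(p, y, w) * sum(w)
  l_each <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(term(c(2, 1, 1)) - term(c(1, 1, 1)), l_each[1],
               tolerance = 1e-12)
  ## class weights are inverse-frequency, normalised to mean 1
  cw <- magcardia:::class_weights(c(1, 0, 0, 0))
  expect_equal(cw[1] / cw[2], 3)
  expect_equal(mean(cw), 1)
})

test_that("patient folds are stratified, exclusive and balanced", {
  pat <- tibble::tibble(patient_id = sprintf("P%02d", 1:40),
                        label = rep(c(1, 0), each = 20))
  f <- stratified_patient_folds(pat, k = 5, seed = 1)
  sizes <- table(f$fold)
  expect_true(all(sizes == 8))
  pos <- tapply(f$label, f$fold, sum)
  expect_true(all(pos == 4))
  expect_silent(audit_fold_assignment(f))
  ## 41 patients: fold sizes differ by at most one
  pat41 <- tibble::tibble(patient_id = sprintf("P%02d", 1:41),
                          label = c(rep(1, 21), rep(0, 20)))
  f41 <- stratified_patient_folds(pat41, k = 5, seed = 2)
  expect_lte(diff(range(table(f41$fold))), 1)
  ## too few patients in a class
  expect_error(stratified_patient_folds(
    tibble::tibble(patient_id = letters[1:6], label = c(1, rep(0, 5))), 5),
    "at least k")
})

test_that("the audit rejects intentionally leaky assignments", {
  pat <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                        label = rep(c(1, 0), 5))
  f <- stratified_patient_folds(pat, k = 5, seed = 3)
  leaky <- rbind(f, tibble::tibble(patient_id = f$patient_id[1],
                                   label = f$label[1],
                                   fold = (f$fold[1] %% 5) + 1))
  expect_error(audit_fold_assignment(leaky), "leaky")
  segs <- lapply(c(pat$patient_id, "P99"), function(p)
    fake_segment(matrix(0, 2, 10), patient_id = p))
  expect_error(audit_fold_assignment(f, segs), "unassigned")
})

test_that("patient aggregation is an order-invariant mean", {
  a <- aggregate_patient(c(0.2, 0.4, 0.6), rep("A", 3))
  expect_equal(a$score, 0.4)
  expect_equal(aggregate_patient(0.9, "B")$score, 0.9)
  sc <- c(0.1, 0.9, 0.5, 0.7)
  id <- c("A", "B", "A", "B")
  perm <- c(3, 1, 4, 2)
  expect_equal(aggregate_patient(sc, id), aggregate_patient(sc[perm], id[perm]))
})

test_that("rank AUC equals brute-force pair counting (ties half credit)", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 3 / 4)
  set.seed(44)
  for (r in 1:20) {
    n <- sample(4:50, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_identical(auc_rank(s, y), brute_auc(s, y))
  }
  expect_error(auc_rank(c(0.1, 0.2), c(1, 1)), "one class")
})

test_that("metrics hit the closed-form reference points", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  ## label permutation null centred on 1/2
  set.seed(45)
  s <- runif(20)
  null_auc <- replicate(1000, auc_rank(s, sample(rep(c(0, 1), 10))))
  expect_equal(mean(null_auc), 0.5, tolerance = 0.05 / 0.5)
})

## small labelled benchmark on the tiny encoder: 12 patients x 2 segments,
## class shifts one channel's amplitude
tiny_labelled_segments <- function(seed = 60L) {
  set.seed(seed)
  segs <- list()
  for (p in 1:12) {
    y <- as.numeric(p > 6)
    for (s in 1:2) {
      m <- matrix(rnorm(8 * 200, sd = 0.5), 8)
      base <- sin(2 * pi * 5 * (1:200) / 200)
      m[3, ] <- m[3, ] + base * (1 + 2 * y)
      segs[[length(segs) + 1L]] <-
        fake_segment(m, patient_id = sprintf("Q%02d", p), segment_index = s,
                     labels = c(cad_multivessel = y, lvef_reduced = 0,
                                af_risk = 0, lad = 0, lcx = 0, rca = 0))
    }
  }
  segs
}

test_that("probe fine-tuning freezes the encoder during warm-up", {
  segs <- tiny_labelled_segments()
  ck <- pretrain(segs, tiny_cfg(),
                 pretrain_config(epochs = 2L, batch_size = 8L, seed = 61L))
  before <- magcardia:::params_checksum(ck$params)
  res <- finetune_probe(ck, segs, "cad_multivessel",
                        probe_config(warmup_epochs = 3L, joint_epochs = 0L,
                                     k_folds = 3L, seed = 62L))
  ## with zero joint epochs the per-fold encoders are the checkpoint itself
  for (mdl in res$models) {
    expect_identical(magcardia:::params_checksum(mdl$encoder$params), before)
  }
  expect_equal(nrow(res$fold_metrics), 3L)
  expect_true(all(c("auc", "sensitivity", "specificity", "accuracy",
                    "precision", "f1") %in% names(res$fold_metrics)))
})

test_that("probe training is reproducible and rejects one-class folds", {
  segs <- tiny_labelled_segments()
  ck <- pretrain(segs, tiny_cfg(),
                 pretrain_config(epochs = 2L, batch_size = 8L, seed = 61L))
  cfg <- probe_config(warmup_epochs = 2L, joint_epochs = 2L, k_folds = 3L,
                      batch_size = 8L, seed = 63L)
  r1 <- finetune_probe(ck, segs, "cad_multivessel", cfg)
  r2 <- finetune_probe(ck, segs, "cad_multivessel", cfg)
  expect_identical(r1$patient_scores$score, r2$patient_scores$score)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
  ## a single-class task cannot be probed
  expect_error(finetune_probe(ck, segs, "af_risk", cfg), "at least k")
})

test_that("the supervised baseline shares the architecture exactly", {
  cfg <- tiny_cfg()
  e1 <- encoder_init(cfg, seed = 1)
  e2 <- encoder_init(cfg, seed = 2)
  expect_identical(n_params(e1), n_params(e2))
  segs <- tiny_labelled_segments()
  pcfg <- probe_config(warmup_epochs = 1L, joint_epochs = 1L, k_folds = 3L,
                       batch_size = 8L, seed = 64L)
  b1 <- train_supervised_baseline(cfg, segs, "cad_multivessel", pcfg)
  b2 <- train_supervised_baseline(cfg, segs, "cad_multivessel", pcfg)
  expect_identical(b1$patient_scores$score, b2$patient_scores$score)
  expect_false(b1$pretrained)
  ## baseline fold encoders have the same parameter count as the SSL path
  expect_identical(n_params(b1$models[[1]]$encoder), n_params(e1))
})

test_that("tidy and glance summarise probe results", {
  segs <- tiny_labelled_segments()
  ck <- pretrain(segs, tiny_cfg(),
                 pretrain_config(epochs = 2L, batch_size = 8L, seed = 61L))
  res <- finetune_probe(ck, segs, "cad_multivessel",
                        probe_config(warmup_epochs = 2L, joint_epochs = 1L,
                                     k_folds = 3L, batch_size = 8L,
                                     seed = 65L))
  td <- tidy(res)
  expect_true(all(c("fold", "metric", "value") %in% names(td)))
  expect_equal(nrow(td), 3L * 6L)
  gl <- glance(res)
  expect_equal(gl$task, "cad_multivessel")
  expect_equal(gl$n_folds, 3L)
  expect_true(gl$auc >= 0 && gl$auc <= 1)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
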