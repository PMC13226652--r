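## Task-specific probing of the learned representation: a shallow head
## (dropout 0.2 -> 64-unit swish layer -> sigmoid) on top of the encoder,
## trained per patient-stratified cross-validation fold with a 5-epoch
## head-only warm-up (encoder frozen) followed by joint fine-tuning with
## class-frequency-weighted binary cross-entropy under Adam. Segment scores
## are aggregated to patient level before metric computation.

#' Build a probing head
#'
#' `sigmoid(w2 . swish(W1 . dropout(e) + b1) + b2)` with a 64-unit hidden
#' layer by default.
#'
#' @param embedding_dim Dimension of the encoder embedding.
#' @param hidden Hidden units.
#' @param seed Optional init seed.
#' @return An `mcg_probe_head`.
#' @export
build_head <- function(embedding_dim, hidden = 64L, seed = NULL) {
  stopifnot(embedding_dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  structure(list(W1 = he_init(hidden, embedding_dim), b1 = rep(0, hidden),
                 w2 = stats::rnorm(hidden, sd = sqrt(2 / hidden)), b2 = 0),
            class = "mcg_probe_head")
}

head_forward <- function(head, e, dropout = 0, train = FALSE) {
  mask <- NULL
  ed <- e
  if (train && dropout > 0) {
    mask <- matrix(stats::runif(length(e)) >= dropout, nrow(e)) / (1 - dropout)
    ed <- e * mask
  }
  a <- head$W1 %*% ed + head$b1
  s <- swish(a)
  logit <- as.numeric(crossprod(s, head$w2)) + head$b2
  list(logit = logit, prob = sigmoid(logit),
       cache = list(ed = ed, a = a, s = s, mask = mask))
}

head_backward <- function(head, cache, dlogit) {
  dw2 <- as.numeric(cache$s %*% dlogit)
  db2 <- sum(dlogit)
  da <- outer(head$w2, dlogit) * swish_grad(cache$a)
  dW1 <- da %*% t(cache$ed)
  db1 <- rowSums(da)
  de <- t(head$W1) %*% da
  if (!is.null(cache$mask)) de <- de * cache$mask
  list(grads = list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2), d_emb = de)
}

#' Patient-level stratified fold assignment
#'
#' Assigns every patient to exactly one of `k` folds, stratified by label so
#' each fold's positive count is within one patient of the global proportion.
#' All segments of a patient inherit its fold, preventing leakage.
#'
#' @param patient_labels Tibble/data frame with `patient_id` and `label`
#'   columns, or a named 0/1 vector.
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @return Tibble `patient_id`, `label`, `fold` (1..k).
#' @export
stratified_patient_folds <- function(patient_labels, k = 5L, seed = 1L) {
  if (!is.data.frame(patient_labels)) {
    patient_labels <- tibble::tibble(patient_id = names(patient_labels),
                                     label = as.numeric(patient_labels))
  }
  tab <- table(factor(patient_labels$label,
                      levels = union(c(0, 1), unique(patient_labels$label))))
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " patients (have ",
         paste(names(tab), tab, sep = ":", collapse = ", "), ")")
  }
  set.seed(as.integer(seed))
  offset <- 0L
  out <- lapply(split(patient_labels, patient_labels$label), function(d) {
    d <- d[sample.int(nrow(d)), , drop = FALSE]
    d$fold <- ((seq_len(nrow(d)) - 1L + offset) %% k) + 1L
    offset <<- (offset + nrow(d)) %% k
    d
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$patient_id)
}

#' Audit a fold assignment for leakage
#'
#' Rejects assignments where a patient appears in more than one fold, and —
#' when segments are supplied — verifies that every fold's training and
#' validation patient sets are disjoint and cover all segments.
#'
#' @param folds Tibble from [stratified_patient_folds()] (or any
#'   `patient_id`/`fold` mapping).
#' @param segments Optional list of segments to check coverage for.
#' @return `TRUE` invisibly; stops with a diagnostic on a leaky assignment.
#' @export
audit_fold_assignment <- function(folds, segments = NULL) {
  dup <- unique(folds$patient_id[duplicated(folds$patient_id)])
  multi <- dplyr::summarise(dplyr::group_by(folds, .data$patient_id),
                            n_folds = dplyr::n_distinct(.data$fold))
  bad <- multi$patient_id[multi$n_folds > 1L]
  if (length(bad) > 0) {
    stop("leaky fold assignment: patients in multiple folds: ",
         paste(bad, collapse = ", "))
  }
  if (length(dup) > 0) folds <- dplyr::distinct(folds, .data$patient_id,
                                                .keep_all = TRUE)
  if (!is.null(segments)) {
    pids <- vapply(segments, function(s) s$patient_id, character(1))
    missing <- setdiff(unique(pids), folds$patient_id)
    if (length(missing) > 0) {
      stop("segments from unassigned patients: ",
           paste(missing, collapse = ", "))
    }
    for (f in sort(unique(folds$fold))) {
      val <- folds$patient_id[folds$fold == f]
      train <- folds$patient_id[folds$fold != f]
      if (length(intersect(val, train)) > 0) stop("train/validation overlap")
    }
  }
  invisible(TRUE)
}

#' Probing / fine-tuning configuration
#'
#' @param warmup_epochs Head-only epochs with the encoder frozen.
#' @param joint_epochs Joint encoder+head epochs.
#' @param lr Adam learning rate for the joint phase (default 1e-3: over the
#'   short desk-scale schedules a smaller rate leaves the encoder
#'   effectively frozen).
#' @param head_lr Adam learning rate for the head-only warm-up.
#' @param batch_size Segments per batch.
#' @param dropout Dropout on the embedding inside the head (training only).
#' @param k_folds Number of patient-stratified folds.
#' @param threshold Operating point on patient scores for thresholded
#'   metrics (fixed, to avoid validation-set tuning).
#' @param aggregate Patient aggregation statistic: "mean" or "median".
#' @param seed Seed for folds, head init and batch order.
#' @return An `mcg_probe_config`.
#' @export
probe_config <- function(warmup_epochs = 5L, joint_epochs = 30L, lr = 1e-3,
                         head_lr = 1e-2, batch_size = 32L, dropout = 0.2,
                         k_folds = 5L, threshold = 0.5, aggregate = "mean",
                         seed = 1L) {
  structure(list(warmup_epochs = as.integer(warmup_epochs),
                 joint_epochs = as.integer(joint_epochs), lr = lr,
                 head_lr = head_lr, batch_size = as.integer(batch_size),
                 dropout = dropout, k_folds = as.integer(k_folds),
                 threshold = threshold,
                 aggregate = match.arg(aggregate, c("mean", "median")),
                 seed = as.integer(seed)),
            class = "mcg_probe_config")
}

seg_task_labels <- function(segments, task) {
  vapply(segments, function(s) {
    if (is.null(s$labels) || is.na(s$labels[task])) {
      stop("segment without label for task ", task)
    }
    as.numeric(s$labels[[task]])
  }, numeric(1))
}

#' Aggregate segment scores to patient level
#'
#' @param scores Numeric segment scores.
#' @param patient_ids Parallel patient identifiers.
#' @param stat "mean" (default) or "median".
#' @return Tibble `patient_id`, `score`.
#' @export
aggregate_patient <- function(scores, patient_ids, stat = "mean") {
  f <- switch(match.arg(stat, c("mean", "median")),
              mean = mean, median = stats::median)
  d <- tibble::tibble(patient_id = patient_ids, score = scores)
  dplyr::summarise(dplyr::group_by(d, .data$patient_id),
                   score = f(.data$score), .groups = "drop")
}

#' Rank-based AUC
#'
#' Equivalent to the Mann-Whitney statistic: ties receive half credit.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a fixed operating point
#'
#' @param scores Patient-level scores.
#' @param labels Binary labels.
#' @param threshold Scores `>= threshold` are called positive.
#' @return One-row tibble: `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  auc <- auc_rank(scores, labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens)
        else NA_real_
  tibble::tibble(auc = auc, sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / length(labels), precision = prec,
                 f1 = f1)
}

## Train one head (+ optionally the encoder) on a training set and score a
## validation set. Shared by the SSL probe and the supervised baseline.
train_probe_fold <- function(enc, sig_train, y_train, sig_val, cfg,
                             warmup = TRUE, joint_epochs = cfg$joint_epochs,
                             seed = 1L) {
  if (length(unique(y_train)) < 2L) stop("single-class training fold")
  set.seed(as.integer(seed))
  head <- build_head(enc$cfg$embed_dim)
  w_all <- class_weights(y_train)
  n <- length(sig_train)

  ## Normalisation statistics are calibrated exactly on the training split
  ## (for a freshly initialised encoder) and then frozen for the whole
  ## supervised phase: with small batches, re-estimating them during
  ## fine-tuning makes the head's input distribution drift away from what
  ## it was fitted to.
  if (!isTRUE(enc$bn$initialized)) {
    enc <- calibrate_bn(enc, sig_train, cfg$batch_size)
  }

  ## a frozen per-dimension standardiser of the embeddings (training-split
  ## statistics) conditions the head's optimisation; it is absorbed into the
  ## head's first layer after training so downstream consumers see a plain
  ## head over raw embeddings
  emb0 <- encode_batched(enc, sig_train)
  std_mu <- rowMeans(emb0)
  std_sd <- pmax(apply(emb0, 1, stats::sd), 1e-8)

  if (warmup && cfg$warmup_epochs > 0L) {
    checksum_before <- params_checksum(enc$params)
    emb <- (emb0 - std_mu) / std_sd
    h_opt <- adam_init(head[1:4])
    for (ep in seq_len(cfg$warmup_epochs)) {
      ord <- sample.int(n)
      i <- 1L
      while (i <= n) {
        idx <- ord[i:min(i + cfg$batch_size - 1L, n)]
        i <- i + cfg$batch_size
        fwd <- head_forward(head, emb[, idx, drop = FALSE], cfg$dropout, TRUE)
        dlogit <- w_all[idx] * (fwd$prob - y_train[idx]) / sum(w_all[idx])
        hb <- head_backward(head, fwd$cache, dlogit)
        st <- adam_step(head[1:4], hb$grads, h_opt, cfg$head_lr)
        head[1:4] <- st$params
        h_opt <- st$state
      }
    }
    stopifnot(identical(params_checksum(enc$params), checksum_before))
  }

  if (joint_epochs > 0L) {
    e_opt <- adam_init(enc$params)
    h_opt <- adam_init(head[1:4])
    for (ep in seq_len(joint_epochs)) {
      ord <- sample.int(n)
      i <- 1L
      while (i <= n) {
        idx <- ord[i:min(i + cfg$batch_size - 1L, n)]
        i <- i + cfg$batch_size
        x <- make_batch_cube(sig_train[idx])
        fw <- encoder_forward(enc, x, keep_cache = TRUE)
        fwd <- head_forward(head, (fw$emb - std_mu) / std_sd,
                            cfg$dropout, TRUE)
        dlogit <- w_all[idx] * (fwd$prob - y_train[idx]) / sum(w_all[idx])
        hb <- head_backward(head, fwd$cache, dlogit)
        eb <- encoder_backward(enc, fw$cache, hb$d_emb / std_sd)
        st <- adam_step(enc$params, eb$grads, e_opt, cfg$lr)
        enc$params <- st$params
        e_opt <- st$state
        st <- adam_step(head[1:4], hb$grads, h_opt, cfg$lr)
        head[1:4] <- st$params
        h_opt <- st$state
      }
    }
  }

  ## absorb the standardiser: head(std(e)) == absorbed_head(e)
  w1_raw <- sweep(head$W1, 2, std_sd, "/")
  head$b1 <- head$b1 - as.numeric(w1_raw %*% std_mu)
  head$W1 <- w1_raw
  emb_val <- encode_batched(enc, sig_val)
  scores <- head_forward(head, emb_val)$prob
  list(head = head, encoder = enc, val_scores = scores)
}

probe_engine <- function(enc_or_cfg, segments, task, cfg, pretrained) {
  sig <- lapply(segments, function(s) s$signal)
  y <- seg_task_labels(segments, task)
  pid <- vapply(segments, function(s) s$patient_id, character(1))
  pat <- dplyr::distinct(tibble::tibble(patient_id = pid, label = y))
  folds <- stratified_patient_folds(pat, k = cfg$k_folds, seed = cfg$seed)
  audit_fold_assignment(folds, segments)
  fold_of <- stats::setNames(folds$fold, folds$patient_id)

  fold_rows <- list()
  score_rows <- list()
  models <- list()
  for (f in sort(unique(folds$fold))) {
    val_idx <- which(fold_of[pid] == f)
    train_idx <- setdiff(seq_along(sig), val_idx)
    enc <- if (pretrained) {
      enc_or_cfg
    } else {
      encoder_init(enc_or_cfg, seed = cfg$seed * 1000L + f)
    }
    res <- train_probe_fold(
      enc, sig[train_idx], y[train_idx], sig[val_idx], cfg,
      warmup = pretrained,
      joint_epochs = if (pretrained) cfg$joint_epochs
                     else cfg$warmup_epochs + cfg$joint_epochs,
      seed = cfg$seed * 100L + f)
    ps <- aggregate_patient(res$val_scores, pid[val_idx], cfg$aggregate)
    ps$label <- pat$label[match(ps$patient_id, pat$patient_id)]
    ps$fold <- f
    score_rows[[f]] <- ps
    fold_rows[[f]] <- dplyr::mutate(
      compute_metrics(ps$score, ps$label, cfg$threshold), fold = f,
      .before = 1)
    models[[f]] <- list(head = res$head, encoder = res$encoder)
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  k <- nrow(fold_metrics)
  summarise_ci <- function(v) {
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    half <- stats::qt(0.975, k - 1) * s / sqrt(k)
    c(mean = m, lo = m - half, hi = m + half)
  }
  summ <- purrr::map_dfr(
    c("auc", "sensitivity", "specificity", "accuracy", "precision", "f1"),
    function(mn) {
      ci <- summarise_ci(fold_metrics[[mn]])
      tibble::tibble(metric = mn, mean = ci["mean"], ci_lo = ci["lo"],
                     ci_hi = ci["hi"])
    })
  structure(list(task = task, pretrained = pretrained,
                 fold_metrics = fold_metrics,
                 patient_scores = dplyr::bind_rows(score_rows),
                 summary = summ, folds = folds, models = models, cfg = cfg),
            class = "mcg_probe_result")
}

#' Fine-tune a probing head on a pretrained encoder
#'
#' Patient-stratified k-fold cross-validation; each fold runs a head-only
#' warm-up with the encoder frozen (asserted via a parameter checksum), then
#' joint optimisation of encoder and head, and finally scores its held-out
#' patients. Fold metrics are summarised as mean with a 95% t-interval.
#'
#' @param encoder A pretrained `mcg_encoder` / `mcg_checkpoint`.
#' @param segments Labelled, QC-passed segments.
#' @param task Task name present in segment labels (e.g. "cad_multivessel").
#' @param cfg An [probe_config()].
#' @return An `mcg_probe_result` with per-fold metrics, patient scores,
#'   summary, fold assignment and the per-fold trained models.
#' @export
finetune_probe <- function(encoder, segments, task, cfg = probe_config()) {
  probe_engine(encoder, segments, task, cfg, pretrained = TRUE)
}

#' Supervised end-to-end baseline
#'
#' The same encoder-head architecture trained from random initialisation with
#' the supervised objective only (no pretraining, no frozen warm-up; the
#' total epoch budget matches warm-up + joint of the probe).
#'
#' @param enc_cfg An [encoder_config()] (architecture only).
#' @inheritParams finetune_probe
#' @return An `mcg_probe_result`.
#' @export
train_supervised_baseline <- function(enc_cfg, segments, task,
                                      cfg = probe_config()) {
  probe_engine(enc_cfg, segments, task, cfg, pretrained = FALSE)
}

#' Number of trainable parameters
#'
#' @param enc An `mcg_encoder` (a head's parameters can be added by the
#'   caller).
#' @return Integer count over encoder + projection head.
#' @export
n_params <- function(enc) {
  cnt <- 0L
  rec <- function(x) {
    for (el in x) if (is.list(el)) rec(el) else cnt <<- cnt + length(el)
  }
  rec(enc$params)
  rec(enc$proj)
  cnt
}

#' @export
print.mcg_probe_result <- function(x, ...) {
  a <- x$summary[x$summary$metric == "auc", ]
  cat(sprintf("<mcg_probe_result> task %s (%s): AUC %.3f (95%% CI %.3f-%.3f) over %d folds\n",
              x$task, if (x$pretrained) "SSL probe" else "supervised baseline",
              a$mean, a$ci_lo, a$ci_hi, nrow(x$fold_metrics)))
  invisible(x)
}
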