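# Training protocol: Adam on the summed dual-unit cross-entropy, mini-batches,
# dropout after each convolution activation, and early stopping on a held-out
# monitoring slice of the training subjects. The feature pipeline (Ledoit-Wolf
# covariance -> tangent embedding) and the class templates are fitted on the
# non-monitor training portion only, and are carried inside the fitted model
# so held-out subjects are embedded without refitting.

#' Training and pipeline configuration
#'
#' Optimization defaults follow the published protocol: Adam with learning
#' rate 1e-4 and weight decay 5e-4, mini-batches of 16, dropout 0.1 after
#' each graph-convolution activation, 10% of training subjects split off as
#' a monitoring set, and training stopped at the highest monitoring accuracy
#' (with a patience horizon). Pipeline defaults: tangent features at the
#' geometric mean, KNN k = 20 (clamped to N - 1 on small atlases),
#' Chebyshev order 3, 64 kernels per convolution layer, 128 hidden units.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight-decay rate added to gradients.
#' @param batch_size Mini-batch size.
#' @param dropout Dropout rate after each convolution activation.
#' @param monitor_fraction Fraction of training subjects held out for early
#'   stopping (stratified by class), in (0, 0.5).
#' @param patience Epochs without monitor improvement before stopping.
#' @param max_epochs Hard epoch cap.
#' @param seed Seed governing every random choice (splits, initialization,
#'   batch order, dropout).
#' @param feature_kind `"tangent"` or `"correlation"`.
#' @param tangent_mean `"geometric"` or `"euclidean"` reference mean.
#' @param standardize Scale time-series columns to unit variance before
#'   covariance estimation.
#' @param graph_k Neighbours per node in template construction.
#' @param K Chebyshev order.
#' @param channels Convolution kernels per layer.
#' @param hidden Fully connected layer width.
#' @return Object of class `fgdn_config`.
#' @export
fgdn_config <- function(learning_rate = 1e-4, weight_decay = 5e-4,
                        batch_size = 16, dropout = 0.1,
                        monitor_fraction = 0.10, patience = 20,
                        max_epochs = 300, seed = 1,
                        feature_kind = c("tangent", "correlation"),
                        tangent_mean = c("geometric", "euclidean"),
                        standardize = FALSE, graph_k = 20, K = 3,
                        channels = 64, hidden = 128) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            dropout >= 0, dropout < 1, patience >= 1, max_epochs >= 1)
  if (monitor_fraction <= 0 || monitor_fraction >= 0.5) {
    stop_fgdn("monitor_fraction must lie in (0, 0.5)")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 monitor_fraction = monitor_fraction,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 feature_kind = match.arg(feature_kind),
                 tangent_mean = match.arg(tangent_mean),
                 standardize = standardize, graph_k = as.integer(graph_k),
                 K = as.integer(K), channels = as.integer(channels),
                 hidden = as.integer(hidden)),
            class = "fgdn_config")
}

# Fold-independent per-subject base features: Pearson matrices for the
# correlation pipeline, Ledoit-Wolf covariances for the tangent pipeline.
prepare_base_features <- function(cohort, cfg) {
  if (cfg$feature_kind == "correlation") {
    mats <- lapply(cohort, pearson_correlation)
  } else {
    mats <- lapply(cohort, ledoit_wolf_covariance,
                   standardize = cfg$standardize)
  }
  names(mats) <- cohort_ids(cohort)
  mats
}

# Final per-subject feature matrices given a fitted pipeline.
apply_feature_pipeline <- function(base, pipeline) {
  if (pipeline$kind == "correlation") return(base)
  lapply(base, tangent_embed, ref = pipeline$tangent_ref)
}

features_to_array <- function(feats) {
  n <- nrow(feats[[1]]$values)
  x <- array(0, c(n, n, length(feats)))
  for (i in seq_along(feats)) x[, , i] <- feats[[i]]$values
  x
}

#' Train a functional graph discriminative network
#'
#' Full pipeline on a labeled training cohort: a stratified
#' `monitor_fraction` slice is held out for early stopping; the tangent
#' reference (for tangent features) and the two class templates are fitted
#' on the remaining subjects; the shared-weight dual-graph network is then
#' optimized with Adam on the summed cross-entropy of both class units.
#' After every epoch the monitoring accuracy is evaluated; the parameters
#' from the best monitoring epoch are restored when training stops
#' (`patience` epochs without improvement, or `max_epochs`).
#'
#' @param cohort List of labeled [roi_timeseries] (diagnosis ASD/HC, both
#'   classes present).
#' @param cfg An [fgdn_config].
#' @param base_features Optional precomputed per-subject base features
#'   (Ledoit-Wolf covariances or Pearson matrices) for these subjects, an
#'   internal speed-up used by the evaluation harness; computed when `NULL`.
#' @return Object of class `fgdn_model`: parameters, templates, rescaled
#'   Laplacians, tangent reference, training history (per-epoch loss and
#'   monitoring accuracy/AUC), and the id sets everything was fitted on.
#' @export
train_fgdn <- function(cohort, cfg = fgdn_config(), base_features = NULL) {
  labels <- cohort_labels(cohort)
  ids <- cohort_ids(cohort)
  if (length(unique(labels[labels != "UNKNOWN"])) < 2) {
    stop_fgdn("training set must contain both ASD and HC subjects")
  }
  n <- cohort[[1]]$n_rois

  monitor_idx <- stratified_holdout(labels, cfg$monitor_fraction, cfg$seed)
  fit_idx <- setdiff(seq_along(cohort), monitor_idx)

  if (is.null(base_features)) base_features <- prepare_base_features(cohort, cfg)
  base_features <- base_features[ids]

  if (cfg$feature_kind == "tangent") {
    ref <- fit_tangent_reference(base_features[fit_idx],
                                 mean_type = cfg$tangent_mean)
    pipeline <- list(kind = "tangent", tangent_ref = ref)
  } else {
    pipeline <- list(kind = "correlation", tangent_ref = NULL)
  }
  feats <- apply_feature_pipeline(base_features, pipeline)

  k_eff <- min(cfg$graph_k, n - 1L)
  templates <- list()
  for (cls in c("ASD", "HC")) {
    mean_fc <- class_mean_connectivity(feats[fit_idx], cls, labels[fit_idx])
    tmpl <- build_template(mean_fc, k_eff, cls)
    tmpl$source_ids <- ids[fit_idx][labels[fit_idx] == cls]
    templates[[tolower(cls)]] <- tmpl
  }
  lap <- list(asd = normalized_laplacian(templates$asd$weights),
              hc = normalized_laplacian(templates$hc$weights))

  x_all <- features_to_array(feats)
  y_all <- as.numeric(labels == "ASD")

  params <- fgdn_params(n, K = cfg$K, channels = cfg$channels,
                        hidden = cfg$hidden, seed = cfg$seed + 1L)
  fit <- optimize_fgdn(params, x_all, y_all, fit_idx, monitor_idx,
                       lap$asd$rescaled, lap$hc$rescaled, cfg,
                       lr = cfg$learning_rate, max_epochs = cfg$max_epochs,
                       patience = cfg$patience, seed = cfg$seed + 2L)

  structure(list(params = fit$params, templates = templates,
                 laplacians = lap, pipeline = pipeline, cfg = cfg,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_monitor_acc = fit$best_acc,
                 trained_on = ids[fit_idx], monitor_ids = ids[monitor_idx],
                 n_rois = n, k_eff = k_eff),
            class = "fgdn_model")
}

# Adam loop with early stopping; shared by train_fgdn and fine_tune_fgdn.
optimize_fgdn <- function(params, x_all, y_all, fit_idx, monitor_idx,
                          lhat_asd, lhat_hc, cfg, lr, max_epochs, patience,
                          seed, early_stop = TRUE) {
  set.seed(seed)
  state <- adam_init(params)
  vec <- params_flatten(params)
  best_params <- params
  best_acc <- -Inf
  best_epoch <- 0L
  since_best <- 0L
  history <- vector("list", max_epochs)
  have_monitor <- length(monitor_idx) > 0

  for (epoch in seq_len(max_epochs)) {
    order_idx <- fit_idx[sample(length(fit_idx))]
    epoch_loss <- 0
    for (start in seq(1, length(order_idx), by = cfg$batch_size)) {
      batch <- order_idx[start:min(start + cfg$batch_size - 1, length(order_idx))]
      res <- fgdn_batch_grad(x_all[, , batch, drop = FALSE], lhat_asd, lhat_hc,
                             y_all[batch], params, dropout = cfg$dropout,
                             training = TRUE)
      epoch_loss <- epoch_loss + res$loss
      state$t <- state$t + 1L
      adam_update_inplace(vec, params_flatten(res$grads), state$m, state$v,
                          state$t, lr, cfg$weight_decay, 0.9, 0.999, 1e-8)
      params <- params_unflatten(vec, params)
    }

    if (have_monitor) {
      pm <- fgdn_predict_batch(x_all[, , monitor_idx, drop = FALSE],
                               lhat_asd, lhat_hc, params)
      truth <- ifelse(y_all[monitor_idx] == 1, "ASD", "HC")
      mon <- compute_metrics(truth, classify(pm[, 1], pm[, 2]),
                             pm[, 1] - pm[, 2])
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss,
                                     monitor_acc = mon$acc,
                                     monitor_auc = mon$auc)
      if (mon$acc > best_acc) {
        best_acc <- mon$acc
        best_params <- params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (early_stop && since_best >= patience) break
    } else {
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss,
                                     monitor_acc = NA_real_,
                                     monitor_auc = NA_real_)
      best_params <- params
      best_epoch <- epoch
    }
  }
  list(params = best_params, best_acc = best_acc, best_epoch = best_epoch,
       history = do.call(rbind, history[!vapply(history, is.null, TRUE)]))
}

#' @export
print.fgdn_model <- function(x, ...) {
  cat(sprintf(paste0("<fgdn_model> N=%d  features=%s  k=%d  trained on %d ",
                     "subjects (+%d monitor)\n  best monitor accuracy %.1f%% ",
                     "at epoch %d\n"),
              x$n_rois, x$pipeline$kind, x$k_eff, length(x$trained_on),
              length(x$monitor_ids), x$best_monitor_acc, x$best_epoch))
  invisible(x)
}

#' Predict class probabilities for new subjects
#'
#' Embeds each subject with the model's stored pipeline (Ledoit-Wolf
#' covariance and training-fold tangent reference, or Pearson correlation),
#' assembles its ASD and HC graphs from the stored templates, and runs the
#' network forward.
#'
#' @param object A fitted [train_fgdn] model.
#' @param cohort List of [roi_timeseries] to score.
#' @param base_features Optional precomputed base features for these
#'   subjects.
#' @param ... Unused.
#' @return Data frame with `subject_id`, `p_asd`, `p_hc`, `score`
#'   (`p_asd - p_hc`, the AUC ranking score) and `pred`.
#' @export
predict.fgdn_model <- function(object, cohort, base_features = NULL, ...) {
  ids <- cohort_ids(cohort)
  if (is.null(base_features)) {
    base_features <- prepare_base_features(cohort, object$cfg)
  }
  feats <- apply_feature_pipeline(base_features[ids], object$pipeline)
  x <- features_to_array(feats)
  predict_from_array(object, x, ids)
}

predict_from_array <- function(model, x, ids) {
  p <- fgdn_predict_batch(x, model$laplacians$asd$rescaled,
                          model$laplacians$hc$rescaled, model$params)
  data.frame(subject_id = ids, p_asd = p[, 1], p_hc = p[, 2],
             score = p[, 1] - p[, 2], pred = classify(p[, 1], p[, 2]),
             stringsAsFactors = FALSE)
}

# Continue training an existing model on (possibly masked) features without
# early stopping -- used by the region-discriminability analysis.
fine_tune_fgdn <- function(model, x_train, y_train, epochs, lr, seed) {
  fit <- optimize_fgdn(model$params, x_train, y_train,
                       fit_idx = seq_len(dim(x_train)[3]),
                       monitor_idx = integer(0),
                       model$laplacians$asd$rescaled,
                       model$laplacians$hc$rescaled, model$cfg,
                       lr = lr, max_epochs = epochs, patience = epochs,
                       seed = seed, early_stop = FALSE)
  model$params <- fit$params
  model
}
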