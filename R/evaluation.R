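# Evaluation harness: classification metrics, stratified k-fold
# cross-validation, leave-one-site-out evaluation, the learning-curve
# experiment, and the region-masking discriminability analysis. Every
# experiment refits the tangent reference, the class templates and the model
# inside each fold from that fold's training subjects only, and asserts the
# id-set separation explicitly.

#' Classification metrics with ASD as the positive class
#'
#' Accuracy, sensitivity (TP / (TP + FN)), specificity (TN / (TN + FP)) and
#' AUC, all on the 0-100 scale. AUC is the Mann-Whitney rank statistic of
#' the scores (probability that a random ASD subject outranks a random HC
#' subject, ties counted half); it is `NA` when the truth contains a single
#' class.
#'
#' @param truth,pred Character vectors of `"ASD"` / `"HC"`.
#' @param scores Numeric ranking scores (higher = more ASD-like); the
#'   pipeline uses `p_asd - p_hc`.
#' @return List with `acc`, `auc`, `sens`, `spec` (percent).
#' @export
compute_metrics <- function(truth, pred, scores) {
  stopifnot(length(truth) > 0, length(truth) == length(pred),
            length(truth) == length(scores))
  pos <- truth == "ASD"
  acc <- 100 * mean(truth == pred)
  sens <- if (any(pos)) 100 * mean(pred[pos] == "ASD") else NA_real_
  spec <- if (any(!pos)) 100 * mean(pred[!pos] == "HC") else NA_real_
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  auc <- if (n_pos > 0 && n_neg > 0) {
    r <- rank(scores)
    100 * (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else NA_real_
  list(acc = acc, auc = auc, sens = sens, spec = spec)
}

new_eval_report <- function(experiment, seed, folds, config = NULL,
                            summary = NULL) {
  metric_cols <- intersect(c("acc", "auc", "sensitivity", "specificity"),
                           names(folds))
  if (is.null(summary)) {
    summary <- data.frame(
      metric = metric_cols,
      mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE),
                    1, USE.NAMES = FALSE),
      sd = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE),
                  1, USE.NAMES = FALSE),
      row.names = NULL)
  }
  structure(list(experiment = experiment, seed = seed, folds = folds,
                 summary = summary, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> experiment=%s  seed=%d  %d folds\n",
              x$experiment, x$seed, nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.1f (%.1f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

report_mean <- function(report, metric) {
  report$summary$mean[report$summary$metric == metric]
}

# Everything the fitted fold model was derived from must be disjoint from
# the test ids.
assert_no_leakage <- function(model, test_ids) {
  seen <- c(model$trained_on, model$monitor_ids,
            model$templates$asd$source_ids, model$templates$hc$source_ids)
  if (!is.null(model$pipeline$tangent_ref)) {
    seen <- c(seen, model$pipeline$tangent_ref$fitted_on)
  }
  overlap <- intersect(seen, test_ids)
  if (length(overlap) > 0) {
    stop_fgdn("information leak: test subjects appear in the fitted model: ",
              paste(utils::head(overlap, 3), collapse = ", "))
  }
  invisible(TRUE)
}

fold_train_seed <- function(seed, fold) as.integer(seed + 1000L * fold)

run_fold <- function(cohort, base, train_idx, test_idx, cfg, fold_seed) {
  cfg_f <- cfg
  cfg_f$seed <- fold_seed
  model <- train_fgdn(cohort[train_idx], cfg_f, base_features = base)
  test_ids <- cohort_ids(cohort[test_idx])
  assert_no_leakage(model, test_ids)
  test_base <- base[test_ids]
  feats <- apply_feature_pipeline(test_base, model$pipeline)
  x_test <- features_to_array(feats)
  pred <- predict_from_array(model, x_test, test_ids)
  truth <- cohort_labels(cohort[test_idx])
  metrics <- compute_metrics(truth, pred$pred, pred$score)
  list(model = model, pred = pred, truth = truth, metrics = metrics,
       x_test = x_test, test_ids = test_ids)
}

#' Stratified k-fold cross-validation
#'
#' Randomly assigns subjects to `n_folds` stratified folds (seeded by the
#' config); for each fold the tangent reference, class templates and network
#' are fitted on the training folds only and evaluated on the held-out fold.
#'
#' @param cohort Labeled cohort (list of [roi_timeseries]).
#' @param n_folds Number of folds (5 and 10 are the conventional settings).
#' @param cfg An [fgdn_config]; `cfg$seed` drives the fold split and all
#'   per-fold training randomness.
#' @param return_models Also return per-fold fitted models and cached test
#'   arrays (used by [region_discriminability]).
#' @return An `eval_report` (experiment `"cv"`) with per-fold ACC/AUC/
#'   sensitivity/specificity and their mean (SD); with
#'   `return_models = TRUE`, a list `report`, `fold_records`, `fold_of`.
#' @export
cross_validate <- function(cohort, n_folds = 5, cfg = fgdn_config(),
                           return_models = FALSE) {
  labels <- cohort_labels(cohort)
  fold_of <- stratified_folds(labels, n_folds, cfg$seed)
  base <- prepare_base_features(cohort, cfg)

  rows <- vector("list", n_folds)
  records <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    if (length(unique(labels[test_idx])) < 2) {
      stop_fgdn("fold ", f, " contains a single class; increase cohort size")
    }
    rec <- run_fold(cohort, base, train_idx, test_idx, cfg,
                    fold_train_seed(cfg$seed, f))
    m <- rec$metrics
    rows[[f]] <- data.frame(fold = f, acc = m$acc, auc = m$auc,
                            sensitivity = m$sens, specificity = m$spec,
                            n_test = length(test_idx))
    if (return_models) {
      rec$train_idx <- train_idx
      rec$test_idx <- test_idx
      records[[f]] <- rec
    }
  }
  report <- new_eval_report("cv", cfg$seed, do.call(rbind, rows),
                            config = list(n_folds = n_folds,
                                          feature_kind = cfg$feature_kind,
                                          graph_k = cfg$graph_k))
  if (!return_models) return(report)
  list(report = report, fold_records = records, fold_of = fold_of,
       base = base)
}

#' Leave-one-site-out evaluation
#'
#' One fold per acquisition site: the site under study is the test set and
#' all remaining sites form the training set, probing robustness to
#' scanner/protocol differences. A test site holding a single class gets
#' `NA` AUC but its accuracy is still reported.
#'
#' @param cohort Labeled multi-site cohort (at least 2 sites).
#' @param cfg An [fgdn_config].
#' @return An `eval_report` (experiment `"loso"`) with one row per site.
#' @export
leave_one_site_out <- function(cohort, cfg = fgdn_config()) {
  sites <- cohort_sites(cohort)
  site_levels <- sort(unique(sites))
  if (length(site_levels) < 2) stop_fgdn("need at least 2 sites")
  base <- prepare_base_features(cohort, cfg)

  rows <- vector("list", length(site_levels))
  for (i in seq_along(site_levels)) {
    s <- site_levels[i]
    test_idx <- which(sites == s)
    train_idx <- which(sites != s)
    rec <- run_fold(cohort, base, train_idx, test_idx, cfg,
                    fold_train_seed(cfg$seed, i))
    stopifnot(!s %in% cohort_sites(cohort[train_idx]))
    m <- rec$metrics
    rows[[i]] <- data.frame(fold = i, site = s, acc = m$acc, auc = m$auc,
                            sensitivity = m$sens, specificity = m$spec,
                            n_test = length(test_idx))
  }
  new_eval_report("loso", cfg$seed, do.call(rbind, rows),
                  config = list(sites = site_levels,
                                feature_kind = cfg$feature_kind))
}

#' Learning-curve experiment
#'
#' For each training fraction, each fold of a stratified `n_folds` split is
#' evaluated after training on a stratified subsample of that fold's
#' training set, while the held-out fold stays unchanged. At fraction 1.0
#' the experiment reproduces [cross_validate] exactly (same seed, same
#' folds, same training order).
#'
#' @param cohort Labeled cohort.
#' @param fractions Ascending training-set fractions in (0, 1].
#' @param cfg An [fgdn_config].
#' @param n_folds Number of folds (default 10).
#' @return An `eval_report` (experiment `"learning_curve"`) whose `folds`
#'   table carries one row per (fraction, fold).
#' @export
learning_curve <- function(cohort, fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           cfg = fgdn_config(), n_folds = 10) {
  if (is.unsorted(fractions)) stop_fgdn("fractions must be sorted ascending")
  if (any(fractions <= 0 | fractions > 1)) {
    stop_fgdn("fractions must lie in (0, 1]")
  }
  labels <- cohort_labels(cohort)
  fold_of <- stratified_folds(labels, n_folds, cfg$seed)
  base <- prepare_base_features(cohort, cfg)

  rows <- list()
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold_of == f)
      pool <- which(fold_of != f)
      if (frac >= 1) {
        train_idx <- pool
      } else {
        set.seed(fold_train_seed(cfg$seed, f) + 500000L + fi)
        sel <- integer(0)
        for (cl in sort(unique(labels[pool]))) {
          members <- pool[labels[pool] == cl]
          n_keep <- round(frac * length(members))
          if (n_keep < 1) {
            stop_fgdn("fraction ", frac, " leaves no training subjects of ",
                      "class ", cl)
          }
          sel <- c(sel, sample(members, n_keep))
        }
        train_idx <- sort(sel)
      }
      rec <- run_fold(cohort, base, train_idx, test_idx, cfg,
                      fold_train_seed(cfg$seed, f))
      m <- rec$metrics
      rows[[length(rows) + 1]] <-
        data.frame(fraction = frac, fold = f, acc = m$acc, auc = m$auc,
                   sensitivity = m$sens, specificity = m$spec,
                   n_train = length(train_idx), n_test = length(test_idx))
    }
  }
  new_eval_report("learning_curve", cfg$seed, do.call(rbind, rows),
                  config = list(fractions = fractions, n_folds = n_folds))
}

# Zero the node-feature rows of every region except `region` (and optionally
# the columns too) across a feature array.
mask_feature_array <- function(x, region, mask_columns = FALSE) {
  keep <- region
  x[-keep, , ] <- 0
  if (mask_columns) x[keep, -keep, ] <- 0
  x
}

#' Region-masking discriminability analysis
#'
#' Measures how much class signal each ROI carries on its own. After a full
#' `n_folds` cross-validation, each region `r` is studied in turn: the
#' node-feature rows of all other regions are clamped to zero (templates
#' untouched), every fold's trained model is fine-tuned on its masked
#' training set (a short Adam run at one tenth of the learning rate, no
#' early stopping), and the masked held-out fold accuracy/AUC is recorded.
#' The discriminative weight of a region is its mean masked validation
#' accuracy; `pct_exceeded` is the share of other regions it beats with a
#' paired two-sided t-test over fold accuracies at p < 0.05.
#'
#' @param cohort Labeled cohort.
#' @param cfg An [fgdn_config].
#' @param n_folds Number of folds (default 10).
#' @param fine_tune_epochs Epochs of masked fine-tuning per region and fold.
#' @param lr_scale Fine-tuning learning-rate multiplier.
#' @param mask_columns Also zero the masked regions' columns within retained
#'   rows.
#' @return Data frame of class `region_scores`, sorted by decreasing mean
#'   accuracy: `region_id` (1-based), `mean_acc`, `mean_auc`, `sd_acc`,
#'   `sd_auc`, `pct_exceeded`.
#' @export
region_discriminability <- function(cohort, cfg = fgdn_config(), n_folds = 10,
                                    fine_tune_epochs = 30, lr_scale = 0.1,
                                    mask_columns = FALSE) {
  cv <- cross_validate(cohort, n_folds, cfg, return_models = TRUE)
  n <- cohort[[1]]$n_rois
  labels <- cohort_labels(cohort)
  ids <- cohort_ids(cohort)

  acc_mat <- matrix(NA_real_, n, n_folds)  # regions x folds
  auc_mat <- matrix(NA_real_, n, n_folds)
  for (f in seq_len(n_folds)) {
    rec <- cv$fold_records[[f]]
    model <- rec$model
    train_ids <- model$trained_on
    train_pos <- match(train_ids, ids)
    feats <- apply_feature_pipeline(cv$base[train_ids], model$pipeline)
    x_train_full <- features_to_array(feats)
    y_train <- as.numeric(labels[train_pos] == "ASD")
    for (r in seq_len(n)) {
      x_train <- mask_feature_array(x_train_full, r, mask_columns)
      tuned <- fine_tune_fgdn(model, x_train, y_train,
                              epochs = fine_tune_epochs,
                              lr = cfg$learning_rate * lr_scale,
                              seed = fold_train_seed(cfg$seed, f) + 7000L + r)
      x_test <- mask_feature_array(rec$x_test, r, mask_columns)
      pred <- predict_from_array(tuned, x_test, rec$test_ids)
      m <- compute_metrics(rec$truth, pred$pred, pred$score)
      acc_mat[r, f] <- m$acc
      auc_mat[r, f] <- m$auc
    }
  }

  pct <- numeric(n)
  for (r in seq_len(n)) {
    beats <- 0L
    for (o in seq_len(n)) {
      if (o == r) next
      diffs <- acc_mat[r, ] - acc_mat[o, ]
      if (mean(diffs) <= 0 || stats::sd(diffs) == 0) {
        if (all(diffs > 0)) beats <- beats + 1L  # uniformly better, zero var
        next
      }
      p <- tryCatch(stats::t.test(acc_mat[r, ], acc_mat[o, ],
                                  paired = TRUE)$p.value,
                    error = function(e) NA_real_)
      if (!is.na(p) && p < 0.05) beats <- beats + 1L
    }
    pct[r] <- 100 * beats / (n - 1)
  }

  out <- data.frame(region_id = seq_len(n),
                    mean_acc = rowMeans(acc_mat),
                    mean_auc = rowMeans(auc_mat, na.rm = TRUE),
                    sd_acc = apply(acc_mat, 1, stats::sd),
                    sd_auc = apply(auc_mat, 1, stats::sd, na.rm = TRUE),
                    pct_exceeded = pct)
  out <- out[order(-out$mean_acc, out$region_id), ]
  rownames(out) <- NULL
  class(out) <- c("region_scores", "data.frame")
  out
}
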