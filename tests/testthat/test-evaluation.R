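test_that("metrics match hand counts and brute-force pair enumeration", {
  m <- compute_metrics(c("ASD", "ASD", "HC", "HC"),
                       c("ASD", "HC", "HC", "HC"),
                       c(0.9, -0.1, -0.2, -0.8))
  expect_equal(m$acc, 75)
  expect_equal(m$sens, 50)
  expect_equal(m$spec, 100)
  expect_equal(m$auc, 100)

  perfect <- compute_metrics(c("ASD", "HC"), c("ASD", "HC"), c(1, -1))
  expect_equal(unlist(perfect), c(acc = 100, auc = 100, sens = 100,
                                  spec = 100))

  # AUC = fraction of (ASD, HC) pairs ranked correctly, ties counted half
  set.seed(55)
  for (trial in 1:10) {
    n <- sample(6:20, 1)
    truth <- sample(c("ASD", "HC"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("ASD", "HC")
    scores <- round(rnorm(n), 1)  # coarse rounding forces ties
    pred <- classify(scores, 0)
    pairs <- expand.grid(a = which(truth == "ASD"), h = which(truth == "HC"))
    brute <- 100 * mean(ifelse(scores[pairs$a] > scores[pairs$h], 1,
                               ifelse(scores[pairs$a] == scores[pairs$h],
                                      0.5, 0)))
    expect_equal(compute_metrics(truth, pred, scores)$auc, brute,
                 tolerance = 1e-12)
  }

  expect_true(is.na(compute_metrics(c("ASD", "ASD"), c("ASD", "ASD"),
                                    c(1, 2))$auc))
})

test_that("training is deterministic and recovers a separable cohort", {
  g <- tiny_cohort(n_per_class = 15)
  cfg <- fast_cfg(seed = 3, channels = 16, hidden = 32)
  m1 <- train_fgdn(g$cohort, cfg)
  m2 <- train_fgdn(g$cohort, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_gte(m1$best_monitor_acc, 75)  # 2 monitor subjects per class
  expect_true(all(c("epoch", "train_loss", "monitor_acc", "monitor_auc")
                  %in% names(m1$history)))
  # single-class training set is fatal
  asd_only <- Filter(function(s) s$diagnosis == "ASD", g$cohort)
  expect_error(train_fgdn(asd_only, cfg), "both ASD and HC")
})

test_that("cross-validation partitions the cohort and summarizes folds", {
  g <- tiny_cohort(n_per_class = 12)
  cfg <- fast_cfg(seed = 11, max_epochs = 25, channels = 12, hidden = 16)
  cv <- cross_validate(g$cohort, 3, cfg, return_models = TRUE)
  rep <- cv$report
  expect_equal(nrow(rep$folds), 3)
  expect_equal(sum(rep$folds$n_test), 24)  # each subject tested exactly once
  expect_equal(sort(unique(cv$fold_of)), 1:3)
  for (m in c("acc", "auc", "sensitivity", "specificity")) {
    expect_equal(report_mean(rep, m), mean(rep$folds[[m]]), tolerance = 1e-9)
    expect_true(all(rep$folds[[m]] >= 0 & rep$folds[[m]] <= 100))
  }
  # identical seed -> bit-identical report
  rep2 <- cross_validate(g$cohort, 3, cfg)
  expect_identical(rep, rep2)
})

test_that("no test subject ever reaches the fitted pipeline", {
  g <- tiny_cohort(n_per_class = 12)
  cfg <- fast_cfg(seed = 13, max_epochs = 10, channels = 8, hidden = 12)
  cv <- cross_validate(g$cohort, 3, cfg, return_models = TRUE)
  ids <- vapply(g$cohort, `[[`, "", "subject_id")
  for (f in 1:3) {
    rec <- cv$fold_records[[f]]
    model <- rec$model
    test_ids <- ids[cv$fold_of == f]
    seen <- c(model$trained_on, model$monitor_ids,
              model$pipeline$tangent_ref$fitted_on,
              model$templates$asd$source_ids, model$templates$hc$source_ids)
    expect_length(intersect(seen, test_ids), 0)
    # tangent reference and templates come from the non-monitor portion only
    expect_length(intersect(model$pipeline$tangent_ref$fitted_on,
                            model$monitor_ids), 0)
    expect_setequal(union(union(seen, test_ids), model$monitor_ids), ids)
  }
})

test_that("leave-one-site-out holds each site out exactly once", {
  g <- tiny_cohort(n_per_class = 12, n_sites = 3)
  cfg <- fast_cfg(seed = 17, max_epochs = 20, channels = 12, hidden = 16)
  rep <- leave_one_site_out(g$cohort, cfg)
  expect_equal(nrow(rep$folds), 3)
  sites <- vapply(g$cohort, `[[`, "", "site")
  expect_setequal(rep$folds$site, unique(sites))
  expect_equal(sum(rep$folds$n_test), length(g$cohort))
  for (i in seq_len(nrow(rep$folds))) {
    expect_equal(rep$folds$n_test[i], sum(sites == rep$folds$site[i]))
  }
  expect_error(leave_one_site_out(
    lapply(g$cohort, function(s) { s$site <- "only"; s }), cfg),
    "at least 2 sites")
})

test_that("learning curve at fraction 1.0 reproduces cross-validation", {
  g <- tiny_cohort(n_per_class = 10)
  cfg <- fast_cfg(seed = 19, max_epochs = 15, channels = 8, hidden = 12)
  cv <- cross_validate(g$cohort, 3, cfg)
  lc <- learning_curve(g$cohort, fractions = c(0.5, 1.0), cfg, n_folds = 3)
  full <- lc$folds[lc$folds$fraction == 1, ]
  expect_equal(full$acc, cv$folds$acc)
  expect_equal(full$auc, cv$folds$auc)
  half <- lc$folds[lc$folds$fraction == 0.5, ]
  expect_true(all(half$n_train < full$n_train))
  expect_error(learning_curve(g$cohort, c(1, 0.2), cfg, 3), "ascending")
  expect_error(learning_curve(g$cohort, c(0.01), cfg, 3), "leaves no")
})

test_that("region masking zeroes exactly the excluded rows", {
  x <- array(1, c(4, 4, 2))
  masked <- fgdn:::mask_feature_array(x, 2)
  expect_equal(masked[2, , 1], rep(1, 4))
  expect_equal(masked[c(1, 3, 4), , ], array(0, c(3, 4, 2)))
  both <- fgdn:::mask_feature_array(x, 2, mask_columns = TRUE)
  expect_equal(both[2, 2, 1], 1)
  expect_equal(sum(both), 2)  # only the (2, 2) cell per subject survives
})

test_that("report writing refuses unwritable paths", {
  g <- tiny_cohort(n_per_class = 6, n_rois = 6)
  rep <- cross_validate(g$cohort, 2, fast_cfg(seed = 23, max_epochs = 2,
                                              channels = 4, hidden = 6))
  expect_error(suppressWarnings(write_report(rep, "/nonexistent-dir/report.json")))
})
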