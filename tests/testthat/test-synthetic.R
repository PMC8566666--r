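test_that("generated cohorts are deterministic functions of the spec", {
  spec <- synthetic_spec(n_subjects_per_class = 4, n_rois = 6,
                         n_timepoints = 20, signal_regions = c(2, 5),
                         seed = 77)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(g1, g2)
  g3 <- generate_cohort(synthetic_spec(n_subjects_per_class = 4, n_rois = 6,
                                       n_timepoints = 20,
                                       signal_regions = c(2, 5), seed = 78))
  expect_false(identical(g1$cohort[[1]]$signal, g3$cohort[[1]]$signal))
})

test_that("every subject covariance is SPD and empirical estimates converge", {
  spec <- synthetic_spec(n_subjects_per_class = 3, n_rois = 8,
                         n_timepoints = 200, seed = 5)
  g <- generate_cohort(spec)
  for (sigma in g$ground_truth$subject_covs) {
    expect_gt(min(eigen(sigma, symmetric = TRUE)$values), 0)
  }
  # Frobenius error of the empirical covariance shrinks ~ 1/sqrt(T)
  err_at <- function(t_len, seed) {
    gg <- generate_cohort(synthetic_spec(n_subjects_per_class = 1, n_rois = 8,
                                         n_timepoints = t_len, n_sites = 1,
                                         subject_noise = 0, seed = seed))
    x <- gg$cohort[[1]]$signal
    emp <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
    sqrt(sum((emp - gg$ground_truth$subject_covs[[1]])^2))
  }
  e_small <- median(sapply(1:5, function(s) err_at(100, s)))
  e_big <- median(sapply(1:5, function(s) err_at(6400, s)))
  expect_lt(e_big, e_small / 3)  # expect ~ 1/8, allow sampling slack
})

test_that("class difference is confined to the planted regions", {
  spec <- synthetic_spec(n_subjects_per_class = 2, n_rois = 10,
                         signal_regions = c(3, 7), effect_size = 0.4,
                         seed = 9)
  g <- generate_cohort(spec)
  gap <- abs(g$ground_truth$cov_asd - g$ground_truth$cov_hc)
  expect_gt(gap[3, 7], 0.3)  # planted entry (up to SPD projection)
  off <- gap
  off[c(3, 7), ] <- 0
  off[, c(3, 7)] <- 0
  expect_lt(max(off), 0.05)  # leakage only through SPD projection

  # effect_size = 0: class means differ only by sampling noise
  null_spec <- synthetic_spec(n_subjects_per_class = 30, n_rois = 6,
                              n_timepoints = 300, signal_regions = c(2, 5),
                              effect_size = 0, subject_noise = 0, seed = 10)
  gn <- generate_cohort(null_spec)
  expect_equal(gn$ground_truth$cov_asd, gn$ground_truth$cov_hc,
               tolerance = 1e-12)
  emp_mean <- function(cls) {
    mats <- lapply(Filter(function(s) s$diagnosis == cls, gn$cohort),
                   function(s) {
                     x <- sweep(s$signal, 2, colMeans(s$signal))
                     crossprod(x) / nrow(x)
                   })
    Reduce(`+`, mats) / length(mats)
  }
  expect_lt(sqrt(sum((emp_mean("ASD") - emp_mean("HC"))^2)), 0.35)
})

test_that("empirical mean covariance difference concentrates on planted pairs", {
  g <- generate_cohort(synthetic_spec(n_subjects_per_class = 100, n_rois = 10,
                                      n_timepoints = 200,
                                      signal_regions = c(3, 7),
                                      effect_size = 0.4, n_sites = 1,
                                      subject_noise = 0.05, seed = 12))
  labs <- vapply(g$cohort, `[[`, "", "diagnosis")
  emp <- lapply(g$cohort, function(s) {
    x <- sweep(s$signal, 2, colMeans(s$signal))
    crossprod(x) / nrow(x)
  })
  mean_of <- function(cls) Reduce(`+`, emp[labs == cls]) / sum(labs == cls)
  gap <- abs(mean_of("ASD") - mean_of("HC"))
  off_gap <- gap[upper.tri(gap)]
  planted <- gap[3, 7]
  expect_gte(planted, sort(off_gap, decreasing = TRUE)[5])  # top decile of 45
})

test_that("true-covariance Bayes-style classification is near perfect", {
  # nearest-class-covariance rule on the true subject covariances: with a
  # strong planted effect and small subject noise this must be almost
  # error-free, guaranteeing the end-to-end recovery task is achievable
  g <- generate_cohort(synthetic_spec(n_subjects_per_class = 50, n_rois = 8,
                                      signal_regions = c(2, 6),
                                      effect_size = 0.6, n_sites = 1,
                                      subject_noise = 0.05, seed = 14))
  gt <- g$ground_truth
  labs <- vapply(g$cohort, `[[`, "", "diagnosis")
  pred <- vapply(seq_along(g$cohort), function(i) {
    sigma <- gt$subject_covs[[g$cohort[[i]]$subject_id]]
    d_asd <- sum((sigma - gt$cov_asd)^2)
    d_hc <- sum((sigma - gt$cov_hc)^2)
    if (d_asd < d_hc) "ASD" else "HC"
  }, character(1))
  expect_gte(mean(pred == labs), 0.98)
})

test_that("the worked example is bit-stable with exact class means", {
  w1 <- generate_worked_example()
  w2 <- generate_worked_example()
  expect_identical(w1, w2)
  labs <- w1$labels
  mats <- lapply(w1$fc, `[[`, "values")
  expect_equal(Reduce(`+`, mats[labs == "ASD"]) / 4, w1$mean_asd,
               tolerance = 1e-15)
  expect_equal(Reduce(`+`, mats[labs == "HC"]) / 4, w1$mean_hc,
               tolerance = 1e-15)
})
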