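test_that("normalized Laplacian matches closed forms", {
  lp <- normalized_laplacian(matrix(c(0, 1, 1, 0), 2))
  expect_equal(lp$laplacian, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sort(eigen(lp$laplacian, symmetric = TRUE)$values), c(0, 2))
  expect_equal(lp$lambda_max, 2)
  expect_equal(lp$rescaled, lp$laplacian - diag(2))

  # no edges: isolated-node convention L = I, lambda_max = 1
  lp0 <- normalized_laplacian(matrix(0, 3, 3))
  expect_equal(lp0$laplacian, diag(3))
  expect_equal(lp0$lambda_max, 1)

  expect_error(normalized_laplacian(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(normalized_laplacian(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("Laplacian spectra sit in their theoretical bands", {
  for (trial in 1:10) {
    w <- random_weights(10, seed = 300 + trial)
    lp <- normalized_laplacian(w)
    ev <- eigen(lp$laplacian, symmetric = TRUE)$values
    expect_true(all(ev >= -1e-9 & ev <= 2 + 1e-9))
    ev_r <- eigen(lp$rescaled, symmetric = TRUE)$values
    expect_true(all(ev_r >= -1 - 1e-9 & ev_r <= 1 + 1e-9))
    # D^{1/2} 1 is the 0-eigenvector
    v0 <- sqrt(rowSums(w))
    expect_lt(max(abs(lp$laplacian %*% v0)), 1e-9)
  }
})

test_that("Chebyshev convolution reduces correctly at K = 1 and scalar order 2", {
  set.seed(31)
  w <- random_weights(6, seed = 31)
  lp <- normalized_laplacian(w)
  x <- matrix(rnorm(6 * 3), 6)
  th0 <- matrix(rnorm(3 * 2), 3)
  # K = 1: graph structure ignored, output = X theta_0
  expect_equal(cheb_conv(x, lp, list(th0)), x %*% th0)
  # scalar recursion: T_2(0.5) = -0.5
  lp_scalar <- list(rescaled = matrix(0.5, 1, 1))
  out <- cheb_conv(matrix(1), lp_scalar$rescaled,
                   list(matrix(0), matrix(0), matrix(1)))
  expect_equal(out[1, 1], 2 * 0.5 * 0.5 - 1)
})

test_that("Chebyshev convolution equals dense spectral filtering", {
  set.seed(37)
  for (trial in 1:10) {
    n <- sample(5:12, 1)
    K <- sample(1:5, 1)
    w <- random_weights(n, seed = 600 + trial)
    lp <- normalized_laplacian(w)
    d_in <- sample(2:4, 1)
    d_out <- sample(2:4, 1)
    x <- matrix(rnorm(n * d_in), n)
    theta <- lapply(1:K, function(k) matrix(rnorm(d_in * d_out), d_in))
    expect_lt(max(abs(cheb_conv(x, lp, theta) -
                      spectral_filter_oracle(x, lp$rescaled, theta))), 1e-8)
  }
})

test_that("a K-order filter only mixes information within K-1 hops", {
  # path graph 1-2-3-4-5-6: perturbing node 6 must not reach node 1
  # through a K = 3 filter (2 hops)
  n <- 6
  w <- matrix(0, n, n)
  for (i in 1:(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  lp <- normalized_laplacian(w)
  set.seed(41)
  theta <- lapply(1:3, function(k) matrix(rnorm(2 * 2), 2))
  x <- matrix(rnorm(n * 2), n)
  x2 <- x
  x2[6, ] <- x2[6, ] + 5
  delta <- cheb_conv(x2, lp, theta) - cheb_conv(x, lp, theta)
  expect_lt(max(abs(delta[1:3, ])), 1e-12)  # nodes > 2 hops away untouched
  expect_gt(max(abs(delta[4:6, ])), 1e-6)
})

test_that("forward pass outputs are probabilities and deterministic", {
  wx <- generate_worked_example()
  ta <- build_template(wx$mean_asd, 2, "ASD")
  th <- build_template(wx$mean_hc, 2, "HC")
  gs <- assemble_graphs(wx$fc[[1]], ta, th)
  params <- fgdn_params(4, K = 3, channels = 6, hidden = 8, seed = 5)
  p <- fgdn_forward(gs$asd, gs$hc, params)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, fgdn_forward(gs$asd, gs$hc, params))
  # identical templates: the two passes coincide, so (p_asd, p_hc) are the
  # two units of a single forward pass
  gs_same <- assemble_graphs(wx$fc[[1]], ta, ta)
  p_same <- fgdn_forward(gs_same$asd, gs_same$hc, params)
  one_pass <- fgdn_forward(gs_same$asd, gs_same$asd, params)
  expect_equal(unname(p_same), unname(one_pass))
  # dropout with a fixed seed is reproducible, and off when not training
  set.seed(1); d1 <- fgdn_forward(gs$asd, gs$hc, params, dropout = 0.5,
                                  training = TRUE)
  set.seed(1); d2 <- fgdn_forward(gs$asd, gs$hc, params, dropout = 0.5,
                                  training = TRUE)
  expect_identical(d1, d2)
  expect_identical(fgdn_forward(gs$asd, gs$hc, params, dropout = 0.5), p)
})

test_that("the decision rule calls ASD only on strict majority of its unit", {
  expect_identical(classify(0.7, 0.3), "ASD")
  expect_identical(classify(0.3, 0.7), "HC")
  expect_identical(classify(0.5, 0.5), "HC")  # ties go to HC
  expect_identical(classify(c(0.9, 0.1), c(0.2, 0.2)), c("ASD", "HC"))
})

test_that("loss matches analytic values and is additive", {
  # uniform prediction: -[log 0.5 + log 0.5] = 2 ln 2 per sample
  expect_equal(fgdn_loss(c(0.5, 0.5), "ASD"), 2 * log(2), tolerance = 1e-12)
  expect_equal(fgdn_loss(matrix(0.5, 3, 2), rep("HC", 3)), 6 * log(2),
               tolerance = 1e-12)
  # perfect confident prediction -> loss ~ 0, and never negative
  eps <- 1e-7
  expect_lt(fgdn_loss(c(1 - eps, eps), "ASD"), 1e-5)
  expect_gte(fgdn_loss(c(1 - eps, eps), "ASD"), 0)
  # batch loss = sum of single-sample losses
  set.seed(43)
  p <- matrix(runif(10), 5, 2)
  labs <- sample(c("ASD", "HC"), 5, replace = TRUE)
  expect_equal(fgdn_loss(p, labs),
               sum(sapply(1:5, function(i) fgdn_loss(p[i, ], labs[i]))),
               tolerance = 1e-12)
  expect_error(fgdn_loss(matrix(0, 0, 2), character(0)), "empty batch")
})

test_that("analytic gradients match central finite differences", {
  g <- tiny_cohort(n_per_class = 3, n_rois = 6, n_timepoints = 40)
  covs <- lapply(g$cohort, ledoit_wolf_covariance)
  ref <- fit_tangent_reference(covs)
  feats <- lapply(covs, tangent_embed, ref = ref)
  labs <- vapply(g$cohort, `[[`, "", "diagnosis")
  ta <- build_template(class_mean_connectivity(feats, "ASD", labs), 2)
  th <- build_template(class_mean_connectivity(feats, "HC", labs), 2)
  la <- normalized_laplacian(ta$weights)$rescaled
  lh <- normalized_laplacian(th$weights)$rescaled
  x <- fgdn:::features_to_array(feats)
  y <- as.numeric(labs == "ASD")
  params <- fgdn_params(6, K = 3, channels = 4, hidden = 5, seed = 47)

  res <- fgdn:::fgdn_batch_grad(x, la, lh, y, params, dropout = 0,
                                training = FALSE)
  v <- fgdn:::params_flatten(params)
  gv <- fgdn:::params_flatten(res$grads)
  loss_at <- function(vv) {
    fgdn:::fgdn_batch_grad(x, la, lh, y,
                           fgdn:::params_unflatten(vv, params),
                           dropout = 0, training = FALSE)$loss
  }
  h <- 1e-5
  set.seed(49)
  for (i in sample(length(v), 80)) {
    e <- v; e[i] <- v[i] + h; up <- loss_at(e)
    e[i] <- v[i] - h; down <- loss_at(e)
    num <- (up - down) / (2 * h)
    expect_lt(abs(num - gv[i]) / max(abs(num) + abs(gv[i]), 1e-6), 1e-5)
  }
})
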