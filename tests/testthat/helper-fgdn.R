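# Shared fixtures and independent oracles used across the suite.

# Small labeled cohort for pipeline tests (well-separated classes).
tiny_cohort <- function(n_per_class = 12, n_rois = 8, n_timepoints = 60,
                        seed = 404, effect_size = 0.6, n_sites = 2) {
  generate_cohort(synthetic_spec(
    n_subjects_per_class = n_per_class, n_rois = n_rois,
    n_timepoints = n_timepoints,
    signal_regions = c(2, min(n_rois, 5)),
    effect_size = effect_size, n_sites = n_sites, site_shift = 0.1,
    subject_noise = 0.05, seed = seed))
}

# Fast training configuration for functional tests (protocol unchanged,
# shorter horizon).
fast_cfg <- function(seed = 1, max_epochs = 60, patience = 10, ...) {
  fgdn_config(seed = seed, max_epochs = max_epochs, patience = patience, ...)
}

# Random SPD matrix with eigenvalues bounded away from zero.
random_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + diag(0.5, n)
}

# Random connected-ish KNN-style weight matrix for Laplacian tests.
random_weights <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  build_template(pts %*% t(pts), k = max(2, n %/% 4))$weights
}

# Independent brute-force template construction: all pairwise distances,
# full sort per node, kernel, union symmetrization. Mirrors the documented
# construction but shares no code with build_template.
brute_force_template <- function(mean_fc, k) {
  n <- nrow(mean_fc)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d[i, j] <- sqrt(sum((mean_fc[i, ] - mean_fc[j, ])^2))
  }
  kept <- matrix(FALSE, n, n)
  dists <- c()
  for (i in 1:n) {
    ord <- setdiff(order(d[i, ]), i)[1:k]  # order() is index-ascending on ties
    kept[i, ord] <- TRUE
    dists <- c(dists, d[i, ord])
  }
  theta <- mean(dists)
  w <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (kept[i, j] || kept[j, i]) {
      w[i, j] <- if (theta > 0) exp(-d[i, j]^2 / (2 * theta^2)) else 1
    }
  }
  diag(w) <- 0
  w
}

# Dense spectral-domain filter: eigendecompose the rescaled Laplacian and
# apply the Chebyshev kernel on the eigenvalues (scalar recursion), i.e.
# U diag(sum_k theta_k T_k(lambda)) U' X channel-by-channel.
spectral_filter_oracle <- function(x, rescaled, theta) {
  e <- eigen(rescaled, symmetric = TRUE)
  K <- length(theta)
  # scalar Chebyshev polynomials at the eigenvalues
  tk <- matrix(0, length(e$values), K)
  tk[, 1] <- 1
  if (K >= 2) tk[, 2] <- e$values
  if (K >= 3) for (k in 3:K) tk[, k] <- 2 * e$values * tk[, k - 1] - tk[, k - 2]
  xhat <- t(e$vectors) %*% x  # graph Fourier transform
  out <- 0
  for (k in seq_len(K)) {
    out <- out + e$vectors %*% (tk[, k] * xhat) %*% theta[[k]]
  }
  out
}

# Relabel a cohort with a permutation of its own labels.
permute_labels <- function(cohort, seed) {
  set.seed(seed)
  labs <- sample(vapply(cohort, function(s) s$diagnosis, character(1)))
  for (i in seq_along(cohort)) cohort[[i]]$diagnosis <- labs[i]
  cohort
}
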