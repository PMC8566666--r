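# Per-subject functional-connectivity estimation: Pearson correlation,
# Ledoit-Wolf shrinkage covariance, and tangent-space embedding of SPD
# covariances at a reference mean fitted on training subjects only.

#' Construct a connectivity matrix record
#'
#' @param values Symmetric numeric N x N matrix.
#' @param subject_id Subject the matrix belongs to.
#' @param kind One of `"correlation"`, `"covariance"`, `"tangent"`.
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, subject_id,
                                kind = c("correlation", "covariance", "tangent")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  assert_finite(values, paste0("connectivity of ", subject_id))
  assert_symmetric(values, 1e-10, paste0("connectivity of ", subject_id))
  if (kind == "correlation") {
    if (max(abs(diag(values) - 1)) > 1e-8 || max(abs(values)) > 1 + 1e-8) {
      stop_fgdn("correlation matrix must have unit diagonal and entries in [-1, 1]")
    }
  }
  structure(list(subject_id = as.character(subject_id), kind = kind,
                 values = unname(values)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s  kind=%s  %d x %d\n", x$subject_id,
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Ledoit-Wolf optimal shrinkage intensity toward the scaled identity
# tr(S)/N * I.  X must already be column-centered; S = X'X / T.
ledoit_wolf_shrinkage <- function(x_centered, s) {
  n_t <- nrow(x_centered)
  n <- ncol(s)
  mu <- sum(diag(s)) / n
  d2 <- sum((s - diag(mu, n))^2) / n
  if (d2 < .Machine$double.eps) return(0)
  sq_norms <- rowSums(x_centered^2)
  # sum_t || x_t x_t' - S ||_F^2, expanded to avoid forming T outer products
  quad <- sum((x_centered %*% s) * x_centered)
  total <- sum(sq_norms^2) - 2 * quad + n_t * sum(s^2)
  b2 <- min(total / (n_t^2 * n), d2)
  b2 / d2
}

#' Ledoit-Wolf shrinkage covariance of a subject's time series
#'
#' Estimates the N x N covariance as the convex combination
#' `(1 - alpha) S + alpha (tr(S)/N) I` of the sample covariance `S`
#' (maximum-likelihood, centered columns, divisor T) and the scaled identity,
#' with the shrinkage intensity `alpha` set by the Ledoit-Wolf formula.
#' Shrinkage keeps the estimate well conditioned even when T is comparable to
#' N, and guarantees a positive-definite matrix whenever `alpha > 0`, which
#' the tangent embedding requires.
#'
#' @param ts A [roi_timeseries] (columns are de-meaned internally).
#' @param standardize If `TRUE`, columns are also scaled to unit variance
#'   before estimation (off by default).
#' @return A `connectivity_matrix` of kind `"covariance"`, with the shrinkage
#'   intensity in attribute `"shrinkage"`.
#' @export
ledoit_wolf_covariance <- function(ts, standardize = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$signal
  x <- sweep(x, 2, colMeans(x))
  if (standardize) {
    sds <- sqrt(colMeans(x^2))
    if (any(sds == 0)) stop_fgdn("cannot standardize a constant ROI column")
    x <- sweep(x, 2, sds, "/")
  }
  n_t <- nrow(x)
  n <- ncol(x)
  s <- crossprod(x) / n_t
  alpha <- ledoit_wolf_shrinkage(x, s)
  out <- (1 - alpha) * s + alpha * diag(sum(diag(s)) / n, n)
  out <- (out + t(out)) / 2
  cm <- connectivity_matrix(out, ts$subject_id, "covariance")
  attr(cm, "shrinkage") <- alpha
  cm
}

#' Pearson correlation connectivity of a subject's time series
#'
#' @param ts A [roi_timeseries]; every ROI column must have nonzero variance.
#' @return A `connectivity_matrix` of kind `"correlation"`.
#' @export
pearson_correlation <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  vars <- apply(ts$signal, 2, stats::var)
  if (any(vars == 0)) {
    stop_fgdn("ROI ", which(vars == 0)[1], " has zero variance; ",
              "correlation is undefined")
  }
  r <- stats::cor(ts$signal)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  connectivity_matrix(r, ts$subject_id, "correlation")
}

#' Fit the tangent-space reference from training covariances
#'
#' Computes the reference point of the tangent embedding as the
#' affine-invariant geometric mean of the training covariance matrices by
#' fixed-point iteration: starting from the Euclidean mean `G`, iterate
#' `G <- G^{1/2} exp(mean_i log(G^{-1/2} C_i G^{-1/2})) G^{1/2}` until the
#' Frobenius norm of the mean log-deviation falls below `tol`. The whitener
#' `G^{-1/2}` maps every covariance into the common tangent space. Fit on
#' training subjects only and reuse the fitted reference for held-out
#' subjects, otherwise test information leaks into the features.
#'
#' @param covs List of `connectivity_matrix` objects of kind `"covariance"`,
#'   all SPD and of equal dimension.
#' @param mean_type `"geometric"` (affine-invariant, default) or
#'   `"euclidean"` (arithmetic mean, no iteration).
#' @param tol Frobenius convergence tolerance of the fixed point.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Object of class `tangent_reference` with fields `mean_cov`,
#'   `whitener` (`G^{-1/2}`) and `fitted_on` (subject ids).
#' @export
fit_tangent_reference <- function(covs, mean_type = c("geometric", "euclidean"),
                                  tol = 1e-6, max_iter = 50) {
  mean_type <- match.arg(mean_type)
  if (length(covs) < 1) stop_fgdn("need at least one covariance matrix")
  mats <- lapply(covs, function(cm) {
    stopifnot(inherits(cm, "connectivity_matrix"))
    if (!is_spd(cm$values)) {
      stop_fgdn("covariance of subject ", cm$subject_id,
                " is not positive definite")
    }
    cm$values
  })
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == n)) stop_fgdn("covariances differ in size")

  g <- Reduce(`+`, mats) / length(mats)
  n_iter <- 0L
  if (mean_type == "geometric") {
    for (it in seq_len(max_iter)) {
      g_half <- sym_sqrtm(g)
      g_ihalf <- sym_inv_sqrtm(g)
      logs <- lapply(mats, function(m) sym_logm(g_ihalf %*% m %*% g_ihalf))
      mean_log <- Reduce(`+`, logs) / length(logs)
      step <- frobenius(mean_log)
      g <- g_half %*% sym_expm(mean_log) %*% g_half
      g <- (g + t(g)) / 2
      n_iter <- it
      if (step < tol) break
      if (it == max_iter) {
        stop_fgdn("geometric mean did not converge in ", max_iter,
                  " iterations (last update ", format(step), ")")
      }
    }
  }
  structure(list(mean_cov = g, whitener = sym_inv_sqrtm(g),
                 fitted_on = vapply(covs, function(cm) cm$subject_id,
                                    character(1)),
                 mean_type = mean_type, n_iter = n_iter),
            class = "tangent_reference")
}

#' @export
print.tangent_reference <- function(x, ...) {
  cat(sprintf("<tangent_reference> %d x %d  mean=%s  fitted on %d subjects\n",
              nrow(x$mean_cov), ncol(x$mean_cov), x$mean_type,
              length(x$fitted_on)))
  invisible(x)
}

#' Tangent-space embedding of a covariance matrix
#'
#' Maps an SPD covariance `C` to the tangent space at the fitted reference
#' `G`: `logm(G^{-1/2} C G^{-1/2})`. The result is symmetric, lives in a
#' vector space (so Euclidean operations such as class means are meaningful),
#' and is the zero matrix exactly when `C` equals the reference.
#'
#' @param cov A `connectivity_matrix` of kind `"covariance"`, SPD.
#' @param ref A fitted [fit_tangent_reference] object.
#' @return A `connectivity_matrix` of kind `"tangent"`.
#' @export
tangent_embed <- function(cov, ref) {
  stopifnot(inherits(cov, "connectivity_matrix"),
            inherits(ref, "tangent_reference"))
  if (!is_spd(cov$values)) {
    stop_fgdn("covariance of subject ", cov$subject_id,
              " is not positive definite; cannot embed")
  }
  w <- ref$whitener
  m <- w %*% cov$values %*% w
  out <- sym_logm((m + t(m)) / 2)
  out <- (out + t(out)) / 2
  connectivity_matrix(out, cov$subject_id, "tangent")
}

#' Invert a tangent embedding
#'
#' Recovers the covariance from its tangent image: `G^{1/2} expm(T) G^{1/2}`.
#' Useful for round-trip verification.
#'
#' @param tangent A `connectivity_matrix` of kind `"tangent"`.
#' @param ref The reference used for embedding.
#' @return A `connectivity_matrix` of kind `"covariance"`.
#' @export
tangent_invert <- function(tangent, ref) {
  stopifnot(inherits(tangent, "connectivity_matrix"),
            inherits(ref, "tangent_reference"))
  g_half <- sym_sqrtm(ref$mean_cov)
  out <- g_half %*% sym_expm(tangent$values) %*% g_half
  connectivity_matrix((out + t(out)) / 2, tangent$subject_id, "covariance")
}
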