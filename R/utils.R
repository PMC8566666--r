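# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fgdn <- function(...) stop(..., call. = FALSE)

assert_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_fgdn(what, " must be a square matrix")
  }
  if (max(abs(m - t(m))) > tol) {
    stop_fgdn(what, " is not symmetric (tolerance ", format(tol), ")")
  }
  invisible(m)
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop_fgdn(what, " contains non-finite values")
  invisible(x)
}

# Apply a scalar function to the eigenvalues of a symmetric matrix.
sym_matfun <- function(m, fun) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- e$vectors
  v %*% (fun(e$values) * t(v))
}

sym_sqrtm <- function(m) sym_matfun(m, sqrt)
sym_inv_sqrtm <- function(m) sym_matfun(m, function(x) 1 / sqrt(x))
sym_logm <- function(m) sym_matfun(m, log)
sym_expm <- function(m) sym_matfun(m, exp)

min_eigval <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

is_spd <- function(m, tol = 1e-10) min_eigval(m) > tol

# Project a symmetric matrix to the SPD cone by clipping eigenvalues.
spd_project <- function(m, floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

frobenius <- function(m) sqrt(sum(m * m))

# Deterministic stratified split: returns indices of the held-out part.
# Sampling order is class-sorted so the result depends only on the seed,
# never on the incoming subject order within a class.
stratified_holdout <- function(labels, fraction, seed) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  idx <- integer(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    n_hold <- max(1L, round(fraction * length(members)))
    if (n_hold >= length(members)) {
      stop_fgdn("holdout fraction leaves no training subjects for class ", cl)
    }
    idx <- c(idx, sample(members, n_hold))
  }
  sort(idx)
}

# Stratified fold assignment: permutes each class and deals folds round-robin.
stratified_folds <- function(labels, n_folds, seed) {
  if (n_folds < 2) stop_fgdn("n_folds must be at least 2")
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (length(members) < n_folds) {
      stop_fgdn("class ", cl, " has fewer subjects (", length(members),
                ") than folds (", n_folds, ")")
    }
    fold[sample(members)] <- rep_len(seq_len(n_folds), length(members))
  }
  fold
}
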