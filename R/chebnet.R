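# The discriminative network itself: symmetric normalized Laplacians with
# exact lambda_max, K-order Chebyshev spectral graph convolution, a 5-layer
# dual-graph architecture (2 conv layers of 64 kernels with PReLU + dropout,
# a fully connected layer, and 2 sigmoid output units), the summed binary
# cross-entropy loss over both class units, and the decision rule. Forward
# and backward passes are written out explicitly so gradients are exact and
# checkable against finite differences.

#' Normalized and rescaled graph Laplacian
#'
#' Computes `L = I - D^{-1/2} W D^{-1/2}` with `D_ii = sum_j W_ij`. Isolated
#' nodes (degree 0) get `L_ii = 1` with zero off-diagonals. `lambda_max` is
#' taken from an exact eigendecomposition (cheap at connectome sizes), and
#' the rescaled operator `Lt = 2 L / lambda_max - I` has spectrum in
#' `[-1, 1]`, the domain of the Chebyshev polynomials.
#'
#' @param w Symmetric nonnegative weight matrix with zero diagonal.
#' @return Object of class `laplacian_pair`: `laplacian`, `rescaled`,
#'   `lambda_max`.
#' @export
normalized_laplacian <- function(w) {
  if (inherits(w, "graph_template")) w <- w$weights
  w <- as.matrix(w)
  assert_symmetric(w, 1e-10, "weight matrix")
  if (any(w < 0)) stop_fgdn("weight matrix has negative entries")
  n <- nrow(w)
  deg <- rowSums(w)
  inv_sqrt_d <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  l <- diag(n) - (inv_sqrt_d * w) %*% diag(inv_sqrt_d, n)
  l <- (l + t(l)) / 2
  lambda_max <- max(eigen(l, symmetric = TRUE, only.values = TRUE)$values)
  rescaled <- 2 * l / lambda_max - diag(n)
  structure(list(laplacian = l, rescaled = (rescaled + t(rescaled)) / 2,
                 lambda_max = lambda_max),
            class = "laplacian_pair")
}

# ---- Chebyshev recursion ---------------------------------------------------
# All applications of T_k(Lt) go through the three-term recursion on the
# signal matrix: T_0 X = X, T_1 X = Lt X, T_k X = 2 Lt T_{k-1} X - T_{k-2} X.

cheb_terms <- function(lhat, xm, K) {
  out <- vector("list", K)
  out[[1]] <- xm
  if (K >= 2) out[[2]] <- lhat %*% xm
  if (K >= 3) {
    for (k in 3:K) out[[k]] <- 2 * (lhat %*% out[[k - 1]]) - out[[k - 2]]
  }
  out
}

cheb_apply_k <- function(lhat, xm, k) {
  if (k == 0) return(xm)
  t_prev <- xm
  t_cur <- lhat %*% xm
  if (k == 1) return(t_cur)
  for (j in 2:k) {
    t_next <- 2 * (lhat %*% t_cur) - t_prev
    t_prev <- t_cur
    t_cur <- t_next
  }
  t_cur
}

#' K-order Chebyshev spectral graph convolution
#'
#' Filters node features with a spectral kernel restricted to a degree-K
#' Chebyshev polynomial of the rescaled Laplacian:
#' `sum_{k=0}^{K-1} T_k(Lt) X theta_k`, where the `T_k` are evaluated by the
#' three-term recursion applied directly to the feature matrix (the dense
#' Fourier basis is never formed). A K-order filter mixes information over at
#' most K-1 hops.
#'
#' @param x Node-feature matrix, N x d_in.
#' @param rescaled Rescaled Laplacian `Lt` (or a `laplacian_pair`).
#' @param theta List of K coefficient matrices, each d_in x d_out.
#' @param bias Optional length-d_out bias added to every node row.
#' @return N x d_out filtered feature matrix.
#' @export
cheb_conv <- function(x, rescaled, theta, bias = NULL) {
  if (inherits(rescaled, "laplacian_pair")) rescaled <- rescaled$rescaled
  x <- as.matrix(x)
  if (!is.list(theta) || length(theta) < 1) {
    stop_fgdn("theta must be a non-empty list of coefficient matrices")
  }
  n <- nrow(x)
  if (nrow(rescaled) != n) stop_fgdn("feature/Laplacian dimension mismatch")
  d_in <- ncol(x)
  if (nrow(theta[[1]]) != d_in) {
    stop_fgdn("theta_k must have ", d_in, " rows to match the features")
  }
  terms <- cheb_terms(rescaled, x, length(theta))
  out <- 0
  for (k in seq_along(theta)) out <- out + terms[[k]] %*% theta[[k]]
  if (!is.null(bias)) out <- out + rep(bias, each = n)
  out
}

# ---- Parameters ------------------------------------------------------------

glorot_uniform <- function(d_in, d_out) {
  limit <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -limit, limit), d_in, d_out)
}

#' Initialize network parameters
#'
#' Two Chebyshev convolution layers (`n_rois -> channels -> channels`, each
#' with K coefficient matrices, a bias and one learnable PReLU slope), a
#' fully connected layer on the flattened node-by-channel activations, and a
#' 2-unit sigmoid output head (unit 1 = ASD, unit 2 = HC). Weights are
#' Glorot-uniform, biases zero, PReLU slopes 0.25.
#'
#' @param n_rois Number of graph nodes N (input feature dimension is also N).
#' @param K Chebyshev order (default 3).
#' @param channels Convolution kernels per layer (default 64).
#' @param hidden Width of the fully connected layer (default 128).
#' @param seed Optional RNG seed for reproducible initialization.
#' @return Object of class `fgdn_params`.
#' @export
fgdn_params <- function(n_rois, K = 3, channels = 64, hidden = 128,
                        seed = NULL) {
  if (K < 1) stop_fgdn("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- list(
    conv1 = list(theta = lapply(seq_len(K),
                                function(k) glorot_uniform(n_rois, channels)),
                 bias = numeric(channels), slope = 0.25),
    conv2 = list(theta = lapply(seq_len(K),
                                function(k) glorot_uniform(channels, channels)),
                 bias = numeric(channels), slope = 0.25),
    fc = list(w = glorot_uniform(n_rois * channels, hidden),
              b = numeric(hidden), slope = 0.25),
    out = list(w = glorot_uniform(hidden, 2), b = numeric(2)))
  attr(p, "dims") <- list(n_rois = n_rois, K = K, channels = channels,
                          hidden = hidden)
  class(p) <- "fgdn_params"
  p
}

#' @export
print.fgdn_params <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("<fgdn_params> N=%d  K=%d  channels=%d  hidden=%d  (%d parameters)\n",
              d$n_rois, d$K, d$channels, d$hidden,
              length(params_flatten(x))))
  invisible(x)
}

# Tree utilities over parameter-shaped nested lists of numerics.
params_flatten <- function(p) unlist(p, use.names = FALSE)

params_unflatten <- function(v, skeleton) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) {
      out <- lapply(node, rebuild)
      attributes(out) <- attributes(node)
      return(out)
    }
    n <- length(node)
    chunk <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(node)) dim(chunk) <- dim(node)
    chunk
  }
  out <- rebuild(skeleton)
  if (pos != length(v)) stop_fgdn("flattened vector length mismatch")
  out
}

# ---- Batched layouts -------------------------------------------------------
# A batch of B subjects with d features per node lives in two layouts:
#   "stack": N x (d*B) matrix, column blocks per subject -> Laplacian matmuls
#   "nb":    (N*B) x d matrix, row blocks per subject   -> theta matmuls and
#            elementwise ops
# Conversions are cheap aperm() reshapes at connectome sizes.

nb_to_stack <- function(anb, n, b) {
  d <- ncol(anb)
  m <- aperm(array(anb, c(n, b, d)), c(1, 3, 2))
  dim(m) <- c(n, d * b)
  m
}

stack_to_nb <- function(am, n, b) {
  d <- ncol(am) / b
  m <- aperm(array(am, c(n, d, b)), c(1, 3, 2))
  dim(m) <- c(n * b, d)
  m
}

prelu <- function(z, slope) pmax(z, 0) + slope * pmin(z, 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

# Both template passes share every parameter, so the ASD-graph batch and the
# HC-graph batch are stacked into one 2B "virtual batch": only the Chebyshev
# recursions run per template, everything else (theta contractions, biases,
# activations, dropout, dense layers) runs once on the stacked batch.
dual_forward <- function(xnb, lhat_asd, lhat_hc, params, n, b,
                         dropout = 0, training = FALSE) {
  d <- attr(params, "dims")
  K <- d$K
  nb <- n * b

  am <- nb_to_stack(xnb, n, b)
  t1a <- cheb_terms(lhat_asd, am, K)
  t1h <- cheb_terms(lhat_hc, am, K)
  ynb1 <- lapply(seq_len(K), function(k) {
    rbind(stack_to_nb(t1a[[k]], n, b), stack_to_nb(t1h[[k]], n, b))
  })
  z1 <- 0
  for (k in seq_len(K)) z1 <- z1 + ynb1[[k]] %*% params$conv1$theta[[k]]
  z1 <- z1 + rep(params$conv1$bias, each = 2 * nb)
  a1 <- prelu(z1, params$conv1$slope)
  m1 <- if (training && dropout > 0) {
    (matrix(stats::runif(length(a1)), nrow(a1)) >= dropout) / (1 - dropout)
  } else 1
  h1 <- a1 * m1

  t2a <- cheb_terms(lhat_asd, nb_to_stack(h1[seq_len(nb), , drop = FALSE],
                                          n, b), K)
  t2h <- cheb_terms(lhat_hc, nb_to_stack(h1[nb + seq_len(nb), , drop = FALSE],
                                         n, b), K)
  ynb2 <- lapply(seq_len(K), function(k) {
    rbind(stack_to_nb(t2a[[k]], n, b), stack_to_nb(t2h[[k]], n, b))
  })
  z2 <- 0
  for (k in seq_len(K)) z2 <- z2 + ynb2[[k]] %*% params$conv2$theta[[k]]
  z2 <- z2 + rep(params$conv2$bias, each = 2 * nb)
  a2 <- prelu(z2, params$conv2$slope)
  m2 <- if (training && dropout > 0) {
    (matrix(stats::runif(length(a2)), nrow(a2)) >= dropout) / (1 - dropout)
  } else 1
  h2 <- a2 * m2

  # flatten each subject's N x channels block to one row, per half
  flat_half <- function(h) {
    v <- aperm(array(h, c(n, b, d$channels)), c(1, 3, 2))
    dim(v) <- c(n * d$channels, b)
    t(v)
  }
  fc_in <- rbind(flat_half(h2[seq_len(nb), , drop = FALSE]),
                 flat_half(h2[nb + seq_len(nb), , drop = FALSE]))
  zf <- fc_in %*% params$fc$w + rep(params$fc$b, each = 2 * b)
  af <- prelu(zf, params$fc$slope)
  zo <- af %*% params$out$w + rep(params$out$b, each = 2 * b)
  s <- sigmoid(zo)

  list(s_asd = s[seq_len(b), , drop = FALSE],
       s_hc = s[b + seq_len(b), , drop = FALSE],
       cache = list(ynb1 = ynb1, z1 = z1, m1 = m1,
                    ynb2 = ynb2, z2 = z2, m2 = m2,
                    fc_in = fc_in, zf = zf, af = af))
}

dual_backward <- function(dzo_a, dzo_h, fwd, lhat_asd, lhat_hc, params, n, b) {
  d <- attr(params, "dims")
  K <- d$K
  nb <- n * b
  ch <- fwd$cache
  dzo <- rbind(dzo_a, dzo_h)

  dw_out <- crossprod(ch$af, dzo)
  db_out <- colSums(dzo)
  daf <- tcrossprod(dzo, params$out$w)

  dzf <- daf * ((ch$zf > 0) + params$fc$slope * (ch$zf <= 0))
  dslope_fc <- sum(daf * pmin(ch$zf, 0))
  dw_fc <- crossprod(ch$fc_in, dzf)
  db_fc <- colSums(dzf)
  dfc_in <- tcrossprod(dzf, params$fc$w)

  unflat_half <- function(rows) {
    dh <- aperm(array(t(rows), c(n, d$channels, b)), c(1, 3, 2))
    dim(dh) <- c(nb, d$channels)
    dh
  }
  dh2 <- rbind(unflat_half(dfc_in[seq_len(b), , drop = FALSE]),
               unflat_half(dfc_in[b + seq_len(b), , drop = FALSE]))

  da2 <- dh2 * ch$m2
  dz2 <- da2 * ((ch$z2 > 0) + params$conv2$slope * (ch$z2 <= 0))
  dslope2 <- sum(da2 * pmin(ch$z2, 0))
  dtheta2 <- lapply(seq_len(K), function(k) crossprod(ch$ynb2[[k]], dz2))
  dbias2 <- colSums(dz2)

  da1_a <- 0
  da1_h <- 0
  for (k in seq_len(K)) {
    g <- tcrossprod(dz2, params$conv2$theta[[k]])
    da1_a <- da1_a + cheb_apply_k(lhat_asd,
                                  nb_to_stack(g[seq_len(nb), , drop = FALSE],
                                              n, b), k - 1)
    da1_h <- da1_h + cheb_apply_k(lhat_hc,
                                  nb_to_stack(g[nb + seq_len(nb), ,
                                                drop = FALSE], n, b), k - 1)
  }
  da1 <- rbind(stack_to_nb(da1_a, n, b), stack_to_nb(da1_h, n, b)) * ch$m1
  dz1 <- da1 * ((ch$z1 > 0) + params$conv1$slope * (ch$z1 <= 0))
  dslope1 <- sum(da1 * pmin(ch$z1, 0))
  dtheta1 <- lapply(seq_len(K), function(k) crossprod(ch$ynb1[[k]], dz1))
  dbias1 <- colSums(dz1)

  g <- list(conv1 = list(theta = dtheta1, bias = dbias1, slope = dslope1),
            conv2 = list(theta = dtheta2, bias = dbias2, slope = dslope2),
            fc = list(w = dw_fc, b = db_fc, slope = dslope_fc),
            out = list(w = dw_out, b = db_out))
  attributes(g) <- attributes(params)
  g
}

# Loss + gradient of a labeled batch under the two class templates.
# x is an N x d x B array of node features; y is 1 for ASD, 0 for HC.
fgdn_batch_grad <- function(x, lhat_asd, lhat_hc, y, params,
                            dropout = 0, training = TRUE, eps = 1e-7) {
  n <- dim(x)[1]
  b <- dim(x)[3]
  xnb <- stack_to_nb(matrix(x, n, dim(x)[2] * b), n, b)
  fwd <- dual_forward(xnb, lhat_asd, lhat_hc, params, n, b, dropout, training)
  p_asd <- fwd$s_asd[, 1]
  p_hc <- fwd$s_hc[, 2]
  preds <- cbind(p_asd, p_hc)
  loss <- fgdn_loss(preds, ifelse(y == 1, "ASD", "HC"), eps = eps)
  dzo_a <- cbind(p_asd - y, numeric(b))
  dzo_h <- cbind(numeric(b), p_hc - (1 - y))
  grads <- dual_backward(dzo_a, dzo_h, fwd, lhat_asd, lhat_hc, params, n, b)
  list(loss = loss, grads = grads, p_asd = p_asd, p_hc = p_hc)
}

# Forward only, no dropout; returns cbind(p_asd, p_hc).
fgdn_predict_batch <- function(x, lhat_asd, lhat_hc, params) {
  n <- dim(x)[1]
  b <- dim(x)[3]
  xnb <- stack_to_nb(matrix(x, n, dim(x)[2] * b), n, b)
  fwd <- dual_forward(xnb, lhat_asd, lhat_hc, params, n, b)
  cbind(p_asd = fwd$s_asd[, 1], p_hc = fwd$s_hc[, 2])
}

#' Forward pass of the dual-graph network for one subject
#'
#' Runs one shared-parameter network twice over the same node features: once
#' under the ASD template's rescaled Laplacian (reading the sigmoid value of
#' the ASD output unit) and once under the HC template's (reading the HC
#' unit). Dropout after each convolution activation is active only when
#' `training = TRUE`.
#'
#' @param asd_graph,hc_graph `functional_graph` objects from
#'   [assemble_graphs]; they must share the identical feature matrix.
#' @param params An [fgdn_params] object.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param training Logical; enables dropout.
#' @return Named numeric vector `c(p_asd = ..., p_hc = ...)`, both in (0, 1).
#' @export
fgdn_forward <- function(asd_graph, hc_graph, params, dropout = 0,
                         training = FALSE) {
  stopifnot(inherits(asd_graph, "functional_graph"),
            inherits(hc_graph, "functional_graph"))
  if (!identical(asd_graph$node_features, hc_graph$node_features)) {
    stop_fgdn("the two graphs must share identical node features")
  }
  x <- asd_graph$node_features
  la <- normalized_laplacian(asd_graph$template$weights)$rescaled
  lh <- normalized_laplacian(hc_graph$template$weights)$rescaled
  n <- nrow(x)
  xnb <- stack_to_nb(matrix(x, n, ncol(x)), n, 1)
  fwd <- dual_forward(xnb, la, lh, params, n, 1, dropout, training)
  c(p_asd = fwd$s_asd[1, 1], p_hc = fwd$s_hc[1, 2])
}

#' Decision rule on the two class-unit outputs
#'
#' A subject is called ASD when its ASD-unit output strictly exceeds the
#' HC-unit output; otherwise (including exact ties) HC.
#'
#' @param p_asd,p_hc Numeric vectors of unit outputs in (0, 1).
#' @return Character vector of `"ASD"` / `"HC"`.
#' @export
classify <- function(p_asd, p_hc) ifelse(p_asd > p_hc, "ASD", "HC")

#' Summed cross-entropy loss over both class units
#'
#' For subject i with one-hot target `(y_i1, y_i2)` ((1,0) for ASD, (0,1)
#' for HC) and unit outputs `(p_i1, p_i2)`, the loss is
#' `-sum_i sum_c [ y_ic log p_ic + (1 - y_ic) log(1 - p_ic) ]`, summed (not
#' averaged) over the batch. Outputs are clipped to `[eps, 1 - eps]` so the
#' loss stays finite.
#'
#' @param preds Two-column matrix `cbind(p_asd, p_hc)` (or a vector of
#'   length 2 for a single subject).
#' @param labels Character vector of `"ASD"` / `"HC"`, aligned with rows.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
fgdn_loss <- function(preds, labels, eps = 1e-7) {
  if (is.null(dim(preds))) preds <- matrix(preds, ncol = 2)
  if (nrow(preds) == 0) stop_fgdn("empty batch")
  if (nrow(preds) != length(labels)) stop_fgdn("preds/labels misaligned")
  p <- pmin(pmax(preds, eps), 1 - eps)
  y <- cbind(as.numeric(labels == "ASD"), as.numeric(labels == "HC"))
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Adam ------------------------------------------------------------------
# Adam with L2-style weight decay added to the raw gradient (decay applied to
# every parameter, matching the convention of mainstream deep-learning
# optimizers). The optimizer state lives on the flattened parameter vector
# and is updated in place by the compiled kernel (src/adam.cpp); the
# structured tree is rebuilt once per step for the forward/backward pass.

adam_init <- function(params) {
  v <- params_flatten(params)
  list(m = numeric(length(v)), v = numeric(length(v)), t = 0L)
}
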