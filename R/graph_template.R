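# Class-specific graph templates: the mean training connectivity of a class
# defines node features (its rows); a KNN rule with a Gaussian kernel turns
# pairwise row distances into a sparse symmetric edge-weight matrix. A test
# subject then borrows each class's template while supplying its own node
# features, giving one graph per candidate class.

#' Element-wise mean connectivity of one class
#'
#' @param train List of `connectivity_matrix` objects (training subjects
#'   only).
#' @param label Class whose subjects to average (`"ASD"` or `"HC"`); matched
#'   against `labels`.
#' @param labels Character vector of class labels aligned with `train`.
#' @return N x N numeric matrix, the arithmetic mean over the class.
#' @export
class_mean_connectivity <- function(train, label, labels) {
  stopifnot(length(train) == length(labels))
  members <- which(labels == label)
  if (length(members) == 0) stop_fgdn("no training subjects of class ", label)
  mats <- lapply(train[members], function(cm) cm$values)
  Reduce(`+`, mats) / length(mats)
}

#' Build a class graph template by KNN + Gaussian kernel
#'
#' Treats the rows of the class-mean connectivity matrix as node features.
#' For each node the Euclidean distances to all other nodes are computed and
#' only the `k` nearest are retained (the per-node distance cutoff is the
#' k-th neighbour distance; ties at the cutoff break by ascending node
#' index). The kernel width `theta` is the mean of all retained directed
#' distances, and each kept pair gets weight `exp(-d^2 / (2 theta^2))`; pairs
#' kept by neither endpoint get weight 0. The directed selection is
#' symmetrized by union (`W <- pmax(W, t(W))`) so every node keeps at least
#' `k` edges and the Laplacian stays symmetric. Coincident rows (distance 0)
#' get weight 1. No self-loops.
#'
#' @param mean_fc Square finite matrix, the class-mean connectivity.
#' @param k Number of neighbours per node, `1 <= k < N`.
#' @param label Class label stored on the template.
#' @return Object of class `graph_template` with fields `class_label`,
#'   `weights`, `k`, `theta`, `source_mean`, and `source_ids` when known.
#' @export
build_template <- function(mean_fc, k, label = "ASD") {
  mean_fc <- as.matrix(mean_fc)
  assert_finite(mean_fc, "mean connectivity")
  n <- nrow(mean_fc)
  if (ncol(mean_fc) != n) stop_fgdn("mean connectivity must be square")
  if (k < 1 || k >= n) {
    stop_fgdn("k must satisfy 1 <= k < N (k = ", k, ", N = ", n, ")")
  }
  d <- as.matrix(stats::dist(mean_fc))  # Euclidean on rows

  # per-node k nearest (self excluded); order() breaks ties by index
  keep <- matrix(FALSE, n, n)
  kept_dists <- numeric(0)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(d[i, others])][seq_len(k)]
    keep[i, nn] <- TRUE
    kept_dists <- c(kept_dists, d[i, nn])
  }
  theta <- mean(kept_dists)

  w <- matrix(0, n, n)
  if (theta > 0) {
    w[keep] <- exp(-d[keep]^2 / (2 * theta^2))
  } else {
    w[keep] <- 1  # all retained pairs coincide
  }
  w <- pmax(w, t(w))  # union-KNN symmetrization
  diag(w) <- 0
  structure(list(class_label = label, weights = w, k = as.integer(k),
                 theta = theta, source_mean = mean_fc, source_ids = NULL),
            class = "graph_template")
}

#' @export
print.graph_template <- function(x, ...) {
  cat(sprintf("<graph_template> class=%s  N=%d  k=%d  theta=%.4g  %d edges\n",
              x$class_label, nrow(x$weights), x$k, x$theta,
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Assemble a subject's class-conditional functional graphs
#'
#' A test subject's connectivity matrix supplies the node features (its
#' rows); the class templates supply the edges. The two returned graphs share
#' the identical, unmodified feature matrix and differ only in template.
#'
#' @param subject_fc The subject's `connectivity_matrix`.
#' @param asd_template,hc_template Fitted [build_template] objects.
#' @return List with elements `asd` and `hc`, each of class
#'   `functional_graph` holding `node_features` (N x N) and `template`.
#' @export
assemble_graphs <- function(subject_fc, asd_template, hc_template) {
  stopifnot(inherits(subject_fc, "connectivity_matrix"),
            inherits(asd_template, "graph_template"),
            inherits(hc_template, "graph_template"))
  n <- nrow(subject_fc$values)
  if (nrow(asd_template$weights) != n || nrow(hc_template$weights) != n) {
    stop_fgdn("subject connectivity is ", n, " x ", n,
              " but templates have different dimension")
  }
  mk <- function(tmpl) {
    structure(list(node_features = subject_fc$values, template = tmpl,
                   subject_id = subject_fc$subject_id),
              class = "functional_graph")
  }
  list(asd = mk(asd_template), hc = mk(hc_template))
}
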