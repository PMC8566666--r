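# Synthetic multi-site two-class cohorts with planted connectivity
# differences. The generator emulates the statistical skeleton of a
# multi-site resting-state cohort: per-subject Gaussian ROI time series whose
# population covariance is a class covariance plus a subject-level
# perturbation, with per-site variance scaling standing in for
# scanner/protocol differences. Class differences live in a known subset of
# regions so recovery can be verified.

#' Specification of a synthetic cohort
#'
#' Defaults describe the cohort used throughout the package's experiments:
#' two balanced classes of 100 subjects across 3 sites, 16 ROIs, 150
#' timepoints, and a covariance difference of magnitude 0.4 planted on the
#' edges among two signal regions.
#'
#' @param n_subjects_per_class Subjects per class.
#' @param n_rois Number of ROIs (atlas size), up to 128.
#' @param n_timepoints Timepoints per subject.
#' @param signal_regions 1-based ROI indices carrying the class difference.
#' @param effect_size Magnitude added to ASD covariance entries among signal
#'   regions (covariance units; base matrices have unit variances).
#' @param n_sites Number of acquisition sites.
#' @param site_shift Half-range of the per-site multiplicative variance
#'   scaling (site factors are evenly spaced in `1 +- site_shift`).
#' @param subject_noise Standard deviation of the symmetric per-subject
#'   covariance perturbation.
#' @param ar_coef Optional AR(1) temporal autocorrelation of the emitted
#'   series (0 = white; the stationary covariance is unchanged).
#' @param seed RNG seed; the cohort is a deterministic function of the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects_per_class = 100, n_rois = 16,
                           n_timepoints = 150, signal_regions = c(4, 8),
                           effect_size = 0.4, n_sites = 3, site_shift = 0.1,
                           subject_noise = 0.1, ar_coef = 0, seed = 1) {
  if (effect_size < 0) stop_fgdn("effect_size must be >= 0")
  if (any(signal_regions < 1 | signal_regions > n_rois)) {
    stop_fgdn("signal_regions must be 1-based indices within 1..n_rois")
  }
  if (n_timepoints < 3) stop_fgdn("need at least 3 timepoints")
  if (abs(ar_coef) >= 1) stop_fgdn("ar_coef must lie in (-1, 1)")
  structure(list(n_subjects_per_class = n_subjects_per_class, n_rois = n_rois,
                 n_timepoints = n_timepoints,
                 signal_regions = as.integer(signal_regions),
                 effect_size = effect_size, n_sites = n_sites,
                 site_shift = site_shift, subject_noise = subject_noise,
                 ar_coef = ar_coef, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Base covariance from a random sparse partial-correlation structure,
# rescaled to unit variances.
base_covariance <- function(n_rois, density = 0.2) {
  prec <- diag(n_rois)
  pairs <- which(upper.tri(prec), arr.ind = TRUE)
  on <- stats::runif(nrow(pairs)) < density
  vals <- stats::runif(nrow(pairs), -0.25, 0.25) * on
  for (r in seq_len(nrow(pairs))) {
    prec[pairs[r, 1], pairs[r, 2]] <- vals[r]
    prec[pairs[r, 2], pairs[r, 1]] <- vals[r]
  }
  ev_min <- min_eigval(prec)
  if (ev_min < 0.1) prec <- prec + diag(0.1 - ev_min, n_rois)
  sigma <- solve(prec)
  d <- 1 / sqrt(diag(sigma))
  sigma <- (d %o% d) * sigma
  (sigma + t(sigma)) / 2
}

#' Generate a synthetic multi-site cohort
#'
#' Builds an HC class covariance from a random sparse partial-correlation
#' structure (unit variances), plants `+-effect_size` on the off-diagonal
#' entries among `signal_regions` to form the ASD class covariance
#' (SPD-projected by eigenvalue clipping at 1e-6), then draws each subject's
#' covariance as class covariance plus a symmetric Gaussian perturbation of
#' scale `subject_noise` (SPD-projected) and applies its site's variance
#' factor. The emitted signal is zero-mean Gaussian with that covariance.
#' Subjects are dealt to sites round-robin within class, so every site holds
#' both classes.
#'
#' @param spec A [synthetic_spec].
#' @return List with `cohort` (list of [roi_timeseries]) and `ground_truth`
#'   (class covariances, signal regions, site factors, per-subject
#'   covariances).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_rois

  cov_hc <- base_covariance(n)
  delta <- matrix(0, n, n)
  sr <- spec$signal_regions
  if (length(sr) >= 2 && spec$effect_size > 0) {
    pr <- utils::combn(sr, 2)
    for (j in seq_len(ncol(pr))) {
      s <- sample(c(-1, 1), 1)
      delta[pr[1, j], pr[2, j]] <- s * spec$effect_size
      delta[pr[2, j], pr[1, j]] <- s * spec$effect_size
    }
  }
  cov_asd <- spd_project(cov_hc + delta, 1e-6)

  site_factors <- if (spec$n_sites == 1) 1 else {
    seq(1 - spec$site_shift, 1 + spec$site_shift, length.out = spec$n_sites)
  }

  cohort <- list()
  subj_covs <- list()
  idx <- 0L
  for (cls in c("ASD", "HC")) {
    cls_cov <- if (cls == "ASD") cov_asd else cov_hc
    for (i in seq_len(spec$n_subjects_per_class)) {
      idx <- idx + 1L
      site <- ((i - 1L) %% spec$n_sites) + 1L
      r <- matrix(stats::rnorm(n * n), n, n)
      pert <- spec$subject_noise * (r + t(r)) / sqrt(2)
      sigma <- spd_project(cls_cov + pert, 1e-6) * site_factors[site]
      z <- matrix(stats::rnorm(spec$n_timepoints * n), spec$n_timepoints, n)
      if (spec$ar_coef != 0) {
        z <- apply(z, 2, function(col) {
          as.numeric(stats::filter(col * sqrt(1 - spec$ar_coef^2),
                                   spec$ar_coef, method = "recursive"))
        })
      }
      x <- z %*% chol(sigma)
      sid <- sprintf("sub%03d", idx)
      cohort[[idx]] <- roi_timeseries(x, sid, sprintf("site%d", site), cls,
                                      atlas_name = "synthetic")
      subj_covs[[sid]] <- sigma
    }
  }
  list(cohort = cohort,
       ground_truth = list(cov_asd = cov_asd, cov_hc = cov_hc,
                           signal_regions = sr, site_factors = site_factors,
                           subject_covs = subj_covs, seed = spec$seed))
}

#' Fixed 4-ROI worked example
#'
#' A deterministic, hand-sized cohort of 8 connectivity matrices (4 per
#' class, 2 sites) built around two hand-written 4 x 4 class-mean matrices.
#' The per-subject matrices are the class mean plus symmetric offsets that
#' cancel exactly, so the class means of the cohort equal the written
#' fixtures to machine precision. Used to verify graph construction and
#' Laplacian code against hand-checkable numbers.
#'
#' @return List with `fc` (list of `connectivity_matrix`), `labels`, `sites`,
#'   `mean_asd`, `mean_hc`.
#' @export
generate_worked_example <- function() {
  mean_asd <- matrix(c(1.0, 0.8, 0.2, 0.0,
                       0.8, 1.0, 0.3, 0.1,
                       0.2, 0.3, 1.0, 0.6,
                       0.0, 0.1, 0.6, 1.0), 4, 4, byrow = TRUE)
  mean_hc <- matrix(c(1.0, 0.2, 0.7, 0.1,
                      0.2, 1.0, 0.2, 0.5,
                      0.7, 0.2, 1.0, 0.3,
                      0.1, 0.5, 0.3, 1.0), 4, 4, byrow = TRUE)
  offset <- matrix(c(0,  1,  0, -1,
                     1,  0,  1,  0,
                     0,  1,  0,  1,
                    -1,  0,  1,  0), 4, 4, byrow = TRUE) * 0.05
  scales <- c(1, -1, 2, -2)  # sums to zero -> exact class means
  fc <- list()
  labels <- character(0)
  sites <- character(0)
  idx <- 0
  for (cls in c("ASD", "HC")) {
    m <- if (cls == "ASD") mean_asd else mean_hc
    for (j in 1:4) {
      idx <- idx + 1
      fc[[idx]] <- connectivity_matrix(m + scales[j] * offset,
                                       sprintf("wx%02d", idx), "covariance")
      labels <- c(labels, cls)
      sites <- c(sites, sprintf("site%d", ((j - 1) %% 2) + 1))
    }
  }
  list(fc = fc, labels = labels, sites = sites,
       mean_asd = mean_asd, mean_hc = mean_hc)
}
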