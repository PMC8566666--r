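# On-disk dialects: headerless TSV time series (rows = timepoints, columns =
# ROIs in atlas order, one file per subject named <subject_id>.tsv), a CSV
# phenotype table `subject_id,site,diagnosis`, JSON evaluation reports, and
# RDS containers for fitted models and templates.

DIAGNOSIS_LEVELS <- c("ASD", "HC", "UNKNOWN")

#' Construct a single-subject ROI time-series record
#'
#' Bundles one subject's BOLD signal matrix (rows are timepoints, columns are
#' atlas regions) with its identifying metadata. This is the unit every
#' connectivity estimator and the training pipeline consume.
#'
#' @param signal Numeric matrix, T timepoints x N ROIs, all values finite,
#'   T >= 3.
#' @param subject_id Character scalar, unique within a cohort.
#' @param site Acquisition-site label (scanner/protocol grouping used by
#'   leave-one-site-out evaluation).
#' @param diagnosis One of `"ASD"`, `"HC"` or `"UNKNOWN"` (case-insensitive).
#' @param atlas_name Name of the parcellation the columns refer to.
#' @return An object of class `roi_timeseries` with fields `signal`,
#'   `subject_id`, `site`, `diagnosis`, `atlas_name`, `n_rois`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(40), 10, 4), "sub01", "siteA", "ASD")
#' ts$n_rois
#' @export
roi_timeseries <- function(signal, subject_id, site = "unknown",
                           diagnosis = "UNKNOWN", atlas_name = "custom") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop_fgdn("signal must be numeric")
  if (nrow(signal) < 3) {
    stop_fgdn("subject ", subject_id, ": need at least 3 timepoints, got ",
              nrow(signal))
  }
  assert_finite(signal, paste0("subject ", subject_id, " signal"))
  diagnosis <- toupper(as.character(diagnosis))
  if (!diagnosis %in% DIAGNOSIS_LEVELS) {
    stop_fgdn("subject ", subject_id, ": diagnosis must be one of ",
              paste(DIAGNOSIS_LEVELS, collapse = "/"), ", got '", diagnosis, "'")
  }
  structure(
    list(signal = unname(signal), subject_id = as.character(subject_id),
         site = as.character(site), diagnosis = diagnosis,
         atlas_name = atlas_name, n_rois = ncol(signal)),
    class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s  site=%s  diagnosis=%s  %d timepoints x %d ROIs (%s)\n",
              x$subject_id, x$site, x$diagnosis, nrow(x$signal), x$n_rois,
              x$atlas_name))
  invisible(x)
}

cohort_labels <- function(cohort) {
  vapply(cohort, function(s) s$diagnosis, character(1))
}

cohort_sites <- function(cohort) {
  vapply(cohort, function(s) s$site, character(1))
}

cohort_ids <- function(cohort) {
  vapply(cohort, function(s) s$subject_id, character(1))
}

read_timeseries_file <- function(path, subject_id) {
  if (!file.exists(path)) {
    stop_fgdn("subject ", subject_id, ": time-series file not found: ", path)
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "numeric",
                           blank.lines.skip = TRUE)
  m <- as.matrix(tab)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_fgdn("non-finite value in ", path, " at row ", bad[1, 1],
              ", column ", bad[1, 2])
  }
  m
}

#' Load a cohort of ROI time series
#'
#' Reads the phenotype table and one headerless TSV per subject
#' (`<subject_id>.tsv`, rows = timepoints, columns = ROIs in atlas order)
#' from `timeseries_dir`. Subjects are returned in phenotype-row order,
#' independent of filesystem listing order.
#'
#' @param timeseries_dir Directory containing `<subject_id>.tsv` files.
#' @param phenotype_path CSV file with header `subject_id,site,diagnosis`.
#' @param atlas_name Atlas label attached to every subject.
#' @return List of [roi_timeseries] objects, one per phenotype row.
#' @export
load_cohort <- function(timeseries_dir, phenotype_path, atlas_name = "custom") {
  pheno <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "site", "diagnosis")
  if (!all(needed %in% names(pheno))) {
    stop_fgdn("phenotype file must have columns ",
              paste(needed, collapse = ", "))
  }
  if (anyDuplicated(pheno$subject_id)) {
    stop_fgdn("duplicate subject_id in phenotype table: ",
              pheno$subject_id[duplicated(pheno$subject_id)][1])
  }
  cohort <- vector("list", nrow(pheno))
  n_cols <- NULL
  for (i in seq_len(nrow(pheno))) {
    sid <- pheno$subject_id[i]
    path <- file.path(timeseries_dir, paste0(sid, ".tsv"))
    m <- read_timeseries_file(path, sid)
    if (is.null(n_cols)) {
      n_cols <- ncol(m)
    } else if (ncol(m) != n_cols) {
      stop_fgdn("subject ", sid, " has ", ncol(m),
                " ROI columns but the cohort has ", n_cols)
    }
    cohort[[i]] <- roi_timeseries(m, sid, pheno$site[i], pheno$diagnosis[i],
                                  atlas_name)
  }
  cohort
}

#' Write a cohort in the on-disk dialect
#'
#' Writes one headerless TSV per subject plus a `phenotype.csv` table, the
#' same layout [load_cohort] reads.
#'
#' @param cohort List of [roi_timeseries].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the phenotype file path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort) {
    utils::write.table(s$signal, file.path(dir, paste0(s$subject_id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  pheno <- data.frame(subject_id = cohort_ids(cohort),
                      site = cohort_sites(cohort),
                      diagnosis = cohort_labels(cohort))
  path <- file.path(dir, "phenotype.csv")
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Serializes an [eval_report] (per-fold metrics plus mean/SD summary) to a
#' machine-readable JSON file that [read_report] restores losslessly.
#'
#' @param report An `eval_report` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "eval_report")) stop_fgdn("not an eval_report")
  if (is.null(report$folds) || nrow(report$folds) == 0) {
    stop_fgdn("report has no fold entries")
  }
  payload <- list(experiment = report$experiment, seed = report$seed,
                  folds = report$folds, summary = report$summary,
                  config = report$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an evaluation report written by [write_report]
#' @param path JSON file path.
#' @return An `eval_report` object.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_eval_report(experiment = payload$experiment,
                  seed = payload$seed,
                  folds = as.data.frame(payload$folds),
                  config = payload$config,
                  summary = as.data.frame(payload$summary))
}

#' Persist a fitted model (or template) to disk
#'
#' Models, graph templates and tangent references are nested numeric arrays;
#' they are stored in R's native serialized container.
#'
#' @param object Any fitted object from this package.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' Read an object written by [write_model]
#' @param path File path.
#' @return The stored object.
#' @export
read_model <- function(path) readRDS(path)
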