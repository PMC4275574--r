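# Plain-text I/O: TSV for series, matrices and summaries; whitespace text
# for motion parameters; JSON for reports and ground truth.

#' Write / read a regional time-series as TSV
#'
#' Rows are time-points, columns are regions, with a header row of region
#' labels.
#'
#' @param ts An `fc_timeseries`.
#' @param path Output file.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "fc_timeseries"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param tr_seconds,subject_id,group Metadata for the reconstructed
#'   object (TSV stores only the matrix).
#' @export
read_timeseries <- function(path, tr_seconds = 2, subject_id = NULL,
                            group = NA_real_) {
  X <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  raw_timeseries(X, tr_seconds = tr_seconds, subject_id = subject_id,
                 group = group)
}

#' Read a motion-parameter file
#'
#' Whitespace-delimited text with one row per time-point and 6 columns
#' (3 translations + 3 rotations), the realignment-output dialect.
#'
#' @param path File path.
#' @return Numeric `n_t` x 6 matrix.
#' @export
read_motion <- function(path) {
  M <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(M) != 6L)
    stop("motion file has ", ncol(M), " columns; expected 6")
  colnames(M) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  M
}

#' Write / read a connectivity matrix as TSV with region-label headers
#'
#' @param mat A `connectivity_matrix`.
#' @param path Output file.
#' @export
write_connectivity <- function(mat, path) {
  M <- unclass(mat)
  df <- data.frame(region = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @param kind Connectivity kind to tag the matrix with.
#' @export
read_connectivity <- function(path, kind = "covariance") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  new_connectivity(M, kind)
}

#' Write a feature vector as TSV of (edge id, value) pairs
#'
#' @param v Feature vector from [vectorize_lower()].
#' @param path Output file.
#' @export
write_features <- function(v, path) {
  utils::write.table(data.frame(edge = names(v), value = as.numeric(v)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dataset (manifest, per-subject TSV series, ground truth) to disk
#'
#' @param dataset An `fc_dataset`.
#' @param dir Output directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$file <- paste0(man$subject_id, ".tsv")
  for (i in seq_len(nrow(man))) {
    id <- as.character(man$subject_id[i])
    write_timeseries(dataset$ts[[id]], file.path(dir, man$file[i]))
    if (!is.null(dataset$ts[[id]]$motion))
      utils::write.table(dataset$ts[[id]]$motion,
                         file.path(dir, paste0("rp_", id, ".txt")),
                         sep = " ", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    tr$precision_patient <- unclass(tr$precision_patient)
    tr$precision_control <- unclass(tr$precision_control)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.tsv`.
#' @param tr_seconds Repetition time to attach to each series.
#' @return An `fc_dataset`.
#' @export
read_dataset <- function(dir, tr_seconds = 2) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  ts <- list()
  for (i in seq_len(nrow(man))) {
    id <- as.character(man$subject_id[i])
    ts[[id]] <- read_timeseries(file.path(dir, man$file[i]),
                                tr_seconds = tr_seconds, subject_id = id,
                                group = man$group[i])
    rp <- file.path(dir, paste0("rp_", id, ".txt"))
    if (file.exists(rp)) ts[[id]]$motion <- read_motion(rp)
  }
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  fc_dataset(ts, man[, c("subject_id", "group")], truth = truth)
}

#' Load a 4-D NIfTI image and integer parcellation into regional means
#'
#' Thin wrapper over [regional_means()] for NIfTI-1 inputs (requires the
#' `RNifti` package).
#'
#' @param image_path 4-D NIfTI image file.
#' @param parcellation_path 3-D integer-labelled NIfTI volume.
#' @param ... Passed to [regional_means()].
#' @return An `fc_timeseries`.
#' @export
regional_means_nifti <- function(image_path, parcellation_path, ...) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI inputs requires the RNifti package")
  img <- RNifti::readNifti(image_path)
  parc <- RNifti::readNifti(parcellation_path)
  tr <- RNifti::pixdim(img)[4L]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  regional_means(unclass(img), unclass(parc), tr_seconds = tr, ...)
}

#' Write / read a trained linear model
#'
#' Weights go to a TSV of (edge id, weight) pairs; penalty, cost, support
#' threshold and any graphical-LASSO penalty go to a JSON sidecar next to
#' it (same path with extension `.json`).
#'
#' @param model An `fc_svm`.
#' @param path Weight TSV path.
#' @export
write_model <- function(model, path) {
  nm <- attr(model, "feature_names")
  if (is.null(nm)) nm <- names(model$weights)
  if (is.null(nm)) nm <- paste0("e", seq_along(model$weights))
  utils::write.table(data.frame(edge = nm, weight = unname(model$weights)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(penalty = model$penalty, C = model$C,
               eps_support = model$eps_support,
               lambda = attr(model, "lambda"),
               sparsity = model$sparsity)
  jsonlite::write_json(meta, paste0(sub("\\.[^.]*$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(sub("\\.[^.]*$", "", path), ".json"),
                              simplifyVector = TRUE)
  w <- stats::setNames(tab$weight, tab$edge)
  m <- new_linear_model(w, meta$penalty, meta$C, meta$eps_support)
  if (!is.null(meta$lambda) && !all(is.na(meta$lambda)))
    attr(m, "lambda") <- meta$lambda
  attr(m, "feature_names") <- tab$edge
  m
}

#' Write a cross-validation report (JSON) and summary row (TSV)
#'
#' The TSV mirrors the standard results-table columns: accuracy,
#' sensitivity, specificity (percent), sparsity and stability
#' (percent, mean +/- sd).
#'
#' @param report A `cv_report`.
#' @param path_json,path_tsv Output files (either may be `NULL` to skip).
#' @param p_value Optional permutation p-value to include.
#' @export
write_cv_report <- function(report, path_json = NULL, path_tsv = NULL,
                            p_value = NA_real_) {
  if (!is.null(path_json)) {
    out <- report
    out$supports <- lapply(out$supports, as.integer)
    jsonlite::write_json(unclass(out), path_json, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  if (!is.null(path_tsv)) {
    utils::write.table(summary_row(report, p_value), path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

summary_row <- function(report, p_value = NA_real_) {
  m <- report$metrics
  data.frame(
    features = report$settings$feature_kind,
    penalty = report$settings$penalty,
    accuracy_pct = round(m$accuracy, 2),
    p_value = p_value,
    sensitivity_pct = round(m$sensitivity, 2),
    specificity_pct = round(m$specificity, 2),
    sparsity_pct = if (is.na(report$sparsity$mean)) NA else
      sprintf("%.2f +/- %.2f", report$sparsity$mean, report$sparsity$sd),
    stability_pct = sprintf("%.2f +/- %.2f", report$stability$mean,
                            report$stability$sd),
    stringsAsFactors = FALSE)
}

#' Write a discriminative network as edge-list and node-degree TSVs
#'
#' @param net A `discriminative_network`.
#' @param path_edges Edge-list TSV (region pair, weight, p-values, flag).
#' @param path_degrees Optional node-degree TSV.
#' @export
write_network <- function(net, path_edges, path_degrees = NULL) {
  utils::write.table(net$edges, path_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_degrees)) {
    deg <- data.frame(region = names(net$node_degrees),
                      degree = as.integer(net$node_degrees))
    utils::write.table(deg, path_degrees, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}
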