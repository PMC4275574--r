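#' Construct a raw regional time-series object
#'
#' Bundles one subject's regional time-series matrix (time-points in rows,
#' regions in columns) with its repetition time, subject identifier, and
#' group label.
#'
#' @param data Numeric matrix, `n_t` time-points x `n_p` regions. Column
#'   names, when present, are taken as region labels.
#' @param tr_seconds Repetition time between consecutive rows, in seconds.
#' @param subject_id Opaque subject identifier.
#' @param group Group label: `+1` (patient) or `-1` (control).
#' @return An object of class `fc_timeseries` with fields `data`,
#'   `tr_seconds`, `subject_id`, `group` and `provenance`.
#' @export
raw_timeseries <- function(data, tr_seconds, subject_id = "subj",
                           group = NA_real_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("time-series must have at least 2 time-points")
  if (anyNA(data) || any(!is.finite(data)))
    stop("time-series contains missing or non-finite values")
  v <- apply(data, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(data)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("R%03d", seq_len(ncol(data)))
  if (!is.na(group) && !group %in% c(-1, 1))
    stop("group must be +1 (patient) or -1 (control)")
  structure(list(data = data, tr_seconds = tr_seconds,
                 subject_id = subject_id, group = group,
                 provenance = character(0)),
            class = "fc_timeseries")
}

#' @export
print.fc_timeseries <- function(x, ...) {
  cat(sprintf("fc_timeseries '%s': %d time-points x %d regions (TR = %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Average a voxel image into regional mean time-series
#'
#' Reduces a 4-D intensity array to one mean time course per labelled region
#' of an integer parcellation sharing the same spatial grid.
#'
#' @param voxel_image 4-D numeric array (x, y, z, time).
#' @param parcellation 3-D integer array of region labels; label 0 (and
#'   negative labels) denote background and are ignored.
#' @param region_labels Optional integer vector of labels to extract, in the
#'   given order; defaults to all distinct positive labels in ascending
#'   order. A requested label with no voxels is an error.
#' @param tr_seconds Repetition time, passed through to the result.
#' @param subject_id,group Passed through to [raw_timeseries()].
#' @return An `fc_timeseries` whose columns are named `L<label>`.
#' @export
regional_means <- function(voxel_image, parcellation, region_labels = NULL,
                           tr_seconds = 1, subject_id = "subj",
                           group = NA_real_) {
  dv <- dim(voxel_image)
  dp <- dim(parcellation)
  if (length(dv) != 4L)
    stop("voxel_image must be a 4-D array (x, y, z, time)")
  if (length(dp) != 3L || !all(dv[1:3] == dp))
    stop("parcellation grid ", paste(dp, collapse = "x"),
         " does not match image grid ", paste(dv[1:3], collapse = "x"))
  labs <- as.integer(round(parcellation))
  if (is.null(region_labels)) {
    region_labels <- sort(unique(labs[labs > 0L]))
  } else {
    region_labels <- as.integer(region_labels)
  }
  if (!length(region_labels)) stop("parcellation contains no positive labels")
  n_t <- dv[4L]
  vox <- matrix(voxel_image, nrow = prod(dv[1:3]), ncol = n_t)
  out <- matrix(NA_real_, nrow = n_t, ncol = length(region_labels))
  for (k in seq_along(region_labels)) {
    sel <- which(labs == region_labels[k])
    if (!length(sel))
      stop("no voxels carry label ", region_labels[k])
    out[, k] <- if (length(sel) == 1L) vox[sel, ] else colMeans(vox[sel, , drop = FALSE])
  }
  colnames(out) <- sprintf("L%d", region_labels)
  raw_timeseries(out, tr_seconds = tr_seconds, subject_id = subject_id,
                 group = group)
}

#' Residual-forming projection matrix
#'
#' Builds the symmetric idempotent projector `R = I - C (C'C)^+ C'` that
#' maps any series onto the orthogonal complement of the confound columns.
#' Rank deficiency in `C` is handled through the pseudoinverse (via SVD).
#'
#' @param confounds Numeric matrix, `n_t` rows x `n_c` confound columns,
#'   with `n_c < n_t`.
#' @return `n_t` x `n_t` projection matrix.
#' @export
residual_forming <- function(confounds) {
  C <- as.matrix(confounds)
  n_t <- nrow(C)
  if (ncol(C) >= n_t)
    stop("number of confounds (", ncol(C), ") must be smaller than the ",
         "number of time-points (", n_t, ")")
  s <- svd(C)
  keep <- s$d > max(dim(C)) * max(s$d, 0) * .Machine$double.eps
  if (!any(keep)) return(diag(n_t))
  U <- s$u[, keep, drop = FALSE]
  diag(n_t) - tcrossprod(U)
}

#' Discrete-cosine drift basis
#'
#' Low-frequency discrete cosine basis used for high-pass filtering: the
#' `K = floor(2 * n_t * tr / cutoff)` slowest non-constant DCT-II basis
#' functions, i.e. those whose period exceeds the cutoff.
#'
#' @param n_t Number of time-points (at least 2).
#' @param tr_seconds Repetition time in seconds.
#' @param cutoff_seconds High-pass cutoff period in seconds (default 128);
#'   must exceed `2 * tr_seconds`.
#' @param k Optional override of the number of basis functions (e.g. to
#'   force exactly 5 regardless of geometry).
#' @return `n_t` x `K` matrix of mutually orthogonal drift regressors; a
#'   zero-column matrix (with a warning) when no frequency falls below the
#'   cutoff.
#' @export
dct_drift_basis <- function(n_t, tr_seconds, cutoff_seconds = 128, k = NULL) {
  if (n_t < 2L) stop("n_t must be at least 2")
  if (cutoff_seconds <= 2 * tr_seconds)
    stop("cutoff period must exceed twice the repetition time")
  K <- if (is.null(k)) floor(2 * n_t * tr_seconds / cutoff_seconds)
       else as.integer(k)
  if (K <= 0L) {
    warning("cutoff period longer than twice the scan duration; ",
            "no drift regressors generated")
    return(matrix(numeric(0), nrow = n_t, ncol = 0L))
  }
  t_idx <- seq_len(n_t) - 1L
  out <- vapply(seq_len(K), function(kk)
    cos(pi * (2 * t_idx + 1) * kk / (2 * n_t)), numeric(n_t))
  colnames(out) <- sprintf("dct%02d", seq_len(K))
  out
}

#' Remove motion and slow-drift confounds from a regional time-series
#'
#' Applies two sequential residualizations to every region: first the motion
#' parameters (always augmented with an intercept column, so the series is
#' demeaned), then the discrete-cosine drift basis. Before the second step
#' the drift basis is itself residualized against the motion confounds, so
#' the drift projection cannot reintroduce motion components: the sequence
#' equals the joint projection onto the complement of the combined confound
#' span, and cleaning is idempotent. The global signal and task regressors
#' are deliberately not removed.
#'
#' @param raw An `fc_timeseries` (see [raw_timeseries()]).
#' @param motion Optional `n_t` x `n_c` matrix of motion parameters (the
#'   6-column realignment dialect, but any column count below `n_t` works).
#' @param cutoff_seconds High-pass cutoff period for [dct_drift_basis()].
#' @param dct_k Optional override of the drift-basis size.
#' @return An `fc_timeseries` with confound-removed data and an updated
#'   provenance trail.
#' @export
clean_timeseries <- function(raw, motion = NULL, cutoff_seconds = 128,
                             dct_k = NULL) {
  stopifnot(inherits(raw, "fc_timeseries"))
  X <- raw$data
  n_t <- nrow(X)
  prov <- raw$provenance

  mot <- cbind(intercept = rep(1, n_t))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_t)
      stop("motion matrix has ", nrow(motion), " rows but the series has ",
           n_t, " time-points")
    mot <- cbind(mot, motion)
  }
  R_mot <- residual_forming(mot)
  X <- R_mot %*% X
  prov <- c(prov, sprintf("motion+intercept residualization (%d columns)",
                          ncol(mot)))

  dct <- dct_drift_basis(n_t, raw$tr_seconds, cutoff_seconds, k = dct_k)
  if (ncol(dct) > 0L) {
    # orthogonalize the drift basis against the removed confounds so the
    # second projection stays inside their orthogonal complement
    X <- residual_forming(R_mot %*% dct) %*% X
    prov <- c(prov, sprintf("DCT high-pass (%d regressors, cutoff %gs)",
                            ncol(dct), cutoff_seconds))
  }

  out <- raw
  out$data <- X
  out$provenance <- prov
  out
}
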