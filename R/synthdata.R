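# Synthetic two-group data with known sparse-precision differences, so the
# whole pipeline (preprocessing -> features -> nested CV -> inference) can be
# validated end to end without any external data.

pd_enforce <- function(M, floor = 0.05) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= floor) {
    delta <- abs(min(ev)) + floor
    M <- M + delta * diag(nrow(M))
    attr(M, "diag_inflation") <- delta
  }
  M
}

#' Random sparse positive-definite precision matrix
#'
#' Off-diagonal support is drawn uniformly over region pairs (support size
#' `round(density * q)` of the `q = n_p (n_p - 1)/2` pairs); nonzero values
#' are uniform in magnitude on `[0.2, 0.4]` with random sign, and the
#' diagonal is set to 1 plus each row's absolute off-diagonal sum, which
#' guarantees strict diagonal dominance and hence positive definiteness.
#'
#' @param n_p Number of regions.
#' @param density Fraction of off-diagonal pairs that are nonzero, in
#'   `[0, 1]`.
#' @param seed Random seed.
#' @return Precision matrix with attribute `support` (two-column index
#'   matrix of the planted pairs, `i > j`).
#' @export
random_sparse_precision <- function(n_p, density, seed = 1) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  set.seed(seed)
  q <- n_p * (n_p - 1) / 2
  n_edges <- round(density * q)
  pairs <- which(lower.tri(diag(n_p)), arr.ind = TRUE)
  A <- matrix(0, n_p, n_p)
  sel <- if (n_edges > 0) sample.int(q, n_edges) else integer(0)
  for (k in sel) {
    val <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.2, 0.4)
    A[pairs[k, 1L], pairs[k, 2L]] <- val
    A[pairs[k, 2L], pairs[k, 1L]] <- val
  }
  diag(A) <- 1 + rowSums(abs(A))
  attr(A, "support") <- pairs[sel, , drop = FALSE]
  A
}

#' Perturb a precision matrix on a known set of edges
#'
#' Creates a second group's template that differs from the base on exactly
#' `n_diff_edges` off-diagonal pairs, each changed symmetrically by
#' `+/- effect`. By default the planted pairs are drawn from the zero
#' entries of the base (edges present in one group and absent in the
#' other); positive definiteness is restored by minimal diagonal inflation
#' when needed, with the smallest eigenvalue floored at 0.05 so that the
#' implied covariance stays on a usable scale.
#'
#' @param base Precision matrix (e.g. from [random_sparse_precision()]).
#' @param n_diff_edges Number of differing region pairs.
#' @param effect Magnitude of the planted precision difference.
#' @param seed Random seed.
#' @param candidates `"zero"` to plant on empty edges of the base,
#'   `"any"` for all off-diagonal pairs.
#' @return A list with `A` (the base, possibly diagonal-inflated), `B`
#'   (the perturbed template), and `planted` (two-column index matrix,
#'   `i > j`).
#' @export
perturb_precision <- function(base, n_diff_edges, effect, seed = 1,
                              candidates = c("zero", "any")) {
  candidates <- match.arg(candidates)
  set.seed(seed)
  n_p <- nrow(base)
  pairs <- which(lower.tri(diag(n_p)), arr.ind = TRUE)
  if (candidates == "zero") {
    zero <- base[lower.tri(base)] == 0
    pairs <- pairs[zero, , drop = FALSE]
  }
  if (nrow(pairs) < n_diff_edges)
    stop("only ", nrow(pairs), " candidate edges for ", n_diff_edges,
         " planted differences")
  sel <- pairs[sample.int(nrow(pairs), n_diff_edges), , drop = FALSE]
  B <- base
  for (k in seq_len(nrow(sel))) {
    s <- sample(c(-1, 1), 1L)
    B[sel[k, 1L], sel[k, 2L]] <- B[sel[k, 1L], sel[k, 2L]] + s * effect
    B[sel[k, 2L], sel[k, 1L]] <- B[sel[k, 1L], sel[k, 2L]]
  }
  B <- pd_enforce(B)
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("could not keep the perturbed precision positive definite; ",
         "reduce the effect size")
  list(A = base, B = B, planted = sel[, c("row", "col"), drop = FALSE])
}

#' Simulate one subject's regional time-series from a precision template
#'
#' Draws `n_t` i.i.d. samples from the zero-mean Gaussian whose covariance
#' is the inverse of a subject-specific precision: the template's nonzero
#' off-diagonals are jittered with Gaussian noise of sd `subject_noise`
#' (positive definiteness restored by diagonal inflation). Optionally adds
#' slow cosine drifts and motion-correlated components together with a
#' matching 6-column motion-parameter matrix.
#'
#' @param precision Group precision template (positive definite).
#' @param n_t Number of time-points.
#' @param tr_seconds Repetition time.
#' @param subject_noise Between-subject jitter sd on the nonzero entries.
#' @param drift_amplitude Amplitude of added low-frequency drifts, as a
#'   multiple of the signal sd (0 disables).
#' @param motion_amplitude Amplitude of an added motion-correlated
#'   component, as a multiple of the signal sd (0 disables).
#' @param ar_phi Optional AR(1) coefficient applied to the innovations to
#'   stress-test the i.i.d. assumption (0 = i.i.d., the default model).
#' @param seed Random seed.
#' @param subject_id,group Passed to [raw_timeseries()].
#' @return An `fc_timeseries`; when `motion_amplitude > 0` the simulated
#'   realignment parameters are attached as field `motion`.
#' @export
simulate_subject <- function(precision, n_t, tr_seconds = 2,
                             subject_noise = 0.05, drift_amplitude = 0,
                             motion_amplitude = 0, ar_phi = 0, seed = 1,
                             subject_id = "subj", group = NA_real_) {
  set.seed(seed)
  n_p <- nrow(precision)
  P <- precision
  if (subject_noise > 0) {
    nz <- which(lower.tri(P) & P != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      jit <- stats::rnorm(nrow(nz), 0, subject_noise)
      for (k in seq_len(nrow(nz))) {
        P[nz[k, 1L], nz[k, 2L]] <- P[nz[k, 1L], nz[k, 2L]] + jit[k]
        P[nz[k, 2L], nz[k, 1L]] <- P[nz[k, 1L], nz[k, 2L]]
      }
    }
    P <- pd_enforce(P)
  }
  Sigma <- solve((P + t(P)) / 2)
  Sigma <- (Sigma + t(Sigma)) / 2
  Z <- matrix(stats::rnorm(n_t * n_p), n_t, n_p)
  if (ar_phi != 0) {
    for (t in 2:n_t) Z[t, ] <- ar_phi * Z[t - 1L, ] +
      sqrt(1 - ar_phi^2) * Z[t, ]
  }
  X <- Z %*% chol(Sigma)
  sig_sd <- mean(apply(X, 2L, stats::sd))

  if (drift_amplitude > 0) {
    t_idx <- seq_len(n_t) - 1L
    n_dr <- 3L
    drift <- vapply(seq_len(n_dr), function(k) {
      period <- stats::runif(1L, 200, 600)  # seconds, below high-pass band
      cos(2 * pi * t_idx * tr_seconds / period + stats::runif(1L, 0, 2 * pi))
    }, numeric(n_t))
    X <- X + drift %*% matrix(stats::rnorm(n_dr * n_p,
                                           sd = drift_amplitude * sig_sd),
                              n_dr, n_p)
  }

  motion <- NULL
  if (motion_amplitude > 0) {
    motion <- apply(matrix(stats::rnorm(n_t * 6L, sd = 0.02), n_t, 6L),
                    2L, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    mix <- matrix(stats::rnorm(6L * n_p), 6L, n_p)
    msd <- mean(apply(motion, 2L, stats::sd))
    X <- X + (motion / msd) %*% mix * (motion_amplitude * sig_sd / sqrt(6))
  }

  out <- raw_timeseries(X, tr_seconds = tr_seconds, subject_id = subject_id,
                        group = group)
  out$motion <- motion
  out
}

#' Specification of a synthetic two-group study
#'
#' Defaults mirror the geometry of a balanced event-related study (19
#' subjects per group, 180 time-points at TR 2 s) on a reduced 20-region
#' parcellation, with 5 region pairs whose precision differs between the
#' groups.
#'
#' @param n_p Number of regions.
#' @param n_t Time-points per subject.
#' @param tr_seconds Repetition time.
#' @param n_per_group Subjects per group.
#' @param base_density Fraction of nonzero off-diagonal precision pairs in
#'   the shared base template.
#' @param n_diff_edges Number of planted differing pairs.
#' @param effect Planted precision-difference magnitude.
#' @param subject_noise Between-subject jitter sd.
#' @param drift_amplitude,motion_amplitude,ar_phi Confound options, see
#'   [simulate_subject()].
#' @param seed Random seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_p = 20, n_t = 180, tr_seconds = 2,
                            n_per_group = 19, base_density = 0.1,
                            n_diff_edges = 5, effect = 0.25,
                            subject_noise = 0.10, drift_amplitude = 0,
                            motion_amplitude = 0, ar_phi = 0, seed = 1) {
  spec <- list(n_p = n_p, n_t = n_t, tr_seconds = tr_seconds,
               n_per_group = n_per_group, base_density = base_density,
               n_diff_edges = n_diff_edges, effect = effect,
               subject_noise = subject_noise,
               drift_amplitude = drift_amplitude,
               motion_amplitude = motion_amplitude, ar_phi = ar_phi,
               seed = seed)
  structure(spec, class = "simulation_spec")
}

#' Container for a two-group time-series dataset
#'
#' @param ts Named list of `fc_timeseries`, one per subject.
#' @param manifest Data frame with columns `subject_id` and `group`.
#' @param truth Optional ground-truth record (templates, planted edges).
#' @return An `fc_dataset`.
#' @export
fc_dataset <- function(ts, manifest, truth = NULL) {
  stopifnot(all(as.character(manifest$subject_id) %in% names(ts)))
  structure(list(ts = ts, manifest = manifest, truth = truth),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("fc_dataset: %d subjects (%d patients, %d controls), %d x %d series\n",
              nrow(x$manifest), sum(x$manifest$group == 1),
              sum(x$manifest$group == -1),
              nrow(x$ts[[1L]]$data), ncol(x$ts[[1L]]$data)))
  invisible(x)
}

#' Simulate a balanced two-group dataset with planted precision differences
#'
#' Builds a base sparse precision template, perturbs it on
#' `spec$n_diff_edges` pairs to form the patient template, and simulates
#' `n_per_group` subjects per group ([simulate_subject()], per-subject seeds
#' derived from `spec$seed`). Patients carry label `+1`, controls `-1`.
#'
#' @param spec A [simulation_spec()].
#' @return An `fc_dataset` whose `truth` field records both templates, the
#'   planted edge list (with canonical `"region|region"` names), and the
#'   seeds.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec") || is.list(spec))
  base <- random_sparse_precision(spec$n_p, spec$base_density,
                                  seed = spec$seed)
  pert <- perturb_precision(base, spec$n_diff_edges, spec$effect,
                            seed = spec$seed + 1L)
  region_labels <- sprintf("R%03d", seq_len(spec$n_p))
  planted_names <- apply(pert$planted, 1L, function(rc)
    paste(region_labels[rc[2L]], region_labels[rc[1L]], sep = "|"))

  ids <- character(0); groups <- numeric(0); ts <- list()
  templates <- list(`1` = pert$B, `-1` = pert$A)
  for (g in c(1, -1)) {
    for (s in seq_len(spec$n_per_group)) {
      id <- sprintf("%s%02d", if (g == 1) "pat" else "ctl", s)
      seed_s <- spec$seed + 1000L * (g == 1) + s
      subj <- simulate_subject(templates[[as.character(g)]], spec$n_t,
                               tr_seconds = spec$tr_seconds,
                               subject_noise = spec$subject_noise,
                               drift_amplitude = spec$drift_amplitude,
                               motion_amplitude = spec$motion_amplitude,
                               ar_phi = spec$ar_phi, seed = seed_s,
                               subject_id = id, group = g)
      colnames(subj$data) <- region_labels
      ts[[id]] <- subj
      ids <- c(ids, id); groups <- c(groups, g)
    }
  }
  manifest <- data.frame(subject_id = ids, group = groups,
                         stringsAsFactors = FALSE)
  fc_dataset(ts, manifest,
             truth = list(spec = unclass(spec),
                          precision_patient = pert$B,
                          precision_control = pert$A,
                          planted = pert$planted,
                          planted_edges = planted_names))
}
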