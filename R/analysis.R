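#' Instantaneous phase via the analytic signal
#'
#' Removes the mean, forms the analytic signal through the FFT (zeroing the
#' negative frequencies and doubling the positive ones) and returns its
#' argument per sample, in `(-pi, pi]`.
#'
#' @param signal Real time series of length >= 4, non-constant after mean
#'   removal.
#' @return Numeric vector of instantaneous phases.
#' @export
hilbert_phase <- function(signal) {
  n <- length(signal)
  if (n < 4) stop("signal must have at least 4 samples", call. = FALSE)
  x <- signal - mean(signal)
  if (stats::sd(x) == 0 || !all(is.finite(x)))
    stop("degenerate signal: zero variance after mean removal", call. = FALSE)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  ph <- Arg(stats::fft(X * w, inverse = TRUE) / n)
  ph[ph <= -pi] <- pi  # principal value in (-pi, pi]
  ph
}

# phase matrix (samples x nodes) of an Ex record after transient removal
hilbert_phases <- function(EX, transient = 0.1) {
  keep <- (floor(nrow(EX) * transient) + 1):nrow(EX)
  apply(EX[keep, , drop = FALSE], 2, hilbert_phase)
}

#' Pairwise phase-locking value matrix
#'
#' Entry (i, j) is the modulus of the time average of
#' `exp(1i * (phi_i(t) - phi_j(t)))`: 1 for perfectly locked phases
#' (including a constant lag), 0 for a uniformly drifting phase
#' difference.  The matrix is symmetric with unit diagonal.
#'
#' @param phases Matrix of instantaneous phases, samples x nodes.
#' @return The N x N PLV matrix.
#' @export
plv_matrix <- function(phases) {
  if (is.list(phases)) {
    len <- lengths(phases)
    if (length(unique(len)) != 1)
      stop("phase series must all have the same length", call. = FALSE)
    phases <- do.call(cbind, phases)
  }
  E <- exp(1i * phases)
  M <- Mod(crossprod(Conj(E), E)) / nrow(phases)
  M[M > 1] <- 1
  diag(M) <- 1
  dimnames(M) <- NULL
  M
}

#' Mean phase-locking of the active network
#'
#' The mean of the upper-triangle PLV entries restricted to active node
#' pairs: the scalar synchronisation level of the whole network.
#'
#' @param plv PLV matrix (all nodes).
#' @param active_mask Logical per-node mask; defaults to all active.
#' @return Scalar in `[0, 1]`.
#' @export
network_plv <- function(plv, active_mask = NULL) {
  if (is.null(active_mask)) active_mask <- rep(TRUE, nrow(plv))
  if (sum(active_mask) < 2)
    stop("need at least 2 active nodes for a network PLV", call. = FALSE)
  M <- plv[active_mask, active_mask, drop = FALSE]
  mean(M[upper.tri(M)])
}

#' Kuramoto order parameter series
#'
#' `R(t)` is the modulus of the across-node mean of `exp(1i * phi_i(t))`:
#' 1 when all phases coincide at that instant, 0 for phases spread
#' uniformly on the circle.
#'
#' @param phases Matrix of instantaneous phases, samples x nodes (>= 2
#'   nodes).
#' @return Numeric vector `R(t)` in `[0, 1]`, one value per sample.
#' @export
order_parameter <- function(phases) {
  if (ncol(phases) < 2)
    stop("need at least 2 nodes for an order parameter", call. = FALSE)
  Mod(rowMeans(exp(1i * phases)))
}

#' Coefficient of variation
#'
#' Population standard deviation divided by the mean.  Scale-invariant for
#' positive scalings; undefined for zero-mean series.
#'
#' @param series Real series with non-zero mean.
#' @return Scalar `sigma / mu` (>= 0 for positive-mean series).
#' @export
coefficient_of_variation <- function(series) {
  m <- mean(series)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  sqrt(mean((series - m)^2)) / m
}

#' Glutamate load summary of a trajectory
#'
#' The headline glutamate series is the sum of the per-node glutamate over
#' active nodes (a 50-node pre-treatment network plateaus near 300 on this
#' scale).  The summary reports its maximum and the mean over the final
#' quarter of samples.
#'
#' @param traj An `epi_trajectory`.
#' @return List with `glu_peak` and `glu_plateau`.
#' @export
glutamate_summary <- function(traj) {
  act <- traj$net$active_mask
  gs <- rowSums(traj$Glu[, act, drop = FALSE])
  nlast <- floor(nrow(traj$Glu) * 0.75)
  list(glu_peak = max(gs), glu_plateau = mean(gs[(nlast + 1):length(gs)]))
}

# across-active-node summed glutamate series
glutamate_series <- function(traj) {
  rowSums(traj$Glu[, traj$net$active_mask, drop = FALSE])
}

#' Synchronisation report of a trajectory
#'
#' Computes the Hilbert phases of the active nodes' excitatory series
#' (after dropping an initial transient), the pairwise PLV matrix, the
#' network PLV, the Kuramoto order-parameter series, the coefficient of
#' variation of the chosen synchrony series, and the glutamate load
#' summary.
#'
#' @param traj An `epi_trajectory`.
#' @param transient Fraction of initial samples dropped before phase
#'   extraction (default 0.1).
#' @param cv_on Series the CV is computed on: `"order"` (Kuramoto order
#'   parameter, default) or `"mean_ex"` (across-node mean excitatory
#'   signal).
#' @return An object of class `epi_sync_report`: list with `plv`
#'   (full-size matrix, `NA` rows/columns for inactive nodes),
#'   `network_plv`, `order_series`, `cv`, `glu_peak`, `glu_plateau`,
#'   `active_mask`, `transient` and `cv_on`.
#' @export
sync_report <- function(traj, transient = 0.1,
                        cv_on = c("order", "mean_ex")) {
  cv_on <- match.arg(cv_on)
  act <- traj$net$active_mask
  ph <- hilbert_phases(traj$Ex[, act, drop = FALSE], transient = transient)
  Msub <- plv_matrix(ph)
  M <- matrix(NA_real_, traj$net$n_nodes, traj$net$n_nodes)
  M[act, act] <- Msub
  rs <- order_parameter(ph)
  cv_series <- if (cv_on == "order") rs else {
    keep <- (floor(nrow(traj$Ex) * transient) + 1):nrow(traj$Ex)
    rowMeans(traj$Ex[keep, act, drop = FALSE])
  }
  gs <- glutamate_summary(traj)
  structure(
    list(plv = M, network_plv = mean(Msub[upper.tri(Msub)]),
         order_series = rs, cv = coefficient_of_variation(cv_series),
         glu_peak = gs$glu_peak, glu_plateau = gs$glu_plateau,
         active_mask = act, transient = transient, cv_on = cv_on),
    class = "epi_sync_report")
}

#' @export
print.epi_sync_report <- function(x, ...) {
  cat(sprintf(
    "<epi_sync_report> network PLV %.3f, CV %.3f, glu peak %.1f / plateau %.1f\n",
    x$network_plv, x$cv, x$glu_peak, x$glu_plateau))
  invisible(x)
}

#' Tidy the pairwise PLV entries of a report
#'
#' @param x An `epi_sync_report`.
#' @param ... Unused.
#' @return Tibble with columns `node_i`, `node_j` (active pairs, i < j) and
#'   `plv`.
#' @export
tidy.epi_sync_report <- function(x, ...) {
  idx <- which(upper.tri(x$plv) & !is.na(x$plv), arr.ind = TRUE)
  tibble::tibble(node_i = idx[, 1], node_j = idx[, 2],
                 plv = x$plv[idx])
}

#' One-row summary of a synchronisation report
#'
#' @param x An `epi_sync_report`.
#' @param ... Unused.
#' @return Tibble with `network_plv`, `cv`, `glu_peak`, `glu_plateau`,
#'   `n_active`.
#' @export
glance.epi_sync_report <- function(x, ...) {
  tibble::tibble(network_plv = x$network_plv, cv = x$cv,
                 glu_peak = x$glu_peak, glu_plateau = x$glu_plateau,
                 n_active = sum(x$active_mask))
}

#' Write a synchronisation report to disk
#'
#' Writes the scalar summary as JSON and the PLV matrix and order-parameter
#' series as CSV files next to it.
#'
#' @param report An `epi_sync_report`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default "sync").
#' @return The JSON path, invisibly.
#' @export
write_sync_report <- function(report, dir, stem = "sync") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plv_csv <- file.path(dir, paste0(stem, "_plv.csv"))
  ord_csv <- file.path(dir, paste0(stem, "_order.csv"))
  utils::write.csv(report$plv, plv_csv, row.names = FALSE)
  utils::write.csv(data.frame(sample = seq_along(report$order_series),
                              R = report$order_series),
                   ord_csv, row.names = FALSE)
  js <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(network_plv = report$network_plv, cv = report$cv,
         glu_peak = report$glu_peak, glu_plateau = report$glu_plateau,
         n_active = sum(report$active_mask), transient = report$transient,
         cv_on = report$cv_on,
         files = list(plv = basename(plv_csv), order = basename(ord_csv))),
    js, auto_unbox = TRUE, digits = NA)
  invisible(js)
}
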