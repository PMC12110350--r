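#' Discharge-mode gallery
#'
#' Simulates the network with every node set to the same discharge mode,
#' for modes 1-4, reproducing the four qualitative regimes: mode 1
#' quiescent, modes 2-3 oscillatory (mode 2 larger and faster than mode 3),
#' mode 4 saturated with glutamate that rises and then stabilises.  The
#' gallery runs on a coupled small-world network by default (`n_nodes`
#' can be lowered, and `coupled = FALSE` gives isolated nodes).
#'
#' @param params Base `epi_params`.
#' @param seed Integer seed (network and initial conditions).
#' @param n_nodes Network size for the gallery (default 50).
#' @param coupled Keep the small-world edges (default) or drop them.
#' @return A tibble with one row per mode: columns `mode`, `trajectory`
#'   (list column), `quiescent`, `oscillatory`, `saturated` (classifier
#'   flags), `ex_amplitude`, `crossing_rate` (mean-crossings of the
#'   mean-node excitatory signal per time unit), `glu_range`,
#'   `glu_plateau`.
#' @export
run_mode_gallery <- function(params = model_params(), seed = 1,
                             n_nodes = 50, coupled = TRUE) {
  cfg <- default_config()
  net <- ws_network(n_nodes, cfg$n0, cfg$p_rewire, seed = seed)
  if (!coupled) {
    A <- matrix(0L, n_nodes, n_nodes)
    net <- as_epi_network(A)
  }
  rows <- purrr::map(1:4, function(m) {
    modes <- structure(list(mode_of_node = rep(m, n_nodes),
                            scheme = "gallery"), class = "epi_modes")
    tr <- simulate_network(net, params, modes = modes, seed = seed + m)
    cls <- classify_discharge(tr)
    tibble::tibble(mode = m, trajectory = list(tr),
                   quiescent = cls$quiescent, oscillatory = cls$oscillatory,
                   saturated = cls$saturated, ex_amplitude = cls$amplitude,
                   crossing_rate = cls$crossing_rate,
                   glu_range = cls$glu_range, glu_plateau = cls$glu_plateau)
  })
  dplyr::bind_rows(rows)
}

# qualitative classification of a (single-mode) trajectory
classify_discharge <- function(traj, quiet_tol = 0.5) {
  n <- nrow(traj$Ex)
  post <- (floor(n * 0.25) + 1):n
  lastq <- (floor(n * 0.75) + 1):n
  firstq <- post[seq_along(lastq)]
  act <- traj$net$active_mask
  mex <- rowMeans(traj$Ex[, act, drop = FALSE])
  gs <- glutamate_series(traj)
  em <- mex[post] - mean(mex[post])
  amplitude <- diff(range(mex[post]))
  crossings <- sum(diff(sign(em)) != 0)
  crossing_rate <- crossings / (length(post) * traj$params$dt)
  glu_range <- diff(range(gs[post]))
  glu_plateau <- mean(gs[lastq])
  # quiescent: flat discharge and (post-transient) glutamate pinned at zero
  quiescent <- amplitude < quiet_tol && max(abs(gs[post])) < quiet_tol
  oscillatory <- !quiescent && crossings >= 3
  # saturated: a sustained glutamate plateau -- the summed concentration
  # never falls far below its peak, unlike the deep swings of burst cycles
  saturated <- !quiescent &&
    glu_plateau > quiet_tol &&
    min(gs[post]) > 0.45 * max(gs)
  list(quiescent = quiescent, oscillatory = oscillatory,
       saturated = saturated, amplitude = amplitude,
       crossing_rate = crossing_rate, glu_range = glu_range,
       glu_plateau = glu_plateau)
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + p) %% 2147483629
  as.integer(s + 1)
}

#' Sweep stimulation over node counts or intensities
#'
#' Runs the stimulation experiment of the paper's protocol: for every
#' waveform kind, grid point and replicate, a fresh stimulation-scheme
#' small-world network is built, the stimulus is applied to the top-degree
#' nodes, the network is simulated and the network PLV of the excitatory
#' phases is recorded.  When sweeping the number of stimulated nodes the
#' intensity is fixed at `fixed_z` (0.1); when sweeping the intensity the
#' node count is fixed at `fixed_n` (20).
#'
#' @param axis `"n_targets"` or `"intensity"`.
#' @param n_nodes Network size (50 or 100; mode allocation scales
#'   proportionally).
#' @param kinds Waveform kinds to run.
#' @param grid Sweep grid; defaults to 0..30 step 2 nodes, or 30 intensity
#'   steps from 0.01 to 0.3.
#' @param replicates Networks (seeds) per grid point (default 10).
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param fixed_z Intensity used on the node-count axis.
#' @param fixed_n Node count used on the intensity axis.
#' @param params Base `epi_params`.
#' @return A tibble of class `epi_sweep` with columns `kind`, `axis`,
#'   `grid_value`, `replicate`, `seed`, `network_plv`.
#' @export
run_stimulation_sweep <- function(axis = c("n_targets", "intensity"),
                                  n_nodes = 50,
                                  kinds = c("random", "sine", "square"),
                                  grid = NULL, replicates = 10, seed = 1,
                                  fixed_z = 0.1, fixed_n = 20,
                                  params = model_params()) {
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "n_targets") seq(0, 30, by = 2)
            else seq(0.01, 0.3, length.out = 30)
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing", call. = FALSE)
  scale <- n_nodes / 50
  cfg <- default_config()
  cases <- tidyr::expand_grid(kind = kinds, grid_value = grid,
                              replicate = seq_len(replicates))
  res <- purrr::pmap(cases, function(kind, grid_value, replicate) {
    # network and run seeds are shared across waveform kinds so that the
    # kinds are compared on identical network realisations (paired design)
    rs <- derive_seed(seed, round(1000 * grid_value), replicate)
    net <- ws_network(n_nodes, cfg$n0, cfg$p_rewire, seed = rs)
    modes <- assign_modes(net, "stimulation")
    if (axis == "n_targets") {
      nt <- round(grid_value * scale); z <- fixed_z
    } else {
      nt <- round(fixed_n * scale); z <- grid_value
    }
    sp <- stimulus_spec(kind, intensity = z, n_targets = nt,
                        seed = rs + match(kind, c("random", "sine", "square")))
    tr <- simulate_network(net, params, modes = modes, stimulus = sp,
                           seed = rs + 2L)
    rep_ <- sync_report(tr)
    tibble::tibble(kind = kind, axis = axis, grid_value = grid_value,
                   replicate = replicate, seed = rs,
                   network_plv = rep_$network_plv)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("epi_sweep", class(out))
  attr(out, "replicates") <- replicates
  out
}

#' Compare surgical resection plans
#'
#' For every replicate a fresh surgery-scheme small-world network is built
#' and each requested plan is applied (plan 0 is the pre-surgical
#' baseline): the targeted discharge-mode groups are deactivated, the
#' remaining network is simulated, and the glutamate load, network PLV and
#' coefficient of variation are recorded.
#'
#' @param n_nodes Network size (mode allocation scales proportionally).
#' @param plans Subset of 0:4.
#' @param replicates Networks (seeds) per plan.
#' @param seed Master seed.
#' @param params Base `epi_params`.
#' @return A tibble of class `epi_resection` with columns `plan`,
#'   `replicate`, `seed`, `n_active`, `glu_peak`, `glu_plateau`,
#'   `network_plv`, `cv`.
#' @export
run_resection_experiment <- function(n_nodes = 50, plans = 0:4,
                                     replicates = 10, seed = 1,
                                     params = model_params()) {
  if (!all(plans %in% 0:4)) stop("`plans` must be a subset of 0:4",
                                 call. = FALSE)
  cases <- tidyr::expand_grid(plan = plans, replicate = seq_len(replicates))
  cfg <- default_config()
  res <- purrr::pmap(cases, function(plan, replicate) {
    rs <- derive_seed(seed, 77, replicate)
    net <- ws_network(n_nodes, cfg$n0, cfg$p_rewire, seed = rs)
    modes <- assign_modes(net, "surgery")
    cut <- resect(net, modes, plan)
    tr <- simulate_network(cut, params, modes = modes, seed = rs + 3L)
    rep_ <- sync_report(tr)
    tibble::tibble(plan = plan, replicate = replicate, seed = rs,
                   n_active = sum(cut$active_mask),
                   glu_peak = rep_$glu_peak, glu_plateau = rep_$glu_plateau,
                   network_plv = rep_$network_plv, cv = rep_$cv)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("epi_resection", class(out))
  attr(out, "replicates") <- replicates
  out
}

#' Write experiment results with a reproducibility manifest
#'
#' Writes each result table as a tidy CSV with a deterministic name and a
#' single JSON manifest echoing the configuration, the seeds used and the
#' package version, so that a rerun from the manifest is bit-for-bit
#' identical.
#'
#' @param results Named list of tibbles (e.g. `list(sweep = ..., resection
#'   = ...)`); may be empty, in which case only the manifest is written.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list echoed into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(results, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop(sprintf("cannot create output directory '%s'", out_dir),
           call. = FALSE)
  }
  files <- list()
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE)
    files[[nm]] <- basename(f)
  }
  seeds <- sort(unique(unlist(
    purrr::map(results, function(r) if ("seed" %in% names(r)) r$seed))))
  manifest <- list(
    package = "epiastro",
    version = as.character(utils::packageVersion("epiastro")),
    config = config, files = files, seeds = seeds)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}
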