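#' Specify an external stimulation waveform
#'
#' Describes the additive stimulus `S(t)` delivered to the excitatory
#' population of the highest-degree nodes.  Three waveforms are available:
#' `random` draws a fresh value uniformly from `[-z, z]` at every
#' integration step (zero mean, so no DC bias), `sine` is
#' `z * sin(2 pi t / period)`, and `square` is the unipolar pulse train
#' that equals `z` while the fractional phase is below `duty` and 0
#' otherwise.
#'
#' @param kind One of `"none"`, `"random"`, `"sine"`, `"square"`.
#' @param intensity Amplitude `z` (>= 0).
#' @param n_targets Number of stimulated high-degree nodes.
#' @param period Waveform period in time units (periodic kinds; > 0).
#' @param duty Square-wave on-fraction in (0, 1).
#' @param seed Seed for the random waveform (`NULL` to inherit the run
#'   seed).
#' @return An object of class `epi_stimulus`.
#' @export
stimulus_spec <- function(kind = c("none", "random", "sine", "square"),
                          intensity = 0.1, n_targets = 0, period = 10,
                          duty = 0.5, seed = NULL) {
  kind <- match.arg(kind)
  if (intensity < 0) stop("`intensity` must be non-negative", call. = FALSE)
  if (n_targets < 0) stop("`n_targets` must be non-negative", call. = FALSE)
  if (kind %in% c("sine", "square") && period <= 0)
    stop("`period` must be positive for periodic waveforms", call. = FALSE)
  if (kind == "square" && (duty <= 0 || duty >= 1))
    stop("`duty` must lie in (0, 1)", call. = FALSE)
  structure(list(kind = kind, intensity = intensity,
                 n_targets = as.integer(n_targets), period = period,
                 duty = duty, seed = seed),
            class = "epi_stimulus")
}

#' @export
print.epi_stimulus <- function(x, ...) {
  cat(sprintf("<epi_stimulus> kind=%s z=%g n=%d\n",
              x$kind, x$intensity, x$n_targets))
  invisible(x)
}

#' Evaluate a stimulation waveform
#'
#' For the `random` kind the waveform is a step function of the integration
#' grid: the draw for step `floor(t / dt) + 1` is returned, reproducibly
#' from the spec's seed.
#'
#' @param spec An `epi_stimulus`.
#' @param t Time(s) at which to evaluate.
#' @param dt Integration step defining the random waveform's redraw grid.
#' @return Stimulus amplitude(s).
#' @export
waveform_value <- function(spec, t, dt = 0.05) {
  z <- spec$intensity
  switch(spec$kind,
    none = rep(0, length(t)),
    sine = z * sin(2 * pi * t / spec$period),
    square = ifelse((t / spec$period) %% 1 < spec$duty, z, 0),
    random = {
      idx <- floor(t / dt) + 1L
      draws <- random_waveform_draws(spec, max(idx), dt)
      draws[idx]
    },
    stop(sprintf("unknown waveform kind '%s'", spec$kind), call. = FALSE))
}

random_waveform_draws <- function(spec, nst, dt) {
  seed <- if (is.null(spec$seed)) 1L else spec$seed
  set.seed(seed)
  stats::runif(nst, -spec$intensity, spec$intensity)
}

#' Wire a stimulus to the top-degree nodes
#'
#' The targets are the first `n_targets` entries of the degree ranking
#' (see [degree_rank()]); all other nodes receive zero.  The waveform is
#' sampled on the integration grid and held constant within each step.
#'
#' @param spec An `epi_stimulus`.
#' @param net An `epi_network`.
#' @param nst Number of integration steps.
#' @param dt Step size.
#' @param default_seed Seed used for the random waveform when the spec has
#'   none of its own.
#' @param targets Optional explicit target nodes (overrides the degree
#'   ranking; used e.g. with a PLV-based selector).
#' @return List with `S` (an `nst` x N stimulus matrix) and `targets`.
#' @export
build_stimulus <- function(spec, net, nst, dt, default_seed = 1,
                           targets = NULL) {
  n_active <- sum(net$active_mask)
  if (spec$n_targets > n_active)
    stop("`n_targets` exceeds the number of active nodes", call. = FALSE)
  if (is.null(targets))
    targets <- utils::head(degree_rank(net), spec$n_targets)
  S <- matrix(0, nst, net$n_nodes)
  if (length(targets) > 0 && spec$kind != "none") {
    tgrid <- (seq_len(nst) - 1) * dt
    w <- if (spec$kind == "random") {
      sp <- spec
      if (is.null(sp$seed)) sp$seed <- default_seed
      random_waveform_draws(sp, nst, dt)
    } else {
      waveform_value(spec, tgrid, dt)
    }
    S[, targets] <- w
  }
  list(S = S, targets = as.integer(targets))
}

#' Rank nodes by their phase-locking row sums in a baseline run
#'
#' An alternative target selector: ranks active nodes by the row sums of
#' the pairwise PLV matrix of an unstimulated baseline trajectory, highest
#' first (ties by ascending index).  Structural degree is the default
#' selector used by [build_stimulus()]; this one operationalises selecting
#' "high-PLV" nodes directly.
#'
#' @param traj A baseline `epi_trajectory`.
#' @param transient Fraction of initial samples dropped before phases.
#' @return Integer vector of active node indices, most phase-locked first.
#' @export
rank_nodes_by_plv <- function(traj, transient = 0.1) {
  act <- traj$net$active_mask
  ph <- hilbert_phases(traj$Ex[, act, drop = FALSE], transient = transient)
  M <- plv_matrix(ph)
  rs <- rowSums(M) - 1
  which(act)[order(-rs, which(act))]
}
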