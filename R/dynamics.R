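#' Sigmoid activation function
#'
#' `f(x) = 1 / (1 + eps^(-x))`, evaluated overflow-safely.  With the model's
#' `eps = 1000` this is a steep logistic: `f(0) = 0.5` and `f` saturates
#' within roughly `|x| < 1`.
#'
#' @param x Activation argument (vectorised).
#' @param eps Sigmoid base (> 1).
#' @return Values in `(0, 1)`, strictly increasing in `x`.
#' @export
sigmoid <- function(x, eps = 1000) {
  stopifnot(eps > 1)
  1 / (1 + exp(-log(eps) * x))
}

#' Astrocyte feedback current
#'
#' The glutamate released by the astrocyte feeds back onto the excitatory
#' population as the current `I_astro = 10 * lambda_a * glu`.
#'
#' @param glu Glutamate concentration.
#' @param lambda_a Astrocyte feedback strength.
#' @return The astrocyte current.
#' @export
astrocyte_current <- function(glu, lambda_a) 10 * lambda_a * glu

#' Calcium level of the astrocyte compartment
#'
#' Calcium follows the firing rate linearly, `Ca = k_ca * f`, with the
#' population rate realised as the sigmoid rate of the excitatory activity
#' (the model's only rate-like quantity).
#'
#' @param ex Excitatory activity.
#' @param k_ca Firing-rate-to-calcium slope.
#' @param eps Sigmoid base.
#' @return Calcium level.
#' @export
calcium <- function(ex, k_ca, eps = 1000) k_ca * sigmoid(ex, eps)

#' Rectified calcium drive of glutamate release
#'
#' `Z = max(0, ca - ca_th)`: glutamate release is driven only by the
#' suprathreshold part of the calcium level.
#'
#' @param ca Calcium level.
#' @param ca_th Calcium threshold.
#' @return Non-negative drive.
#' @export
rectified_drive <- function(ca, ca_th) pmax(0, ca - ca_th)

#' Time-derivative of the network state
#'
#' Evaluates the coupled field equations at one instant.  Per active node:
#' \deqn{dEx/dt = \tau_{ex} (h_{ex} - Ex + C_1 f[Ex] - C_2 f[In] +
#'   c_{net} \sum_j a_{ij} f[Ex_j] + C_u f[I_{astro}]) + S}
#' \deqn{dIn/dt = (h_{in} - In + C_3 Ex) / \tau_{in}}
#' \deqn{dGlu/dt = (-Glu + Z - \kappa h) / \mu, \qquad
#'   dh/dt = (-h + Glu) / \eta}
#' where `Z` is the rectified calcium drive and `f` the sigmoid.  The
#' inhibitory time scale acts as a relaxation time constant, so the mode-1
#' override (`tau_in = 0.001`) makes inhibition track excitation almost
#' instantly and pins the population in a quiescent rest.  Inactive nodes
#' get zero derivatives.
#'
#' @param state List with numeric vectors `Ex`, `In`, `Glu`, `h`.
#' @param params An `epi_params`, or a list of per-node parameter vectors
#'   as produced by mode expansion.
#' @param net An `epi_network`.
#' @param s_now Per-node stimulus value (recycled if scalar).
#' @return List of derivatives with elements `Ex`, `In`, `Glu`, `h`.
#' @export
derivatives <- function(state, params, net, s_now = 0) {
  n <- net$n_nodes
  for (f in c("Ex", "In", "Glu", "h"))
    if (length(state[[f]]) != n)
      stop("state dimension does not match the network", call. = FALSE)
  eps <- if (inherits(params, "epi_params")) params$eps else 1000
  pv <- if (inherits(params, "epi_params")) expand_params(params, NULL, n)
        else params
  s_now <- rep_len(s_now, n)
  fE <- sigmoid(state$Ex, eps)
  fI <- sigmoid(state$In, eps)
  coup <- as.vector(net$adjacency %*% fE)
  ia <- astrocyte_current(state$Glu, pv$lambda_a)
  Z <- rectified_drive(calcium(state$Ex, pv$k_ca, eps), pv$ca_th)
  dEx <- pv$tau_ex * (pv$h_ex - state$Ex + pv$C1 * fE - pv$C2 * fI +
                        pv$c_net * coup + pv$Cu * sigmoid(ia, eps)) + s_now
  dIn <- (pv$h_in - state$In + pv$C3 * state$Ex) / pv$tau_in
  dGlu <- (-state$Glu + Z - pv$kappa * state$h) / pv$mu_glu
  dh <- (-state$h + state$Glu) / pv$eta_h
  inact <- !net$active_mask
  dEx[inact] <- dIn[inact] <- dGlu[inact] <- dh[inact] <- 0
  list(Ex = dEx, In = dIn, Glu = dGlu, h = dh)
}

#' Advance the state by one step
#'
#' `euler` takes `state + dt * derivatives`; `rk4` the classical four-stage
#' update with the stimulus sampled at the stage times through `s_fun`.
#' Raises an error naming the step if the state leaves the finite range.
#'
#' @param state List of state vectors (`Ex`, `In`, `Glu`, `h`).
#' @param params Parameters (see [derivatives()]).
#' @param net An `epi_network`.
#' @param s_now Per-node stimulus at the step start (euler), or a function
#'   of time when `method = "rk4"` and `s_fun` is not given.
#' @param dt Step size (>= 0).
#' @param method `"euler"` or `"rk4"`.
#' @param t Current time (used to sample `s_fun` at RK4 stage times).
#' @param s_fun Optional function `t -> per-node stimulus`.
#' @param step_index Index used in blow-up error messages.
#' @return The advanced state.
#' @export
step_state <- function(state, params, net, s_now = 0, dt,
                       method = c("euler", "rk4"), t = 0, s_fun = NULL,
                       step_index = NA_integer_) {
  method <- match.arg(method)
  if (dt < 0) stop("`dt` must be non-negative", call. = FALSE)
  add <- function(s, d, w) Map(function(a, b) a + w * b, s, d)
  if (method == "euler") {
    out <- add(state, derivatives(state, params, net, s_now), dt)
  } else {
    sf <- if (!is.null(s_fun)) s_fun else function(tt) s_now
    k1 <- derivatives(state, params, net, sf(t))
    k2 <- derivatives(add(state, k1, dt / 2), params, net, sf(t + dt / 2))
    k3 <- derivatives(add(state, k2, dt / 2), params, net, sf(t + dt / 2))
    k4 <- derivatives(add(state, k3, dt), params, net, sf(t + dt))
    out <- Map(function(s, a, b, c, d) s + dt / 6 * (a + 2 * b + 2 * c + d),
               state, k1, k2, k3, k4)
  }
  if (!all(vapply(out, function(v) all(is.finite(v)), TRUE)))
    stop(sprintf("state became non-finite at step %s", step_index),
         call. = FALSE)
  out
}

#' Simulate the coupled network
#'
#' Integrates the astrocyte-neuron field equations over the network from a
#' seeded initial condition, recording all state variables and the stimulus
#' on the output grid `t = 0, dt, ..., t_total`.  The default integrator is
#' forward Euler refined with `n_sub` equal substeps per output step
#' (`n_sub = 10` by default, so an effective step of `dt / 10`), with the
#' inhibitory relaxation advanced by an exact exponential update so that
#' near-instant inhibition (mode 1) remains stable; `method = "rk4"` runs a
#' classical Runge-Kutta integrator instead (useful for convergence
#' checks).  Runs are bitwise reproducible for a fixed seed and method.
#'
#' @param net An `epi_network`.
#' @param params An `epi_params` (base parameters before mode overrides).
#' @param modes Optional `epi_modes` giving per-node discharge modes.
#' @param stimulus Optional `epi_stimulus` specification.
#' @param seed Integer seed for the initial condition (and, unless the
#'   stimulus carries its own seed, the random waveform).
#' @param init `"uniform"` draws the neural states independently from
#'   U(-0.1, 0.1) per node and the glutamate pair from the analogous
#'   uniform range on its concentration scale; `"zero"` starts at the
#'   origin; alternatively a
#'   named list with numeric vectors `Ex`, `In`, `Glu`, `h` gives the
#'   initial condition explicitly.
#' @param method `"euler"` (substepped, default) or `"rk4"`.
#' @param n_sub Number of substeps per output step (euler only).
#' @return An object of class `epi_trajectory`: list with `times`, state
#'   matrices `Ex`, `In`, `Glu`, `h` (samples x nodes), the stimulus record
#'   `S`, the stimulated `targets`, and the run metadata (`params`, `modes`,
#'   `net`, `seed`, `method`, `n_sub`).
#' @examples
#' net <- ws_network(10, 2, 0.2, seed = 1)
#' tr <- simulate_network(net, model_params(t_total = 10), seed = 1)
#' dim(tr$Ex)
#' @export
simulate_network <- function(net, params = model_params(), modes = NULL,
                             stimulus = NULL, seed = 1,
                             init = c("uniform", "zero"),
                             method = c("euler", "rk4"), n_sub = 10) {
  method <- match.arg(method)
  n <- net$n_nodes
  nst <- round(params$t_total / params$dt)
  times <- seq(0, by = params$dt, length.out = nst + 1)

  set.seed(seed)
  if (is.list(init)) {
    stopifnot(all(c("Ex", "In", "Glu", "h") %in% names(init)))
    st <- lapply(init[c("Ex", "In", "Glu", "h")], rep_len, n)
  } else {
    init <- match.arg(init)
    if (init == "uniform") {
      # Ex/In start on the activation scale; the glutamate pair starts on
      # its own concentration scale, a fixed fraction of the suprathreshold
      # calcium range, so that runs are invariant under joint rescaling of
      # (k_ca, ca_th, lambda_a)
      g0 <- 0.07 * (params$k_ca - params$ca_th)
      st <- list(Ex = stats::runif(n, -0.1, 0.1),
                 In = stats::runif(n, -0.1, 0.1),
                 Glu = stats::runif(n, -g0, g0),
                 h = stats::runif(n, -g0, g0))
    } else {
      st <- list(Ex = numeric(n), In = numeric(n), Glu = numeric(n),
                 h = numeric(n))
    }
  }
  for (f in names(st)) st[[f]][!net$active_mask] <- 0

  targets <- integer(0)
  if (!is.null(stimulus) && stimulus$kind != "none" &&
      stimulus$n_targets > 0) {
    built <- build_stimulus(stimulus, net, nst = nst, dt = params$dt,
                            default_seed = seed)
    S <- built$S
    targets <- built$targets
  } else {
    S <- matrix(0, nst, n)
  }

  pv <- expand_params(params, modes, n)

  if (method == "euler") {
    res <- .sim_core(net$adjacency + 0, pv, S, net$active_mask,
                     st$Ex, st$In, st$Glu, st$h, nst, params$dt,
                     as.integer(n_sub), params$eps)
  } else {
    res <- list(Ex = matrix(0, nst + 1, n), In = matrix(0, nst + 1, n),
                Glu = matrix(0, nst + 1, n), h = matrix(0, nst + 1, n))
    res$Ex[1, ] <- st$Ex; res$In[1, ] <- st$In
    res$Glu[1, ] <- st$Glu; res$h[1, ] <- st$h
    cur <- st
    for (s in seq_len(nst)) {
      cur <- step_state(cur, c(pv, list(eps = params$eps)), net,
                        s_now = S[s, ], dt = params$dt, method = "rk4",
                        step_index = s)
      res$Ex[s + 1, ] <- cur$Ex; res$In[s + 1, ] <- cur$In
      res$Glu[s + 1, ] <- cur$Glu; res$h[s + 1, ] <- cur$h
    }
  }

  structure(
    list(times = times, Ex = res$Ex, In = res$In, Glu = res$Glu, h = res$h,
         S = rbind(S, S[nst, , drop = FALSE] * 0), targets = targets,
         params = params, modes = modes, net = net, seed = seed,
         method = method, n_sub = n_sub),
    class = "epi_trajectory")
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf(
    "<epi_trajectory> %d nodes x %d samples (dt = %g, %s), seed %s\n",
    ncol(x$Ex), nrow(x$Ex), x$params$dt, x$method, format(x$seed)))
  invisible(x)
}

#' Derived per-sample series of a trajectory
#'
#' Recomputes the calcium level, the rectified drive and the astrocyte
#' current from the recorded states and parameters.
#'
#' @param traj An `epi_trajectory`.
#' @return List of matrices `Ca`, `Z`, `I_astro` (samples x nodes).
#' @export
derived_series <- function(traj) {
  n <- ncol(traj$Ex)
  pv <- expand_params(traj$params, traj$modes, n)
  Ca <- calcium(traj$Ex, matrix(pv$k_ca, nrow(traj$Ex), n, byrow = TRUE),
                traj$params$eps)
  Z <- rectified_drive(Ca, matrix(pv$ca_th, nrow(traj$Ex), n, byrow = TRUE))
  Ia <- astrocyte_current(traj$Glu,
                          matrix(pv$lambda_a, nrow(traj$Ex), n, byrow = TRUE))
  list(Ca = Ca, Z = Z, I_astro = Ia)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x An `epi_trajectory`.
#' @param derived Also attach the derived `Ca`, `Z` and `I_astro` columns.
#' @param ... Unused.
#' @return A tibble with columns `time`, `node` (1-based), `Ex`, `In`,
#'   `Glu`, `h`, `S` and optionally the derived series.
#' @export
tidy.epi_trajectory <- function(x, derived = FALSE, ...) {
  n <- ncol(x$Ex)
  out <- tibble::tibble(
    time = rep(x$times, n),
    node = rep(seq_len(n), each = length(x$times)),
    Ex = as.vector(x$Ex), In = as.vector(x$In),
    Glu = as.vector(x$Glu), h = as.vector(x$h),
    S = as.vector(x$S))
  if (derived) {
    d <- derived_series(x)
    out$Ca <- as.vector(d$Ca)
    out$Z <- as.vector(d$Z)
    out$I_astro <- as.vector(d$I_astro)
  }
  out
}

#' One-row summary of a trajectory
#'
#' @param x An `epi_trajectory`.
#' @param ... Unused.
#' @return A tibble with the run dimensions and the glutamate load summary
#'   (peak and final-quarter plateau of the across-active-node sum).
#' @export
glance.epi_trajectory <- function(x, ...) {
  gs <- glutamate_summary(x)
  tibble::tibble(
    n_nodes = ncol(x$Ex), n_active = sum(x$net$active_mask),
    n_samples = nrow(x$Ex), dt = x$params$dt, t_total = x$params$t_total,
    method = x$method, seed = x$seed,
    glu_peak = gs$glu_peak, glu_plateau = gs$glu_plateau)
}

#' Write a trajectory as tidy CSV plus a JSON run summary
#'
#' @param traj An `epi_trajectory`.
#' @param csv_path Path of the tidy CSV (time, node, Ex, In, Glu, h, S).
#' @param json_path Optional path of a compact JSON summary (parameters,
#'   seed, glutamate summaries, stimulated targets).
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, json_path = NULL) {
  utils::write.csv(tidy.epi_trajectory(traj), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    gs <- glutamate_summary(traj)
    meta <- list(params = unclass(traj$params), seed = traj$seed,
                 method = traj$method, n_sub = traj$n_sub,
                 targets = traj$targets,
                 glu_peak = gs$glu_peak, glu_plateau = gs$glu_plateau)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
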