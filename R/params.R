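#' Model parameters of the coupled astrocyte-neuron system
#'
#' Builds the full parameter set of the per-node dynamics.  The neural-mass
#' constants (`tau_ex`, `tau_in`, `h_ex`, `h_in`, `C1`, `C2`, `C3`, `Cu`,
#' `eps`) carry their published defaults; the astrocytic constants
#' (`lambda_a`, `k_ca`, `ca_th`, `kappa`, `mu_glu`, `eta_h`) and the network
#' coupling coefficient `c_net` are calibration constants whose shipped
#' values live in the default configuration file
#' (`system.file("extdata", "default-config.yaml", package = "epiastro")`),
#' selected so that the four single-parameter discharge modes and the
#' pre-treatment network signatures are reproduced (see the package
#' vignette for the calibration procedure).
#'
#' @param ... Named overrides of any field.
#' @param config Optional path to a YAML configuration supplying defaults;
#'   `NULL` uses the shipped calibration.
#' @return An object of class `epi_params` (named list of scalars).
#' @examples
#' p <- model_params()
#' p$tau_ex
#' model_params(t_total = 200)$t_total
#' @export
model_params <- function(..., config = NULL) {
  defaults <- default_config(config)
  p <- defaults[param_fields()]
  over <- list(...)
  bad <- setdiff(names(over), param_fields())
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p[names(over)] <- over
  p <- lapply(p, as.numeric)
  validate_params(p)
  structure(p, class = "epi_params")
}

param_fields <- function() {
  c("tau_ex", "tau_in", "h_ex", "h_in", "C1", "C2", "C3", "Cu",
    "lambda_a", "k_ca", "ca_th", "kappa", "mu_glu", "eta_h", "eps",
    "c_net", "dt", "t_total")
}

validate_params <- function(p) {
  pos <- c("tau_ex", "tau_in", "mu_glu", "eta_h", "dt")
  for (f in pos)
    if (p[[f]] <= 0) stop(sprintf("`%s` must be positive", f), call. = FALSE)
  if (p$eps <= 1) stop("`eps` must exceed 1", call. = FALSE)
  if (p$t_total < p$dt) stop("`t_total` must be at least `dt`", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.epi_params <- function(x, ...) {
  cat("<epi_params>\n")
  cat(paste(sprintf("  %-8s %g", names(x), unlist(x)), collapse = "\n"), "\n")
  invisible(x)
}

#' Apply a single-parameter discharge-mode override
#'
#' Each discharge mode is selected by overriding exactly one constant:
#' mode 1 sets `tau_in = 0.001` (near-instant inhibitory tracking: a
#' quiescent pinned rest), mode 2 sets `h_ex = -0.6` (high-frequency large-amplitude
#' oscillation), mode 3 sets `tau_ex = 0.6` (slower, smaller, intermittent
#' oscillation) and mode 4 sets `kappa = 1` (overdamped glutamate recovery,
#' a saturated discharge with plateauing glutamate).  All other fields are
#' untouched, and applying a mode twice equals applying it once.
#'
#' @param params An `epi_params`.
#' @param mode Integer 1-4.
#' @return A modified copy of `params`.
#' @export
apply_mode <- function(params, mode) {
  if (!mode %in% 1:4) stop("`mode` must be 1, 2, 3 or 4", call. = FALSE)
  ov <- mode_overrides()[[as.character(mode)]]
  params[[names(ov)]] <- unname(ov)
  params
}

mode_overrides <- function() {
  list(`1` = c(tau_in = 0.001),
       `2` = c(h_ex = -0.6),
       `3` = c(tau_ex = 0.6),
       `4` = c(kappa = 1))
}

# expand scalar params + mode assignment into per-node parameter vectors
expand_params <- function(params, modes = NULL, n) {
  vec_fields <- setdiff(param_fields(), c("eps", "dt", "t_total"))
  pv <- lapply(params[vec_fields], rep, length.out = n)
  if (!is.null(modes)) {
    m <- modes$mode_of_node
    if (length(m) != n) stop("mode assignment does not match network size",
                             call. = FALSE)
    for (mode in names(mode_overrides())) {
      ov <- mode_overrides()[[mode]]
      sel <- !is.na(m) & m == as.integer(mode)
      pv[[names(ov)]][sel] <- unname(ov)
    }
  }
  pv
}

# ---- configuration -------------------------------------------------------

#' Flat YAML configuration for simulator runs
#'
#' A configuration is a flat named list covering the model constants, the
#' network specification (`n_nodes`, `n0`, `p_rewire`, `net_seed`), the
#' mode-allocation `scheme`, the stimulus fields (`stim_kind`, `stim_z`,
#' `stim_n`, `stim_period`, `stim_duty`, `stim_seed`), the integrator
#' (`method`, `n_sub`, `init`) and the run `seed`.  `default_config()`
#' returns the shipped calibration, optionally overridden by a user file.
#'
#' @param path YAML file path (`NULL` for the shipped defaults).
#' @param cfg A configuration list.
#' @return `default_config()`/`read_config()` return a named list;
#'   `write_config()` returns `path` invisibly.
#' @name config
NULL

#' @rdname config
#' @export
default_config <- function(path = NULL) {
  base <- yaml::read_yaml(system.file("extdata", "default-config.yaml",
                                      package = "epiastro"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(base))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    base[names(user)] <- user
  }
  base
}

#' @rdname config
#' @export
read_config <- function(path) default_config(path)

#' @rdname config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
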