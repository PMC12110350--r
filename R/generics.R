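#' Turn an epiastro object into a tidy tibble
#'
#' Broom-style generic: methods exist for trajectories
#' ([tidy.epi_trajectory()]) and synchronisation reports
#' ([tidy.epi_sync_report()]).
#'
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/run summary of an epiastro object
#'
#' Broom-style generic: methods exist for trajectories and synchronisation
#' reports.
#'
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
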