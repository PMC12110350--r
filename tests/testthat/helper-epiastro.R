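# shared fixtures: small deterministic networks and fast parameter sets

ring4 <- function() ws_network(4, 2, 0, seed = 1)

star4 <- function() {
  A <- matrix(0L, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1L
  as_epi_network(A)
}

# uncoupled single-population "network"
solo_net <- function() as_epi_network(matrix(0L, 1, 1))

# short-run parameters for fast dynamical tests
quick_params <- function(...) model_params(t_total = 20, ...)

all_mode <- function(mode, n) {
  structure(list(mode_of_node = rep(as.integer(mode), n),
                 scheme = "gallery"), class = "epi_modes")
}
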