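#' Build a Watts-Strogatz small-world substrate
#'
#' Constructs the binary symmetric connection matrix of a Watts-Strogatz
#' small-world graph: a ring lattice in which every node is connected to its
#' `n0 / 2` nearest neighbours on each side, followed by single-end rewiring
#' of each lattice edge with probability `p`.  Rewiring moves an edge end to
#' a uniformly drawn node, rejecting self-loops and duplicate edges, and the
#' result is symmetrised, so the edge count of the ring lattice is preserved
#' exactly.
#'
#' @param n Number of nodes (>= 3).
#' @param n0 Ring degree: the initial number of neighbours of each node
#'   (even, `n0 < n`).  `n0 = 2` gives a cycle.
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Integer seed for the rewiring draws.
#' @return An object of class `epi_network`: a list with elements `n_nodes`,
#'   `adjacency` (binary symmetric matrix with zero diagonal), `active_mask`
#'   (logical; resected nodes are `FALSE`), and `seed`.
#' @examples
#' net <- ws_network(50, n0 = 2, p = 0.5, seed = 1)
#' sum(net$adjacency) / 2  # 50 edges, as in the unrewired ring
#' @export
ws_network <- function(n, n0 = 2, p = 0.5, seed = 1) {
  if (n < 3) stop("`n` must be at least 3", call. = FALSE)
  if (n0 %% 2 != 0 || n0 < 2) stop("`n0` must be a positive even ring degree", call. = FALSE)
  if (n0 >= n) stop("`n0` must be smaller than `n`", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)

  A <- matrix(0L, n, n)
  half <- n0 / 2
  for (k in seq_len(half)) {
    i <- seq_len(n)
    j <- ((i - 1 + k) %% n) + 1
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }

  if (p > 0) {
    set.seed(seed)
    for (k in seq_len(half)) {
      for (i in seq_len(n)) {
        j <- ((i - 1 + k) %% n) + 1
        if (A[i, j] == 0L) next  # already rewired away
        if (stats::runif(1) < p) {
          cand <- which(A[i, ] == 0L & seq_len(n) != i)
          cand <- setdiff(cand, j)
          if (length(cand) == 0L) next
          jn <- cand[sample.int(length(cand), 1L)]
          A[i, j] <- A[j, i] <- 0L
          A[i, jn] <- A[jn, i] <- 1L
        }
      }
    }
  }

  new_epi_network(A, active = rep(TRUE, n), seed = seed)
}

new_epi_network <- function(adjacency, active, seed = NA_integer_) {
  validate_adjacency(adjacency, active)
  structure(
    list(n_nodes = nrow(adjacency),
         adjacency = adjacency,
         active_mask = active,
         seed = seed),
    class = "epi_network")
}

validate_adjacency <- function(A, active) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric", call. = FALSE)
  if (length(active) != nrow(A)) stop("active mask length mismatch", call. = FALSE)
  if (any(A[!active, ] != 0) || any(A[, !active] != 0))
    stop("inactive nodes must have zeroed rows and columns", call. = FALSE)
  invisible(TRUE)
}

#' Wrap a user-supplied adjacency matrix
#'
#' @param adjacency Square binary symmetric matrix with zero diagonal.
#' @param active_mask Optional logical per-node mask (default all active).
#' @return An `epi_network`.
#' @export
as_epi_network <- function(adjacency, active_mask = NULL) {
  A <- as.matrix(adjacency)
  storage.mode(A) <- "integer"
  if (is.null(active_mask)) active_mask <- rep(TRUE, nrow(A))
  new_epi_network(A, active_mask)
}

#' @export
print.epi_network <- function(x, ...) {
  cat(sprintf("<epi_network> %d nodes (%d active), %d edges\n",
              x$n_nodes, sum(x$active_mask), sum(x$adjacency) / 2))
  invisible(x)
}

#' Node degrees of a network
#'
#' @param net An `epi_network`.
#' @return Integer vector of degrees (zero for inactive nodes).
#' @export
node_degrees <- function(net) {
  as.integer(rowSums(net$adjacency))
}

#' Rank active nodes by descending degree
#'
#' Ties are broken by ascending node index so that rankings are
#' deterministic and reproducible.
#'
#' @param net An `epi_network`.
#' @return Integer vector: a permutation of the active node indices with
#'   non-increasing degree.
#' @export
degree_rank <- function(net) {
  idx <- which(net$active_mask)
  deg <- node_degrees(net)[idx]
  idx[order(-deg, idx)]
}

mode_scheme_props <- function(scheme) {
  # allocation fractions by discharge mode, taken in degree-rank order
  switch(scheme,
    stimulation = c(`2` = 19 / 50, `3` = 11 / 50, `1` = 20 / 50),
    surgery     = c(`2` = 20 / 50, `3` = 8 / 50, `4` = 2 / 50, `1` = 20 / 50),
    stop(sprintf("unknown mode-allocation scheme '%s'", scheme), call. = FALSE))
}

largest_remainder <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Allocate discharge modes to nodes by degree rank
#'
#' Nodes are ranked by descending degree and split into consecutive groups.
#' Under the `stimulation` scheme the top 38% of nodes carry discharge
#' mode 2, the next 22% mode 3 and the remaining 40% mode 1 (19/11/20 at
#' N = 50).  Under the `surgery` scheme the split is 40% mode 2, 16%
#' mode 3, 4% mode 4 and 40% mode 1 (20/8/2/20 at N = 50).  For sizes where
#' the fractions are not integral, counts are rounded by largest remainder.
#'
#' @param net An `epi_network`.
#' @param scheme `"stimulation"` or `"surgery"`.
#' @return An object of class `epi_modes`: list with `mode_of_node`
#'   (integer per node, `NA` for inactive nodes) and `scheme`.
#' @export
assign_modes <- function(net, scheme = c("stimulation", "surgery")) {
  scheme <- match.arg(scheme)
  props <- mode_scheme_props(scheme)
  rk <- degree_rank(net)
  counts <- largest_remainder(props, length(rk))
  mode_of_node <- rep(NA_integer_, net$n_nodes)
  at <- 1L
  for (g in seq_along(counts)) {
    if (counts[g] == 0L) next
    grp <- rk[at:(at + counts[g] - 1L)]
    mode_of_node[grp] <- as.integer(names(props)[g])
    at <- at + counts[g]
  }
  structure(list(mode_of_node = mode_of_node, scheme = scheme),
            class = "epi_modes")
}

#' @export
print.epi_modes <- function(x, ...) {
  tb <- table(x$mode_of_node)
  cat(sprintf("<epi_modes> scheme '%s': %s\n", x$scheme,
              paste(sprintf("mode %s: %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Surgically resect the node groups of a resection plan
#'
#' Removes every active node carrying the plan's discharge modes: plan 1
#' removes mode-2 nodes, plan 2 mode-3, plan 3 mode-4, and plan 4 all
#' epilepsy-related nodes (modes 2, 3 and 4).  Removed nodes stay in the
#' arrays with zeroed adjacency rows/columns and `active_mask = FALSE`, so
#' node indices remain stable across plans; the submatrix of the remaining
#' nodes is untouched.
#'
#' @param net An `epi_network`.
#' @param modes An `epi_modes` allocated with the `surgery` scheme.
#' @param plan Integer 1-4 (or 0 for no resection).
#' @return The resected `epi_network`.
#' @export
resect <- function(net, modes, plan) {
  if (!plan %in% 0:4) stop("`plan` must be one of 0, 1, 2, 3, 4", call. = FALSE)
  if (!inherits(modes, "epi_modes") || modes$scheme != "surgery")
    stop("`modes` must use the surgery allocation scheme", call. = FALSE)
  drop_modes <- switch(as.character(plan),
    `0` = integer(0), `1` = 2L, `2` = 3L, `3` = 4L, `4` = c(2L, 3L, 4L))
  gone <- which(net$active_mask & modes$mode_of_node %in% drop_modes)
  A <- net$adjacency
  A[gone, ] <- 0L
  A[, gone] <- 0L
  active <- net$active_mask
  active[gone] <- FALSE
  new_epi_network(A, active, seed = net$seed)
}

# ---- adjacency / mode table I/O ------------------------------------------

#' Read and write adjacency matrices and edge lists
#'
#' `read_adjacency()` expects a whitespace-delimited square 0/1 matrix;
#' `read_edge_list()` expects two whitespace-delimited columns of 0-based
#' node indices, one undirected edge per line (`n` may be given when
#' isolated high-index nodes exist).  The writers produce the same formats.
#'
#' @param path File path.
#' @param net An `epi_network`.
#' @param n Number of nodes (edge lists only; default inferred).
#' @return The readers return an `epi_network`; writers return `path`
#'   invisibly.
#' @name adjacency-io
NULL

#' @rdname adjacency-io
#' @export
read_adjacency <- function(path) {
  A <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(A) <- NULL
  as_epi_network(A)
}

#' @rdname adjacency-io
#' @export
write_adjacency <- function(net, path) {
  utils::write.table(net$adjacency, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname adjacency-io
#' @export
read_edge_list <- function(path, n = NULL) {
  e <- utils::read.table(path, header = FALSE)
  if (ncol(e) != 2) stop("edge list must have two columns", call. = FALSE)
  e <- as.matrix(e) + 1L  # 0-based on disk
  if (is.null(n)) n <- max(e)
  A <- matrix(0L, n, n)
  A[e] <- 1L
  A[e[, 2:1, drop = FALSE]] <- 1L
  as_epi_network(A)
}

#' @rdname adjacency-io
#' @export
write_edge_list <- function(net, path) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  utils::write.table(idx - 1L, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write mode-assignment tables
#'
#' Two-column table `node_id` (0-based), `mode`; tab-separated with header.
#'
#' @param modes An `epi_modes`.
#' @param path File path.
#' @param scheme Scheme label to attach on read.
#' @return `read_modes()` returns an `epi_modes`; `write_modes()` returns
#'   `path` invisibly.
#' @name modes-io
NULL

#' @rdname modes-io
#' @export
write_modes <- function(modes, path) {
  d <- data.frame(node_id = seq_along(modes$mode_of_node) - 1L,
                  mode = modes$mode_of_node)
  utils::write.table(d, path, row.names = FALSE, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname modes-io
#' @export
read_modes <- function(path, scheme = "stimulation") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- rep(NA_integer_, max(d$node_id) + 1L)
  m[d$node_id + 1L] <- as.integer(d$mode)
  structure(list(mode_of_node = m, scheme = scheme), class = "epi_modes")
}
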