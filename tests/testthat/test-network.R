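test_that("unrewired ring lattice is the expected cycle", {
  net <- ring4()
  expect_equal(net$n_nodes, 4)
  # 4-cycle: a_ij = 1 iff |i - j| mod 4 in {1, 3}
  expected <- outer(0:3, 0:3, function(i, j) as.integer((abs(i - j) %% 4) %in% c(1, 3)))
  expect_equal(unname(net$adjacency), expected)
  # determinism without randomness
  expect_identical(ws_network(50, 2, 0, seed = 1)$adjacency,
                   ws_network(50, 2, 0, seed = 99)$adjacency)
})

test_that("rewiring preserves edge count, symmetry and zero diagonal", {
  for (p in c(0, 0.5, 1)) {
    for (seed in 1:20) {
      net <- ws_network(50, 2, p, seed = seed)
      A <- net$adjacency
      expect_equal(sum(A) / 2, 50)
      expect_equal(A, t(A))
      expect_true(all(diag(A) == 0))
      expect_true(all(A %in% 0:1))
    }
  }
  # ring degree 4 doubles the edge count
  expect_equal(sum(ws_network(50, 4, 0.5, seed = 3)$adjacency) / 2, 100)
})

test_that("ws_network rejects invalid parameters", {
  expect_error(ws_network(50, 50, 0.5), "n0")
  expect_error(ws_network(50, 2, 1.5), "p")
  expect_error(ws_network(50, 2, -0.1), "p")
  expect_error(ws_network(2, 2, 0.5), "n")
  expect_error(ws_network(50, 3, 0.5), "even")
})

test_that("degree ranking is descending with index tie-break", {
  expect_equal(degree_rank(ring4()), 1:4)      # all degrees equal
  expect_equal(degree_rank(star4())[1], 1)     # hub first
  # ranking length matches active nodes after resection
  net <- ws_network(50, 2, 0.5, seed = 7)
  modes <- assign_modes(net, "surgery")
  cut <- resect(net, modes, 1)
  expect_equal(length(degree_rank(cut)), sum(cut$active_mask))
  # brute-force check on a rewired network
  deg <- rowSums(net$adjacency)
  rk <- degree_rank(net)
  expect_true(all(diff(deg[rk]) <= 0))
})

test_that("mode allocation matches the scheme counts", {
  net <- ws_network(50, 2, 0.5, seed = 11)
  st <- assign_modes(net, "stimulation")
  expect_equal(as.integer(table(st$mode_of_node)[c("1", "2", "3")]),
               c(20L, 19L, 11L))
  su <- assign_modes(net, "surgery")
  expect_equal(as.integer(table(su$mode_of_node)[c("1", "2", "3", "4")]),
               c(20L, 20L, 8L, 2L))
  # proportional scaling at N = 100
  net100 <- ws_network(100, 2, 0.5, seed = 11)
  su100 <- assign_modes(net100, "surgery")
  expect_equal(as.integer(table(su100$mode_of_node)[c("1", "2", "3", "4")]),
               c(40L, 40L, 16L, 4L))
  # groups are taken in degree-rank order: top node carries mode 2
  rk <- degree_rank(net)
  expect_equal(su$mode_of_node[rk[1]], 2L)
  expect_equal(su$mode_of_node[rk[50]], 1L)
  expect_error(assign_modes(net, "unknown"))
})

test_that("mode allocation partitions the active nodes", {
  net <- ws_network(50, 2, 0.5, seed = 3)
  for (scheme in c("stimulation", "surgery")) {
    m <- assign_modes(net, scheme)
    expect_equal(sum(!is.na(m$mode_of_node)), sum(net$active_mask))
  }
})

test_that("resection removes the planned groups and is idempotent", {
  net <- ws_network(50, 2, 0.5, seed = 5)
  modes <- assign_modes(net, "surgery")
  cut1 <- resect(net, modes, 1)
  expect_equal(sum(cut1$active_mask), 30)
  gone <- which(!cut1$active_mask)
  expect_true(all(cut1$adjacency[gone, ] == 0))
  expect_true(all(cut1$adjacency[, gone] == 0))
  keep <- which(cut1$active_mask)
  expect_equal(cut1$adjacency[keep, keep], net$adjacency[keep, keep])
  expect_equal(cut1$adjacency, t(cut1$adjacency))

  cut4 <- resect(net, modes, 4)
  expect_equal(sum(cut4$active_mask), 20)
  expect_equal(sum(resect(net, modes, 2)$active_mask), 42)
  expect_equal(sum(resect(net, modes, 3)$active_mask), 48)

  # idempotence and the plan-0 identity
  expect_identical(resect(cut1, modes, 1), cut1)
  expect_identical(resect(net, modes, 0)$adjacency, net$adjacency)

  expect_error(resect(net, modes, 5), "plan")
  expect_error(resect(net, assign_modes(net, "stimulation"), 1), "surgery")
})

test_that("adjacency, edge-list and mode tables round-trip through disk", {
  net <- ws_network(20, 2, 0.5, seed = 9)
  f1 <- tempfile(fileext = ".mat.txt")
  write_adjacency(net, f1)
  expect_equal(read_adjacency(f1)$adjacency, unname(net$adjacency))

  f2 <- tempfile(fileext = ".edges")
  write_edge_list(net, f2)
  back <- read_edge_list(f2, n = 20)
  expect_equal(back$adjacency, unname(net$adjacency))

  modes <- assign_modes(net, "surgery")
  f3 <- tempfile(fileext = ".tsv")
  write_modes(modes, f3)
  expect_equal(read_modes(f3, "surgery")$mode_of_node, modes$mode_of_node)
})

test_that("invalid adjacency matrices are rejected", {
  A <- matrix(0L, 3, 3); A[1, 2] <- 1L           # asymmetric
  expect_error(as_epi_network(A), "symmetric")
  B <- diag(1L, 3)                               # nonzero diagonal
  expect_error(as_epi_network(B), "diagonal")
  C <- matrix(0L, 3, 3); C[1, 2] <- C[2, 1] <- 2L
  expect_error(as_epi_network(C), "0/1")
})
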