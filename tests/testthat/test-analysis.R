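test_that("hilbert phase tracks a pure tone and stays in the principal range", {
  dt <- 0.05
  t <- seq(0, 100 - dt, by = dt)   # whole periods of a 10-unit tone
  x <- cos(2 * pi * t / 10)
  ph <- hilbert_phase(x)
  expect_true(all(ph > -pi & ph <= pi + 1e-12))
  un <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi)) -
        2 * pi * cumsum(c(0, diff(ph) > pi))
  inner <- 100:1900   # away from the window edges
  slope <- stats::coef(stats::lm(un[inner] ~ t[inner]))[2]
  expect_lt(abs(slope - 2 * pi / 10) / (2 * pi / 10), 0.01)
  expect_error(hilbert_phase(rep(3, 100)), "degenerate")
  expect_error(hilbert_phase(c(1, 2)), "4 samples")
})

test_that("pairwise PLV has its closed-form values", {
  T <- 200
  ph1 <- 2 * pi * (1:T) / 50
  # identical series and a constant lag both give PLV 1
  M <- plv_matrix(cbind(ph1, ph1, ph1 + 1.2))
  expect_equal(M, matrix(1, 3, 3), tolerance = 1e-12)
  # uniformly drifting difference sums the T-th roots of unity: PLV 0
  M2 <- plv_matrix(cbind(ph1, ph1 + 2 * pi * (1:T) / T))
  expect_lt(M2[1, 2], 1e-10)
  expect_error(plv_matrix(list(ph1, ph1[-1])), "length")
})

test_that("PLV matrices are bounded, symmetric with unit diagonal", {
  set.seed(1)
  ph <- matrix(runif(300, -pi, pi), 100, 3)
  M <- plv_matrix(ph)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 3))
})

test_that("white-noise PLV shrinks with the series length", {
  set.seed(7)
  mean_plv <- function(T) {
    mean(replicate(20, {
      M <- plv_matrix(matrix(runif(2 * T, -pi, pi), T, 2))
      M[1, 2]
    }))
  }
  expect_lt(mean_plv(2000), mean_plv(50))
})

test_that("network PLV averages active upper-triangle entries only", {
  expect_equal(network_plv(matrix(1, 4, 4)), 1)
  M <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(network_plv(M), 0.6)   # diagonal excluded
  # masked nodes drop out of the pair set
  M3 <- matrix(0.5, 3, 3); diag(M3) <- 1
  M3[1, 2] <- M3[2, 1] <- 0.9
  expect_equal(network_plv(M3, c(TRUE, TRUE, FALSE)), 0.9)
  expect_error(network_plv(M3, c(TRUE, FALSE, FALSE)), "2 active")
})

test_that("Kuramoto order parameter hits its closed forms", {
  expect_equal(order_parameter(matrix(c(1.3, 1.3, 1.3), 1, 3)), 1)
  expect_equal(order_parameter(matrix(c(0, pi), 1, 2)), 0)
  k <- 8
  expect_lt(order_parameter(matrix(2 * pi * (0:(k - 1)) / k, 1, k)), 1e-12)
  ph <- matrix(runif(50, -pi, pi), 10, 5)
  R <- order_parameter(ph)
  expect_true(all(R >= 0 & R <= 1))
  expect_error(order_parameter(matrix(0, 5, 1)), "2 nodes")
})

test_that("coefficient of variation uses the population deviation", {
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)
  x <- rgamma(100, 3)
  expect_equal(coefficient_of_variation(5 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("glutamate summary reports peak and final-quarter plateau", {
  net <- solo_net()
  tr <- simulate_network(net, quick_params(), seed = 1, init = "zero")
  tr$Glu[] <- 0
  gs <- glutamate_summary(tr)
  expect_equal(gs$glu_peak, 0)
  expect_equal(gs$glu_plateau, 0)
  n <- nrow(tr$Glu)
  tr$Glu[, 1] <- c(seq(0, 10, length.out = floor(n / 2)),
                   rep(10, n - floor(n / 2)))
  gs <- glutamate_summary(tr)
  expect_equal(gs$glu_peak, 10)
  expect_equal(gs$glu_plateau, 10)
  # peak dominates the plateau for arbitrary series
  set.seed(2)
  for (i in 1:10) {
    tr$Glu[, 1] <- rnorm(n)
    gs <- glutamate_summary(tr)
    expect_gte(gs$glu_peak, gs$glu_plateau)
  }
})

test_that("sync reports satisfy their invariants on a real run", {
  net <- ws_network(20, 2, 0.5, seed = 17)
  modes <- assign_modes(net, "stimulation")
  tr <- simulate_network(net, model_params(), modes = modes, seed = 2)
  rp <- sync_report(tr)
  act <- rp$active_mask
  M <- rp$plv[act, act]
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, sum(act)))
  expect_true(rp$network_plv >= 0 && rp$network_plv <= 1)
  expect_gte(rp$cv, 0)
  expect_true(all(rp$order_series >= 0 & rp$order_series <= 1))
  # writing produces the JSON + CSV trio
  d <- tempfile(); js <- write_sync_report(rp, d)
  expect_true(file.exists(js))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$network_plv, rp$network_plv)
  expect_true(file.exists(file.path(d, meta$files$plv)))
})

test_that("PLV is stable against the transient window once settled", {
  net <- ws_network(50, 4, 0.5, seed = 1)
  modes <- assign_modes(net, "stimulation")
  tr <- simulate_network(net, model_params(), modes = modes, seed = 101)
  p10 <- sync_report(tr, transient = 0.1)$network_plv
  p20 <- sync_report(tr, transient = 0.2)$network_plv
  expect_lt(abs(p10 - p20), 0.06)
  # including the settling transient shifts the value only moderately
  p00 <- sync_report(tr, transient = 0)$network_plv
  expect_lt(abs(p10 - p00), 0.15)
})
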