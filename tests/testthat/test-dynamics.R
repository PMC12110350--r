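test_that("sigmoid is the steep logistic with its closed-form values", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1, eps = 1000), 1000 / 1001)
  x <- seq(-3, 3, by = 0.1)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_true(all(sigmoid(c(-1e6, 1e6)) >= 0 & sigmoid(c(-1e6, 1e6)) <= 1))
  expect_error(sigmoid(0, eps = 1))
})

test_that("astrocyte current and calcium follow their definitions", {
  expect_equal(astrocyte_current(0, 5), 0)
  expect_equal(astrocyte_current(7, 0), 0)
  expect_equal(astrocyte_current(2, 0.5), 10)
  expect_equal(calcium(0, 1), 0.5)
  expect_equal(calcium(3, 0), 0)
  ex <- seq(-2, 2, by = 0.05)
  expect_true(all(diff(calcium(ex, 7)) >= 0))
})

test_that("rectified drive is non-negative and piecewise linear", {
  expect_equal(rectified_drive(5, 5), 0)
  expect_equal(rectified_drive(4.8, 5), 0)
  expect_equal(rectified_drive(5.3, 5), 0.3)
  ca <- runif(100, 0, 10)
  expect_true(all(rectified_drive(ca, 5) >= 0))
})

test_that("derivatives at the origin match hand arithmetic", {
  net <- solo_net()
  p <- model_params()
  st <- list(Ex = 0, In = 0, Glu = 0, h = 0)
  d <- derivatives(st, p, net)
  # tau_ex*(h_ex + C1*f(0) - C2*f(0) + Cu*f(0)) = 1.97*(-0.5+0.5-7.5+3)
  expect_equal(d$Ex, 1.97 * (-0.5 + 0.5 - 15 * 0.5 + 6 * 0.5))
  expect_equal(d$Ex, -8.865)
  # inhibitory input relaxes at rate 1/tau_in: (h_in - 0 + 0)/3
  expect_equal(d$In, -1.4 / 3)
  # h = Glu is the fixed point of the recovery equation
  st2 <- list(Ex = 0.3, In = -0.2, Glu = 0.7, h = 0.7)
  expect_equal(derivatives(st2, p, net)$h, 0)
  expect_error(derivatives(list(Ex = c(0, 0), In = 0, Glu = 0, h = 0), p, net),
               "dimension")
})

test_that("network sum enters the excitatory derivative through a_ij", {
  net <- ring4()
  p <- model_params(c_net = 2)
  st <- list(Ex = c(5, 0, 0, 0), In = rep(-10, 4), Glu = rep(0, 4),
             h = rep(0, 4))
  d <- derivatives(st, p, net)
  # node 2 and 4 are neighbours of node 1 (f(5) ~ 1), node 3 is not
  fE <- sigmoid(st$Ex, p$eps)
  coup <- as.vector(net$adjacency %*% fE)
  expect_equal(coup[2], fE[1] + fE[3])
  expect_gt(d$Ex[2], d$Ex[3])
})

test_that("euler step is state plus dt times the derivative", {
  net <- solo_net()
  p <- model_params()
  st <- list(Ex = 0, In = 0, Glu = 0, h = 0)
  expect_identical(step_state(st, p, net, dt = 0, method = "euler"), st)
  s1 <- step_state(st, p, net, dt = 0.05, method = "euler")
  expect_equal(s1$Ex, 0.05 * -8.865)
  d <- derivatives(st, p, net)
  for (f in names(st)) expect_equal(s1[[f]], st[[f]] + 0.05 * d[[f]])
})

test_that("euler converges to rk4 as the step shrinks", {
  net <- solo_net()
  run <- function(dt, method, n_sub = 1) {
    p <- model_params(dt = dt, t_total = 10)
    simulate_network(net, p, seed = 4, init = "zero", method = method,
                     n_sub = n_sub)
  }
  ref <- run(0.005, "rk4")
  sup <- sapply(c(0.05, 0.01, 0.005), function(dt) {
    eu <- run(dt, "euler")
    idx <- seq(1, nrow(eu$Ex))
    tref <- ref$times
    # compare on the coarse grid
    j <- match(round(eu$times, 10), round(tref, 10))
    max(abs(eu$Ex[, 1] - ref$Ex[j, 1]))
  })
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 0.5 * sup[1])
})

test_that("simulation grid, determinism and blow-up reporting behave", {
  net <- ws_network(10, 2, 0.5, seed = 2)
  p <- model_params()
  tr <- simulate_network(net, p, seed = 3)
  expect_equal(nrow(tr$Ex), 2001)   # 2000 steps + initial sample
  expect_equal(tr$times[2001], 100)

  tr2 <- simulate_network(net, p, seed = 3)
  expect_identical(tr$Ex, tr2$Ex)
  expect_identical(tr$Glu, tr2$Glu)

  # zero-noise runs are seed-independent given identical initial conditions
  a <- simulate_network(net, quick_params(), seed = 1, init = "zero")
  b <- simulate_network(net, quick_params(), seed = 2, init = "zero")
  expect_identical(a$Ex, b$Ex)
})

test_that("inactive nodes stay frozen at zero", {
  net <- ws_network(10, 2, 0.5, seed = 2)
  modes <- assign_modes(net, "surgery")
  cut <- resect(net, modes, 4)
  tr <- simulate_network(cut, quick_params(), modes = modes, seed = 5)
  gone <- which(!cut$active_mask)
  expect_true(all(tr$Ex[, gone] == 0))
  expect_true(all(tr$Glu[, gone] == 0))
})

test_that("trajectories tidy into long tibbles with derived series", {
  net <- ws_network(5, 2, 0.2, seed = 1)
  tr <- simulate_network(net, quick_params(), seed = 1)
  td <- tidy(tr, derived = TRUE)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 401 * 5)
  expect_true(all(c("time", "node", "Ex", "In", "Glu", "h", "S",
                    "Ca", "Z", "I_astro") %in% names(td)))
  expect_true(all(td$Z >= 0))
  g <- glance(tr)
  expect_equal(g$n_nodes, 5)
  expect_equal(g$glu_peak, glutamate_summary(tr)$glu_peak)
})
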