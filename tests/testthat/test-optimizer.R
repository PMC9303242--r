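test_that("fitness combines components under the scenario rule", {
  two <- tradeoff_scenario(
    list(make_component("linear", slope = 1),
         make_component("linear", slope = 1)), rule = "multiplicative")
  expect_equal(fitness(two, c(2, 3)), 6)
  add <- tradeoff_scenario(two$components, rule = "additive")
  expect_equal(fitness(add, c(2, 3)), 5)

  s <- load_scenario("fig1_multiplicative")
  expect_equal(fitness(s, c(0.36, 0.64)),
               (1.5 * 0.36 - 0.7 * 0.36^2) * 0.64)
  expect_error(fitness(s, c(1, 2, 3)), "does not match")
  expect_error(fitness(s, c(-1, 2)), "nonnegative")
})

test_that("interior optima match the closed-form first-order conditions", {
  sa <- load_scenario("fig1_additive")
  a <- optimize_allocation(sa, 1)
  expect_equal(a$u[1], u1_additive_closed, tolerance = 1e-8)
  expect_equal(a$x[1], x1_additive_closed, tolerance = 1e-8)
  expect_alloc_valid(a, 1)
  # the additive optimum is budget-independent once interior
  a2 <- optimize_allocation(sa, 1.3)
  expect_equal(a2$u[1], u1_additive_closed, tolerance = 1e-8)

  sm <- load_scenario("fig1_multiplicative")
  m <- optimize_allocation(sm, 1)
  expect_equal(m$u[1], u1_mult_closed_R1, tolerance = 1e-8)
  expect_lt(m$gradient_residual, 1e-6)
  expect_alloc_valid(m, 1)
})

test_that("degenerate and symmetric budgets are handled exactly", {
  sym <- load_scenario("symmetric_linear")
  s <- optimize_allocation(sym, 2)
  expect_equal(s$u, c(1, 1), tolerance = 1e-9)
  expect_equal(s$W, 1, tolerance = 1e-9)

  z <- optimize_allocation(sym, 0)
  expect_equal(z$u, c(0, 0))
  expect_error(optimize_allocation(sym, -1), "nonnegative")

  # overflowing components produce an evaluation error naming the point
  boom <- tradeoff_scenario(
    list(make_component("double-exponential", a = 800),
         make_component("linear", slope = 1)), rule = "multiplicative")
  expect_error(optimize_allocation(boom, 6), "non-finite fitness at u1")
})

test_that("solver matches the brute-force oracle on the worked examples", {
  sym <- load_scenario("symmetric_linear")
  b <- brute_force_allocation(sym, 2, grid_n = 10001)
  expect_lt(abs(b$u[1] - 1), 2e-4)

  sa <- load_scenario("fig1_additive")
  ba <- brute_force_allocation(sa, 1, grid_n = 10001)
  expect_lt(abs(ba$u[1] - u1_additive_closed), 2e-4)

  sm <- load_scenario("fig1_multiplicative")
  bm <- brute_force_allocation(sm, 1, grid_n = 10001)
  om <- optimize_allocation(sm, 1)
  expect_lt(abs(om$W - bm$W), 1e-7)
  expect_gte(om$W, bm$W)
  expect_error(brute_force_allocation(sm, 1, grid_n = 1), "at least 2")
})

test_that("solver beats or ties the grid oracle on random scenarios", {
  classes <- c("decelerating", "linear", "accelerating")
  grid_n <- 10000
  for (seed in 1:50) {
    cl <- classes[(seed %% 3) + 1]
    sc <- random_scenario(seed, cl)
    R_max <- if (cl == "accelerating") 4 else 8
    R <- 0.2 + (seed * 0.61) %% (R_max - 0.2)
    o <- optimize_allocation(sc, R, n_scan = 2048)
    b <- brute_force_allocation(sc, R, grid_n = grid_n)
    expect_gte(o$W, b$W - 1e-7)
    if (!o$multiplicity)
      expect_lte(abs(o$u[1] - b$u[1]), 2 * R / (grid_n - 1))
    expect_alloc_valid(o, R)
  }
})

test_that("interior multiplicative optima equalise selection gradients", {
  for (seed in 1:15) {
    sc <- random_scenario(seed, "decelerating")
    R <- 0.5 + (seed * 0.37) %% 6
    o <- optimize_allocation(sc, R)
    if (all(o$interior_flags)) {
      s1 <- selection_gradient(sc$components[[1]], o$u[1])
      s2 <- selection_gradient(sc$components[[2]], o$u[2])
      expect_lt(abs(s1 - s2), 1e-6)
    }
  }
})

test_that("interior additive optima equalise marginal returns", {
  for (seed in 1:10) {
    sc0 <- random_scenario(seed, "decelerating")
    sc <- tradeoff_scenario(sc0$components, rule = "additive")
    R <- 4 + (seed * 0.53) %% 4
    o <- optimize_allocation(sc, R)
    if (all(o$interior_flags)) {
      d1 <- component_derivative(sc$components[[1]], o$u[1], 1)
      d2 <- component_derivative(sc$components[[2]], o$u[2], 1)
      expect_lt(abs(d1 - d2), 1e-6)
    }
  }
})

test_that("multiplicative optima are invariant to rescaling one component", {
  for (seed in c(3, 11, 19)) {
    sc <- random_scenario(seed, "decelerating")
    R <- 3.3
    base <- optimize_allocation(sc, R)
    for (cfac in c(0.1, 7)) {
      p <- sc$components[[1]]$params
      scaled <- tradeoff_scenario(
        list(make_component("affine-quadratic", c = cfac * p$c,
                            a = cfac * p$a, b = cfac * p$b),
             sc$components[[2]]), rule = "multiplicative")
      o <- optimize_allocation(scaled, R)
      expect_equal(o$u, base$u, tolerance = 1e-8)
      expect_equal(o$W, cfac * base$W, tolerance = 1e-8)
    }
  }
})

test_that("three-component allocation approaches the symmetric optimum", {
  sc <- tradeoff_scenario(
    list(make_component("linear", slope = 1),
         make_component("linear", slope = 1),
         make_component("linear", slope = 1)), rule = "multiplicative")
  o <- optimize_allocation(sc, 3)
  expect_equal(o$u, c(1, 1, 1), tolerance = 1e-3)
  expect_alloc_valid(o, 3)
  b <- brute_force_allocation(sc, 3, grid_n = 301)
  expect_gte(o$W, b$W - 1e-4)
})

test_that("allocation paths annotate jumps and corner segments", {
  s3 <- load_scenario("fig3")
  p <- allocation_path(s3, seq(0, 6, length.out = 501))
  expect_equal(nrow(p$discontinuities), 1)
  mid <- (p$discontinuities$R_low + p$discontinuities$R_high) / 2
  expect_equal(round(mid, 1), 2.9)
  expect_lte(p$discontinuities$R_high - p$discontinuities$R_low, 1e-4)
  # u1 jumps up, u2 down across the discontinuity
  expect_gt(p$discontinuities$u1_high, p$discontinuities$u1_low + 1)
  # corner: no signal at low budgets
  corners1 <- p$corner_segments[p$corner_segments$component == 1, ]
  expect_gte(nrow(corners1), 1)
  expect_equal(corners1$R_low[1], 0)

  sm <- load_scenario("fig1_multiplicative")
  pm <- allocation_path(sm, seq(0.2, 1.4, length.out = 100))
  expect_equal(nrow(pm$discontinuities), 0)
  expect_true(all(diff(pm$table$u_1) > 0))

  # constant paths trivially have no jumps
  sa <- load_scenario("fig1_additive")
  pa <- allocation_path(sa, seq(0.5, 1.4, length.out = 50))
  expect_equal(nrow(pa$discontinuities), 0)
  expect_equal(pa$table$u_1, rep(u1_additive_closed, 50), tolerance = 1e-7)
  expect_error(allocation_path(sa, c(1, 0.5)), "strictly increasing")
})

test_that("marginal-condition diagnostics certify optima and corners", {
  sa <- load_scenario("fig1_additive")
  va <- verify_marginal_conditions(sa, optimize_allocation(sa, 1))
  expect_lt(va$interior_residual, 1e-6)
  expect_true(va$pass)

  sym <- load_scenario("symmetric_linear")
  vs <- verify_marginal_conditions(sym, optimize_allocation(sym, 2))
  expect_lt(vs$interior_residual, 1e-9)

  # fig3 at R = 1 is a no-signal corner: S2(u2) >= S1(0) must hold
  s3 <- load_scenario("fig3")
  a3 <- optimize_allocation(s3, 1)
  expect_equal(a3$u[1], 0)
  v3 <- verify_marginal_conditions(s3, a3)
  expect_true(v3$pass)
  expect_equal(v3$corner_checks$component, 1)
  s2_at_1 <- selection_gradient(s3$components[[2]], 1)
  s1_at_0 <- selection_gradient(s3$components[[1]], 0)
  expect_gte(s2_at_1, s1_at_0)
  expect_equal(v3$corner_checks$marginal_at_zero, s1_at_0)
})

test_that("deliberately perturbed allocations fail the diagnostics", {
  sm <- load_scenario("fig1_multiplicative")
  a <- optimize_allocation(sm, 1)
  a$u <- a$u + c(0.1, -0.1)
  a$interior_flags <- a$u > 0
  v <- verify_marginal_conditions(sm, a)
  expect_false(v$pass)
})
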