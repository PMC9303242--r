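test_that("catalog forms evaluate to their closed-form values", {
  quad <- make_component("quadratic", a = 1.5, b = 0.7)
  expect_equal(evaluate_component(quad, 1), 0.8)
  expect_equal(evaluate_component(quad, 0), 0)

  lin <- make_component("linear", slope = 1)
  expect_equal(evaluate_component(lin, 2.5), 2.5)
  expect_equal(evaluate_component(make_component("linear", slope = 1), 3), 3)

  # exp-erf at u = 0: exp(erf(-9)) is e^(-1) to double precision
  ee <- make_component("exp-erf", a = 0.1, s = 3, m = 3)
  expect_equal(evaluate_component(ee, 0), exp(erf(-9)))
  expect_equal(evaluate_component(ee, 0), exp(-1), tolerance = 1e-12)

  dexp <- make_component("double-exponential")
  expect_equal(evaluate_component(dexp, 0), 1)

  ps <- make_component("power-sum", a = 1, b = 1, p = 20)
  expect_equal(evaluate_component(ps, 1), 2)
  expect_equal(evaluate_component(ps, 2), 2 + 2^20)
})

test_that("analytic derivatives match their symbolic forms at spot points", {
  quad <- make_component("quadratic", a = 1.5, b = 0.7)
  expect_equal(component_derivative(quad, 0, 1), 1.5)
  expect_equal(component_derivative(quad, 1, 2), -1.4)

  lin <- make_component("linear", slope = 2)
  expect_equal(component_derivative(lin, 5, 2), 0)

  # x = u + u^20: x'' = 20*19*u^18 = 380 at u = 1
  ps <- make_component("power-sum", a = 1, b = 1, p = 20)
  expect_equal(component_derivative(ps, 1, 2), 380)
})

test_that("analytic derivatives agree with central differences on random points", {
  set.seed(42)
  comps <- list(
    make_component("linear", slope = 1.3, intercept = 0.4),
    make_component("quadratic", a = 1.5, b = 0.7),
    make_component("affine-quadratic", c = 0.2, a = 1, b = 0.5),
    make_component("power-sum", a = 1, b = 1, p = 20),
    make_component("exp-erf", a = 0.1, s = 3, m = 3),
    make_component("double-exponential", a = 1, k = 1))
  ranges <- list(c(0.1, 10), c(0.1, 1), c(0.1, 1), c(0.1, 2.5),
                 c(0.1, 6), c(0.1, 6))
  for (i in seq_along(comps)) {
    u <- runif(100, ranges[[i]][1], ranges[[i]][2])
    d1 <- component_derivative(comps[[i]], u, 1)
    d2 <- component_derivative(comps[[i]], u, 2)
    expect_equal(d1, fd_deriv(comps[[i]], u, 1), tolerance = 1e-5,
                 info = comps[[i]]$form)
    expect_equal(d2, fd_deriv(comps[[i]], u, 2,
                              h = 1e-4 * pmax(1, abs(u))),
                 tolerance = 1e-4, info = comps[[i]]$form)
  }
})

test_that("user-tabulated components fall back to finite differences", {
  tc <- tabulated_component(function(u) exp(1 - exp(-u)), name = "viability")
  u <- c(0.5, 1, 2)
  ref <- make_component("double-exponential")
  expect_equal(component_derivative(tc, u, 1),
               component_derivative(ref, u, 1), tolerance = 1e-6)
  expect_equal(component_derivative(tc, u, 2),
               component_derivative(ref, u, 2), tolerance = 1e-4)
  # one-sided at the domain edge stays finite
  expect_true(is.finite(component_derivative(tc, 0, 1)))
  expect_true(is.finite(component_derivative(tc, 0, 2)))
})

test_that("selection gradient is the proportional derivative x'/x", {
  lin <- make_component("linear", slope = 1)
  expect_equal(selection_gradient(lin, 2), 0.5)
  # exp(1 - exp(-u)): S(u) = exp(-u)
  dexp <- make_component("double-exponential")
  expect_equal(selection_gradient(dexp, 0), 1)
  expect_equal(selection_gradient(dexp, log(2)), 0.5)
  u <- seq(0.2, 5, length.out = 20)
  expect_equal(selection_gradient(dexp, u), exp(-u), tolerance = 1e-12)
  expect_error(selection_gradient(lin, 0), "undefined")
})

test_that("honesty-breakdown margin classifies curvature regimes", {
  lin <- make_component("linear", slope = 1)
  u <- c(0.5, 1, 3, 10)
  expect_equal(condition8_margin(lin, u), rep(-1, 4))

  # exponentials e^(ku) are the knife-edge neutral case: margin identically
  # zero (exp-erf with s = 0 is exactly exponential, with exact derivatives)
  for (k in c(0.3, 1, 2)) {
    ek <- make_component("exp-erf", a = k, s = 0, m = 0)
    u20 <- seq(0.1, 3, length.out = 20)
    mg <- condition8_margin(ek, u20)
    expect_lt(max(abs(mg) / exp(2 * k * u20)), 1e-9)
  }

  # strongly accelerating power sum: m(1) = 380*2 - 21^2 = 319
  ps <- make_component("power-sum", a = 1, b = 1, p = 20)
  expect_equal(condition8_margin(ps, 1), 319)
})

test_that("margin is negative wherever returns are linear or decelerating", {
  set.seed(7)
  for (rep in 1:20) {
    a <- runif(1, 0.5, 2); c0 <- runif(1, 0.1, 1)
    b <- runif(1, 0, 0.4 * a / 5)
    comp <- make_component("affine-quadratic", c = c0, a = a, b = b)
    u <- runif(50, 0.01, 5)
    expect_true(all(condition8_margin(comp, u) < 0))
  }
})

test_that("component errors are raised for bad inputs", {
  expect_error(make_component("nosuch"), "unknown component form")
  expect_error(make_component("quadratic", a = 1), "missing required")
  quad <- make_component("quadratic", a = 1.5, b = 0.7)
  expect_error(component_derivative(quad, 1, 3), "order")
  expect_error(evaluate_component(quad, -1), "below the domain")
  # margin preconditions: positive value, positive slope
  expect_error(condition8_margin(quad, 2), "nonpositive|slope")
  lin0 <- make_component("linear", slope = 1)
  expect_error(condition8_margin(lin0, 0), "positive")
  # overflow is reported, not returned
  big <- make_component("double-exponential", a = 800)
  expect_error(evaluate_component(big, 5), "non-finite")
})
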