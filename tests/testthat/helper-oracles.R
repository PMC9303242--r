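# Shared fixtures and independent oracles used across the test files.

# Central finite differences of a component's value function, independent of
# the analytic derivative code paths.
fd_deriv <- function(component, u, order = 1, h = 1e-5 * pmax(1, abs(u))) {
  f <- component$fn
  if (order == 1) (f(u + h) - f(u - h)) / (2 * h)
  else (f(u + h) - 2 * f(u) + f(u - h)) / h^2
}

# Closed-form optima for the concave-quadratic-vs-linear example
# (x1 = 1.5 u - 0.7 u^2, x2 = u2):
# additive:        x1' = x2'  =>  1.5 - 1.4 u1 = 1  =>  u1 = 5/14
# multiplicative (R = 1): dW/du1 = 2.1 u^2 - 4.4 u + 1.5 = 0, smaller root
u1_additive_closed <- 5 / 14
x1_additive_closed <- 1.5 * (5 / 14) - 0.7 * (5 / 14)^2  # 25/56
u1_mult_closed_R1 <- (4.4 - sqrt(4.4^2 - 4 * 2.1 * 1.5)) / (2 * 2.1)  # 3/7

expect_alloc_valid <- function(alloc, R) {
  expect_equal(sum(alloc$u), R, tolerance = 1e-9)
  expect_true(all(alloc$u >= 0))
  recomputed <- if (alloc$rule == "additive") sum(alloc$x) else prod(alloc$x)
  expect_equal(alloc$W, recomputed)
}
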