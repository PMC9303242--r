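# Fitness-component functions x_i(u_i) with analytic first and second
# derivatives. Components are positive-valued traits that (on the ranges of
# interest) increase with the investment u_i made in them.

#' Gauss error function
#'
#' \eqn{\mathrm{erf}(z) = 2\Phi(z\sqrt{2}) - 1}, computed from the normal CDF.
#'
#' @param z numeric vector.
#' @return numeric vector of the same length.
#' @export
erf <- function(z) 2 * stats::pnorm(sqrt(2) * z) - 1

# derivative of erf
erf_d1 <- function(z) 2 / sqrt(pi) * exp(-z^2)

#' Built-in fitness-component catalog
#'
#' Constructs a fitness component \eqn{x(u)} from a closed catalog of
#' functional forms, with analytic first and second derivatives wired in.
#' Available forms (parameters with defaults in brackets):
#'
#' \describe{
#'   \item{`linear`}{\eqn{x = c + a u}; params `slope` (a, 1), `intercept`
#'     (c, 0).}
#'   \item{`quadratic`}{\eqn{x = a u - b u^2}; params `a`, `b`. Increasing and
#'     concave for \eqn{u < a/(2b)}.}
#'   \item{`affine-quadratic`}{\eqn{x = c + a u - b u^2}; params `c`, `a`, `b`.
#'     A positive intercept `c` gives some payoff even at zero investment.}
#'   \item{`power-sum`}{\eqn{x = c + a u + b u^p}; params `intercept` (c, 0),
#'     `a` (1), `b` (1), `p` (20). Strongly accelerating for large `p`.}
#'   \item{`exp-erf`}{\eqn{x = \exp[a u + \mathrm{erf}(s (u - m))]}; params
#'     `a` (0.1), `s` (3), `m` (3). A sigmoidal jump in log-payoff around
#'     \eqn{u = m}.}
#'   \item{`double-exponential`}{\eqn{x = \exp[a (1 - e^{-k u})]}; params
#'     `a` (1), `k` (1). Saturating log-payoff; its selection gradient
#'     \eqn{a k e^{-k u}} is strictly decreasing.}
#' }
#'
#' @param form catalog form name (see above).
#' @param ... named real parameters for the form.
#' @param name optional display name; defaults to the form name.
#' @param domain_min lower end of the investment domain (default 0).
#' @return an object of class `component_fn`.
#' @seealso [tabulated_component()] for user-supplied functions,
#'   [evaluate_component()], [component_derivative()].
#' @examples
#' x1 <- make_component("quadratic", a = 1.5, b = 0.7)
#' evaluate_component(x1, 1) # 0.8
#' @export
make_component <- function(form, ..., name = form, domain_min = 0) {
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) && is.list(params[[1L]]))
    params <- params[[1L]]
  builder <- .component_catalog[[form]]
  if (is.null(builder))
    stop("unknown component form '", form, "'; available: ",
         paste(names(.component_catalog), collapse = ", "), call. = FALSE)
  def <- builder(params)
  structure(
    list(name = name, form = form, params = def$params,
         domain_min = domain_min,
         fn = def$fn, d1 = def$d1, d2 = def$d2),
    class = "component_fn")
}

.param <- function(params, key, default = NULL) {
  v <- params[[key]]
  if (is.null(v)) {
    if (is.null(default))
      stop("missing required parameter '", key, "'", call. = FALSE)
    v <- default
  }
  as.numeric(v)
}

.component_catalog <- list(
  "linear" = function(p) {
    a <- .param(p, "slope", 1); c0 <- .param(p, "intercept", 0)
    list(params = list(slope = a, intercept = c0),
         fn = function(u) c0 + a * u,
         d1 = function(u) rep_len(a, length(u)),
         d2 = function(u) rep_len(0, length(u)))
  },
  "quadratic" = function(p) {
    a <- .param(p, "a"); b <- .param(p, "b")
    list(params = list(a = a, b = b),
         fn = function(u) a * u - b * u^2,
         d1 = function(u) a - 2 * b * u,
         d2 = function(u) rep_len(-2 * b, length(u)))
  },
  "affine-quadratic" = function(p) {
    c0 <- .param(p, "c"); a <- .param(p, "a"); b <- .param(p, "b")
    list(params = list(c = c0, a = a, b = b),
         fn = function(u) c0 + a * u - b * u^2,
         d1 = function(u) a - 2 * b * u,
         d2 = function(u) rep_len(-2 * b, length(u)))
  },
  "power-sum" = function(p) {
    c0 <- .param(p, "intercept", 0); a <- .param(p, "a", 1)
    b <- .param(p, "b", 1); pw <- .param(p, "p", 20)
    list(params = list(intercept = c0, a = a, b = b, p = pw),
         fn = function(u) c0 + a * u + b * u^pw,
         d1 = function(u) a + b * pw * u^(pw - 1),
         d2 = function(u) b * pw * (pw - 1) * u^(pw - 2))
  },
  "exp-erf" = function(p) {
    a <- .param(p, "a", 0.1); s <- .param(p, "s", 3); m <- .param(p, "m", 3)
    g  <- function(u) a * u + erf(s * (u - m))
    g1 <- function(u) a + s * erf_d1(s * (u - m))
    g2 <- function(u) -2 * s^3 * (u - m) * erf_d1(s * (u - m))
    list(params = list(a = a, s = s, m = m),
         fn = function(u) exp(g(u)),
         d1 = function(u) exp(g(u)) * g1(u),
         d2 = function(u) exp(g(u)) * (g2(u) + g1(u)^2))
  },
  "double-exponential" = function(p) {
    a <- .param(p, "a", 1); k <- .param(p, "k", 1)
    g  <- function(u) a * (1 - exp(-k * u))
    g1 <- function(u) a * k * exp(-k * u)
    g2 <- function(u) -a * k^2 * exp(-k * u)
    list(params = list(a = a, k = k),
         fn = function(u) exp(g(u)),
         d1 = function(u) exp(g(u)) * g1(u),
         d2 = function(u) exp(g(u)) * (g2(u) + g1(u)^2))
  }
)

#' Fitness component from a user-supplied function
#'
#' Wraps an arbitrary (vectorised) function of investment as a
#' `component_fn`. Derivatives are computed by central finite differences
#' with step \eqn{h = 10^{-6} \max(1, |u|)}, one-sided at `domain_min`.
#'
#' @param fn vectorised function of one nonnegative argument.
#' @param name display name.
#' @param domain_min lower end of the investment domain (default 0).
#' @return an object of class `component_fn` with `form = "user-tabulated"`.
#' @export
tabulated_component <- function(fn, name = "user", domain_min = 0) {
  stopifnot(is.function(fn))
  d1 <- function(u) {
    h <- 1e-6 * pmax(1, abs(u))
    lo <- pmax(u - h, domain_min)
    (fn(u + h) - fn(lo)) / (u + h - lo)
  }
  d2 <- function(u) {
    h <- 1e-4 * pmax(1, abs(u))
    at_edge <- (u - h) < domain_min
    out <- (fn(u + h) - 2 * fn(u) + fn(pmax(u - h, domain_min))) / h^2
    if (any(at_edge)) {
      ue <- u[at_edge]; he <- h[at_edge]
      out[at_edge] <- (fn(ue + 2 * he) - 2 * fn(ue + he) + fn(ue)) / he^2
    }
    out
  }
  structure(
    list(name = name, form = "user-tabulated", params = list(),
         domain_min = domain_min, fn = fn, d1 = d1, d2 = d2),
    class = "component_fn")
}

.check_domain <- function(component, u) {
  if (any(u < component$domain_min - 1e-12))
    stop("investment u = ", format(min(u)), " below the domain of component '",
         component$name, "' (domain_min = ", component$domain_min, ")",
         call. = FALSE)
}

#' Evaluate a fitness component
#'
#' @param component a `component_fn`.
#' @param u nonnegative investment(s).
#' @return \eqn{x(u)}, vectorised over `u`.
#' @export
evaluate_component <- function(component, u) {
  stopifnot(inherits(component, "component_fn"))
  .check_domain(component, u)
  x <- component$fn(u)
  if (any(!is.finite(x)))
    stop("component '", component$name, "' is non-finite at u = ",
         format(u[which(!is.finite(x))[1L]]), call. = FALSE)
  x
}

#' First or second derivative of a fitness component
#'
#' Analytic for catalog forms; finite differences for user-tabulated ones.
#'
#' @inheritParams evaluate_component
#' @param order 1 or 2.
#' @return \eqn{x'(u)} or \eqn{x''(u)}, vectorised over `u`.
#' @export
component_derivative <- function(component, u, order = 1) {
  stopifnot(inherits(component, "component_fn"))
  if (!order %in% c(1, 2))
    stop("derivative order must be 1 or 2", call. = FALSE)
  .check_domain(component, u)
  if (order == 1) component$d1(u) else component$d2(u)
}

#' Selection gradient (elasticity) of a fitness component
#'
#' The proportional derivative \eqn{S(u) = x'(u)/x(u)}: the relative gain in
#' the component (and hence, under multiplicative fitness, in fitness) per
#' unit of additional investment. At an interior optimum of a multiplicative
#' trade-off, all funded components have equal selection gradients.
#'
#' @inheritParams evaluate_component
#' @return \eqn{S(u)}, vectorised over `u`. Errors where \eqn{x(u) = 0}.
#' @export
selection_gradient <- function(component, u) {
  x <- evaluate_component(component, u)
  if (any(x == 0))
    stop("selection gradient undefined: component '", component$name,
         "' is zero at u = ", format(u[which(x == 0)[1L]]), call. = FALSE)
  component_derivative(component, u, 1) / x
}

#' Honesty-breakdown margin of a viability component
#'
#' For a positive, increasing component the selection gradient
#' \eqn{S = x'/x} is locally *increasing* in investment exactly when
#' \eqn{x''/x' > x'/x}, i.e. when returns accelerate strongly enough. This
#' function returns the equivalent polynomial margin
#' \deqn{m(u) = x''(u)\,x(u) - x'(u)^2,}
#' whose sign classifies the regime: `m > 0` means S is increasing there (the
#' necessary condition for honesty to break down holds), `m < 0` means S is
#' decreasing, `m = 0` is the knife-edge neutral case (e.g. exponentials).
#' The margin can never be positive for linear (\eqn{x'' = 0}) or
#' decelerating (\eqn{x'' < 0}) components.
#'
#' @inheritParams evaluate_component
#' @return \eqn{m(u)}, vectorised over `u`. Requires \eqn{x(u) > 0} and
#'   \eqn{x'(u) > 0}.
#' @export
condition8_margin <- function(component, u) {
  x <- evaluate_component(component, u)
  d1 <- component_derivative(component, u, 1)
  if (any(x <= 0))
    stop("margin requires a positive component value; '", component$name,
         "' is nonpositive at u = ", format(u[which(x <= 0)[1L]]),
         call. = FALSE)
  if (any(d1 <= 0))
    stop("margin requires an increasing component; '", component$name,
         "' has nonpositive slope at u = ", format(u[which(d1 <= 0)[1L]]),
         call. = FALSE)
  component_derivative(component, u, 2) * x - d1^2
}

#' @export
print.component_fn <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), vapply(x$params, format, ""), sep = "=",
          collapse = ", ") else "none"
  cat("<component_fn> ", x$name, " [", x$form, "], params: ", ps, "\n",
      sep = "")
  invisible(x)
}
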