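# Trade-off scenarios: an ordered set of fitness components plus the rule
# (additive or multiplicative) by which they combine into fitness. By
# convention the first component is the signal / mating-success component,
# whose investment u1 defines signal honesty.

#' Construct a trade-off scenario
#'
#' @param components list of [component_fn][make_component] objects
#'   (length >= 2). The first is the signal (mating-success) component.
#' @param rule `"multiplicative"` (fitness is the product of the components)
#'   or `"additive"` (the sum).
#' @param labels optional display names, one per component.
#' @param name optional scenario name.
#' @param meta optional list of metadata (e.g. `recommended_R` range).
#' @return an object of class `tradeoff_scenario`.
#' @export
tradeoff_scenario <- function(components,
                              rule = c("multiplicative", "additive"),
                              labels = NULL, name = "scenario",
                              meta = list()) {
  rule <- match.arg(rule)
  if (!is.list(components) ||
      !all(vapply(components, inherits, TRUE, "component_fn")))
    stop("'components' must be a list of component_fn objects", call. = FALSE)
  if (length(components) < 2L)
    stop("a trade-off needs at least two components", call. = FALSE)
  if (is.null(labels))
    labels <- vapply(components, `[[`, "", "name")
  stopifnot(length(labels) == length(components))
  structure(list(components = components, rule = rule, labels = labels,
                 name = name, meta = meta),
            class = "tradeoff_scenario")
}

#' @export
print.tradeoff_scenario <- function(x, ...) {
  cat("<tradeoff_scenario> ", x$name, " (", x$rule, ", n = ",
      length(x$components), ")\n", sep = "")
  for (i in seq_along(x$components))
    cat("  x", i, " (", x$labels[i], "): ", x$components[[i]]$form, "\n",
        sep = "")
  invisible(x)
}

.scenario_catalog <- function() list(
  fig1_additive = function() tradeoff_scenario(
    list(make_component("quadratic", a = 1.5, b = 0.7, name = "mating success"),
         make_component("linear", slope = 1, name = "viability")),
    rule = "additive", name = "fig1_additive",
    meta = list(recommended_R = c(0, 1.4))),
  fig1_multiplicative = function() tradeoff_scenario(
    list(make_component("quadratic", a = 1.5, b = 0.7, name = "mating success"),
         make_component("linear", slope = 1, name = "viability")),
    rule = "multiplicative", name = "fig1_multiplicative",
    meta = list(recommended_R = c(0, 1.4))),
  fig2 = function() tradeoff_scenario(
    list(make_component("affine-quadratic", c = 0.2, a = 1, b = 0.5,
                        name = "mating success"),
         make_component("power-sum", a = 1, b = 1, p = 20,
                        name = "viability")),
    rule = "multiplicative", name = "fig2",
    # u2^20 overflows quickly; keep budgets modest
    meta = list(recommended_R = c(0, 3))),
  fig3 = function() tradeoff_scenario(
    list(make_component("exp-erf", a = 0.1, s = 3, m = 3,
                        name = "mating success"),
         make_component("double-exponential", a = 1, k = 1,
                        name = "viability")),
    rule = "multiplicative", name = "fig3",
    meta = list(recommended_R = c(0, 6))),
  symmetric_linear = function() tradeoff_scenario(
    list(make_component("linear", slope = 1, name = "mating success"),
         make_component("linear", slope = 1, name = "viability")),
    rule = "multiplicative", name = "symmetric_linear",
    meta = list(recommended_R = c(0, 4)))
)

#' Load a built-in scenario
#'
#' The catalog holds the worked examples used throughout the package
#' documentation:
#' \describe{
#'   \item{`fig1_additive`}{\eqn{x_1 = 1.5u_1 - 0.7u_1^2}, \eqn{x_2 = u_2},
#'     additive fitness \eqn{W = x_1 + x_2}. Optimal signal investment is the
#'     same for every budget: no information in the signal.}
#'   \item{`fig1_multiplicative`}{same components, \eqn{W = x_1 x_2}. Honest.}
#'   \item{`fig2`}{\eqn{x_1 = 0.2 + u_1 - 0.5u_1^2},
#'     \eqn{x_2 = u_2 + u_2^{20}}, multiplicative. The strongly accelerating
#'     viability returns break honesty at high budgets.}
#'   \item{`fig3`}{\eqn{x_1 = \exp[0.1u_1 + \mathrm{erf}(3(u_1-3))]},
#'     \eqn{x_2 = \exp[1 - e^{-u_2}]}, multiplicative. Honest despite a
#'     no-signal corner at low budgets and a discontinuous jump.}
#'   \item{`symmetric_linear`}{\eqn{x_1 = u_1}, \eqn{x_2 = u_2},
#'     multiplicative; the optimum splits the budget equally.}
#' }
#'
#' @param name scenario name.
#' @return a [tradeoff_scenario()].
#' @export
load_scenario <- function(name) {
  cat_ <- .scenario_catalog()
  f <- cat_[[name]]
  if (is.null(f))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(cat_), collapse = ", "), call. = FALSE)
  f()
}

#' List the built-in scenarios
#'
#' @return character vector of catalog names.
#' @export
list_scenarios <- function() names(.scenario_catalog())

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random multiplicative trade-off scenario
#'
#' Generates a two-component multiplicative scenario for property-based
#' testing. The signal component \eqn{x_1} is an increasing concave quadratic
#' with a positive intercept, so it is strictly positive and strictly
#' increasing on the working range `[0, u_max]` by construction. The
#' viability component \eqn{x_2} is drawn from the requested curvature class:
#' \describe{
#'   \item{`decelerating`}{concave quadratic with positive intercept
#'     (\eqn{x'' < 0}); its selection gradient is strictly decreasing.}
#'   \item{`linear`}{positive slope and intercept (\eqn{x'' = 0}); selection
#'     gradient strictly decreasing.}
#'   \item{`accelerating`}{power-sum \eqn{c + a u + b u^p} with a high
#'     exponent (\eqn{x'' \ge 0}, strongly accelerating at high investment).}
#' }
#' The same seed always yields the identical scenario; the caller's RNG
#' state is left untouched.
#'
#' @param seed integer seed.
#' @param viability_curvature curvature class of the viability component.
#' @param u_max upper end of the working range (default 10).
#' @return a [tradeoff_scenario()] with `meta$u_max` and
#'   `meta$viability_curvature` recorded.
#' @export
random_scenario <- function(seed,
                            viability_curvature = c("decelerating", "linear",
                                                    "accelerating"),
                            u_max = 10) {
  viability_curvature <- match.arg(viability_curvature)
  .with_seed(seed, {
    a1 <- stats::runif(1, 0.5, 2)
    c1 <- stats::runif(1, 0.1, 1)
    # keep x1' = a1 - 2 b1 u > 0 on [0, u_max]
    b1 <- stats::runif(1, 0, 0.45 * a1 / u_max)
    x1 <- make_component("affine-quadratic", c = c1, a = a1, b = b1,
                         name = "mating success")
    x2 <- switch(viability_curvature,
      decelerating = {
        a2 <- stats::runif(1, 0.5, 2)
        c2 <- stats::runif(1, 0.1, 1)
        b2 <- stats::runif(1, 0.05 * a2 / u_max, 0.45 * a2 / u_max)
        make_component("affine-quadratic", c = c2, a = a2, b = b2,
                       name = "viability")
      },
      linear = make_component("linear", slope = stats::runif(1, 0.5, 2),
                              intercept = stats::runif(1, 0.1, 1),
                              name = "viability"),
      accelerating = {
        p <- sample(6:20, 1)
        # scale b so the power term matters well inside the working range
        u_half <- stats::runif(1, 0.3, 0.8) * u_max
        b <- u_half^(1 - p)
        make_component("power-sum", intercept = stats::runif(1, 0.1, 1),
                       a = 1, b = b, p = p, name = "viability")
      })
    tradeoff_scenario(list(x1, x2), rule = "multiplicative",
                      name = paste0("random_", viability_curvature, "_", seed),
                      meta = list(u_max = u_max,
                                  viability_curvature = viability_curvature))
  })
}

# ---- scenario config (YAML) -------------------------------------------------

#' Read a scenario from a YAML config file
#'
#' The config dialect is YAML with top-level keys `rule`
#' (`additive` | `multiplicative`), optional `name`, and `components`: a list
#' of `{form, params}` maps using the catalog form and parameter names of
#' [make_component()]. Example:
#'
#' ```yaml
#' rule: multiplicative
#' components:
#'   - form: quadratic
#'     params: {a: 1.5, b: 0.7}
#'   - form: linear
#'     params: {slope: 1}
#' ```
#'
#' @param path file path.
#' @return a [tradeoff_scenario()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rule) || is.null(cfg$components))
    stop("scenario config must have 'rule' and 'components' fields",
         call. = FALSE)
  comps <- lapply(cfg$components, function(cc) {
    if (is.null(cc$form))
      stop("each component needs a 'form' field", call. = FALSE)
    params <- if (is.null(cc$params)) list() else cc$params
    nm <- if (is.null(cc$name)) cc$form else cc$name
    make_component(cc$form, params, name = nm)
  })
  tradeoff_scenario(comps, rule = cfg$rule,
                    name = if (is.null(cfg$name)) "config" else cfg$name)
}

#' Write a scenario to a YAML config file
#'
#' Only catalog-form components can be serialised; user-tabulated components
#' raise an error.
#'
#' @param scenario a [tradeoff_scenario()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "tradeoff_scenario"))
  forms <- vapply(scenario$components, `[[`, "", "form")
  if (any(forms == "user-tabulated"))
    stop("user-tabulated components cannot be serialised to config",
         call. = FALSE)
  cfg <- list(
    name = scenario$name, rule = scenario$rule,
    components = lapply(scenario$components, function(cc)
      list(form = cc$form, name = cc$name, params = cc$params)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
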