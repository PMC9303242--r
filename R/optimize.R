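# Constrained allocation: maximise W(x_1(u_1), ..., x_n(u_n)) over the
# simplex u_i >= 0, sum(u_i) = R. For n = 2 the problem reduces to one
# dimension in u1; the objective can be multimodal (e.g. sigmoidal signal
# payoffs), so the search is a dense scan that brackets every local maximum,
# followed by golden-section refinement and, where possible, a final polish
# by root-finding on the analytic first-order condition.

#' Combined fitness of an investment vector
#'
#' Evaluates every component at its investment and combines them under the
#' scenario rule: the sum for additive fitness, the product for
#' multiplicative fitness.
#'
#' @param scenario a [tradeoff_scenario()].
#' @param u numeric vector of investments, one per component.
#' @return fitness `W` (scalar).
#' @export
fitness <- function(scenario, u) {
  stopifnot(inherits(scenario, "tradeoff_scenario"))
  if (length(u) != length(scenario$components))
    stop("length(u) = ", length(u), " does not match the scenario's ",
         length(scenario$components), " components", call. = FALSE)
  if (any(!is.finite(u)) || any(u < 0))
    stop("investments must be finite and nonnegative", call. = FALSE)
  x <- mapply(function(cc, ui) evaluate_component(cc, ui),
              scenario$components, u)
  if (scenario$rule == "additive") sum(x) else prod(x)
}

.combine <- function(rule, ...) {
  xs <- list(...)
  out <- xs[[1L]]
  for (x in xs[-1L]) out <- if (rule == "additive") out + x else out * x
  out
}

# d/du1 of the two-component objective at fixed R (u2 = R - u1)
.grad2 <- function(scenario, R) {
  c1 <- scenario$components[[1L]]; c2 <- scenario$components[[2L]]
  if (scenario$rule == "additive") {
    function(u1) c1$d1(u1) - c2$d1(R - u1)
  } else {
    function(u1) c1$d1(u1) * c2$fn(R - u1) - c1$fn(u1) * c2$d1(R - u1)
  }
}

# refine one bracketed local maximum of a 1D objective
.refine_bracket <- function(wfun, gfun, lo, hi) {
  if (hi - lo < 4e-14 * max(1, hi)) return((lo + hi) / 2)
  um <- stats::optimize(wfun, c(lo, hi), maximum = TRUE,
                        tol = 1e-10)$maximum
  glo <- gfun(lo); ghi <- gfun(hi)
  if (is.finite(glo) && is.finite(ghi) && glo > 0 && ghi < 0) {
    ur <- tryCatch(stats::uniroot(gfun, c(lo, hi), tol = 1e-13)$root,
                   error = function(e) NULL)
    if (!is.null(ur)) {
      wr <- wfun(ur); wm <- wfun(um)
      # prefer the stationary point unless it is genuinely worse
      if (wr >= wm - 1e-12 * max(1, abs(wm))) um <- ur
    }
  }
  um
}

# core 1D solve for two components: returns candidate u1 values
.candidates2 <- function(scenario, R, n_scan) {
  c1 <- scenario$components[[1L]]; c2 <- scenario$components[[2L]]
  u1g <- seq(0, R, length.out = max(n_scan, 16L))
  x1 <- c1$fn(u1g); x2 <- c2$fn(R - u1g)
  w <- .combine(scenario$rule, x1, x2)
  bad <- which(!is.finite(w))
  if (length(bad))
    stop("non-finite fitness at u1 = ", format(u1g[bad[1L]]), ", R = ",
         format(R), "; restrict the budget range or rescale the components",
         call. = FALSE)
  wfun <- function(u1) .combine(scenario$rule, c1$fn(u1), c2$fn(R - u1))
  gfun <- .grad2(scenario, R)
  m <- length(u1g)
  loc <- which(w >= c(-Inf, w[-m]) & w >= c(w[-1L], -Inf))
  loc <- loc[loc > 1L & loc < m]
  cand <- vapply(loc, function(i)
    .refine_bracket(wfun, gfun, u1g[i - 1L], u1g[i + 1L]), 0)
  unique(c(0, cand, R))
}

.interior_eps <- 1e-12

.gradient_residual <- function(scenario, u, x) {
  interior <- u > .interior_eps
  if (sum(interior) < 2L) return(NA_real_)
  vals <- if (scenario$rule == "additive") {
    mapply(function(cc, ui) cc$d1(ui), scenario$components[interior],
           u[interior])
  } else {
    if (any(x[interior] == 0)) return(NA_real_)
    mapply(function(cc, ui) cc$d1(ui) / cc$fn(ui),
           scenario$components[interior], u[interior])
  }
  max(vals) - min(vals)
}

.new_allocation <- function(scenario, R, u, multiplicity = FALSE) {
  x <- mapply(function(cc, ui) evaluate_component(cc, ui),
              scenario$components, u)
  W <- if (scenario$rule == "additive") sum(x) else prod(x)
  structure(list(R = R, u = u, x = x, W = W, rule = scenario$rule,
                 interior_flags = u > .interior_eps,
                 gradient_residual = .gradient_residual(scenario, u, x),
                 multiplicity = multiplicity),
            class = "allocation")
}

#' Globally optimal allocation of a resource budget
#'
#' Finds a global maximiser of fitness on the simplex
#' \eqn{\{u \ge 0, \sum_i u_i = R\}}. For two components the search is a
#' dense scan over \eqn{u_1 \in [0, R]} (bracketing all local maxima,
#' including both corners), each bracket refined by golden-section search and
#' polished on the analytic first-order condition. For more than two
#' components the problem is reduced recursively (optimise the first
#' investment against the optimal allocation of the remainder), with coarser
#' inner scans; this is best-effort and [brute_force_allocation()] is
#' available as a cross-check for small `n`.
#'
#' If two local optima tie in fitness within `tie_tol`, the allocation with
#' the smaller `u[1]` is returned and `multiplicity = TRUE` is set; the
#' budget at which this happens is exactly a discontinuity of the optimal
#' allocation path.
#'
#' @param scenario a [tradeoff_scenario()].
#' @param R nonnegative resource budget.
#' @param n_scan number of scan points for the outer 1D search (default
#'   4096).
#' @param tie_tol fitness tolerance within which two optima count as tied
#'   (default 1e-9).
#' @return an object of class `allocation` with fields `R`, `u`, `x`, `W`,
#'   `interior_flags`, `gradient_residual` (max pairwise mismatch of the
#'   first-order condition among funded components: derivatives under the
#'   additive rule, selection gradients under the multiplicative rule) and
#'   `multiplicity`.
#' @export
optimize_allocation <- function(scenario, R, n_scan = 4096, tie_tol = 1e-9) {
  stopifnot(inherits(scenario, "tradeoff_scenario"))
  if (!is.finite(R) || R < 0) stop("R must be a nonnegative number",
                                   call. = FALSE)
  n <- length(scenario$components)
  if (R == 0)
    return(.new_allocation(scenario, R, rep(0, n)))
  if (n == 2L) {
    cand <- .candidates2(scenario, R, n_scan)
    wfun <- function(u1) .combine(scenario$rule,
                                  scenario$components[[1L]]$fn(u1),
                                  scenario$components[[2L]]$fn(R - u1))
    wv <- vapply(cand, wfun, 0)
    best <- max(wv)
    tied <- which(wv >= best - tie_tol * max(1, abs(best)))
    # group ties that are genuinely distinct optima (not refinement twins)
    u1s <- sort(cand[tied])
    multi <- length(u1s) > 1L && (max(u1s) - min(u1s)) > 1e-6 * max(1, R)
    u1 <- u1s[1L]
    return(.new_allocation(scenario, R, c(u1, R - u1), multiplicity = multi))
  }
  # n > 2: recursive reduction
  sol <- .solve_recursive(scenario$components, scenario$rule, R,
                          n_scan_outer = max(257L, n_scan %/% 16L))
  u <- sol$u
  u[n] <- max(0, R - sum(u[-n]))  # absorb rounding into the last component
  .new_allocation(scenario, R, u)
}

# recursive best-effort solver for n > 2 components; returns list(u, W)
.solve_recursive <- function(comps, rule, R, n_scan_outer) {
  n <- length(comps)
  if (n == 1L)
    return(list(u = R, W = evaluate_component(comps[[1L]], R)))
  if (n == 2L) {
    sc <- tradeoff_scenario(comps, rule = rule)
    cand <- .candidates2(sc, R, max(129L, n_scan_outer %/% 2L))
    wfun <- function(u1) .combine(rule, comps[[1L]]$fn(u1),
                                  comps[[2L]]$fn(R - u1))
    wv <- vapply(cand, wfun, 0)
    i <- which.max(wv)
    return(list(u = c(cand[i], R - cand[i]), W = wv[i]))
  }
  inner <- function(u1) .solve_recursive(comps[-1L], rule, R - u1,
                                         n_scan_outer)
  value <- function(u1)
    .combine(rule, evaluate_component(comps[[1L]], u1), inner(u1)$W)
  u1g <- seq(0, R, length.out = n_scan_outer)
  wv <- vapply(u1g, value, 0)
  if (any(!is.finite(wv)))
    stop("non-finite fitness at u1 = ",
         format(u1g[which(!is.finite(wv))[1L]]), call. = FALSE)
  i <- which.max(wv)
  lo <- u1g[max(1L, i - 1L)]; hi <- u1g[min(length(u1g), i + 1L)]
  u1 <- if (hi > lo)
    stats::optimize(value, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
  else lo
  if (value(u1) < wv[i]) u1 <- u1g[i]
  rest <- inner(u1)
  list(u = c(u1, rest$u),
       W = .combine(rule, evaluate_component(comps[[1L]], u1), rest$W))
}

#' Brute-force allocation by exhaustive gridding
#'
#' Evaluates fitness on a uniform grid over the simplex and returns the best
#' grid point with no refinement. Intended as an independent oracle for
#' testing the solver, not for production use.
#'
#' @inheritParams optimize_allocation
#' @param grid_n number of grid points per free dimension (>= 2).
#' @return an `allocation` at the best grid point.
#' @export
brute_force_allocation <- function(scenario, R, grid_n = 10001) {
  stopifnot(inherits(scenario, "tradeoff_scenario"))
  if (!is.finite(R) || R < 0) stop("R must be a nonnegative number",
                                   call. = FALSE)
  if (grid_n < 2) stop("grid_n must be at least 2", call. = FALSE)
  n <- length(scenario$components)
  if (R == 0) return(.new_allocation(scenario, R, rep(0, n)))
  if (n == 2L) {
    u1g <- seq(0, R, length.out = grid_n)
    w <- .combine(scenario$rule,
                  scenario$components[[1L]]$fn(u1g),
                  scenario$components[[2L]]$fn(R - u1g))
    if (any(!is.finite(w)))
      stop("non-finite fitness at u1 = ",
           format(u1g[which(!is.finite(w))[1L]]), call. = FALSE)
    i <- which.max(w)
    return(.new_allocation(scenario, R, c(u1g[i], R - u1g[i])))
  }
  if (n > 3L || grid_n^(n - 1) > 4e7)
    stop("exhaustive gridding is limited to n <= 3 components ",
         "(and modest grids)", call. = FALSE)
  u1g <- seq(0, R, length.out = grid_n)
  best_w <- -Inf; best_u <- rep(0, n)
  for (u1 in u1g) {
    u2g <- seq(0, R - u1, length.out = grid_n)
    w <- .combine(scenario$rule,
                  evaluate_component(scenario$components[[1L]], u1),
                  scenario$components[[2L]]$fn(u2g),
                  scenario$components[[3L]]$fn(R - u1 - u2g))
    i <- which.max(w)
    if (w[i] > best_w) { best_w <- w[i]; best_u <- c(u1, u2g[i], R - u1 - u2g[i]) }
  }
  .new_allocation(scenario, R, best_u)
}

#' @export
print.allocation <- function(x, ...) {
  cat("<allocation> R = ", format(x$R), ", rule = ", x$rule, "\n", sep = "")
  tab <- data.frame(u = x$u, x = x$x, interior = x$interior_flags)
  rownames(tab) <- paste0("component_", seq_along(x$u))
  print(tab)
  cat("W = ", format(x$W),
      ", gradient residual = ", format(x$gradient_residual),
      if (isTRUE(x$multiplicity)) " (multiple optima)" else "", "\n", sep = "")
  invisible(x)
}

# ---- allocation paths -------------------------------------------------------

#' Optimal allocations along a grid of resource budgets
#'
#' Solves the allocation problem at every budget in `R_grid` and annotates
#' the resulting path: discontinuities of \eqn{u_1^*(R)} (jumps between
#' coexisting optima) are detected and their locations refined by bisection
#' on `R`; maximal budget intervals on which some component receives zero
#' investment are reported as corner segments.
#'
#' @inheritParams optimize_allocation
#' @param R_grid strictly increasing vector of nonnegative budgets.
#' @param jump_threshold minimum |change in u1| between adjacent grid points
#'   to count as a jump; default `max(0.05, 10 * median adjacent |change|)`.
#' @param refine_width target width of each refined discontinuity bracket
#'   (default 1e-4).
#' @return an object of class `allocation_path`: the scenario, the grid, the
#'   per-budget allocations, a `table` data frame (columns `R`,
#'   `u_1..u_n`, `x_1..x_n`, `W`, `multiplicity`), `discontinuities`
#'   (refined brackets), and `corner_segments`.
#' @export
allocation_path <- function(scenario, R_grid, n_scan = 4096,
                            jump_threshold = NULL, refine_width = 1e-4) {
  stopifnot(inherits(scenario, "tradeoff_scenario"))
  if (length(R_grid) < 1L || any(!is.finite(R_grid)) || any(R_grid < 0))
    stop("R_grid must be nonnegative and finite", call. = FALSE)
  if (length(R_grid) > 1L && any(diff(R_grid) <= 0))
    stop("R_grid must be strictly increasing", call. = FALSE)
  allocs <- lapply(R_grid, function(R)
    tryCatch(optimize_allocation(scenario, R, n_scan = n_scan),
             error = function(e)
               stop("allocation failed at R = ", format(R), ": ",
                    conditionMessage(e), call. = FALSE)))
  n <- length(scenario$components)
  um <- t(vapply(allocs, `[[`, numeric(n), "u"))
  xm <- t(vapply(allocs, `[[`, numeric(n), "x"))
  tab <- data.frame(R = R_grid, um, xm,
                    W = vapply(allocs, `[[`, 0, "W"),
                    multiplicity = vapply(allocs, `[[`, TRUE, "multiplicity"))
  names(tab) <- c("R", paste0("u_", seq_len(n)), paste0("x_", seq_len(n)),
                  "W", "multiplicity")
  path <- structure(list(scenario = scenario, R_grid = R_grid,
                         allocations = allocs, table = tab, n_scan = n_scan,
                         discontinuities = NULL, corner_segments = NULL),
                    class = "allocation_path")
  path$discontinuities <- detect_discontinuities(path,
                                                 jump_threshold = jump_threshold,
                                                 refine_width = refine_width)
  path$corner_segments <- .corner_segments(tab, n)
  path
}

.corner_segments <- function(tab, n) {
  out <- list()
  for (i in seq_len(n)) {
    z <- tab[[paste0("u_", i)]] <= .interior_eps
    r <- rle(z)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      out[[length(out) + 1L]] <- data.frame(component = i,
                                            R_low = tab$R[starts[k]],
                                            R_high = tab$R[ends[k]])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(component = integer(), R_low = numeric(),
                  R_high = numeric())
}

#' Detect and refine discontinuities of the optimal signal investment
#'
#' Flags adjacent budget pairs whose optimal \eqn{u_1} differ by more than
#' `jump_threshold` and narrows each bracket by bisection on `R`
#' (re-optimising at each midpoint and assigning it to the branch whose
#' \eqn{u_1} it is closer to) until the bracket is at most `refine_width`
#' wide.
#'
#' @param path an [allocation_path()].
#' @inheritParams allocation_path
#' @return data frame with columns `R_low`, `R_high`, `u1_low`, `u1_high`;
#'   zero rows when the path has no jumps.
#' @export
detect_discontinuities <- function(path, jump_threshold = NULL,
                                   refine_width = 1e-4) {
  stopifnot(inherits(path, "allocation_path"))
  tab <- path$table
  if (nrow(tab) < 2L)
    return(data.frame(R_low = numeric(), R_high = numeric(),
                      u1_low = numeric(), u1_high = numeric()))
  du <- abs(diff(tab$u_1))
  if (is.null(jump_threshold))
    jump_threshold <- max(0.05, 10 * stats::median(du))
  idx <- which(du > jump_threshold)
  if (!length(idx))
    return(data.frame(R_low = numeric(), R_high = numeric(),
                      u1_low = numeric(), u1_high = numeric()))
  out <- lapply(idx, function(i) {
    lo <- tab$R[i]; hi <- tab$R[i + 1L]
    u_lo <- tab$u_1[i]; u_hi <- tab$u_1[i + 1L]
    while (hi - lo > refine_width) {
      mid <- (lo + hi) / 2
      am <- optimize_allocation(path$scenario, mid, n_scan = path$n_scan)
      if (abs(am$u[1L] - u_lo) <= abs(am$u[1L] - u_hi)) {
        lo <- mid; u_lo <- am$u[1L]
      } else {
        hi <- mid; u_hi <- am$u[1L]
      }
    }
    data.frame(R_low = lo, R_high = hi, u1_low = u_lo, u1_high = u_hi)
  })
  do.call(rbind, out)
}

#' @export
print.allocation_path <- function(x, ...) {
  cat("<allocation_path> ", x$scenario$name, ": ", length(x$R_grid),
      " budgets in [", format(min(x$R_grid)), ", ", format(max(x$R_grid)),
      "]\n", sep = "")
  nd <- nrow(x$discontinuities)
  cat("  discontinuities: ", nd, sep = "")
  if (nd) cat(" (near R = ",
              paste(format((x$discontinuities$R_low +
                            x$discontinuities$R_high) / 2, digits = 4),
                    collapse = ", "), ")", sep = "")
  cat("\n  corner segments: ", nrow(x$corner_segments), "\n", sep = "")
  invisible(x)
}

#' Check the first-order (marginal) optimality conditions
#'
#' At an interior optimum every funded component must offer the same marginal
#' return: equal derivatives \eqn{x_i'} under additive fitness, equal
#' selection gradients (elasticities) \eqn{S_i = x_i'/x_i} under
#' multiplicative fitness. A component left unfunded (a corner) must not
#' offer a better marginal deal at zero than the funded components do at
#' their optima: \eqn{S_i(u_i) \ge S_j(0)} for every funded `i` and unfunded
#' `j` (derivatives in place of gradients under the additive rule).
#'
#' @param scenario the [tradeoff_scenario()] the allocation was produced for.
#' @param allocation an [optimize_allocation()] result.
#' @param tol pass/fail tolerance (default 1e-6).
#' @return a list with `interior_residual` (max pairwise mismatch, `NA` when
#'   fewer than two components are funded), `corner_checks` (data frame with
#'   one row per unfunded component: its marginal value at zero, the minimum
#'   marginal value among funded components, and the margin), and `pass`.
#' @export
verify_marginal_conditions <- function(scenario, allocation, tol = 1e-6) {
  stopifnot(inherits(scenario, "tradeoff_scenario"),
            inherits(allocation, "allocation"))
  u <- allocation$u
  interior <- allocation$interior_flags
  marginal <- function(cc, ui) {
    if (scenario$rule == "additive") cc$d1(ui)
    else {
      x <- cc$fn(ui)
      if (x == 0) NA_real_ else cc$d1(ui) / x
    }
  }
  m_int <- mapply(marginal, scenario$components[interior], u[interior])
  m_int <- m_int[is.finite(m_int)]
  interior_residual <- if (length(m_int) >= 2L) max(m_int) - min(m_int)
  else NA_real_
  corner_idx <- which(!interior)
  corner_checks <- if (length(corner_idx) && length(m_int)) {
    do.call(rbind, lapply(corner_idx, function(j) {
      m0 <- marginal(scenario$components[[j]], scenario$components[[j]]$domain_min)
      data.frame(component = j, marginal_at_zero = m0,
                 min_interior_marginal = min(m_int),
                 margin = min(m_int) - m0)
    }))
  } else data.frame(component = integer(), marginal_at_zero = numeric(),
                    min_interior_marginal = numeric(), margin = numeric())
  pass <- (is.na(interior_residual) || interior_residual < tol) &&
    (!nrow(corner_checks) ||
       all(is.na(corner_checks$margin) | corner_checks$margin >= -tol))
  list(interior_residual = interior_residual, corner_checks = corner_checks,
       pass = pass)
}
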