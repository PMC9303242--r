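# Fitness-set geometry for two-component trade-offs: the phenotype set is
# the curve of trait combinations (x1(u1), x2(R - u1)) reachable at a fixed
# budget R; fitness isoclines are loci of constant W (lines under additive
# fitness, hyperbolas under multiplicative fitness); and the optimal locus
# traces the tangency points as R grows.

.new_curve <- function(points, label, meta = list()) {
  structure(list(points = points, label = label, meta = meta),
            class = "sb_curve")
}

#' @export
print.sb_curve <- function(x, ...) {
  cat("<curve> ", x$label, ": ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sb_curve <- function(x, ...) x$points

#' Phenotype set at a fixed budget
#'
#' The parametric curve \eqn{\{(x_1(u_1), x_2(R - u_1)) : u_1 \in [0, R]\}}
#' of trait combinations achievable with budget `R`, sampled uniformly
#' in \eqn{u_1}.
#'
#' @param scenario a two-component [tradeoff_scenario()].
#' @param R nonnegative budget.
#' @param n_points samples along the curve (default 256).
#' @return a curve object; its `points` data frame has columns `u1`, `x1`,
#'   `x2`.
#' @export
phenotype_set <- function(scenario, R, n_points = 256) {
  stopifnot(inherits(scenario, "tradeoff_scenario"))
  if (length(scenario$components) != 2L)
    stop("phenotype sets are only defined for two-component scenarios",
         call. = FALSE)
  if (!is.finite(R) || R < 0) stop("R must be nonnegative", call. = FALSE)
  u1 <- if (R == 0) 0 else seq(0, R, length.out = max(2L, n_points))
  pts <- data.frame(
    u1 = u1,
    x1 = evaluate_component(scenario$components[[1L]], u1),
    x2 = evaluate_component(scenario$components[[2L]], R - u1))
  .new_curve(pts, label = paste0("phenotype set, R = ", format(R)),
             meta = list(type = "phenotype_set", R = R))
}

#' Fitness isocline
#'
#' The locus of trait combinations with equal fitness: the line
#' \eqn{x_2 = W - x_1} under additive fitness, the downward-convex hyperbola
#' \eqn{x_2 = W / x_1} under multiplicative fitness.
#'
#' @param rule `"additive"` or `"multiplicative"`.
#' @param W_level fitness level (must be positive for multiplicative).
#' @param x1_range length-2 range of `x1` to draw over; must exclude 0 for
#'   the multiplicative rule.
#' @param n_points samples (default 256).
#' @return a curve object with `points` columns `x1`, `x2`.
#' @export
isocline <- function(rule = c("multiplicative", "additive"), W_level,
                     x1_range, n_points = 256) {
  rule <- match.arg(rule)
  stopifnot(length(x1_range) == 2L, x1_range[1L] < x1_range[2L])
  if (rule == "multiplicative") {
    if (W_level <= 0)
      stop("multiplicative isoclines need W_level > 0", call. = FALSE)
    if (x1_range[1L] <= 0)
      stop("x1_range must be strictly positive for multiplicative isoclines",
           call. = FALSE)
  }
  x1 <- seq(x1_range[1L], x1_range[2L], length.out = max(2L, n_points))
  x2 <- if (rule == "multiplicative") W_level / x1 else W_level - x1
  .new_curve(data.frame(x1 = x1, x2 = x2),
             label = paste0("isocline, W = ", format(W_level)),
             meta = list(type = "isocline", rule = rule, W = W_level))
}

#' Optimal locus of an allocation path
#'
#' The sequence of optimal trait combinations \eqn{(x_1^*, x_2^*)} ordered
#' by budget. Discontinuities of the path are carried over as explicit gap
#' rows (`NA` coordinates), so that plotting the locus does not draw a
#' connecting segment across a jump.
#'
#' @param path a two-component [allocation_path()].
#' @return a curve object; `points` has columns `R`, `x1`, `x2`, `gap`
#'   (logical marker rows).
#' @export
optimal_locus <- function(path) {
  stopifnot(inherits(path, "allocation_path"))
  tab <- path$table
  if (!"x_2" %in% names(tab))
    stop("optimal loci are only defined for two-component paths",
         call. = FALSE)
  pts <- data.frame(R = tab$R, x1 = tab$x_1, x2 = tab$x_2, gap = FALSE)
  disc <- path$discontinuities
  if (!is.null(disc) && nrow(disc)) {
    for (i in seq_len(nrow(disc))) {
      at <- which(pts$R > disc$R_low[i] & !pts$gap)[1L]
      gap_row <- data.frame(R = (disc$R_low[i] + disc$R_high[i]) / 2,
                            x1 = NA_real_, x2 = NA_real_, gap = TRUE)
      pts <- rbind(pts[seq_len(at - 1L), ], gap_row,
                   pts[seq(at, nrow(pts)), ])
    }
    rownames(pts) <- NULL
  }
  .new_curve(pts, label = "optimal locus",
             meta = list(type = "optimal_locus",
                         n_gaps = if (is.null(disc)) 0L else nrow(disc)))
}

#' Tangency of the phenotype set with its fitness isocline
#'
#' At an interior optimum the phenotype set touches the highest reachable
#' fitness isocline, so their tangent directions are parallel. This checks
#' that the normalised cross product of the two tangents vanishes within
#' `tol`. For a corner allocation the tangency construction does not apply
#' and `NA` is returned (distinct from `FALSE`).
#'
#' @param scenario a two-component [tradeoff_scenario()].
#' @param R the budget the allocation was computed at.
#' @param allocation an [optimize_allocation()] result (or any allocation to
#'   test).
#' @param tol tolerance on the normalised cross product (default 1e-6).
#' @return `TRUE`, `FALSE`, or `NA` for corner allocations.
#' @export
tangency_check <- function(scenario, R, allocation, tol = 1e-6) {
  stopifnot(inherits(scenario, "tradeoff_scenario"),
            inherits(allocation, "allocation"))
  if (length(scenario$components) != 2L)
    stop("tangency is only defined for two-component scenarios",
         call. = FALSE)
  u1 <- allocation$u[1L]; u2 <- allocation$u[2L]
  if (u1 <= .interior_eps || u2 <= .interior_eps) return(NA)
  c1 <- scenario$components[[1L]]; c2 <- scenario$components[[2L]]
  # phenotype-set tangent: d/du1 (x1(u1), x2(R - u1))
  t_set <- c(c1$d1(u1), -c2$d1(u2))
  # isocline tangent at (x1, x2): additive (1, -1); multiplicative (1, -x2/x1)
  x1 <- c1$fn(u1); x2 <- c2$fn(u2)
  t_iso <- if (scenario$rule == "additive") c(1, -1) else c(1, -x2 / x1)
  t_set <- t_set / sqrt(sum(t_set^2))
  t_iso <- t_iso / sqrt(sum(t_iso^2))
  cross <- t_set[1L] * t_iso[2L] - t_set[2L] * t_iso[1L]
  abs(cross) < tol
}
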