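# Signal honesty: a signal is honest when optimal signal investment u1* is
# non-decreasing in the resource budget R, so that receivers can infer
# quality from signal size. The viability component's selection gradient
# governs when honesty can break down: an increasing gradient (accelerating
# returns, positive honesty-breakdown margin) is necessary, though not
# sufficient, for dishonesty; a strictly decreasing gradient guarantees
# honesty.

#' Honesty report for an allocation path
#'
#' Classifies an [allocation_path()] as honest (optimal signal investment
#' \eqn{u_1^*} non-decreasing in the budget `R`, up to `tol`) or dishonest,
#' listing the budget intervals on which \eqn{u_1^*} strictly decreases.
#' A leading corner segment with \eqn{u_1^* = 0} is reported separately and
#' does not count as dishonest: absent signals simply place an individual in
#' the lower range of quality. The report also evaluates the two theoretical
#' diagnostics on the viability component over the investments the path
#' actually visits: the honesty-breakdown margin ([condition8_margin()];
#' intervals where it is positive are necessary for any dishonesty) and
#' strict decrease of its selection gradient ([s2_monotonicity()]; when true
#' honesty is guaranteed, so a violation in the same report indicates a
#' solver failure and raises a warning).
#'
#' @param path an [allocation_path()] over an increasing budget grid
#'   (at least 2 points).
#' @param tol absolute tolerance on decreases of \eqn{u_1^*}; decreases
#'   smaller than this (refinement noise) are ignored. Default 1e-6.
#' @param n_probe probe points for the gradient diagnostics (default 512).
#' @return an object of class `honesty_report` with fields `honest`,
#'   `violation_intervals` (data frame `R_low`, `R_high`), `x1_monotone`,
#'   `x1_constant` (flat signal value: no information rather than
#'   dishonesty), `corner_prefix` (`c(R_low, R_high)` or `NULL`),
#'   `condition8_positive_intervals`, `s2_strictly_decreasing`.
#' @export
honesty_report <- function(path, tol = 1e-6, n_probe = 512) {
  stopifnot(inherits(path, "allocation_path"))
  tab <- path$table
  if (nrow(tab) < 2L)
    stop("honesty needs a path over at least two budgets", call. = FALSE)
  scenario <- path$scenario

  viol <- .decrease_intervals(tab$R, tab$u_1, tol)
  x1viol <- .decrease_intervals(tab$R, tab$x_1, tol)
  honest <- nrow(viol) == 0L

  corner_prefix <- NULL
  if (tab$u_1[1L] <= tol) {
    k <- which(tab$u_1 > tol)
    last0 <- if (length(k)) k[1L] - 1L else nrow(tab)
    corner_prefix <- c(tab$R[1L], tab$R[last0])
  }

  # diagnostics on the viability component over the visited u2 range
  comp2 <- scenario$components[[2L]]
  u2 <- tab$u_2
  lo <- min(u2); hi <- max(u2)
  if (comp2$fn(lo) <= 0) lo <- lo + max(1e-6, 1e-6 * hi)
  cond8 <- NULL
  s2dec <- NA
  if (hi > lo) {
    regimes <- tryCatch(
      classify_regimes(comp2, c(lo, hi), n_probe = n_probe),
      error = function(e) NULL)
    if (!is.null(regimes))
      cond8 <- regimes[regimes$sign > 0, c("u_low", "u_high")]
    s2 <- tryCatch(s2_monotonicity(comp2, c(lo, hi), n_probe = n_probe),
                   error = function(e) NULL)
    if (!is.null(s2)) s2dec <- s2$decreasing
  }
  if (isTRUE(s2dec) && !honest)
    warning("path is non-monotone although the viability selection ",
            "gradient is strictly decreasing; this indicates a solver ",
            "failure, not dishonesty", call. = FALSE)

  structure(list(
    honest = honest,
    violation_intervals = viol,
    x1_monotone = nrow(x1viol) == 0L,
    x1_constant = (max(tab$x_1) - min(tab$x_1)) < tol,
    corner_prefix = corner_prefix,
    condition8_positive_intervals = cond8,
    s2_strictly_decreasing = s2dec,
    scenario_name = scenario$name,
    R_range = range(tab$R), tol = tol), class = "honesty_report")
}

# maximal R-intervals over which y strictly decreases by more than tol
.decrease_intervals <- function(R, y, tol) {
  dec <- diff(y) < -tol
  r <- rle(dec)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- lapply(which(r$values), function(k)
    data.frame(R_low = R[starts[k]], R_high = R[ends[k] + 1L]))
  if (length(out)) do.call(rbind, out)
  else data.frame(R_low = numeric(), R_high = numeric())
}

#' @export
print.honesty_report <- function(x, ...) {
  cat("<honesty_report> ", x$scenario_name, " on R in [",
      format(x$R_range[1L]), ", ", format(x$R_range[2L]), "]\n", sep = "")
  cat("  honest: ", x$honest,
      if (x$x1_constant) "  (signal constant: uninformative, not dishonest)",
      "\n", sep = "")
  if (nrow(x$violation_intervals))
    cat("  u1 decreases on ",
        paste0("[", format(x$violation_intervals$R_low, digits = 4), ", ",
               format(x$violation_intervals$R_high, digits = 4), "]",
               collapse = ", "), "\n", sep = "")
  if (!is.null(x$corner_prefix))
    cat("  no-signal corner prefix: R in [",
        format(x$corner_prefix[1L], digits = 4), ", ",
        format(x$corner_prefix[2L], digits = 4), "]\n", sep = "")
  cat("  viability selection gradient strictly decreasing: ",
      x$s2_strictly_decreasing, "\n", sep = "")
  invisible(x)
}

#' Is the selection gradient strictly decreasing on a range?
#'
#' Probes \eqn{S(u) = x'(u)/x(u)} at `n_probe` uniformly spaced points and
#' reports whether successive values strictly decrease (by more than a
#' 1e-12 margin). This is a numerical check at the probe resolution, not a
#' proof. When false, a witness pair \eqn{u_a < u_b} with
#' \eqn{S(u_a) \le S(u_b)} is returned.
#'
#' @param component a [component_fn][make_component] with \eqn{x, x' > 0} on
#'   the range.
#' @param u_range length-2 interval of investments.
#' @param n_probe number of probe points (default 512).
#' @return list with `decreasing` (logical) and `witness` (`c(u_a, u_b)` or
#'   `NULL`).
#' @export
s2_monotonicity <- function(component, u_range, n_probe = 512) {
  stopifnot(inherits(component, "component_fn"), length(u_range) == 2L)
  u <- seq(u_range[1L], u_range[2L], length.out = max(3L, n_probe))
  s <- selection_gradient(component, u)
  if (any(!is.finite(s)))
    stop("selection gradient non-finite on the probe range", call. = FALSE)
  bad <- which(diff(s) >= -1e-12)
  if (!length(bad)) list(decreasing = TRUE, witness = NULL)
  else list(decreasing = FALSE, witness = c(u[bad[1L]], u[bad[1L] + 1L]))
}

#' Sign regimes of the honesty-breakdown margin
#'
#' Partitions an investment range into maximal intervals on which the
#' honesty-breakdown margin \eqn{m(u) = x''x - (x')^2} (see
#' [condition8_margin()]) has constant sign. The margin is probed at
#' `n_probe` points; each sign change is located by root bisection. Margins
#' smaller than `zero_tol` (relative to the local scale) are classified as
#' zero — exponential components sit exactly on this knife edge.
#'
#' @inheritParams s2_monotonicity
#' @param zero_tol relative tolerance for classifying the margin as zero
#'   (default 1e-9).
#' @return data frame with columns `u_low`, `u_high`, `sign` (-1, 0, 1).
#' @export
classify_regimes <- function(component, u_range, n_probe = 512,
                             zero_tol = 1e-9) {
  stopifnot(inherits(component, "component_fn"), length(u_range) == 2L)
  u <- seq(u_range[1L], u_range[2L], length.out = max(8L, n_probe))
  m <- condition8_margin(component, u)
  scale <- pmax(component$fn(u)^2, 1)  # margin has units of x^2
  sgn <- ifelse(abs(m) <= zero_tol * scale, 0L, ifelse(m > 0, 1L, -1L))
  r <- rle(as.integer(sgn))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- length(r$values)
  lo <- u[starts]; hi <- u[ends]
  # sharpen nonzero-sign boundaries by bisection on the margin
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (r$values[i] * r$values[i + 1L] == -1L) {
        root <- stats::uniroot(function(v) condition8_margin(component, v),
                               c(hi[i], lo[i + 1L]), tol = 1e-10)$root
        hi[i] <- root; lo[i + 1L] <- root
      }
    }
  }
  data.frame(u_low = lo, u_high = hi, sign = r$values)
}
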