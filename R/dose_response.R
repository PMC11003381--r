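# Dose-response regression of performance against dietary quality metrics:
# ordinary least-squares lines and a continuous two-segment linear-plateau
# ("broken-line") model
#
#     y = plateau - slope * max(0, b - x),   slope >= 0,
#
# the standard estimator of nutrient-requirement thresholds: the response
# rises linearly up to the breakpoint b and is flat beyond it. For fixed b
# the two linear parameters have a closed-form least-squares solution, so the
# breakpoint is profiled: the RSS is minimized over a dense grid of candidate
# breakpoints, then refined locally. The search is deterministic, so a fit is
# exactly reproducible.

#' Simple linear regression fit
#'
#' Ordinary least squares of `y` on `x`; the slope p-value comes from the
#' t-distribution on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, with nonzero
#'   variance in `x`.
#' @return A list of class `linear_fit`: `slope`, `intercept`, `r2`,
#'   `p_slope`, `rss`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_slope = sm$coefficients[2, 4],
                 rss = sum(stats::resid(fit)^2),
                 n = n),
            class = "linear_fit")
}

# closed-form profiled RSS of the linear-plateau model at one candidate
# breakpoint; returns list(rss, plateau, slope). The regressor is
# z = max(0, b - x) and the model y = plateau - slope * z with slope >= 0;
# when the unconstrained coefficient violates the sign constraint (or z is
# degenerate) the constrained optimum is the flat model.
.lp_profile <- function(b, x, y, syy, ybar) {
  z <- pmax(0, b - x)
  zbar <- mean(z)
  szz <- sum((z - zbar)^2)
  if (szz == 0) {
    return(list(rss = syy, plateau = ybar, slope = 0))
  }
  szy <- sum((z - zbar) * (y - ybar))
  beta <- szy / szz
  if (beta > 0) {  # would imply a falling limb; constrained optimum is flat
    return(list(rss = syy, plateau = ybar, slope = 0))
  }
  rss <- syy - beta * szy
  list(rss = max(rss, 0), plateau = ybar - beta * zbar, slope = -beta)
}

#' Linear-plateau (broken-line) least-squares fit
#'
#' Fits `y = plateau - slope * max(0, b - x)` with `slope >= 0` and
#' continuity at the breakpoint `b`. The breakpoint is profiled over
#' `n_grid` equally spaced candidates spanning `[min(x), max(x)]`, the two
#' linear parameters being refit in closed form at each candidate, and the
#' best candidate is refined by golden-section search between its grid
#' neighbours. Deterministic: no random restarts.
#'
#' If the data carry no rising limb (constant `y`, or only a falling trend),
#' the fit degenerates to the flat model: `slope = 0`, `plateau = mean(y)`,
#' breakpoint at `min(x)` and `all_plateau = TRUE`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @param n_grid Number of candidate breakpoints (default 512).
#' @return A list of class `broken_line_fit`: `breakpoint`, `slope`,
#'   `plateau`, `rss`, `r2`, `converged`, `all_plateau`, `n`.
#' @export
#' @examples
#' x <- c(76, 77, 78, 79, 80, 81, 82, 83)
#' y <- 2.46 - 0.25 * pmax(0, 79.5 - x)
#' fit_linear_plateau(x, y)$breakpoint  # 79.5
fit_linear_plateau <- function(x, y, n_grid = 512) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite input", call. = FALSE)
  }
  if (diff(range(x)) == 0) stop("x has zero range", call. = FALSE)
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)

  grid <- seq(min(x), max(x), length.out = n_grid)
  rss_grid <- vapply(grid, function(b) .lp_profile(b, x, y, syy, ybar)$rss,
                     numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  opt <- stats::optimize(function(b) .lp_profile(b, x, y, syy, ybar)$rss,
                         interval = c(lo, hi), tol = 1e-10)
  cand <- .lp_profile(opt$minimum, x, y, syy, ybar)
  best_b <- opt$minimum
  best <- cand
  # the grid winner can beat the refined point when the RSS is piecewise
  if (rss_grid[i] < best$rss) {
    best_b <- grid[i]
    best <- .lp_profile(best_b, x, y, syy, ybar)
  }
  if (best$slope == 0) best_b <- min(x)
  structure(list(breakpoint = best_b,
                 slope = best$slope,
                 plateau = best$plateau,
                 rss = best$rss,
                 r2 = if (syy > 0) 1 - best$rss / syy else NA_real_,
                 converged = TRUE,
                 all_plateau = best$slope == 0,
                 n = n),
            class = "broken_line_fit")
}

#' Quadratic-plateau least-squares fit
#'
#' Sensitivity-analysis alternative to [fit_linear_plateau()]: the rising
#' limb is the parabola `y = plateau - k * (b - x)^2` (k >= 0) joining the
#' plateau smoothly at `b`. Same deterministic profiling strategy.
#'
#' @inheritParams fit_linear_plateau
#' @return A list of class `broken_line_fit` (with `model = "quadratic-plateau"`
#'   and curvature `k` in place of `slope`'s interpretation; `slope` holds k).
#' @export
fit_quadratic_plateau <- function(x, y, n_grid = 512) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)
  prof <- function(b) {
    z <- pmax(0, b - x)^2
    zbar <- mean(z)
    szz <- sum((z - zbar)^2)
    if (szz == 0) return(list(rss = syy, plateau = ybar, slope = 0))
    szy <- sum((z - zbar) * (y - ybar))
    beta <- szy / szz
    if (beta > 0) return(list(rss = syy, plateau = ybar, slope = 0))
    list(rss = max(syy - beta * szy, 0), plateau = ybar - beta * zbar,
         slope = -beta)
  }
  grid <- seq(min(x), max(x), length.out = n_grid)
  rss_grid <- vapply(grid, function(b) prof(b)$rss, numeric(1))
  i <- which.min(rss_grid)
  opt <- stats::optimize(function(b) prof(b)$rss,
                         interval = c(grid[max(i - 1L, 1L)],
                                      grid[min(i + 1L, n_grid)]), tol = 1e-10)
  best_b <- opt$minimum
  best <- prof(best_b)
  if (rss_grid[i] < best$rss) {
    best_b <- grid[i]
    best <- prof(best_b)
  }
  if (best$slope == 0) best_b <- min(x)
  structure(list(breakpoint = best_b, slope = best$slope,
                 plateau = best$plateau, rss = best$rss,
                 r2 = if (syy > 0) 1 - best$rss / syy else NA_real_,
                 converged = TRUE, all_plateau = best$slope == 0,
                 n = length(x), model = "quadratic-plateau"),
            class = "broken_line_fit")
}

#' @export
print.broken_line_fit <- function(x, ...) {
  cat(sprintf("%s fit: breakpoint %.3f, slope %.4f, plateau %.4f (RSS %.5g, R2 %.3f)\n",
              if (!is.null(x$model)) x$model else "linear-plateau",
              x$breakpoint, x$slope, x$plateau, x$rss, x$r2))
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: slope %.4f, intercept %.4f (R2 %.3f, p = %.3g)\n",
              x$slope, x$intercept, x$r2, x$p_slope))
  invisible(x)
}

#' Predict from a broken-line fit
#'
#' Piecewise evaluation: the rising limb below the breakpoint, the plateau at
#' and above it; continuous at the breakpoint.
#'
#' @param object A `broken_line_fit`.
#' @param x Numeric vector of predictor values.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.broken_line_fit <- function(object, x, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge", call. = FALSE)
  if (identical(object$model, "quadratic-plateau")) {
    object$plateau - object$slope * pmax(0, object$breakpoint - x)^2
  } else {
    object$plateau - object$slope * pmax(0, object$breakpoint - x)
  }
}

#' Predict from a linear fit
#'
#' @param object A `linear_fit`.
#' @param x Numeric vector of predictor values.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.linear_fit <- function(object, x, ...) {
  object$intercept + object$slope * x
}
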