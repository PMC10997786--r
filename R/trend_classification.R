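## Eight-way expression-velocity trend taxonomy and its classifier.
##
## Direction (increasing/decreasing) comes from the fitted endpoints, the
## velocity qualifier (constant / accelerating / decelerating) from the
## significance of the quadratic term and the position of the parabola's
## vertex relative to the analysis window, and the Maxima/Minima labels
## from the observed per-day means.

#' The eight trend labels
#'
#' @return Character vector of the eight ASCII trend codes, in canonical
#'   order.
#' @export
trend_levels <- function() {
  c("INC_CONST", "INC_ACCEL", "INC_DECEL",
    "DEC_CONST", "DEC_ACCEL", "DEC_DECEL",
    "MAXIMA", "MINIMA")
}

#' Display strings for trend labels
#'
#' Maps ASCII trend codes to the display form used in figures
#' (e.g. `"Decreasing, ↓ velocity"`). Accelerating means the absolute
#' expression velocity |f'(t)| grows through time, decelerating that it
#' shrinks.
#'
#' @param code character vector of codes from [trend_levels()].
#' @return Character vector of display strings.
#' @export
trend_display <- function(code) {
  map <- c(INC_CONST = "Increasing, constant",
           INC_ACCEL = "Increasing, ↑ velocity",
           INC_DECEL = "Increasing, ↓ velocity",
           DEC_CONST = "Decreasing, constant",
           DEC_ACCEL = "Decreasing, ↑ velocity",
           DEC_DECEL = "Decreasing, ↓ velocity",
           MAXIMA = "Maxima", MINIMA = "Minima")
  unname(map[code])
}

#' Classify a fitted quadratic into one of eight velocity trends
#'
#' Decision procedure, in order:
#' 1. `MAXIMA` if the first and last observed day means are both strictly
#'    less than every interior day mean; `MINIMA` if both strictly greater.
#' 2. Direction: increasing iff the fitted value at the window end exceeds
#'    the fitted value at the window start (tie broken by the sign of the
#'    derivative at the window midpoint).
#' 3. If the quadratic coefficient is not significant (`p_A >= alpha`), the
#'    curve is treated as linear: `*_CONST`.
#' 4. Otherwise the vertex `t* = -B/(2A)` decides: at or beyond the window
#'    end the speed `|f'|` shrinks through the window (`*_DECEL`); at or
#'    before the window start it grows (`*_ACCEL`); a strictly interior
#'    vertex not already caught by rule 1 is labelled by the endpoint with
#'    the larger `|f'|`.
#'
#' @param fit a `regression_fit` (from [fit_quadratic()]) or a list with
#'   elements `A`, `B`, `C` and `p_A`.
#' @param window numeric length-2, the analysis window `(t_min, t_max)`.
#' @param day_means observed mean expression per day, in day order
#'   (length >= 3).
#' @param alpha significance level for the quadratic term (default 0.05).
#' @return A single trend code (see [trend_levels()]).
#' @export
classify_trend <- function(fit, window, day_means, alpha = 0.05) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (length(day_means) < 3) stop("classify_trend needs >= 3 day means")
  A <- fit$A; B <- fit$B; C <- fit$C; p_A <- fit$p_A
  k <- length(day_means)
  interior <- day_means[2:(k - 1)]
  if (day_means[1] < min(interior) && day_means[k] < min(interior))
    return("MAXIMA")
  if (day_means[1] > max(interior) && day_means[k] > max(interior))
    return("MINIMA")
  f <- function(t) A * t^2 + B * t + C
  fp <- function(t) 2 * A * t + B
  d <- f(window[2]) - f(window[1])
  inc <- if (d != 0) d > 0 else fp(mean(window)) > 0
  dir <- if (inc) "INC" else "DEC"
  if (is.na(p_A) || p_A >= alpha) return(paste0(dir, "_CONST"))
  if (A == 0)
    stop("internal inconsistency: A == 0 with significant quadratic term")
  vertex <- -B / (2 * A)
  shape <- if (vertex >= window[2]) "DECEL"
  else if (vertex <= window[1]) "ACCEL"
  else if (abs(fp(window[1])) > abs(fp(window[2]))) "DECEL"
  else "ACCEL"
  paste0(dir, "_", shape)
}

#' Fitted-curve and velocity table
#'
#' Evaluates the fitted quadratic `f(t) = A t^2 + B t + C` and its
#' derivative (the expression velocity) on an evenly spaced grid, for
#' plotting trend panels.
#'
#' @param fit a `regression_fit` or list with `A`, `B`, `C`.
#' @param window numeric length-2 `(t_min, t_max)`.
#' @param n_points number of grid points (>= 2).
#' @return data.frame with columns `t`, `fitted`, `derivative`.
#' @export
velocity_profile <- function(fit, window, n_points = 100) {
  if (n_points < 2) stop("n_points must be >= 2")
  t <- seq(window[1], window[2], length.out = n_points)
  data.frame(t = t,
             fitted = fit$A * t^2 + fit$B * t + fit$C,
             derivative = 2 * fit$A * t + fit$B)
}

#' Attach trend labels to a DEG table
#'
#' For each DEG row, computes the observed per-day mean expression within
#' its stratum (after any day masking already applied to the set) and runs
#' [classify_trend()].
#'
#' @param degs a `deg_table` from [find_timecourse_degs()].
#' @param ms the `metacell_set` the DEGs were computed from.
#' @param alpha significance level for the quadratic term.
#' @return `degs` with added columns `trend` (ASCII code) and
#'   `trend_display`.
#' @export
assign_trends <- function(degs, ms, alpha = 0.05) {
  stopifnot(inherits(ms, "metacell_set"))
  if (nrow(degs) == 0) {
    degs$trend <- character(0)
    degs$trend_display <- character(0)
    return(degs)
  }
  trend <- character(nrow(degs))
  for (i in seq_len(nrow(degs))) {
    stratum <- degs$cell_type[i]
    sel <- if (identical(stratum, "all")) rep(TRUE, nrow(ms$meta))
           else ms$meta$cell_type == stratum
    days <- ms$meta$day[sel]
    v <- ms$expression[sel, degs$gene[i]]
    dm <- tapply(v, days, mean)
    dm <- dm[order(as.numeric(names(dm)))]
    window <- range(as.numeric(names(dm)))
    trend[i] <- classify_trend(degs[i, ], window, as.numeric(dm), alpha = alpha)
  }
  degs$trend <- trend
  degs$trend_display <- trend_display(trend)
  degs
}
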