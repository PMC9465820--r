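#' Moving-window instantaneous growth rates
#'
#' Log10-transforms the confluence series and fits an ordinary
#' least-squares line in consecutive time windows, advancing by a fixed
#' shift. A 24-h window at 1.5-h sampling corresponds to 16 consecutive
#' data points; window and shift sizes are quantized to whole points
#' (`round(hours / dt)`), and partial trailing windows are dropped. Windows
#' containing non-positive confluence are skipped with a flag. Rates are the
#' fitted slopes, in log10 confluence change per hour, so they are invariant
#' to rescaling confluence by a positive constant.
#'
#' @param curve a [simulate_confluence_curve()] data.frame or any data.frame
#'   with `time_h` and `confluence` on a regular time grid.
#' @param window_hours,shift_hours window span and shift (hours).
#' @return data.frame of class `growth_rates`: `window`, `t_start`, `t_end`,
#'   `rate`, `intercept` (log10 confluence at t = 0 of the tangent),
#'   `r_squared`, `mean_confluence`, `skipped`. Attribute `points_per_window`
#'   records the quantization.
#' @export
moving_window_rates <- function(curve, window_hours = 24, shift_hours = 8) {
  t <- curve$time_h
  y <- curve$confluence
  stopifnot(length(t) >= 2)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("time grid must be regular")
  dt <- dt[1]
  n_win <- max(2L, round(window_hours / dt))
  n_shift <- max(1L, round(shift_hours / dt))
  starts <- seq(1L, length(t) - n_win + 1L, by = n_shift)
  if (length(starts) == 0) stop("series shorter than one window")
  rows <- lapply(seq_along(starts), function(w) {
    idx <- starts[w]:(starts[w] + n_win - 1L)
    ti <- t[idx]; yi <- y[idx]
    if (any(yi <= 0))
      return(data.frame(window = w, t_start = ti[1], t_end = ti[n_win],
                        rate = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_,
                        mean_confluence = mean(yi), skipped = TRUE))
    li <- log10(yi)
    slope <- stats::cov(ti, li) / stats::var(ti)
    intercept <- mean(li) - slope * mean(ti)
    tss <- sum((li - mean(li))^2)
    rss <- sum((li - intercept - slope * ti)^2)
    data.frame(window = w, t_start = ti[1], t_end = ti[n_win],
               rate = slope, intercept = intercept,
               r_squared = if (tss == 0) 1 else 1 - rss / tss,
               mean_confluence = mean(yi), skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "points_per_window") <- n_win
  attr(out, "points_per_shift") <- n_shift
  class(out) <- c("growth_rates", "data.frame")
  out
}

#' Lag time by tangent intersection with the initial confluence
#'
#' The lag is the time at which the tangent to the log10 growth curve in the
#' maximum-rate window meets the initial confluence:
#' `lag = (log10(c_init) - a) / b` with `a`, `b` the intercept and slope of
#' that window's fit. Windows whose mean confluence exceeds the plateau
#' threshold are excluded from max-rate selection so the tangent is never
#' taken on a saturated region. If no window has a positive rate the lag is
#' censored at the series end.
#'
#' @param curve the confluence series (as in [moving_window_rates()]).
#' @param rates optional precomputed [moving_window_rates()] result.
#' @param initial_confluence confluence reference for the intersection;
#'   default the first observation of the series.
#' @param plateau_threshold windows with mean confluence above this are
#'   ignored when picking the maximum rate (default 0.95).
#' @param ... passed to [moving_window_rates()] when `rates` is `NULL`.
#' @return list of class `lag_estimate`: `lag_time` (hours), `max_rate`,
#'   `window` (row index of the max-rate window), `initial_confluence`,
#'   `censored`, `negative_flag`.
#' @export
lag_time <- function(curve, rates = NULL, initial_confluence = NULL,
                     plateau_threshold = 0.95, ...) {
  if (is.null(rates)) rates <- moving_window_rates(curve, ...)
  if (is.null(initial_confluence)) initial_confluence <- curve$confluence[1]
  stopifnot(initial_confluence > 0)
  ok <- !rates$skipped & rates$mean_confluence <= plateau_threshold &
    is.finite(rates$rate)
  if (!any(ok) || max(rates$rate[ok]) <= 0) {
    return(structure(list(lag_time = NA_real_, max_rate = NA_real_,
                          window = NA_integer_,
                          initial_confluence = initial_confluence,
                          censored = TRUE, negative_flag = FALSE),
                     class = "lag_estimate"))
  }
  w <- which(ok)[which.max(rates$rate[ok])]
  b <- rates$rate[w]
  a <- rates$intercept[w]
  lag <- (log10(initial_confluence) - a) / b
  structure(list(lag_time = lag, max_rate = b, window = w,
                 initial_confluence = initial_confluence,
                 censored = FALSE, negative_flag = lag < 0),
            class = "lag_estimate")
}

#' Expected lag at a given initial confluence, by interpolation
#'
#' Piecewise-linear interpolation of reference `(initial confluence, lag)`
#' pairs measured in untreated cultures; queries outside the reference hull
#' are extended linearly along the nearest segment and flagged. The excess
#' lag of a treated culture is its observed lag minus this expectation.
#'
#' @param reference data.frame with columns `initial_confluence` and `lag`
#'   (>= 2 rows).
#' @param query initial confluence value(s) to evaluate.
#' @param observed optional observed lag(s), same length as `query`; when
#'   given, `excess_lag` is returned.
#' @return data.frame: `query`, `expected_lag`, `extrapolated`, and
#'   `excess_lag` when `observed` is supplied.
#' @export
expected_lag_interpolation <- function(reference, query, observed = NULL) {
  stopifnot(all(c("initial_confluence", "lag") %in% names(reference)),
            nrow(reference) >= 2)
  ref <- reference[order(reference$initial_confluence), ]
  x <- ref$initial_confluence
  y <- ref$lag
  n <- length(x)
  expected <- vapply(query, function(q) {
    if (q <= x[1]) {
      y[1] + (q - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
    } else if (q >= x[n]) {
      y[n] + (q - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    } else {
      stats::approx(x, y, xout = q)$y
    }
  }, numeric(1))
  out <- data.frame(query = query, expected_lag = expected,
                    extrapolated = query < x[1] | query > x[n])
  if (!is.null(observed)) out$excess_lag <- observed - expected
  out
}
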