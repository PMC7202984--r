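# Iterative Loess decomposition and cross-correlation lag analysis.

#' Decompose a series into three Loess components of increasing frequency
#'
#' Local regression (degree-2 Loess with tricube weights) is applied three
#' times with strictly decreasing spans; each pass smooths the current
#' residual and the smooth is subtracted before the next pass.  The three
#' smooths — Loess #1 (slowest) to Loess #3 (fastest) — plus the final
#' residual sum back to the input exactly (telescoping identity).
#'
#' @param series A `circ_series` (or tibble with `time`, `value`).
#' @param spans Three strictly decreasing smoothing fractions (default
#'   `c(0.3, 0.06, 0.012)`).  A degree-2 tricube smoother transmits an
#'   oscillation essentially intact only when its window is at most about
#'   half the period, so on a 30-min series these windows (540, 108 and
#'   21.6 s) pass the slow / mid / fast bands to components #1-#3 in turn.
#' @param degree Local polynomial degree (default 2).
#' @return A `circ_loess`: tibble with `time`, `loess1`, `loess2`, `loess3`,
#'   `residual`; the spans are kept as an attribute.
#' @export
loess_decompose <- function(series, spans = c(0.3, 0.06, 0.012), degree = 2) {
  if (length(spans) != 3 || any(diff(spans) >= 0)) {
    abort("`spans` must be three strictly decreasing fractions.")
  }
  t <- series$time
  if (length(t) * min(spans) < 10) {
    abort("smallest span covers fewer than 10 points.")
  }
  resid <- series$value
  comps <- list()
  for (k in 1:3) {
    fit <- loess(resid ~ t, span = spans[k], degree = degree,
                 family = "gaussian")
    comps[[k]] <- predict(fit, t)
    resid <- resid - comps[[k]]
  }
  structure(tibble(time = t, loess1 = comps[[1]], loess2 = comps[[2]],
                   loess3 = comps[[3]], residual = resid),
            spans = spans, series_name = attr(series, "name"),
            class = c("circ_loess", class(tibble())))
}

#' Cross-correlation function between two uniform series
#'
#' Pearson correlation of the overlapping segments at every displacement on
#' the series' own sample grid (0.1-s steps for 10 Hz series), with the mean
#' and variance taken from each overlap (local normalisation).  Sign
#' convention: a positive `lag_at_max` means the first series lags the
#' second (`a(t) ~ b(t - lag)`).
#'
#' @param a,b `circ_series` on identical grids.
#' @param max_lag Largest displacement examined, s; must be below half the
#'   common duration.
#' @return A `circ_ccf`: tibble with `lag` (s) and `correlation` (`NA` where
#'   an overlap is degenerate), with `ccf_max` and `lag_at_max` attributes
#'   (see [glance.circ_ccf()]).
#' @export
cross_correlation <- function(a, b, max_lag = 30) {
  sa <- series_values(a)
  sb <- series_values(b)
  if (length(sa$x) != length(sb$x) || abs(sa$t[1] - sb$t[1]) > 1e-9 ||
      abs(sa$dt - sb$dt) > 1e-12) {
    abort("`a` and `b` must share the same time grid; see `align_series()`.")
  }
  n <- length(sa$x)
  dt <- sa$dt
  if (max_lag >= n * dt / 2) abort("`max_lag` must be below half the duration.")
  kmax <- round(max_lag / dt)
  lags <- (-kmax):kmax
  corr <- vapply(lags, function(k) {
    if (k >= 0) {
      u <- sa$x[(1 + k):n]; v <- sb$x[1:(n - k)]
    } else {
      u <- sa$x[1:(n + k)]; v <- sb$x[(1 - k):n]
    }
    if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
    stats::cor(u, v)
  }, numeric(1))
  out <- tibble(lag = lags * dt, correlation = corr)
  best <- if (all(is.na(corr))) NA_integer_ else which.max(corr)
  structure(out,
            ccf_max = if (is.na(best)) NA_real_ else corr[best],
            lag_at_max = if (is.na(best)) NA_real_ else lags[best] * dt,
            names_ab = c(attr(a, "name") %||% "a", attr(b, "name") %||% "b"),
            class = c("circ_ccf", class(tibble())))
}

#' @export
print.circ_ccf <- function(x, ...) {
  nm <- attr(x, "names_ab")
  cat("<circ_ccf> ", nm[1], " vs ", nm[2], ": CCF_max = ",
      round(attr(x, "ccf_max"), 3), " at lag ", attr(x, "lag_at_max"),
      " s\n", sep = "")
  invisible(x)
}

#' Compose pairwise lags along a chain of variables
#'
#' Lags measured within a common oscillatory band add: if `a` lags `b` by
#' `lag_ab` and `b` lags `c` by `lag_bc`, then `a` lags `c` by their sum
#' (e.g. R-amplitude trailing SBP by 8.2 s and SBP trailing HR by 3.5 s puts
#' R-amplitude 11.7 s behind HR).
#'
#' @param lag_ab,lag_bc Lags in seconds.
#' @return `lag_ab + lag_bc`, seconds.
#' @export
compose_lags <- function(lag_ab, lag_bc) lag_ab + lag_bc
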