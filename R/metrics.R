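#' Sliding-window evaluation grid
#'
#' Internal helper shared by the sliding statistics: trailing half-open
#' windows `(t - window, t]` evaluated at `stride`-spaced times.
#' @noRd
.window_bounds <- function(times, window, stride, eval_times = NULL) {
  if (is.null(eval_times))
    eval_times <- seq(times[1L], times[length(times)], by = stride)
  lo <- findInterval(eval_times - window, times)        # last index <= t - w
  hi <- findInterval(eval_times, times)                 # last index <= t
  list(eval_times = eval_times, lo = lo, hi = hi)
}

#' Sliding-window histogram of the output measure
#'
#' For each evaluation time `t`, counts the samples with time in the
#' trailing window `(t - window, t]`, binned over `[0, 1]`. Counts in a
#' window always sum to the number of samples it contains; an empty
#' window yields all-zero counts.
#'
#' @param y_series Output-measure samples (values in `[0, 1]`).
#' @param times Sample times (sorted, same length as `y_series`).
#' @param window Window length in seconds (default 300, i.e. 5 min).
#' @param n_bins Number of bins over `[0, 1]` (default 50).
#' @param stride Seconds between evaluations (default 0.3, one input
#'   frame at the standard frame rate).
#' @param eval_times Optional explicit evaluation times (overrides
#'   `stride`).
#' @return A list with `times` (evaluation times), `counts` (matrix,
#'   rows = evaluations, columns = bins) and `breaks` (bin edges).
#' @export
sliding_histogram <- function(y_series, times, window = 300, n_bins = 50L,
                              stride = 0.3, eval_times = NULL) {
  stopifnot(length(y_series) == length(times), n_bins >= 2L, window > 0)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(y_series, breaks, left.open = TRUE), 1L),
              n_bins)
  wb <- .window_bounds(times, window, stride, eval_times)
  counts <- matrix(0L, length(wb$eval_times), n_bins)
  for (b in seq_len(n_bins)) {
    cs <- c(0L, cumsum(bin == b))
    counts[, b] <- cs[wb$hi + 1L] - cs[wb$lo + 1L]
  }
  list(times = wb$eval_times, counts = counts, breaks = breaks)
}

#' Sliding-window mean of a series
#'
#' Mean over the trailing window `(t - window, t]` at each evaluation
#' time; `NA` for empty windows.
#'
#' @inheritParams sliding_histogram
#' @param x Numeric series.
#' @return A data frame with columns `time` and `mean`.
#' @export
sliding_mean <- function(x, times, window = 300, stride = 0.3,
                         eval_times = NULL) {
  stopifnot(length(x) == length(times))
  wb <- .window_bounds(times, window, stride, eval_times)
  cs <- c(0, cumsum(x))
  n <- wb$hi - wb$lo
  m <- (cs[wb$hi + 1L] - cs[wb$lo + 1L]) / n
  m[n == 0L] <- NA_real_
  data.frame(time = wb$eval_times, mean = m)
}

#' Sliding-window input-output correlation
#'
#' Pearson correlation of the input measure `z` and output measure `y`
#' within each trailing window `(t - window, t]`. Windows in which
#' either series has (numerically) zero variance, or fewer than two
#' samples, yield `NA` rather than a silent zero.
#'
#' @inheritParams sliding_histogram
#' @param z_series Input-measure samples.
#' @param y_series Output-measure samples.
#' @return A data frame with columns `time` and `correlation`
#'   (in `[-1, 1]` where defined).
#' @export
io_correlation <- function(z_series, y_series, times, window = 300,
                           stride = 0.3, eval_times = NULL) {
  stopifnot(length(z_series) == length(y_series),
            length(y_series) == length(times))
  # centring on the global means improves cancellation without changing r
  z0 <- z_series - mean(z_series)
  y0 <- y_series - mean(y_series)
  wb <- .window_bounds(times, window, stride, eval_times)
  cz <- c(0, cumsum(z0));  cy <- c(0, cumsum(y0))
  czz <- c(0, cumsum(z0^2)); cyy <- c(0, cumsum(y0^2))
  czy <- c(0, cumsum(z0 * y0))
  n <- wb$hi - wb$lo
  sz <- cz[wb$hi + 1L] - cz[wb$lo + 1L]
  sy <- cy[wb$hi + 1L] - cy[wb$lo + 1L]
  szz <- czz[wb$hi + 1L] - czz[wb$lo + 1L]
  syy <- cyy[wb$hi + 1L] - cyy[wb$lo + 1L]
  szy <- czy[wb$hi + 1L] - czy[wb$lo + 1L]
  vz <- szz - sz^2 / n
  vy <- syy - sy^2 / n
  scale_z <- szz / pmax(n, 1L)  # typical magnitude, for the zero-variance test
  scale_y <- syy / pmax(n, 1L)
  r <- rep(NA_real_, length(n))
  ok <- n >= 2L & vz > 1e-12 * pmax(scale_z, 1e-300) * n &
    vy > 1e-12 * pmax(scale_y, 1e-300) * n
  r[ok] <- pmin(pmax((szy[ok] - sz[ok] * sy[ok] / n[ok]) /
                       sqrt(vz[ok] * vy[ok]), -1), 1)
  data.frame(time = wb$eval_times, correlation = r)
}

#' Detect convergence of the adapted parameters
#'
#' Declares convergence at the earliest time after which every recorded
#' parameter stays within `+/- tolerance` of its trailing-window mean
#' (window = `horizon`) for a full horizon. Operationalizes "run until
#' the adaptation no longer changes qualitatively".
#'
#' @param param_series Numeric matrix or data frame, one column per
#'   parameter (e.g. gain and bias trajectories).
#' @param times Sample times.
#' @param tolerance Absolute tolerance; `NULL` (default) uses 2% of the
#'   magnitude of the trailing-window mean, per sample and parameter.
#' @param horizon Horizon in seconds (default 300).
#' @return A list with `converged` (logical) and `time` (the convergence
#'   time, or `NA` if never satisfied).
#' @export
convergence_monitor <- function(param_series, times, tolerance = NULL,
                                horizon = 300) {
  p <- as.matrix(param_series)
  stopifnot(nrow(p) == length(times), horizon > 0)
  t_end <- times[length(times)]
  if (times[1L] + 2 * horizon > t_end + 1e-9)
    return(list(converged = FALSE, time = NA_real_))
  lo <- findInterval(times - horizon, times)
  hi <- seq_along(times)
  n <- hi - lo
  ok <- rep(TRUE, length(times))
  for (j in seq_len(ncol(p))) {
    cs <- c(0, cumsum(p[, j]))
    m <- (cs[hi + 1L] - cs[lo + 1L]) / n
    tol <- if (is.null(tolerance)) 0.02 * abs(m) else tolerance
    ok <- ok & abs(p[, j] - m) <= tol
  }
  # trailing means only meaningful once a full window is available
  full <- times >= times[1L] + horizon
  bad_times <- times[full & !ok]
  cand <- times[full]
  cand <- cand[cand + horizon <= t_end + 1e-9]
  if (length(cand) == 0L) return(list(converged = FALSE, time = NA_real_))
  if (length(bad_times) == 0L)
    return(list(converged = TRUE, time = cand[1L]))
  nb <- findInterval(cand, bad_times, left.open = TRUE) + 1L
  next_bad <- c(bad_times, Inf)[nb]
  hit <- next_bad > cand + horizon
  if (!any(hit)) return(list(converged = FALSE, time = NA_real_))
  list(converged = TRUE, time = cand[which(hit)[1L]])
}

#' Recovery time of the output statistics after an input switch
#'
#' Tracks the sliding-window mean of the output measure. The pre-switch
#' reference is the window mean just before the switch; recovery is the
#' first post-switch time at which the sliding mean, having left the
#' `+/- band` relative band around the reference, re-enters it. Returns
#' 0 if the sliding mean never leaves the band, and `NA` if it never
#' returns.
#'
#' @param y_series Output-measure samples.
#' @param times Sample times.
#' @param switch_time Time of the input manipulation (seconds).
#' @param window Sliding window in seconds (default 300).
#' @param band Relative band half-width (default 0.25).
#' @param stride Evaluation stride in seconds (default 0.3).
#' @return Recovery time in seconds after the switch (0, positive, or
#'   `NA`).
#' @export
recovery_time <- function(y_series, times, switch_time, window = 300,
                          band = 0.25, stride = 0.3) {
  sm <- sliding_mean(y_series, times, window, stride)
  ref_i <- findInterval(switch_time, sm$time)
  if (ref_i < 1L) stop("switch time precedes the series", call. = FALSE)
  ref <- sm$mean[ref_i]
  post <- sm$time > switch_time
  within <- abs(sm$mean[post] - ref) <= band * abs(ref)
  if (all(within, na.rm = TRUE)) return(0)
  first_out <- which(!within)[1L]
  back <- which(within & seq_along(within) > first_out)
  if (length(back) == 0L) return(NA_real_)
  sm$time[post][back[1L]] - switch_time
}
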