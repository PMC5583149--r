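#' Plot the sliding output distribution of a run
#'
#' Histogram-over-time image of the output measure (vertical axis:
#' output bins over `[0, 1]`; horizontal: time), on a linear or
#' logarithmic color scale, with the gain, bias and sliding input-output
#' correlation beneath.
#'
#' @param run A `dnf_run` from [run_experiment].
#' @param log_scale Use a logarithmic color scale (default `FALSE`).
#' @param window Sliding window in seconds (default 300).
#' @param stride Evaluation stride in seconds (default 6).
#' @return Invisibly, the sliding histogram used for the image.
#' @export
plot_run <- function(run, log_scale = FALSE, window = 300, stride = 6) {
  tr <- run$sim$trace
  sh <- sliding_histogram(tr$y, tr$t, window = window, stride = stride)
  corr <- io_correlation(tr$z, tr$y, tr$t, window = window, stride = stride)
  cnt <- sh$counts
  img <- if (log_scale) log1p(cnt) else pmin(cnt, 100)
  old <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::image(sh$times / 60, (sh$breaks[-1] + sh$breaks[-length(sh$breaks)]) / 2,
                  img, col = grDevices::gray.colors(64, 1, 0),
                  xlab = "", ylab = "output y",
                  main = sprintf("output distribution over time%s",
                                 if (log_scale) " (log scale)" else ""))
  graphics::plot(tr$t / 60, tr$a, type = "l", xlab = "", ylab = "gain a")
  graphics::plot(tr$t / 60, tr$b, type = "l", xlab = "", ylab = "bias b")
  graphics::plot(corr$time / 60, corr$correlation, type = "l",
                 ylim = c(-1, 1), xlab = "time [min]", ylab = "corr(z, y)")
  invisible(sh)
}

#' Plot an input series as an intensity image
#'
#' @param series An [input_series].
#' @return Invisibly, `NULL`.
#' @export
plot_input <- function(series) {
  graphics::image(frame_times(series) / 60,
                  seq_len(series$n_sites) * series$extent / series$n_sites,
                  series$frames, col = grDevices::gray.colors(64, 1, 0),
                  xlab = "time [min]", ylab = "orientation [deg]",
                  main = "input S(x, t)")
  invisible(NULL)
}
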