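#' Synthetic tactile input scenario
#'
#' Describes a population-coded contact stream standing in for recorded
#' haptic data: per frame there are 0, 1 or 2 simultaneous contacts
#' (two-finger contacts at opposing orientations), each with a
#' circularity value in (0, 1) that sets its activation amplitude, and
#' each contact's population response is Gaussian-blurred across the
#' orientation dimension. Contacts persist for a geometric number of
#' frames to emulate slowly varying exploration.
#'
#' @param fps Frames per second (default 10/3, i.e. one frame per 0.3 s,
#'   an exact multiple of the 0.01 s Euler step).
#' @param duration Total duration in seconds.
#' @param circularity_alpha,circularity_beta Shape parameters of the Beta
#'   law that circularity values are drawn from (default Beta(2, 5):
#'   right-skewed, high-circularity contacts are a minority).
#' @param p_contacts Probabilities of 0 / 1 / 2 simultaneous contacts
#'   (default `c(0.3, 0.4, 0.3)`); must sum to 1.
#' @param blur_sigma Gaussian blur width in degrees (default 10.8, i.e.
#'   3 sites on the 100-site / 360-degree grid).
#' @param amplitude_scale Activation units per unit circularity
#'   (default 6, giving input amplitudes in `[0, 6]`).
#' @param combine How overlapping bumps combine: `"max"` (default; two
#'   nearby contacts cannot exceed the encoding ceiling) or `"sum"`.
#' @param persistence_mean Mean contact lifetime in frames (geometric,
#'   support >= 1; default 2). Use 1 for frame-independent resampling.
#' @param scale_factor,offset,switch_time Input manipulation: frames at
#'   `t >= switch_time` are transformed as `S -> scale_factor * S +
#'   offset` (defaults 1 / 0 / `Inf`, i.e. no manipulation).
#' @param loop_block Seconds of freshly generated input to loop over the
#'   full duration (`NULL`, the default, generates the whole stream);
#'   315 s emulates a looped recording period.
#' @param seed Integer seed making the series reproducible.
#' @return An object of class `input_scenario`.
#' @export
input_scenario <- function(fps = 10 / 3, duration = 1800,
                           circularity_alpha = 2, circularity_beta = 5,
                           p_contacts = c(0.3, 0.4, 0.3),
                           blur_sigma = 10.8, amplitude_scale = 6,
                           combine = c("max", "sum"),
                           persistence_mean = 2,
                           scale_factor = 1, offset = 0, switch_time = Inf,
                           loop_block = NULL, seed = NULL) {
  if (!is.numeric(fps) || fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (length(p_contacts) != 3L || any(p_contacts < 0) ||
      abs(sum(p_contacts) - 1) > 1e-8)
    stop("`p_contacts` must be 3 probabilities summing to 1", call. = FALSE)
  if (amplitude_scale <= 0)
    stop("`amplitude_scale` must be positive", call. = FALSE)
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  if (persistence_mean < 1)
    stop("`persistence_mean` must be >= 1 frame", call. = FALSE)
  structure(list(fps = fps, duration = duration,
                 circularity_alpha = circularity_alpha,
                 circularity_beta = circularity_beta,
                 p_contacts = p_contacts, blur_sigma = blur_sigma,
                 amplitude_scale = amplitude_scale,
                 combine = match.arg(combine),
                 persistence_mean = persistence_mean,
                 scale_factor = scale_factor, offset = offset,
                 switch_time = switch_time, loop_block = loop_block,
                 seed = seed),
            class = "input_scenario")
}

#' Draw the contacts of one frame
#'
#' Draws the contact count from `p_contacts`; the first orientation is
#' uniform on `[0, 360)`, and a second contact (the opposing finger)
#' sits at the first orientation plus 180 degrees modulo 360.
#' Circularities are independent Beta draws. Consumes the current R
#' random-number stream.
#'
#' @param scenario An [input_scenario].
#' @return A data frame with columns `orientation` and `circularity`,
#'   0 to 2 rows.
#' @export
sample_contacts <- function(scenario) {
  stopifnot(inherits(scenario, "input_scenario"))
  k <- sample.int(3L, 1L, prob = scenario$p_contacts) - 1L
  if (k == 0L)
    return(data.frame(orientation = numeric(0), circularity = numeric(0)))
  th <- stats::runif(1, 0, 360)
  orientation <- if (k == 2L) c(th, (th + 180) %% 360) else th
  circularity <- stats::rbeta(k, scenario$circularity_alpha,
                              scenario$circularity_beta)
  data.frame(orientation = orientation, circularity = circularity)
}

#' Population-encode contacts into an input frame
#'
#' Each contact contributes a circular Gaussian bump centred at its
#' orientation with peak amplitude `amplitude_scale * circularity` and
#' width `blur_sigma` (degrees); overlapping bumps combine by
#' element-wise maximum (default) or sum. With `blur_sigma = 0` the bump
#' degenerates to a single activated site nearest the contact.
#'
#' @param contacts Data frame as returned by [sample_contacts].
#' @param grid A periodic [field_grid].
#' @param scenario The [input_scenario].
#' @return Numeric input frame of length `grid$n_sites`, all values
#'   >= 0 (before any manipulation).
#' @export
encode_population <- function(contacts, grid, scenario) {
  frame <- numeric(grid$n_sites)
  if (nrow(contacts) == 0L) return(frame)
  for (i in seq_len(nrow(contacts))) {
    amp <- scenario$amplitude_scale * contacts$circularity[i]
    if (scenario$blur_sigma == 0) {
      bump <- numeric(grid$n_sites)
      d <- abs(grid$sites - contacts$orientation[i])
      if (grid$periodic) d <- pmin(d, grid$extent - d)
      bump[which.min(d)] <- amp
    } else {
      d <- abs(grid$sites - contacts$orientation[i])
      if (grid$periodic) d <- pmin(d, grid$extent - d)
      bump <- amp * exp(-d^2 / (2 * scenario$blur_sigma^2))
    }
    frame <- if (scenario$combine == "max") pmax(frame, bump) else frame + bump
  }
  frame
}

#' Frame-sampled input series
#'
#' Container for a time-ordered stack of per-site input frames presented
#' to the field with zero-order hold.
#'
#' @param frames Numeric matrix, rows = frames, columns = grid sites.
#' @param frame_dt Seconds per frame.
#' @param grid The [field_grid] the frames live on.
#' @return An object of class `input_series`.
#' @export
input_series <- function(frames, frame_dt, grid) {
  frames <- as.matrix(frames)
  if (ncol(frames) != grid$n_sites)
    stop("frame width does not match the grid", call. = FALSE)
  if (frame_dt <= 0) stop("`frame_dt` must be positive", call. = FALSE)
  structure(list(frames = frames, frame_dt = frame_dt,
                 n_sites = grid$n_sites, extent = grid$extent,
                 periodic = grid$periodic),
            class = "input_series")
}

#' @export
print.input_series <- function(x, ...) {
  cat(sprintf("input_series: %d frames x %d sites, %g s per frame (%g s total)\n",
              nrow(x$frames), ncol(x$frames), x$frame_dt,
              nrow(x$frames) * x$frame_dt))
  invisible(x)
}

#' Frame times of an input series
#' @param series An [input_series].
#' @return Numeric vector: the onset time of each frame.
#' @export
frame_times <- function(series) {
  (seq_len(nrow(series$frames)) - 1) * series$frame_dt
}

#' Generate a synthetic input series
#'
#' Samples contacts frame by frame (holding each contact configuration
#' for a geometric number of frames with mean `persistence_mean`) and
#' population-encodes them on the grid. With `loop_block` set, only that
#' many seconds are generated and then looped to the full duration,
#' emulating a repeatedly presented recording. Seeded deterministically
#' from `scenario$seed` without disturbing the caller's RNG state. Any
#' scale/offset manipulation in the scenario is *not* applied here; see
#' [manipulate_series].
#'
#' @param scenario An [input_scenario].
#' @param grid A periodic [field_grid].
#' @return An [input_series] of `ceiling(duration * fps)` frames.
#' @export
generate_series <- function(scenario, grid) {
  stopifnot(inherits(scenario, "input_scenario"), inherits(grid, "field_grid"))
  n_frames <- as.integer(ceiling(scenario$duration * scenario$fps))
  n_gen <- if (is.null(scenario$loop_block)) n_frames else
    min(n_frames, as.integer(ceiling(scenario$loop_block * scenario$fps)))

  if (!is.null(scenario$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(scenario$seed)
  }

  frames <- matrix(0, n_gen, grid$n_sites)
  p_new <- 1 / scenario$persistence_mean
  remaining <- 0L
  current <- NULL
  for (i in seq_len(n_gen)) {
    if (remaining <= 0L) {
      current <- sample_contacts(scenario)
      remaining <- stats::rgeom(1, p_new) + 1L
    }
    frames[i, ] <- encode_population(current, grid, scenario)
    remaining <- remaining - 1L
  }
  if (n_gen < n_frames)
    frames <- frames[rep(seq_len(n_gen), length.out = n_frames), , drop = FALSE]
  input_series(frames, 1 / scenario$fps, grid)
}

#' Apply a scale/offset manipulation to an input series
#'
#' Frames at `t >= switch_time` are transformed element-wise as
#' `S -> scale_factor * S + offset`; earlier frames are untouched. This
#' implements sudden changes of the input variance (scaling) or mean
#' (shifting).
#'
#' @param series An [input_series].
#' @param scenario The [input_scenario] carrying `scale_factor`, `offset`
#'   and `switch_time`.
#' @return The manipulated [input_series].
#' @export
manipulate_series <- function(series, scenario) {
  stopifnot(inherits(series, "input_series"))
  post <- frame_times(series) >= scenario$switch_time
  if (any(post))
    series$frames[post, ] <- scenario$scale_factor * series$frames[post, ] +
      scenario$offset
  series
}

#' Read and write input series as CSV
#'
#' The on-disk format is plain CSV, rows = frames and columns = sites,
#' preceded by a single comment line holding the grid metadata, so that
#' user-recorded data can replace the generator.
#'
#' @param series An [input_series].
#' @param path File path.
#' @return `write_input_series` returns `path` invisibly;
#'   `read_input_series` returns the [input_series].
#' @export
write_input_series <- function(series, path) {
  stopifnot(inherits(series, "input_series"))
  meta <- sprintf("# frame_dt=%.17g n_sites=%d extent=%.17g periodic=%d",
                  series$frame_dt, series$n_sites, series$extent,
                  as.integer(series$periodic))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(series$frames, con, sep = ",", row.names = FALSE,
                     col.names = sprintf("s%03d", seq_len(series$n_sites)))
  invisible(path)
}

#' @rdname write_input_series
#' @export
read_input_series <- function(path) {
  meta <- readLines(path, n = 1L)
  if (!startsWith(meta, "#"))
    stop("missing metadata header line", call. = FALSE)
  kv <- strsplit(sub("^#\\s*", "", meta), "\\s+")[[1]]
  vals <- stats::setNames(
    as.numeric(sub("^[^=]+=", "", kv)),
    sub("=.*$", "", kv)
  )
  frames <- as.matrix(utils::read.csv(path, comment.char = "#"))
  dimnames(frames) <- NULL
  grid <- field_grid(vals[["n_sites"]], vals[["extent"]],
                     vals[["periodic"]] == 1)
  input_series(frames, vals[["frame_dt"]], grid)
}
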