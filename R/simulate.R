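#' Simulate a dynamic neural field with intrinsic plasticity
#'
#' Integrates the field dynamics over a frame-sampled input series with
#' zero-order hold (each frame is presented for `floor(frame_dt / dt)`
#' Euler steps) and, if `ip` is given, co-adapts the transfer gain and
#' bias online. The loop is an inlined, allocation-free equivalent of
#' composing [field_step], [output_measure], [input_measure] and
#' [ip_step]; the equivalence is asserted in the test suite.
#'
#' @param series An [input_series].
#' @param grid The matching [field_grid].
#' @param kernel_values Kernel vector from [make_kernel].
#' @param tp Initial [transfer_params].
#' @param dyn [dynamics_config].
#' @param ip An [ip_config], or `NULL` to freeze the parameters.
#' @param fisher Initial [fisher_state] (default zero).
#' @param init_state Initial [field_state] (default: zero activation at
#'   `t = 0`). Supplying the `state` of a previous run resumes it.
#' @param record_every Record the trace every this many Euler steps
#'   (default 1).
#' @return An object of class `dnf_sim`: a list with `trace` (data frame
#'   with columns `t`, `y`, `z`, `a`, `b`, `da_dt`, `db_dt`), and the
#'   final `state`, `tp` and `fisher` for resuming.
#' @examples
#' grid <- field_grid(100)
#' sc <- input_scenario(duration = 30, seed = 1)
#' ser <- generate_series(sc, grid)
#' sim <- simulate_dnf(ser, grid, make_kernel(kernel_params(), grid),
#'                     transfer_params(1, -5), dynamics_config(),
#'                     ip_config())
#' tail(sim$trace$b, 1) # bias after 30 s of adaptation
#' @export
simulate_dnf <- function(series, grid, kernel_values, tp, dyn, ip = NULL,
                         fisher = NULL, init_state = NULL,
                         record_every = 1L) {
  stopifnot(inherits(series, "input_series"), inherits(grid, "field_grid"),
            inherits(tp, "transfer_params"), inherits(dyn, "dynamics_config"))
  if (is.null(fisher)) fisher <- fisher_state()
  n <- grid$n_sites
  # same computational path as lateral_input(), bit for bit
  periodic <- grid$periodic
  if (periodic) Kf <- stats::fft(kernel_values)
  else W <- interaction_matrix(kernel_values, grid)
  dt <- dyn$dt
  rr <- dt / dyn$tau
  spf <- max(1L, as.integer(floor(series$frame_dt / dt + 1e-9)))
  frames <- series$frames
  nf <- nrow(frames)
  total <- nf * spf

  u <- if (is.null(init_state)) numeric(n) else init_state$u
  if (length(u) != n) stop("initial state does not match the grid", call. = FALSE)
  t_now <- if (is.null(init_state)) 0 else init_state$t
  a <- tp$a; b <- tp$b
  F11 <- fisher$f[1, 1]; F12 <- fisher$f[1, 2]; F22 <- fisher$f[2, 2]

  learn <- !is.null(ip)
  if (learn) {
    stopifnot(inherits(ip, "ip_config"))
    eta <- ip$eta; mu <- ip$mu; ng <- ip$use_natural_gradient
    lam <- ip$lambda; eps <- ip$eps
    per_frame <- ip$cadence == "frame"
    c1 <- 2 + 1 / mu
    # frame cadence: unit-weight per-update increments at the frame rate;
    # step cadence: continuous-time rates integrated with the Euler step
    ip_dt <- if (per_frame) 1 else dt
  }

  n_rec <- length(seq.int(1L, total, by = record_every))
  rec_t <- numeric(n_rec); rec_y <- numeric(n_rec); rec_z <- numeric(n_rec)
  rec_a <- numeric(n_rec); rec_b <- numeric(n_rec)
  rec_da <- numeric(n_rec); rec_db <- numeric(n_rec)
  ri <- 0L; k <- 0L
  da_t <- 0; db_t <- 0

  for (fi in seq_len(nf)) {
    S <- frames[fi, ]
    for (s in seq_len(spf)) {
      g <- stats::plogis(a * u + b)
      drive <- if (periodic)
        Re(stats::fft(stats::fft(g) * Kf, inverse = TRUE)) / n
      else drop(W %*% g)
      u <- u + rr * (-u + S + drive)
      t_now <- t_now + dt
      k <- k + 1L
      zi <- which.max(u)
      z_t <- u[zi]
      if (!is.finite(z_t))
        stop(sprintf("field activation diverged at step %d (t = %g s)",
                     k, t_now), call. = FALSE)
      y_t <- stats::plogis(a * z_t + b)

      if (learn && (!per_frame || s == spf)) {
        rb <- 1 - c1 * y_t + y_t * y_t / mu    # bias rate at eta = 1
        if (ng) {
          g1 <- -(1 / a + z_t * rb); g2 <- -rb
          F11 <- (1 - lam) * F11 + lam * g1 * g1
          F12 <- (1 - lam) * F12 + lam * g1 * g2
          F22 <- (1 - lam) * F22 + lam * g2 * g2
          d11 <- F11 + eps; d22 <- F22 + eps
          det <- d11 * d22 - F12 * F12
          da_t <- -eta * (d22 * g1 - F12 * g2) / det
          db_t <- -eta * (d11 * g2 - F12 * g1) / det
        } else {
          db_t <- eta * rb
          da_t <- eta / a + z_t * db_t
        }
        a <- a + ip_dt * da_t
        if (a < .A_MIN) a <- .A_MIN
        b <- b + ip_dt * db_t
      }

      if ((k - 1L) %% record_every == 0L) {
        ri <- ri + 1L
        rec_t[ri] <- t_now; rec_y[ri] <- y_t; rec_z[ri] <- z_t
        rec_a[ri] <- a; rec_b[ri] <- b
        rec_da[ri] <- da_t; rec_db[ri] <- db_t
      }
    }
  }

  structure(list(
    trace = data.frame(t = rec_t, y = rec_y, z = rec_z, a = rec_a, b = rec_b,
                       da_dt = rec_da, db_dt = rec_db),
    state = field_state(drop(u), t_now),
    tp = transfer_params(a, b),
    fisher = fisher_state(matrix(c(F11, F12, F12, F22), 2, 2)),
    steps = total, dt = dt
  ), class = "dnf_sim")
}

#' @export
print.dnf_sim <- function(x, ...) {
  cat(sprintf(paste0("dnf_sim: %d steps (%.1f s simulated), ",
                     "final a = %.4g, b = %.4g\n"),
              x$steps, x$state$t, x$tp$a, x$tp$b))
  invisible(x)
}

#' Save and restore a simulation snapshot
#'
#' Writes the resumable state of a run (field activation, clock, gain,
#' bias, Fisher estimate) to a self-describing serialized container.
#' Resuming from a snapshot and the remaining input frames reproduces
#' the uninterrupted trajectory exactly.
#'
#' @param sim A `dnf_sim` object.
#' @param path File path.
#' @return `save_snapshot` returns `path` invisibly; `load_snapshot`
#'   returns a list with `state`, `tp` and `fisher`, suitable for the
#'   corresponding arguments of [simulate_dnf].
#' @export
save_snapshot <- function(sim, path) {
  stopifnot(inherits(sim, "dnf_sim"))
  saveRDS(list(u = sim$state$u, t = sim$state$t,
               a = sim$tp$a, b = sim$tp$b, fisher = sim$fisher$f),
          path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  x <- readRDS(path)
  list(state = field_state(x$u, x$t),
       tp = transfer_params(x$a, x$b),
       fisher = fisher_state(x$fisher))
}
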