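#' Field integration settings
#'
#' Time constant and explicit-Euler step for the field dynamics
#' `tau * du/dt = -u + S + (omega * g(u))`.
#'
#' @param tau Field time constant in seconds (default 0.1).
#' @param dt Euler step in seconds (default 0.01); must satisfy
#'   `0 < dt <= tau`.
#' @return An object of class `dynamics_config`.
#' @export
dynamics_config <- function(tau = 0.1, dt = 0.01) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0 || dt > tau)
    stop("`dt` must satisfy 0 < dt <= tau", call. = FALSE)
  structure(list(tau = tau, dt = dt), class = "dynamics_config")
}

#' Field activation state
#'
#' Bundles the per-site activation `u(x, t)` with the simulation clock.
#'
#' @param u Numeric vector of activations, one per grid site; all finite.
#' @param t Simulation time in seconds.
#' @return An object of class `field_state`.
#' @export
field_state <- function(u, t = 0) {
  u <- as.numeric(u)
  if (!all(is.finite(u))) stop("activations must be finite", call. = FALSE)
  structure(list(u = u, t = t), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state: %d sites at t = %g s, u in [%g, %g]\n",
              length(x$u), x$t, min(x$u), max(x$u)))
  invisible(x)
}

#' Recurrent lateral drive
#'
#' Convolves the transferred field output with the interaction kernel:
#' `drive[i] = sum_j omega(d(i, j)) * out[j]`, a circular convolution on a
#' periodic grid (computed via FFT) and a truncated (zero-padded) sum
#' otherwise. The convolution is a plain discrete sum over sites, without
#' a `spacing` weighting: the kernel amplitudes are calibrated against
#' the site count, the usual convention in discretized field models.
#'
#' @param output_values Transferred output `g(u)` per site.
#' @param kernel_values Kernel vector from [make_kernel] on the same grid.
#' @param grid The [field_grid].
#' @return Numeric vector of per-site recurrent drive.
#' @export
lateral_input <- function(output_values, kernel_values, grid) {
  n <- grid$n_sites
  if (length(output_values) != n || length(kernel_values) != n)
    stop("output and kernel must match the grid size", call. = FALSE)
  if (grid$periodic) {
    Re(stats::fft(stats::fft(output_values) * stats::fft(kernel_values),
                  inverse = TRUE)) / n
  } else {
    drop(interaction_matrix(kernel_values, grid) %*% output_values)
  }
}

#' One explicit Euler step of the field dynamics
#'
#' Advances `u <- u + (dt / tau) * (-u + S + lateral)` where `lateral` is
#' the kernel-weighted sum of the transferred output, and the clock by
#' `dt`. There is no separate additive resting level: it lives in the
#' transfer bias (`b = a * h`), so with zero input and zero kernel the
#' field relaxes to zero activation.
#'
#' @param state A [field_state].
#' @param input_frame Per-site external input `S(x, t)`.
#' @param kernel_values Kernel vector from [make_kernel].
#' @param tp [transfer_params] (gain and bias of the sigmoid).
#' @param cfg [dynamics_config].
#' @param grid The [field_grid].
#' @return The updated [field_state].
#' @export
field_step <- function(state, input_frame, kernel_values, tp, cfg, grid) {
  u <- state$u
  if (length(input_frame) != length(u))
    stop("input frame length does not match the field", call. = FALSE)
  drive <- lateral_input(transfer(u, tp), kernel_values, grid)
  u_new <- u + (cfg$dt / cfg$tau) * (-u + input_frame + drive)
  if (!all(is.finite(u_new)))
    stop(sprintf("field activation diverged (non-finite) at t = %g s",
                 state$t + cfg$dt), call. = FALSE)
  field_state(u_new, state$t + cfg$dt)
}

#' Scalar output and input measures of the field
#'
#' `output_measure` is the maximum of the transferred field,
#' `y(t) = max_x g(u(x, t))`, in (0, 1): the field's confidence in its
#' current detection. `input_measure` is the activation at the site of
#' that maximum, `z(t) = u(argmax_x g(u(x, t)), t)`; because the transfer
#' is strictly increasing this equals `max(u)`. Ties are broken by the
#' lowest site index.
#'
#' @param state A [field_state].
#' @param tp [transfer_params].
#' @return A scalar: `y` in (0, 1) for `output_measure`, the activation
#'   `z` for `input_measure`.
#' @export
output_measure <- function(state, tp) {
  stats::plogis(tp$a * state$u[which.max(state$u)] + tp$b)
}

#' @rdname output_measure
#' @export
input_measure <- function(state, tp) {
  state$u[which.max(state$u)]
}
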