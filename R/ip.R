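#' Intrinsic-plasticity settings
#'
#' Configuration of the homeostatic adaptation of the transfer gain and
#' bias. The learning rules descend the Kullback-Leibler divergence
#' between the distribution of the scalar output measure and an
#' exponential target with mean `mu`; with `use_natural_gradient` the
#' Euclidean gradient is premultiplied by the regularized inverse of an
#' online Fisher-information estimate.
#'
#' @param eta Learning rate per second (default 0.001).
#' @param mu Target-distribution mean in (0, 1) (default 0.2).
#' @param use_natural_gradient Logical (default `TRUE`).
#' @param lambda Fisher low-pass coefficient in (0, 1] (default 1e-4,
#'   i.e. `tau / 1000` for the standard time constant; 0.01 is the other
#'   value in circulation and can be set here).
#' @param eps Tikhonov regularization added to the Fisher tensor before
#'   inversion (default 1e-4).
#' @param cadence `"frame"` (default): one update per input frame,
#'   applying the learning rules as per-update increments (the discrete
#'   reading of the printed difference rules, matching a realtime
#'   processing loop at the frame rate); `"step"`: one update per Euler
#'   step, scaled by `dt` (the continuous-time reading, with `eta` in
#'   units of per second). The frame cadence reproduces the adaptation
#'   timescales of the reference experiments; the step cadence is about
#'   3.3 times slower at the standard frame rate.
#' @return An object of class `ip_config`.
#' @export
ip_config <- function(eta = 0.001, mu = 0.2, use_natural_gradient = TRUE,
                      lambda = 1e-4, eps = 1e-4,
                      cadence = c("frame", "step")) {
  if (!is.numeric(eta) || eta <= 0) stop("`eta` must be positive", call. = FALSE)
  if (!is.numeric(mu) || mu <= 0 || mu >= 1)
    stop("`mu` must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1)
    stop("`lambda` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be positive", call. = FALSE)
  structure(list(eta = eta, mu = mu,
                 use_natural_gradient = isTRUE(use_natural_gradient),
                 lambda = lambda, eps = eps,
                 cadence = match.arg(cadence)),
            class = "ip_config")
}

#' Running Fisher-information estimate
#'
#' Symmetric positive-semidefinite 2x2 moving-average estimate of the
#' Fisher information of the (gain, bias) parameters, accumulated from
#' per-sample gradient outer products.
#'
#' @param f A symmetric PSD 2x2 matrix (default zero).
#' @return An object of class `fisher_state`.
#' @export
fisher_state <- function(f = matrix(0, 2, 2)) {
  f <- as.matrix(f)
  if (!identical(dim(f), c(2L, 2L)) || !all(is.finite(f)))
    stop("Fisher estimate must be a finite 2x2 matrix", call. = FALSE)
  if (max(abs(f - t(f))) > 1e-10)
    stop("Fisher estimate must be symmetric", call. = FALSE)
  if (min(eigen(f, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("Fisher estimate must be positive semidefinite", call. = FALSE)
  structure(list(f = f), class = "fisher_state")
}

#' Intrinsic-plasticity learning rates
#'
#' `bias_rate` is the bias learning rule
#' `db/dt = eta * (1 - (2 + 1/mu) * y + y^2 / mu)`, a downward-opening
#' quadratic in the output measure `y`: positive for small `y` (raise the
#' resting level when the field is silent), negative for large `y`
#' (lower it when the field is active). `gain_rate` is
#' `da/dt = eta / a + z * db/dt`: the gain drifts up at `eta / a` and is
#' additionally steered by the input measure `z` in the direction of the
#' bias change.
#'
#' @param y Output measure in `[0, 1]`.
#' @param z Input measure (activation units).
#' @param db_dt A bias rate as returned by `bias_rate`.
#' @param a Current gain (> 0).
#' @param mu Target mean in (0, 1).
#' @param eta Learning rate.
#' @return The parameter rate of change, per second.
#' @examples
#' bias_rate(0, 0.2, 1) # 1
#' bias_rate(1, 0.2, 1) # 1 - 7 + 5 = -1
#' @export
bias_rate <- function(y, mu, eta) {
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be positive", call. = FALSE)
  eta * (1 - (2 + 1 / mu) * y + y^2 / mu)
}

#' @rdname bias_rate
#' @export
gain_rate <- function(z, db_dt, a, eta) {
  if (!is.numeric(a) || a <= 0) stop("gain `a` must be positive", call. = FALSE)
  eta / a + z * db_dt
}

#' Per-sample Euclidean gradient of the divergence loss
#'
#' The gradient of the per-sample Kullback-Leibler integrand with respect
#' to (gain, bias), i.e. `(-gain_rate, -bias_rate)` with the learning
#' rate factored out, so that `-eta * euclidean_gradient(...)` reproduces
#' the plain-gradient parameter rates exactly.
#'
#' @inheritParams bias_rate
#' @return Numeric 2-vector `(dL/da, dL/db)`.
#' @export
euclidean_gradient <- function(y, z, a, mu) {
  r <- bias_rate(y, mu, 1)
  c(-(1 / a + z * r), -r)
}

#' Update the online Fisher estimate
#'
#' Exponential moving average of the gradient outer product:
#' `F <- (1 - lambda) * F + lambda * grad %o% grad`. Symmetry and
#' positive semidefiniteness are preserved exactly.
#'
#' @param fs A [fisher_state].
#' @param grad Per-sample gradient 2-vector.
#' @param lambda Low-pass coefficient in (0, 1].
#' @return The updated [fisher_state].
#' @export
update_fisher <- function(fs, grad, lambda) {
  stopifnot(inherits(fs, "fisher_state"))
  f <- (1 - lambda) * fs$f + lambda * tcrossprod(grad)
  structure(list(f = f), class = "fisher_state")
}

# 2x2 symmetric solve of (f + eps I) s = g; det >= eps^2 > 0 for PSD f
.solve_regularized <- function(f, g, eps) {
  d11 <- f[1, 1] + eps
  d22 <- f[2, 2] + eps
  d12 <- f[1, 2]
  det <- d11 * d22 - d12 * d12
  if (!is.finite(det) || det <= 0)
    stop("regularized Fisher tensor is numerically singular", call. = FALSE)
  c(d22 * g[1] - d12 * g[2], d11 * g[2] - d12 * g[1]) / det
}

#' Natural-gradient parameter update
#'
#' Applies `theta <- theta - eta * (F + eps I)^-1 grad` with an exact
#' 2x2 inversion of the regularized Fisher tensor, then clamps the gain
#' from below (at 1e-6) to keep the transfer orientation-preserving.
#'
#' @param tp [transfer_params] holding the current (gain, bias).
#' @param grad Euclidean gradient 2-vector.
#' @param fs [fisher_state].
#' @param eta Step size.
#' @param eps Tikhonov regularization (> 0).
#' @return The updated [transfer_params].
#' @export
natural_update <- function(tp, grad, fs, eta, eps) {
  stopifnot(inherits(tp, "transfer_params"), inherits(fs, "fisher_state"))
  s <- .solve_regularized(fs$f, grad, eps)
  a <- max(tp$a - eta * s[1], .A_MIN)
  structure(list(a = a, b = tp$b - eta * s[2]), class = "transfer_params")
}

#' One intrinsic-plasticity update
#'
#' Integrates the learning rules over one Euler step of length `dt`.
#' With the natural gradient, the per-sample Euclidean gradient first
#' updates the Fisher estimate and the regularized natural step is then
#' applied with step size `eta * dt`; otherwise the plain rates are
#' accumulated as `(a, b) <- (a, b) + dt * (da/dt, db/dt)`. The gain is
#' clamped below at 1e-6 in both paths.
#'
#' @param tp [transfer_params].
#' @param fs [fisher_state] (carried through untouched on the plain path).
#' @param y Output measure for this sample.
#' @param z Input measure for this sample.
#' @param cfg [ip_config].
#' @param dt Integration step in seconds.
#' @return A list with elements `tp` and `fisher`.
#' @export
ip_step <- function(tp, fs, y, z, cfg, dt) {
  stopifnot(inherits(cfg, "ip_config"))
  if (cfg$use_natural_gradient) {
    g <- euclidean_gradient(y, z, tp$a, cfg$mu)
    fs <- update_fisher(fs, g, cfg$lambda)
    tp <- natural_update(tp, g, fs, cfg$eta * dt, cfg$eps)
  } else {
    db <- bias_rate(y, cfg$mu, cfg$eta)
    da <- gain_rate(z, db, tp$a, cfg$eta)
    tp <- structure(list(a = max(tp$a + dt * da, .A_MIN), b = tp$b + dt * db),
                    class = "transfer_params")
  }
  list(tp = tp, fisher = fs)
}

#' Empirical divergence of output samples from the exponential target
#'
#' Histogram-based Kullback-Leibler divergence (in nats) of a sample of
#' output measures against the exponential density with mean `mu`,
#' renormalized on (0, 1) because the logistic output cannot exceed 1.
#' A diagnostic only; the learning rules do not use it.
#'
#' @param y_samples Output-measure samples in (0, 1).
#' @param mu Target mean (> 0).
#' @param n_bins Number of histogram bins over `[0, 1]` (default 50).
#' @return Non-negative divergence estimate in nats.
#' @export
empirical_kld <- function(y_samples, mu, n_bins = 50L) {
  if (length(y_samples) == 0L) stop("no samples given", call. = FALSE)
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be positive", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(y_samples, breaks, left.open = TRUE), 1L),
              n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(y_samples)
  # target bin masses: truncated exponential on (0, 1)
  q <- (exp(-breaks[-length(breaks)] / mu) - exp(-breaks[-1] / mu)) /
    (1 - exp(-1 / mu))
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}
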