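#' Discretized feature dimension of a dynamic neural field
#'
#' Builds the sampling grid for a one-dimensional field spanned over a
#' (by default periodic) feature dimension such as contact orientation in
#' degrees. Sites are placed at `0, spacing, 2*spacing, ...` where
#' `spacing = extent / n_sites`.
#'
#' @param n_sites Number of sample points (>= 3).
#' @param extent Length of the feature dimension in its own units
#'   (default 360 degrees).
#' @param periodic Logical; if `TRUE` (default) the dimension wraps, so
#'   distances and lateral interactions are circular.
#' @return An object of class `field_grid` with elements `n_sites`,
#'   `extent`, `periodic`, `spacing` and `sites` (site positions).
#' @examples
#' g <- field_grid(100)
#' g$spacing # 3.6 degrees per site
#' @export
field_grid <- function(n_sites = 100L, extent = 360, periodic = TRUE) {
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 3L)
    stop("`n_sites` must be an integer >= 3", call. = FALSE)
  if (!is.numeric(extent) || length(extent) != 1L || extent <= 0)
    stop("`extent` must be a positive scalar", call. = FALSE)
  spacing <- extent / n_sites
  structure(
    list(n_sites = n_sites, extent = extent, periodic = isTRUE(periodic),
         spacing = spacing, sites = (seq_len(n_sites) - 1) * spacing),
    class = "field_grid"
  )
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: %d sites over [0, %g)%s, spacing %g\n",
              x$n_sites, x$extent, if (x$periodic) " (periodic)" else "",
              x$spacing))
  invisible(x)
}

#' Lateral interaction kernel parameters
#'
#' Parameters of the difference-of-Gaussians ("Mexican hat") interaction
#' kernel: short-range excitation minus long-range inhibition. The
#' inhibition strength is stored as a positive magnitude and always
#' subtracted. Widths are in grid-index units (sites), matching the
#' convention in which the kernel amplitudes are calibrated against a
#' fixed field size.
#'
#' @param c_exc Excitation strength (> 0).
#' @param sigma_exc Excitation width in sites (> 0).
#' @param c_inh Inhibition strength, positive magnitude (>= 0).
#' @param sigma_inh Inhibition width in sites (> sigma_exc).
#' @return An object of class `kernel_params`.
#' @examples
#' kernel_params() # the standard preset: 14 / 2 / 7 / 6
#' @export
kernel_params <- function(c_exc = 14, sigma_exc = 2, c_inh = 7, sigma_inh = 6) {
  if (!is.numeric(sigma_exc) || sigma_exc <= 0 ||
      !is.numeric(sigma_inh) || sigma_inh <= 0)
    stop("kernel widths must be positive", call. = FALSE)
  if (sigma_inh <= sigma_exc)
    stop("`sigma_inh` must exceed `sigma_exc` (long-range inhibition)",
         call. = FALSE)
  if (c_exc <= 0) stop("`c_exc` must be positive", call. = FALSE)
  if (c_inh < 0)
    stop("`c_inh` is a positive magnitude (it is always subtracted)",
         call. = FALSE)
  structure(list(c_exc = c_exc, sigma_exc = sigma_exc,
                 c_inh = c_inh, sigma_inh = sigma_inh),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("kernel_params: exc %g (sigma %g), inh %g (sigma %g)\n",
              x$c_exc, x$sigma_exc, x$c_inh, x$sigma_inh))
  invisible(x)
}

#' Evaluate the interaction kernel on a grid
#'
#' Computes `omega(d) = c_exc * exp(-d^2 / (2 sigma_exc^2)) -
#' c_inh * exp(-d^2 / (2 sigma_inh^2))` at the distance (in grid-index
#' units) between site 1 and every site. On a periodic grid the distance
#' is circular, `d = min(m, n - m)` for index offset `m`, so the returned
#' vector is symmetric under reversal of the offset.
#'
#' With `normalized = TRUE` each Gaussian is divided by its own
#' `sqrt(2 pi) * sigma`, so the strengths specify the *integrated*
#' lateral weight rather than the peak value — the convention of common
#' neural-field software, in which kernel strengths stay comparable
#' across widths. The standard preset uses this convention: with peak-
#' value Gaussians the 14/2/7/6 kernel puts the field deep in the
#' self-sustaining memory regime, where detections never release and the
#' output decouples from the input, while the integrated-weight reading
#' places it at the detection instability that the adaptation is
#' designed to straddle (see the package vignette).
#'
#' @param params A [kernel_params] object.
#' @param grid A [field_grid] object.
#' @param normalized If `TRUE`, use area-normalized Gaussians (strength
#'   = integrated weight). Default `FALSE` (strength = peak value).
#' @return Numeric vector of length `grid$n_sites`: the kernel at index
#'   offsets `0 .. n_sites - 1`.
#' @examples
#' k <- make_kernel(kernel_params(), field_grid(100))
#' k[1] # omega(0) = 14 - 7 = 7
#' @export
make_kernel <- function(params, grid, normalized = FALSE) {
  stopifnot(inherits(params, "kernel_params"), inherits(grid, "field_grid"))
  m <- seq_len(grid$n_sites) - 1
  d <- if (grid$periodic) pmin(m, grid$n_sites - m) else m
  s_exc <- if (normalized) sqrt(2 * pi) * params$sigma_exc else 1
  s_inh <- if (normalized) sqrt(2 * pi) * params$sigma_inh else 1
  params$c_exc / s_exc * exp(-d^2 / (2 * params$sigma_exc^2)) -
    params$c_inh / s_inh * exp(-d^2 / (2 * params$sigma_inh^2))
}

#' Lateral interaction matrix
#'
#' Expands a kernel vector (as returned by [make_kernel]) into the full
#' site-by-site coupling matrix `W[i, j] = omega(d(i, j))`: circulant on a
#' periodic grid, Toeplitz otherwise. Used to apply the lateral
#' interaction as a matrix-vector product.
#'
#' @param kernel_values Kernel vector from [make_kernel].
#' @param grid The matching [field_grid].
#' @return An `n_sites` x `n_sites` numeric matrix.
#' @export
interaction_matrix <- function(kernel_values, grid) {
  n <- grid$n_sites
  if (length(kernel_values) != n)
    stop("kernel length does not match grid size", call. = FALSE)
  i <- matrix(seq_len(n), n, n)
  off <- abs(i - t(i))
  if (grid$periodic) off <- pmin(off, n - off)
  matrix(kernel_values[off + 1L], n, n)
}
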