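#' Gain and bias of the parametric sigmoid transfer function
#'
#' The field output is `g(u) = 1 / (1 + exp(-(a * u + b)))`: a logistic
#' with global gain `a` and bias `b`. The bias encodes a gain-dependent
#' resting level `h = b / a`; with a negative bias the half-activation
#' point `u = -b/a` acts as the detection threshold of the field. These
#' two parameters are the state adapted by intrinsic plasticity.
#'
#' @param a Gain (> 0).
#' @param b Bias (typically negative).
#' @return An object of class `transfer_params`.
#' @examples
#' tp <- transfer_params(1, -5) # standard initialisation
#' resting_level(tp)            # h = b / a = -5
#' @export
transfer_params <- function(a = 1, b = -5) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("gain `a` must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("bias `b` must be a finite scalar", call. = FALSE)
  structure(list(a = a, b = b), class = "transfer_params")
}

#' @export
print.transfer_params <- function(x, ...) {
  cat(sprintf("transfer_params: gain a = %g, bias b = %g (threshold -b/a = %g)\n",
              x$a, x$b, -x$b / x$a))
  invisible(x)
}

#' @rdname transfer_params
#' @param tp A `transfer_params` object.
#' @export
resting_level <- function(tp) tp$b / tp$a

# lower clamp on the gain: keeps the transfer orientation-preserving and
# the eta/a learning term finite
.A_MIN <- 1e-6

#' Apply the sigmoid transfer function
#'
#' Element-wise logistic of `a * u + b`, computed through [stats::plogis]
#' (overflow-safe in both tails). Strictly increasing in `u`; output in
#' the open interval (0, 1); half-activation exactly at `u = -b/a`.
#'
#' @param u Numeric vector of activation values.
#' @param tp A [transfer_params] object.
#' @return Numeric vector of outputs in (0, 1).
#' @examples
#' transfer(0, transfer_params(1, 0))    # 0.5
#' transfer(0.5, transfer_params(2, -1)) # 0.5
#' @export
transfer <- function(u, tp) {
  stopifnot(inherits(tp, "transfer_params"))
  stats::plogis(tp$a * u + tp$b)
}
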