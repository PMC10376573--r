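#' Pseudo-Huber loss
#'
#' Smooth robust loss `delta^2 * (sqrt(1 + (x/delta)^2) - 1)`. It behaves
#' like the squared loss (`x^2/2`) for small residuals and like the absolute
#' loss (`delta * |x|`) for large ones, making it robust to outliers while
#' remaining differentiable everywhere.
#'
#' @param x residuals; a numeric scalar, vector or array.
#' @param delta the transition scale between quadratic and linear behaviour
#'   (must be positive). Default 1.
#' @return elementwise loss values, same shape as `x`, all nonnegative.
#' @examples
#' pseudo_huber(3, delta = 1)   # sqrt(10) - 1
#' @export
pseudo_huber <- function(x, delta = 1) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a single positive number")
  delta^2 * (sqrt(1 + (x / delta)^2) - 1)
}

#' Derivative of the pseudo-Huber loss with respect to the residual
#' @noRd
pseudo_huber_grad <- function(x, delta = 1) {
  x / sqrt(1 + (x / delta)^2)
}

#' Log-cosh loss
#'
#' `log(cosh(x))`, a twice-differentiable robust loss. Computed
#' overflow-safely: for large `|x|` the identity
#' `log(cosh(x)) = |x| - log(2) + log(1 + exp(-2|x|))` is used, so values up
#' to `|x| = 1e4` and beyond do not overflow.
#'
#' @param x residuals; numeric scalar, vector or array.
#' @return elementwise loss values, same shape as `x`, all nonnegative.
#' @examples
#' log_cosh(1)    # ~0.433781
#' log_cosh(50)   # ~50 - log(2)
#' @export
log_cosh <- function(x) {
  ax <- abs(x)
  ax - log(2) + log1p(exp(-2 * ax))
}

#' Combined autoencoder reconstruction loss
#'
#' The scale-adaptation module is trained with a custom loss combining two
#' pseudo-Huber terms on the high-resolution side (the high-resolution
#' branch output and the latent feature map, each compared against the
#' high-resolution target) with one log-cosh term on the low-resolution
#' branch (the reconstruction at the original input size compared against
#' the original image):
#'
#' `w_hi * (mean PH(high - target) + mean PH(f_ae - target)) +
#'  w_lo * mean logcosh(low - original)`
#'
#' Each term is a mean over all pixels and channels.
#'
#' @param outputs an `oct_ae_outputs` object (or a list with elements
#'   `f_ae`, `high_res`, `low_res_reconstruction`) as returned by
#'   [ae_forward()].
#' @param original the original input image as an H x W x 3 array.
#' @param target_hi the high-resolution reconstruction target (same shape
#'   as `outputs$high_res`).
#' @param config an [ae_config()]; supplies `delta` and `loss_weights`.
#' @return a single nonnegative number; zero iff every residual is zero.
#' @export
ae_loss <- function(outputs, original, target_hi, config) {
  stopifnot(is.list(outputs))
  if (!identical(dim(outputs$high_res), dim(target_hi)))
    stop("shape mismatch: high_res ", paste(dim(outputs$high_res), collapse = "x"),
         " vs target_hi ", paste(dim(target_hi), collapse = "x"))
  if (!identical(dim(outputs$f_ae), dim(target_hi)))
    stop("shape mismatch: f_ae vs target_hi")
  if (!identical(dim(outputs$low_res_reconstruction), dim(original)))
    stop("shape mismatch: low_res_reconstruction ",
         paste(dim(outputs$low_res_reconstruction), collapse = "x"),
         " vs original ", paste(dim(original), collapse = "x"))
  w <- config$loss_weights
  hi <- mean(pseudo_huber(outputs$high_res - target_hi, config$delta)) +
        mean(pseudo_huber(outputs$f_ae - target_hi, config$delta))
  lo <- mean(log_cosh(outputs$low_res_reconstruction - original))
  w[1] * hi + w[2] * lo
}
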