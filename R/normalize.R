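#' Whole-image T2w intensity normalization
#'
#' MRI is not a calibrated modality, so T2w intensities are standardized per
#' subject before any wall-signal measurement: every voxel is mapped through
#'
#' \deqn{f(x) = (x - \mu_x) / \sigma_x + 3\sigma_x}
#'
#' where \eqn{\mu_x} and \eqn{\sigma_x} are the mean and population standard
#' deviation over *all* voxels of the original volume (background included).
#' The result has SD exactly 1 and mean \eqn{3\sigma_x}, so the offset keeps
#' wall intensities positive while the per-subject scale is removed.
#'
#' @param volume a [brw_volume()] (any modality; typically T2w-like).
#' @return A list of class `brw_normalization`: `volume` (the normalized
#'   [brw_volume()]), `mu_x`, `sigma_x`.
#' @export
normalize_t2 <- function(volume) {
  stopifnot(is_volume(volume))
  x <- volume$data
  n <- length(x)
  if (n < 2) stop("volume must have at least 2 voxels", call. = FALSE)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)  # population SD over the whole image
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate input: constant volume has zero intensity SD, ",
         "normalization is undefined", call. = FALSE)
  }
  out <- (x - mu) / sigma + 3 * sigma
  structure(list(
    volume = brw_volume(out, spacing = volume$spacing,
                        modality = volume$modality, origin = volume$origin),
    mu_x = mu, sigma_x = sigma
  ), class = "brw_normalization")
}

#' Apply the normalization map to a scalar intensity
#'
#' Maps a raw intensity through the same transform as [normalize_t2()] using
#' a fitted result's `mu_x`/`sigma_x` — the analytic oracle for what a mean
#' wall signal becomes after normalization.
#'
#' @param norm a `brw_normalization` result.
#' @param x raw intensity value(s).
#' @return Normalized intensity value(s).
#' @export
normalize_value <- function(norm, x) {
  stopifnot(inherits(norm, "brw_normalization"))
  (x - norm$mu_x) / norm$sigma_x + 3 * norm$sigma_x
}

#' @export
print.brw_normalization <- function(x, ...) {
  cat(sprintf("<brw_normalization> mu_x = %.4g, sigma_x = %.4g\n",
              x$mu_x, x$sigma_x))
  cat(sprintf("  normalized mean = %.4g (= 3*sigma_x), SD = 1\n",
              3 * x$sigma_x))
  invisible(x)
}
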