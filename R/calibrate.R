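# Calibration (localization) of the plot random effect for a new stand.
#
# Each family's conditional mean m(d) is invertible in (alpha + phi); the
# calibrated effect is the per-tree inversion averaged over the sub-sample.
# For G3/G4 the inversion of the mean (which carries the lognormal
# sigma^2/4 * (1 - e^{-beta d}) correction) is used, so a single-tree
# calibration makes the conditional mean pass exactly through that tree.

#' Calibrate the random effect from a sub-sample of trees
#'
#' Given a fitted mixed-effects model (or a plain parameter set) and a small
#' sub-sample of \eqn{m} measured trees from a new stand, returns the
#' closed-form calibrated \eqn{\hat\phi}: the mean-inversion of each tree's
#' (d, h) averaged over trees.  This is a mean inversion, not a posterior
#' mode — it does not shrink toward 0 for sparse data (see
#' [hd_laplace_plot()] for the shrinking mode).
#'
#' Bertalanffy trees whose denominator
#' \eqn{\ln((1-\gamma e^{-\beta d})/(1-\gamma))} is within 1e-8 of zero are
#' dropped from the average with a warning; all families require
#' \eqn{d > d_0}.
#'
#' @param object an \code{hd_fit} (mixed) or [hd_params()] object.
#' @param newdata data frame with columns \code{d_cm} and \code{h_m}
#'   (\eqn{m \ge 1} rows).
#' @param family family code, only needed when \code{object} is a bare
#'   parameter set whose family should be checked.
#' @return The scalar \eqn{\hat\phi}.
#' @examples
#' p <- hd_params("V", alpha = 26.63, beta = 0.0667, sigma = 0.606,
#'                sigma_phi = 3.94)
#' sub <- data.frame(d_cm = c(20, 30), h_m = c(21, 25))
#' hd_calibrate(p, sub)
#' @export
hd_calibrate <- function(object, newdata, family = NULL) {
  p <- as_hd_params(object)
  code <- if (is.null(family)) p$family else hd_family_code(family)
  if (p$family != code)
    stop("params are for family ", p$family, ", not ", code, call. = FALSE)
  d <- newdata$d_cm; h <- newdata$h_m
  if (is.null(d) || is.null(h) || length(d) < 1L)
    stop("'newdata' needs at least one row with d_cm and h_m",
         call. = FALSE)
  d0 <- hd_d0(code)
  if (any(d <= d0))
    stop("calibration requires d > d0 = ", d0, call. = FALSE)
  a <- p$alpha; b <- p$beta; s2 <- p$sigma^2
  phi_j <- switch(code,
    V = {
      e <- exp(-b * d)
      (h - a - (H0 - a) * e) / (1 - e)
    },
    G3 = {
      e <- exp(-b * d)
      (log(h) - log(H0) * e) * b / (1 - e) - s2 / 4 * (e - 1) - a
    },
    G4 = {
      e <- exp(-b * d)
      (log(h - p$gamma) - log(H0 - p$gamma) * e) * b / (1 - e) -
        s2 / 4 * (e - 1) - a
    },
    B = {
      den <- log1p(-p$gamma * exp(-b * d)) - log1p(-p$gamma)
      drop_idx <- abs(den) < 1e-8
      if (any(drop_idx)) {
        warning(sum(drop_idx),
                " tree(s) dropped from Bertalanffy calibration ",
                "(near-zero denominator at small d)")
        if (all(drop_idx))
          stop("no usable trees for calibration", call. = FALSE)
      }
      ((log(h) - log(H0)) / den - a)[!drop_idx]
    },
    G = (log(h) - log(H0) + b * (d - 0.001)) / log(d / 0.001) - a)
  mean(phi_j)
}
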