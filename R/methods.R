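# S3 methods for "hd_fit" objects.

#' @export
print.hd_fit <- function(x, digits = 4, ...) {
  fam <- hd_families()
  cat("SDE height-diameter model: ", fam$name[fam$code == x$family],
      " (", x$mode, " effects)\n", sep = "")
  cat("  n =", x$n_obs, "trees in", x$n_plots, "plots\n")
  print(round(x$coefficients, digits))
  cat("logLik:", format(x$loglik, digits = digits + 3),
      "  AIC:", format(x$aic, digits = digits + 3),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.hd_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.hd_fit")
}

#' @export
print.summary.hd_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  fam <- hd_families()
  cat("SDE height-diameter model: ", fam$name[fam$code == f$family],
      " (", f$mode, " effects)\n", sep = "")
  cat("  n =", f$n_obs, "trees in", f$n_plots, "plots;",
      if (f$converged) "converged" else "NOT converged", "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nlogLik:", format(f$loglik, digits = digits + 3),
      "  AIC:", format(f$aic, digits = digits + 3), "\n")
  if (f$mode == "mixed")
    cat("Random effect: phi_i on alpha;",
        length(f$ranef), "plot modes (see hd_ranef)\n")
  invisible(x)
}

#' @export
coef.hd_fit <- function(object, ...) object$coefficients

#' @export
logLik.hd_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.hd_fit <- function(object, ...) object$vcov

#' Per-plot random-effect modes of a mixed fit
#'
#' @param object an \code{hd_fit} from \code{mode = "mixed"}.
#' @return Named vector of plot-level \eqn{\hat\phi_i} (posterior modes under
#'   the fitted parameters); \code{NULL} for fixed-effects fits.
#' @export
hd_ranef <- function(object) {
  stopifnot(inherits(object, "hd_fit"))
  object$ranef
}

#' Predict heights from a fitted model
#'
#' @param object an \code{hd_fit}.
#' @param newdata data frame with a \code{d_cm} column (defaults to the
#'   training data).
#' @param type \code{"mean"} (conditional mean), \code{"quantile"}
#'   (conditional quantile at \code{p}), or \code{"stochastic"} (a random
#'   draw from the fitted transition law, the stochastic-prediction scheme:
#'   \eqn{\hat h = F^{-1}(U)} with \eqn{U \sim \mathrm{Unif}(0,1)}).
#' @param phi random effect: a number (0 = population curve), a vector
#'   recycled over rows, or \code{"ranef"} to look up each row's
#'   \code{plot_id} in the fitted plot modes.
#' @param p probability for \code{type = "quantile"}.
#' @param seed optional seed for \code{type = "stochastic"}.
#' @param ... unused.
#' @return Vector of heights, m.
#' @export
predict.hd_fit <- function(object, newdata = NULL,
                           type = c("mean", "quantile", "stochastic"),
                           phi = 0, p = 0.5, seed = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  d <- newdata$d_cm
  if (is.null(d)) stop("'newdata' needs a d_cm column", call. = FALSE)
  if (identical(phi, "ranef")) {
    if (is.null(object$ranef))
      stop("no random effects in a fixed-effects fit", call. = FALSE)
    phi <- unname(object$ranef[as.character(newdata$plot_id)])
    phi[is.na(phi)] <- 0
  }
  switch(type,
    mean = hd_mean(object$family, object$params, d = d, phi = phi),
    quantile = hd_quantile(object$family, object$params, d = d,
                           p_q = p, phi = phi),
    stochastic = {
      if (!is.null(seed)) set.seed(seed)
      u <- stats::runif(length(d))
      hd_quantile(object$family, object$params, d = d, p_q = u, phi = phi)
    })
}

#' @export
fitted.hd_fit <- function(object, ...) {
  phi <- if (object$mode == "mixed") "ranef" else 0
  predict(object, type = "mean", phi = phi)
}

#' @export
residuals.hd_fit <- function(object, ...) {
  object$data$h_m - fitted(object)
}

#' Simulate new datasets from a fitted model
#'
#' Redraws plot effects \eqn{\phi_i \sim N(0, \hat\sigma_\phi^2)} (mixed
#' fits) and heights from the fitted transition law at the training
#' diameters.
#'
#' @param object an \code{hd_fit}.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with \code{nsim} columns of simulated heights,
#'   one row per training observation.
#' @export
simulate.hd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data$d_cm
  pid <- match(object$data$plot_id, unique(object$data$plot_id))
  sp <- if (object$mode == "mixed") object$coefficients[["sigma_phi"]] else 0
  out <- replicate(nsim, {
    phi <- stats::rnorm(max(pid), 0, sp)[pid]
    hd_sample(length(d), object$family, object$params, d = d, phi = phi)
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.hd_fit <- function(x, p_band = c(0.1, 0.9), n_grid = 100, ...) {
  d <- x$data$d_cm
  grid <- seq(max(min(d) * 0.5, hd_d0(x$family) + 1e-3), max(d) * 1.05,
              length.out = n_grid)
  m <- hd_mean(x$family, x$params, d = grid)
  lo <- hd_quantile(x$family, x$params, d = grid, p_q = p_band[1])
  hi <- hd_quantile(x$family, x$params, d = grid, p_q = p_band[2])
  graphics::plot(d, x$data$h_m, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "diameter at breast height (cm)",
                 ylab = "total height (m)",
                 ylim = range(x$data$h_m, lo, hi), ...)
  graphics::lines(grid, m, lwd = 2)
  graphics::lines(grid, lo, lty = 2)
  graphics::lines(grid, hi, lty = 2)
  graphics::legend("bottomright", bty = "n",
                   legend = c("conditional mean",
                              sprintf("%g / %g quantiles", p_band[1],
                                      p_band[2])),
                   lty = c(1, 2), lwd = c(2, 1))
  invisible(x)
}
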