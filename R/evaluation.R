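# Model comparison and predictive fit statistics.

#' Kullback-Leibler information criterion between two fitted densities
#'
#' Sample estimate of the expected log-density difference,
#' \deqn{\mathrm{KLIC} = \frac{1}{n} \sum_i \sum_j \left[\ln f_A(h_{ij},
#' d_{ij}) - \ln f_B(h_{ij}, d_{ij})\right],}
#' positive values favoring model A.  Mixed-effects fits evaluate each
#' plot's density at that plot's estimated random-effect mode; fixed fits
#' use \eqn{\phi = 0}.  Observations outside either model's support are
#' excluded with a warning; the exclusion count is attached as attribute
#' \code{"n_excluded"}.
#'
#' @param data data frame with \code{plot_id}, \code{d_cm}, \code{h_m}.
#' @param fitA,fitB \code{hd_fit} objects (any families/modes).
#' @return Scalar KLIC (n = number of retained observations).
#' @export
hd_klic <- function(data, fitA, fitB) {
  la <- hd_fit_logdens(fitA, data)
  lb <- hd_fit_logdens(fitB, data)
  ok <- is.finite(la) & is.finite(lb)
  n_excl <- sum(!ok)
  if (n_excl > 0)
    warning(n_excl, " observation(s) outside a model's support excluded")
  out <- mean(la[ok] - lb[ok])
  attr(out, "n_excluded") <- n_excl
  out
}

# per-observation log density under a fit, using the fit's own per-plot
# random-effect modes where available
hd_fit_logdens <- function(fit, data) {
  stopifnot(inherits(fit, "hd_fit"))
  phi <- if (fit$mode == "mixed" && !is.null(fit$ranef)) {
    ph <- unname(fit$ranef[as.character(data$plot_id)])
    ph[is.na(ph)] <- 0
    ph
  } else 0
  hd_density(fit$family, fit$params, d = data$d_cm, h = data$h_m,
             phi = phi, log = TRUE)
}

#' Predictive fit statistics
#'
#' For observed heights \eqn{y} and predictions \eqn{\hat y}: mean bias
#' \eqn{B = \frac{1}{n}\sum(y_i - \hat y_i)}, bias variation
#' \eqn{\xi = \frac{1}{n-1}\sum(y_i - \hat y_i - B)^2}, prediction accuracy
#' \eqn{\delta = \sqrt{B^2 + \xi}}, adjusted coefficient of determination
#' \eqn{\bar R^2 = 1 - \frac{n-1}{n-p}\,\mathrm{RSS}/\mathrm{TSS}}, and
#' \eqn{\mathrm{AICC} = n \ln(\mathrm{RSS}) + 2p}.  Note this AICC is the
#' residual-sum-of-squares form used for ranking height-diameter equations
#' — not the small-sample-corrected AIC that shares the name elsewhere.
#'
#' @param observed,predicted equal-length numeric vectors (heights, m).
#' @param n_par number of model parameters p (n > p required).
#' @return List of class \code{"hd_fit_statistics"}: \code{bias},
#'   \code{bias_var}, \code{delta}, \code{r2_adj}, \code{aicc}, \code{rss},
#'   \code{n}, \code{p}.  A zero RSS yields \code{aicc = -Inf} with
#'   \code{degenerate = TRUE}.
#' @export
hd_fit_statistics <- function(observed, predicted, n_par) {
  n <- length(observed)
  stopifnot(n == length(predicted), n > n_par, n >= 2)
  r <- observed - predicted
  B <- mean(r)
  xi <- sum((r - B)^2) / (n - 1)
  delta <- sqrt(B^2 + xi)
  rss <- sum(r^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    stop("constant observations: adjusted R^2 undefined", call. = FALSE)
  r2 <- 1 - (n - 1) / (n - n_par) * rss / tss
  degenerate <- rss == 0
  aicc <- if (degenerate) -Inf else n * log(rss) + 2 * n_par
  structure(list(bias = B, bias_var = xi, delta = delta, r2_adj = r2,
                 aicc = aicc, rss = rss, n = n, p = n_par,
                 degenerate = degenerate),
            class = "hd_fit_statistics")
}

#' @export
print.hd_fit_statistics <- function(x, digits = 4, ...) {
  cat("Prediction fit statistics (n = ", x$n, ", p = ", x$p, ")\n",
      sep = "")
  v <- c(bias = x$bias, bias_var = x$bias_var, delta = x$delta,
         r2_adj = x$r2_adj, aicc = x$aicc)
  print(round(v, digits))
  invisible(x)
}

#' Residual diagnostics table
#'
#' Pairs each prediction with its residual and adds a locally weighted
#' (lowess) smooth of residuals against predictions, for the standard
#' residual-versus-fitted diagnostic.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param span lowess smoother span.
#' @return Data frame with columns \code{predicted}, \code{residual},
#'   \code{smooth} (the lowess fit evaluated at each prediction).
#' @export
hd_residual_diagnostics <- function(observed, predicted, span = 2 / 3) {
  stopifnot(length(observed) == length(predicted))
  r <- observed - predicted
  sm <- stats::lowess(predicted, r, f = span)
  smooth <- stats::approx(sm$x, sm$y, xout = predicted, rule = 2)$y
  data.frame(predicted = predicted, residual = r, smooth = smooth)
}
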