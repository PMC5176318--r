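# Transition laws of the five diffusions, conditional on H(d0) = 1.3.
#
# Every family reduces to a Gaussian law on a transformed height scale:
#   V : h           ~ N(mu, lambda2)
#   G3: log h       ~ N(mu, lambda2)
#   G4: log(h - g)  ~ N(mu, lambda2)
#   B : log h       ~ N(mu, lambda2)
#   G : log h       ~ N(mu, lambda2)
# with mu LINEAR in the random effect phi (slope b below) — the property the
# estimation layer relies on.  hd_law() is the single source of (mu, lambda2).

# internal: location/scale of the transition law, vectorized over d.
# Returns list(dist, mu, lambda2, b = d mu / d phi, shift, d0).
hd_law <- function(family, params, phi, d) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  if (p$family != code)
    stop("params are for family ", p$family, ", not ", code, call. = FALSE)
  d0 <- hd_d0(code)
  if (any(d < d0 - 1e-12))
    stop("diameter below the initial diameter d0 = ", d0, call. = FALSE)
  a <- p$alpha + phi
  b <- p$beta
  s2 <- p$sigma^2
  if (code %in% c("V", "G3", "G4")) {
    e1 <- exp(-b * d)
    e2 <- exp(-2 * b * d)
    lambda2 <- s2 * (1 - e2) / (2 * b)
    slope <- (1 - e1) / b
  }
  out <- switch(code,
    # Vasicek mean reverts to the asymptote a itself: the drift is
    # beta * (a - H), so mu = a + (1.3 - a) e^{-beta d}
    V = list(dist = "normal",
             mu = H0 * e1 + a * (1 - e1),
             lambda2 = lambda2, b = 1 - e1, shift = 0),
    G3 = list(dist = "lognormal",
              mu = log(H0) * e1 + (a - s2 / 2) * slope,
              lambda2 = lambda2, b = slope, shift = 0),
    G4 = list(dist = "shifted-lognormal",
              mu = log(H0 - p$gamma) * e1 + (a - s2 / 2) * slope,
              lambda2 = lambda2, b = slope, shift = p$gamma),
    B = {
      lr <- log1p(-p$gamma * exp(-b * d)) - log1p(-p$gamma)
      list(dist = "lognormal",
           mu = log(H0) + a * lr - s2 * d / 2,
           lambda2 = s2 * d, b = lr, shift = 0)
    },
    G = {
      ld <- log(d / 0.001)
      list(dist = "lognormal",
           mu = log(H0) + a * ld - (b + s2 / 2) * (d - 0.001),
           lambda2 = s2 * (d - 0.001), b = ld, shift = 0)
    })
  out$d0 <- d0
  out$mu <- out$mu + 0 * d  # recycle to length(d)
  out
}

#' Transition-law location and scale
#'
#' Returns the building blocks of the conditional law of \eqn{H(d)}: the
#' distribution family (\code{"normal"}, \code{"lognormal"} or
#' \code{"shifted-lognormal"}), location \eqn{\mu_K(d)}, scale
#' \eqn{\lambda_K^2(d)}, the shift (\eqn{\gamma}, G4 only) and the initial
#' diameter \code{d0}.  \eqn{\lambda^2(d_0) = 0}: the law is degenerate at
#' 1.3 m there.
#'
#' @inheritParams hd_mean
#' @return List with elements \code{dist}, \code{mu}, \code{lambda2},
#'   \code{shift}, \code{d0} (\code{mu}, \code{lambda2} vectorized over
#'   \code{d}).
#' @export
hd_transition_law <- function(family, params, d, phi = 0) {
  law <- hd_law(family, params, phi, d)
  list(dist = law$dist, mu = law$mu,
       lambda2 = law$lambda2 + 0 * law$mu,
       shift = law$shift, d0 = law$d0)
}

# transformed observation scale: identity for V, log otherwise
hd_obs_scale <- function(law, h) {
  switch(law$dist,
         normal = h,
         lognormal = log(h),
         `shifted-lognormal` = log(h - law$shift))
}

#' Conditional mean and variance of tree height at a given diameter
#'
#' Closed-form first two moments of the transition law of \eqn{H(d)} given
#' \eqn{H(d_0)=1.3}.  For Vasicek the mean is
#' \eqn{(\alpha+\phi) + (1.3-(\alpha+\phi))e^{-\beta d}} and the variance
#' \eqn{\sigma^2(1-e^{-2\beta d})/(2\beta)}; for the lognormal families the
#' standard lognormal moments \eqn{e^{\mu+\lambda^2/2}} and
#' \eqn{e^{2\mu+\lambda^2}(e^{\lambda^2}-1)} are used (plus the shift
#' \eqn{\gamma} on the G4 mean).  At \eqn{d = d_0} the law is degenerate and
#' \code{(1.3, 0)} is returned.
#'
#' @inheritParams hd_deterministic
#' @param phi plot random effect added to \code{alpha} (scalar or vector
#'   recycled against \code{d}).
#' @return Heights in m (mean) or m\eqn{^2} (variance).
#' @examples
#' p <- hd_params("G3", alpha = 0.4324, beta = 0.1354, sigma = 0.0429)
#' hd_mean("G3", p, d = 25)
#' hd_variance("G3", p, d = 25)
#' @export
hd_mean <- function(family, params, d, phi = 0) {
  law <- hd_law(family, params, phi, d)
  m <- switch(law$dist,
    normal = law$mu,
    lognormal = exp(law$mu + law$lambda2 / 2),
    `shifted-lognormal` = law$shift + exp(law$mu + law$lambda2 / 2))
  m[d == law$d0] <- H0
  m
}

#' @rdname hd_mean
#' @export
hd_variance <- function(family, params, d, phi = 0) {
  law <- hd_law(family, params, phi, d)
  v <- switch(law$dist,
    normal = law$lambda2 + 0 * law$mu,
    exp(2 * law$mu + law$lambda2) * expm1(law$lambda2))
  v[d == law$d0] <- 0
  v
}

check_not_degenerate <- function(law, d) {
  if (any(d == law$d0))
    stop("transition law is degenerate at d = d0 = ", law$d0,
         " (all mass at 1.3 m)", call. = FALSE)
}

#' Transition density, distribution and quantile functions
#'
#' The conditional law of height \eqn{H(d)} given \eqn{H(d_0) = 1.3}:
#' normal for Vasicek, lognormal for G3/B/G, and lognormal shifted by
#' \eqn{\gamma} for G4.  \code{hd_density} returns 0 outside the support
#' (\eqn{h \le 0} for the lognormal families, \eqn{h \le \gamma} for G4).
#' At \eqn{d = d_0} the law is degenerate at 1.3 m and these functions raise
#' an error; use [hd_mean()]/[hd_variance()] there.
#'
#' @inheritParams hd_mean
#' @param h height, m.
#' @param q height quantile, m.
#' @param p probability in (0,1).
#' @param log,lower.tail as in [stats::dnorm()].
#' @return \code{hd_density}: density in 1/m; \code{hd_cdf}: probability;
#'   \code{hd_quantile}: height in m.
#' @examples
#' p <- hd_params("V", alpha = 26.63, beta = 0.0667, sigma = 0.606)
#' hd_density("V", p, d = 25, h = 20)
#' hd_quantile("V", p, d = 25, p_q = c(0.1, 0.5, 0.9))
#' @export
hd_density <- function(family, params, d, h, phi = 0, log = FALSE) {
  law <- hd_law(family, params, phi, d)
  check_not_degenerate(law, d)
  n <- max(length(d), length(h), length(law$mu))
  h <- rep_len(h, n)
  mu <- rep_len(law$mu, n)
  sd <- rep_len(sqrt(law$lambda2), n)
  out <- rep(if (log) -Inf else 0, n)
  ok <- switch(law$dist,
               normal = rep(TRUE, n),
               lognormal = h > 0,
               `shifted-lognormal` = h > law$shift)
  if (any(ok)) {
    y <- hd_obs_scale(law, h[ok])
    ld <- stats::dnorm(y, mu[ok], sd[ok], log = TRUE)
    if (law$dist != "normal") ld <- ld - y  # Jacobian 1/h (or 1/(h - gamma))
    out[ok] <- if (log) ld else exp(ld)
  }
  out
}

#' @rdname hd_density
#' @export
hd_cdf <- function(family, params, d, q, phi = 0, lower.tail = TRUE) {
  law <- hd_law(family, params, phi, d)
  check_not_degenerate(law, d)
  n <- max(length(d), length(q), length(law$mu))
  q <- rep_len(q, n)
  mu <- rep_len(law$mu, n)
  sd <- rep_len(sqrt(law$lambda2), n)
  below <- switch(law$dist,
                  normal = rep(FALSE, n),
                  lognormal = q <= 0,
                  `shifted-lognormal` = q <= law$shift)
  out <- numeric(n)
  out[below] <- if (lower.tail) 0 else 1
  ok <- !below
  if (any(ok))
    out[ok] <- stats::pnorm(hd_obs_scale(law, q[ok]), mu[ok], sd[ok],
                            lower.tail = lower.tail)
  out
}

#' @rdname hd_density
#' @param p_q probabilities for \code{hd_quantile}.
#' @export
hd_quantile <- function(family, params, d, p_q, phi = 0) {
  if (any(p_q <= 0 | p_q >= 1))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  law <- hd_law(family, params, phi, d)
  check_not_degenerate(law, d)
  n <- max(length(d), length(p_q), length(law$mu))
  z <- stats::qnorm(rep_len(p_q, n))
  y <- rep_len(law$mu, n) + z * rep_len(sqrt(law$lambda2), n)
  switch(law$dist,
         normal = y,
         lognormal = exp(y),
         `shifted-lognormal` = law$shift + exp(y))
}

#' Exact draws from the transition law
#'
#' Samples heights at diameter \code{d} directly from the closed-form
#' normal/lognormal transition law — no Euler discretization of the SDE is
#' involved, so the draws are exact.
#'
#' @inheritParams hd_density
#' @param n number of draws.
#' @return Vector of heights, m.
#' @export
hd_sample <- function(n, family, params, d, phi = 0) {
  law <- hd_law(family, params, phi, d)
  check_not_degenerate(law, d)
  y <- stats::rnorm(n, rep_len(law$mu, n), rep_len(sqrt(law$lambda2), n))
  switch(law$dist,
         normal = y,
         lognormal = exp(y),
         `shifted-lognormal` = law$shift + exp(y))
}
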