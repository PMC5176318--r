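# Derived stand attributes: slenderness ratio, mean stem volume and
# coefficients of variation of height and volume as functions of diameter.

#' Stem volume model coefficients
#'
#' Power-form stem volume regression \eqn{V(d,h) = b_1 d^{b_2} h^{b_3}}
#' (V in m\eqn{^3}, d in cm, h in m).  Defaults are weighted-least-squares
#' estimates for Scots pine.
#'
#' @param b1,b2,b3 positive coefficients.
#' @return List of class \code{"hd_volume"}.
#' @export
hd_volume_params <- function(b1 = 5.8e-5, b2 = 1.8801, b3 = 0.9723) {
  stopifnot(b1 > 0, b2 > 0, b3 >= 0)
  structure(list(b1 = b1, b2 = b2, b3 = b3), class = "hd_volume")
}

# quadrature of f(h) * density over the support intersected with
# [lower, upper]; tol is the absolute/relative tolerance of integrate()
hd_expect <- function(fun, family, params, d, phi, lower = -Inf,
                      upper = Inf, tol = 1e-10) {
  law <- hd_law(family, params, phi, d)
  lo <- switch(law$dist, normal = -Inf, lognormal = 0,
               `shifted-lognormal` = law$shift)
  lo <- max(lo, lower)
  val <- stats::integrate(function(h)
    fun(h) * hd_density(family, params, d = d, h = h, phi = phi),
    lower = lo, upper = upper, rel.tol = tol, abs.tol = tol,
    subdivisions = 500L)
  val$value
}

#' Slenderness ratio at a given diameter
#'
#' Expected height-to-diameter ratio
#' \eqn{R(d) = \int_0^{50} (h/d)\, f_K(h, d)\, dh}, the conventional index
#' of windthrow resistance; the integral runs over the height support
#' truncated to (0, 50] m.  By default the ratio is returned in m/cm;
#' \code{percent = TRUE} multiplies by 100 (the usual plotted convention).
#'
#' @inheritParams hd_mean
#' @param percent return \eqn{100 \cdot h/d}.
#' @param upper upper integration bound for height, m.
#' @return Slenderness ratio (vectorized over \code{d}).
#' @export
hd_slenderness <- function(family, params, d, phi = 0, percent = FALSE,
                           upper = 50) {
  out <- vapply(seq_along(d), function(i)
    hd_expect(function(h) h / d[i], family, params, d[i], phi,
              lower = 0, upper = upper), numeric(1))
  if (percent) out * 100 else out
}

#' Mean stem volume at a given diameter
#'
#' \eqn{\bar V(d) = \int_{h>0} b_1 d^{b_2} h^{b_3} f_K(h, d)\, dh}.  For the
#' lognormal families (G3, B, G) the fractional moment is closed form:
#' \eqn{b_1 d^{b_2} \exp(b_3 \mu + b_3^2 \lambda^2 / 2)}; for Vasicek and
#' shifted-lognormal G4 adaptive quadrature over \eqn{h > 0} is used (any
#' negative-height Vasicek mass is excluded; its magnitude is returned in
#' attribute \code{"truncated_mass"}).
#'
#' @inheritParams hd_mean
#' @param volume an [hd_volume_params()] object.
#' @param method \code{"auto"} (closed form where exact, else quadrature),
#'   \code{"closed"} or \code{"quadrature"}.
#' @return Mean stem volume, m\eqn{^3} (vectorized over \code{d}).
#' @export
hd_mean_volume <- function(family, params, d, phi = 0,
                           volume = hd_volume_params(),
                           method = c("auto", "closed", "quadrature")) {
  method <- match.arg(method)
  code <- hd_family_code(family)
  lognormal <- code %in% c("G3", "B", "G")
  if (method == "closed" && !lognormal)
    stop("closed form only available for the lognormal families",
         call. = FALSE)
  use_closed <- lognormal && method != "quadrature"
  if (use_closed) {
    law <- hd_law(code, params, phi, d)
    return(volume$b1 * d^volume$b2 *
             exp(volume$b3 * law$mu + volume$b3^2 * law$lambda2 / 2))
  }
  out <- vapply(seq_along(d), function(i)
    hd_expect(function(h) volume$b1 * d[i]^volume$b2 * h^volume$b3,
              code, params, d[i], phi, lower = 0), numeric(1))
  if (code == "V") {
    tm <- hd_cdf(code, params, d = d, q = 0)
    attr(out, "truncated_mass") <- tm
  }
  out
}

#' Coefficients of variation of height and volume
#'
#' \code{hd_cv_height} is \eqn{100\sqrt{v(d)}/m(d)}: the dispersion of tree
#' heights at diameter \code{d} as a percent of the conditional mean.
#' \code{hd_cv_volume} is the analogous percent CV of stem volume
#' \eqn{V(d,h) = b_1 d^{b_2} h^{b_3}}; the diameter factor
#' \eqn{b_1 d^{b_2}} cancels, and for the lognormal families the closed
#' form \eqn{100\sqrt{e^{b_3^2 \lambda^2} - 1}} is used (quadrature over
#' \eqn{h > 0} for Vasicek and G4).
#'
#' @inheritParams hd_mean_volume
#' @return CV in percent (vectorized over \code{d}).
#' @export
hd_cv_height <- function(family, params, d, phi = 0) {
  100 * sqrt(hd_variance(family, params, d = d, phi = phi)) /
    hd_mean(family, params, d = d, phi = phi)
}

#' @rdname hd_cv_height
#' @export
hd_cv_volume <- function(family, params, d, phi = 0,
                         volume = hd_volume_params()) {
  code <- hd_family_code(family)
  if (code %in% c("G3", "B", "G")) {
    law <- hd_law(code, params, phi, d)
    return(100 * sqrt(expm1(volume$b3^2 * law$lambda2)) + 0 * law$mu)
  }
  vapply(seq_along(d), function(i) {
    ev <- hd_expect(function(h) h^volume$b3, code, params, d[i], phi,
                    lower = 0)
    ev2 <- hd_expect(function(h) h^(2 * volume$b3), code, params, d[i],
                     phi, lower = 0)
    100 * sqrt(pmax(ev2 - ev^2, 0)) / ev
  }, numeric(1))
}

#' Evaluate a stand attribute over a diameter grid
#'
#' Vectorized driver for quantile, slenderness, mean-volume and CV curves,
#' returning a tidy table suitable for plotting or CSV export.
#'
#' @param attribute one of \code{"mean"}, \code{"quantile"},
#'   \code{"slenderness"}, \code{"mean_volume"}, \code{"cv_height"},
#'   \code{"cv_volume"}.
#' @inheritParams hd_mean_volume
#' @param d_grid strictly increasing vector of diameters, cm.
#' @param p probability for \code{attribute = "quantile"}.
#' @param ... passed to the underlying attribute function.
#' @return Data frame with columns \code{d_cm} and \code{value}, plus the
#'   request in attributes.
#' @export
hd_attribute_curve <- function(attribute, family, params, d_grid, phi = 0,
                               p = 0.5, volume = hd_volume_params(), ...) {
  if (any(diff(d_grid) <= 0))
    stop("'d_grid' must be strictly increasing", call. = FALSE)
  code <- hd_family_code(family)
  value <- switch(match.arg(attribute,
                            c("mean", "quantile", "slenderness",
                              "mean_volume", "cv_height", "cv_volume")),
    mean = hd_mean(code, params, d = d_grid, phi = phi),
    quantile = hd_quantile(code, params, d = d_grid, p_q = p, phi = phi),
    slenderness = hd_slenderness(code, params, d = d_grid, phi = phi, ...),
    mean_volume = as.numeric(hd_mean_volume(code, params, d = d_grid,
                                            phi = phi, volume = volume,
                                            ...)),
    cv_height = hd_cv_height(code, params, d = d_grid, phi = phi),
    cv_volume = hd_cv_volume(code, params, d = d_grid, phi = phi,
                             volume = volume))
  out <- data.frame(d_cm = d_grid, value = value)
  attr(out, "attribute") <- attribute
  attr(out, "family") <- code
  attr(out, "phi") <- phi
  out
}
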