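#' Model families for SDE height-diameter models
#'
#' The package models total tree height \eqn{H(d)} at breast-height diameter
#' \eqn{d} (cm) by five diffusion processes of the Ornstein-Uhlenbeck family,
#' each started at the breast-height constant \eqn{H(d_0) = 1.3} m:
#' Vasicek (\code{"V"}), three-parameter Gompertz (\code{"G3"}),
#' four-parameter Gompertz (\code{"G4"}), Bertalanffy (\code{"B"}) and
#' Gamma/Malthusian (\code{"G"}).  The Vasicek transition law is normal; G3,
#' B and G are lognormal; G4 is a lognormal shifted by its threshold
#' parameter \eqn{\gamma}.
#'
#' @return A data frame with one row per family: \code{code}, \code{name},
#'   \code{distribution} (transition-law family), \code{d0} (initial
#'   diameter, cm) and \code{has_gamma}.
#' @examples
#' hd_families()
#' @export
hd_families <- function() {
  data.frame(
    code = c("V", "G3", "G4", "B", "G"),
    name = c("Vasicek", "Gompertz 3-parameter", "Gompertz 4-parameter",
             "Bertalanffy", "Gamma"),
    distribution = c("normal", "lognormal", "shifted-lognormal",
                     "lognormal", "lognormal"),
    d0 = c(0, 0, 0, 0, 0.001),
    has_gamma = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# breast-height initial condition H(d0) = 1.3 m, shared by all families
H0 <- 1.3

#' Normalize a family specifier to its code
#'
#' Accepts the short code (\code{"V"}, \code{"G3"}, \code{"G4"}, \code{"B"},
#' \code{"G"}) or a long name (\code{"vasicek"}, \code{"gompertz3"},
#' \code{"gompertz4"}, \code{"bertalanffy"}, \code{"gamma"}),
#' case-insensitively.
#'
#' @param family character scalar.
#' @return One of \code{"V"}, \code{"G3"}, \code{"G4"}, \code{"B"}, \code{"G"}.
#' @export
hd_family_code <- function(family) {
  if (inherits(family, "hd_params")) return(family$family)
  stopifnot(is.character(family), length(family) == 1L)
  key <- tolower(family)
  map <- c(v = "V", vasicek = "V",
           g3 = "G3", gompertz3 = "G3", `gompertz-3` = "G3",
           g4 = "G4", gompertz4 = "G4", `gompertz-4` = "G4",
           b = "B", bertalanffy = "B",
           g = "G", gamma = "G")
  code <- map[key]
  if (is.na(code))
    stop("unknown model family: '", family, "'", call. = FALSE)
  unname(code)
}

hd_d0 <- function(code) if (code == "G") 0.001 else 0

#' Construct and validate a parameter set
#'
#' Bundles the fixed-effects parameters of one SDE height-diameter model
#' (and optionally the random-effect standard deviation) after checking the
#' family-specific domain constraints:
#' \itemize{
#'   \item \code{sigma > 0} always; \code{sigma_phi >= 0} when supplied;
#'   \item \code{beta > 0} for V, G3, G4 and B (mean reversion /
#'     deceleration); \code{beta} is unconstrained in sign for the Gamma
#'     family, which is routinely fitted with a small negative rate;
#'   \item \code{0 < gamma < 1} for Bertalanffy (so \eqn{1-\gamma e^{-\beta
#'     d} > 0} on \eqn{d \ge 0}); \code{gamma < 1.3} for G4 (the initial
#'     height must lie in the support \eqn{h > \gamma});
#'   \item \code{gamma} must be absent for V, G3 and G.
#' }
#'
#' @param family family code or name, see [hd_family_code()].
#' @param alpha growth-level parameter (asymptotic height in m for V;
#'   dimensionless rate otherwise).
#' @param beta rate parameter (1/cm).
#' @param gamma threshold/shape parameter (G4: m, may be strongly negative;
#'   B: dimensionless in (0,1)).  Omit for the other families.
#' @param sigma diffusion coefficient (> 0).
#' @param sigma_phi standard deviation of the plot random effect
#'   \eqn{\phi_i \sim N(0, \sigma_\phi^2)} added to \code{alpha}; \code{NULL}
#'   for a purely fixed-effects parameter set.
#' @return An object of class \code{"hd_params"}: a list with elements
#'   \code{family}, \code{alpha}, \code{beta}, \code{gamma} (or \code{NULL}),
#'   \code{sigma}, \code{sigma_phi} (or \code{NULL}).
#' @examples
#' hd_params("vasicek", alpha = 26.63, beta = 0.0667, sigma = 0.606,
#'           sigma_phi = 3.94)
#' @export
hd_params <- function(family, alpha, beta, gamma = NULL, sigma,
                      sigma_phi = NULL) {
  code <- hd_family_code(family)
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
    as.numeric(x)
  }
  alpha <- chk_num(alpha, "alpha")
  beta  <- chk_num(beta, "beta")
  sigma <- chk_num(sigma, "sigma")
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (code %in% c("V", "G3", "G4", "B") && beta <= 0)
    stop("'beta' must be > 0 for family ", code, call. = FALSE)
  has_gamma <- code %in% c("G4", "B")
  if (has_gamma) {
    if (is.null(gamma))
      stop("family ", code, " requires a 'gamma' parameter", call. = FALSE)
    gamma <- chk_num(gamma, "gamma")
    if (code == "B" && (gamma <= 0 || gamma >= 1))
      stop("Bertalanffy requires 0 < gamma < 1", call. = FALSE)
    if (code == "G4" && gamma >= H0)
      stop("Gompertz-4 requires gamma < 1.3", call. = FALSE)
  } else if (!is.null(gamma)) {
    stop("family ", code, " takes no 'gamma' parameter", call. = FALSE)
  }
  if (!is.null(sigma_phi)) {
    sigma_phi <- chk_num(sigma_phi, "sigma_phi")
    if (sigma_phi < 0) stop("'sigma_phi' must be >= 0", call. = FALSE)
  }
  structure(list(family = code, alpha = alpha, beta = beta,
                 gamma = if (has_gamma) gamma else NULL,
                 sigma = sigma, sigma_phi = sigma_phi),
            class = "hd_params")
}

#' @export
print.hd_params <- function(x, ...) {
  fam <- hd_families()
  cat("SDE height-diameter parameters (",
      fam$name[fam$code == x$family], ")\n", sep = "")
  v <- unlist(x[c("alpha", "beta", "gamma", "sigma", "sigma_phi")])
  print(v, ...)
  invisible(x)
}

as_hd_params <- function(object) {
  if (inherits(object, "hd_params")) return(object)
  if (inherits(object, "hd_fit")) return(object$params)
  stop("expected an 'hd_params' or 'hd_fit' object", call. = FALSE)
}

#' Deterministic height-diameter trajectory
#'
#' The solution of each family's underlying ordinary differential equation
#' (the SDE with the noise switched off): a Mitscherlich curve for Vasicek,
#' Gompertz curves for G3/G4, a sigmoidal Bertalanffy curve and the regulated
#' Malthusian (Gamma) curve.  All trajectories pass through 1.3 m at the
#' initial diameter (\eqn{d_0 = 0}, or 0.001 cm for the Gamma family).
#'
#' @param family family code or name.
#' @param params an [hd_params()] object (its \code{sigma} is ignored here).
#' @param d vector of diameters, cm; must be \code{>= d0}.
#' @param phi optional offset added to \code{alpha} (plot random effect).
#' @return Vector of heights, m.
#' @examples
#' p <- hd_params("V", alpha = 30.69, beta = 0.0479, sigma = 1.06)
#' hd_deterministic("V", p, d = c(0, 20, 40))
#' @export
hd_deterministic <- function(family, params, d, phi = 0) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  if (p$family != code)
    stop("params are for family ", p$family, ", not ", code, call. = FALSE)
  d0 <- hd_d0(code)
  if (any(d < d0 - 1e-12))
    stop("diameter below the initial diameter d0 = ", d0, call. = FALSE)
  a <- p$alpha + phi
  b <- p$beta
  switch(code,
    V  = a + (H0 - a) * exp(-b * d),
    G3 = exp(a / b - (a / b - log(H0)) * exp(-b * d)),
    G4 = p$gamma +
      exp(a / b - (a / b - log(H0 - p$gamma)) * exp(-b * d)),
    B  = H0 * ((1 - p$gamma * exp(-b * d)) / (1 - p$gamma))^a,
    G  = H0 * (d / 0.001)^a * exp(-b * (d - 0.001))
  )
}
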