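# Maximum likelihood estimation, fixed and mixed effects.
#
# All five transition laws are Gaussian on a transformed height scale y
# (y = h for V, log h for G3/B/G, log(h - gamma) for G4) with location
# mu = c_j + b_j * phi linear in the plot effect phi.  Consequently the
# per-plot integrand exp(g(phi)) of the marginal likelihood is exactly
# Gaussian in phi: the Laplace approximation is exact, the mode phi_hat is
# available in closed form, and -g''(phi) = A_i is constant in phi.

# per-observation components at phi = 0: y, c (location), b (d mu / d phi),
# lambda2, logJ (log Jacobian of y(h)); support flag ok.
hd_components <- function(code, p, d, h) {
  law <- hd_law(code, p, phi = 0, d = d)
  ok <- switch(law$dist,
               normal = rep(TRUE, length(h)),
               lognormal = h > 0,
               `shifted-lognormal` = h > law$shift)
  y <- rep(NA_real_, length(h))
  y[ok] <- hd_obs_scale(law, h[ok])
  logJ <- if (law$dist == "normal") numeric(length(h)) else y
  list(y = y, c = law$mu, b = law$b + 0 * law$mu,
       lambda2 = law$lambda2 + 0 * law$mu, logJ = logJ, ok = ok)
}

#' Log-likelihood of a height-diameter SDE model
#'
#' \code{hd_loglik_fixed} is the cross-sectional fixed-effects
#' log-likelihood \eqn{\sum_i \sum_j \ln f_K(h_{ij}, d_{ij} | \theta, \phi =
#' 0)}.  \code{hd_loglik_mixed} integrates the plot effect out of every
#' plot's likelihood by the Laplace method (exact here, see
#' [hd_laplace_plot()]) and sums over plots.  Observations outside the
#' family's support make the fixed log-likelihood \code{-Inf}.
#'
#' @param family family code or name.
#' @param params an [hd_params()] object (with \code{sigma_phi} set for the
#'   mixed version).
#' @param data a data frame with columns \code{d_cm}, \code{h_m} (and
#'   \code{plot_id} for the mixed version).
#' @return Log-likelihood value; the mixed version carries the per-plot
#'   modes as attribute \code{"phi_hat"}.
#' @export
hd_loglik_fixed <- function(family, params, data) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  cm <- hd_components(code, p, data$d_cm, data$h_m)
  if (!all(cm$ok)) return(-Inf)
  sum(stats::dnorm(cm$y, cm$c, sqrt(cm$lambda2), log = TRUE) - cm$logJ)
}

#' @rdname hd_loglik_fixed
#' @export
hd_loglik_mixed <- function(family, params, data) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  if (is.null(p$sigma_phi) || p$sigma_phi <= 0)
    stop("mixed log-likelihood requires sigma_phi > 0", call. = FALSE)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(data$plot_id)) stop("'data' needs a plot_id column", call. = FALSE)
  cm <- hd_components(code, p, data$d_cm, data$h_m)
  if (!all(cm$ok)) return(-Inf)
  pid <- match(data$plot_id, unique(data$plot_id))
  M <- max(pid)
  sp2 <- p$sigma_phi^2
  w <- 1 / cm$lambda2
  A <- rowsum(cm$b^2 * w, pid)[, 1] + 1 / sp2        # = -g''(phi), constant
  Bsum <- rowsum(cm$b * (cm$y - cm$c) * w, pid)[, 1]
  phi_hat <- Bsum / A
  resid <- cm$y - cm$c - cm$b * phi_hat[pid]
  g_at_mode <- sum(-0.5 * log(2 * pi * cm$lambda2) - cm$logJ -
                     resid^2 / (2 * cm$lambda2)) +
    sum(stats::dnorm(phi_hat, 0, p$sigma_phi, log = TRUE))
  ll <- g_at_mode + M * 0.5 * log(2 * pi) - 0.5 * sum(log(A))
  attr(ll, "phi_hat") <- phi_hat
  ll
}

#' Per-plot objective g and its Laplace-approximated integral
#'
#' \code{hd_plot_g} evaluates \eqn{g(\phi) = \sum_j \ln f_K(h_j, d_j |
#' \theta, \phi) + \ln N(\phi; 0, \sigma_\phi^2)} for one plot.
#' \code{hd_laplace_plot} returns the Laplace approximation of
#' \eqn{\ln \int e^{g(\phi)} d\phi}, i.e. \eqn{g(\hat\phi) +
#' \frac{1}{2}\ln 2\pi - \frac{1}{2}\ln(-g''(\hat\phi))}, together with the
#' mode \eqn{\hat\phi}.  Because \eqn{\mu_K} is linear in \eqn{\phi} for
#' every family, \eqn{g} is exactly quadratic: the mode is closed-form, the
#' curvature is constant, and the Laplace value equals the exact marginal
#' log-likelihood of the plot.
#'
#' @inheritParams hd_loglik_fixed
#' @param sigma_phi random-effect standard deviation (> 0).
#' @param plot_data data frame with columns \code{d_cm}, \code{h_m}
#'   (possibly zero rows: the prior integrates to one and the plot
#'   contributes 0).
#' @param phi scalar plot effect at which to evaluate \code{g}.
#' @return \code{hd_plot_g}: a scalar. \code{hd_laplace_plot}: a list with
#'   \code{value}, \code{phi_hat} and \code{neg_g2} (\eqn{-g''}).
#' @export
hd_plot_g <- function(family, params, sigma_phi, plot_data, phi) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  stopifnot(sigma_phi > 0)
  ll <- if (nrow(plot_data) == 0L) 0 else {
    cm <- hd_components(code, p, plot_data$d_cm, plot_data$h_m)
    if (!all(cm$ok)) return(-Inf)
    sum(stats::dnorm(cm$y, cm$c + cm$b * phi, sqrt(cm$lambda2),
                     log = TRUE) - cm$logJ)
  }
  ll + stats::dnorm(phi, 0, sigma_phi, log = TRUE)
}

#' @rdname hd_plot_g
#' @export
hd_laplace_plot <- function(family, params, sigma_phi, plot_data) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  stopifnot(sigma_phi > 0)
  if (nrow(plot_data) == 0L) {
    # integral of the prior alone is 1
    return(list(value = 0, phi_hat = 0, neg_g2 = 1 / sigma_phi^2))
  }
  cm <- hd_components(code, p, plot_data$d_cm, plot_data$h_m)
  if (!all(cm$ok)) return(list(value = -Inf, phi_hat = NA_real_,
                               neg_g2 = NA_real_))
  w <- 1 / cm$lambda2
  A <- sum(cm$b^2 * w) + 1 / sigma_phi^2
  phi_hat <- sum(cm$b * (cm$y - cm$c) * w) / A
  g <- hd_plot_g(code, p, sigma_phi, plot_data, phi_hat)
  list(value = g + 0.5 * log(2 * pi) - 0.5 * log(A),
       phi_hat = phi_hat, neg_g2 = A)
}

## ---- parameter transforms (unconstrained optimization scale) ----

hd_par_names <- function(code, mixed) {
  nm <- c("alpha", "beta",
          if (code %in% c("G4", "B")) "gamma", "sigma",
          if (mixed) "sigma_phi")
  nm
}

# theta (natural, named) <-> t (unconstrained); gmax used by G4 only
hd_to_unconstrained <- function(code, theta, gmax = NULL) {
  t <- theta
  t["beta"] <- if (code == "G") theta["beta"] else log(theta["beta"])
  t["sigma"] <- log(theta["sigma"])
  if ("sigma_phi" %in% names(theta)) t["sigma_phi"] <- log(theta["sigma_phi"])
  if (code == "B") t["gamma"] <- stats::qlogis(theta["gamma"])
  if (code == "G4") t["gamma"] <- log(gmax - theta["gamma"])
  t
}

hd_from_unconstrained <- function(code, t, gmax = NULL) {
  theta <- t
  theta["beta"] <- if (code == "G") t["beta"] else exp(t["beta"])
  theta["sigma"] <- exp(t["sigma"])
  if ("sigma_phi" %in% names(t)) theta["sigma_phi"] <- exp(t["sigma_phi"])
  if (code == "B") theta["gamma"] <- stats::plogis(t["gamma"])
  if (code == "G4") theta["gamma"] <- gmax - exp(t["gamma"])
  theta
}

hd_theta_to_params <- function(code, theta) {
  hd_params(code, alpha = theta[["alpha"]], beta = theta[["beta"]],
            gamma = if (code %in% c("G4", "B")) theta[["gamma"]],
            sigma = theta[["sigma"]],
            sigma_phi = if ("sigma_phi" %in% names(theta))
              theta[["sigma_phi"]])
}

## ---- starting values: least squares on the deterministic trajectory ----

hd_start_values <- function(code, data, mixed) {
  d <- data$d_cm; h <- data$h_m
  dbar <- mean(d)
  start <- switch(code,
    V  = list(alpha = max(h) + 1, beta = 2 / dbar),
    G3 = list(alpha = 2 / dbar * log(max(h)), beta = 2 / dbar),
    G4 = list(alpha = 2 / dbar * log(max(h) + 50), beta = 2 / dbar,
              gamma = -50),
    B  = list(alpha = 1, beta = 2 / dbar, gamma = 0.9),
    G  = NULL)
  est <- NULL
  if (code == "G") {
    # Gamma trajectory is linear on the log scale: exact LS start
    co <- stats::coef(stats::lm(I(log(h) - log(H0)) ~
                                  I(log(d / 0.001)) + I(d - 0.001) - 1))
    est <- c(alpha = unname(co[1]), beta = -unname(co[2]))
  } else {
    fml <- switch(code,
      V  = h ~ alpha + (1.3 - alpha) * exp(-beta * d),
      G3 = h ~ exp(alpha / beta -
                     (alpha / beta - log(1.3)) * exp(-beta * d)),
      G4 = h ~ gamma + exp(alpha / beta -
                             (alpha / beta - log(1.3 - gamma)) *
                               exp(-beta * d)),
      B  = h ~ 1.3 * ((1 - gamma * exp(-beta * d)) / (1 - gamma))^alpha)
    lower <- switch(code,
      V  = c(alpha = 1.4, beta = 1e-4),
      G3 = c(alpha = 1e-4, beta = 1e-4),
      G4 = c(alpha = 1e-4, beta = 1e-4, gamma = -1e4),
      B  = c(alpha = 1e-4, beta = 1e-4, gamma = 1e-4))
    upper <- switch(code,
      V  = c(alpha = Inf, beta = 2),
      G3 = c(alpha = 10, beta = 2),
      G4 = c(alpha = 10, beta = 2, gamma = min(min(h), H0) - 1e-3),
      B  = c(alpha = 50, beta = 2, gamma = 1 - 1e-6),
      G  = NULL)
    fit <- try(minpack.lm::nlsLM(fml, data = data.frame(d = d, h = h),
                                 start = start, lower = lower,
                                 upper = upper,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)), silent = TRUE)
    est <- if (inherits(fit, "try-error")) unlist(start) else
      stats::coef(fit)
  }
  # sigma start: residual SD on the observation scale mapped through the
  # family's variance function at the mean diameter
  p0 <- hd_theta_to_params(code, c(est, sigma = 1))
  mu0 <- hd_deterministic(code, p0, d)
  r <- if (code == "V") h - mu0 else
    log(pmax(h - if (code == "G4") est[["gamma"]] else 0, 1e-6)) -
    log(pmax(mu0 - if (code == "G4") est[["gamma"]] else 0, 1e-6))
  sd_r <- max(stats::sd(r), 1e-4)
  scale_at <- switch(code,
    V = , G3 = , G4 = sqrt((1 - exp(-2 * est[["beta"]] * dbar)) /
                             (2 * est[["beta"]])),
    B = sqrt(dbar),
    G = sqrt(dbar - 0.001))
  sigma0 <- sd_r / scale_at
  theta <- c(est, sigma = unname(sigma0))
  if (mixed) {
    # between-plot spread of per-plot mean residuals on the phi scale
    cm <- hd_components(code, hd_theta_to_params(code, theta),
                        data$d_cm, data$h_m)
    zb <- (cm$y - cm$c) / cm$b
    phi0 <- tapply(zb[cm$ok & is.finite(zb)],
                   data$plot_id[cm$ok & is.finite(zb)], mean)
    sp0 <- stats::sd(phi0, na.rm = TRUE)
    if (!is.finite(sp0) || sp0 <= 0) sp0 <- sigma0 / 2
    theta <- c(theta, sigma_phi = unname(max(sp0, sigma0 / 4)))
  }
  theta[hd_par_names(code, mixed)]
}

## ---- numeric derivatives ----

num_gradient <- function(f, x, step = NULL) {
  if (is.null(step)) step <- 1e-4 * pmax(1, abs(x))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- step[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * step[i])
  }
  g
}

num_hessian <- function(f, x, step = NULL) {
  k <- length(x)
  if (is.null(step)) step <- 1e-5 * pmax(1, abs(x))
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- step[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step[i]^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- numeric(k); ej[j] <- step[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * step[i] * step[j])
    }
  }
  H
}

## ---- the fitting function ----

#' Fit an SDE height-diameter model by maximum likelihood
#'
#' Fits one of the five diffusion families to a cross-sectional tree table,
#' either with fixed effects only (\code{mode = "fixed"}) or with a plot
#' random effect on \code{alpha} integrated out by the (here exact) Laplace
#' approximation (\code{mode = "mixed"}).  Optimization runs on an
#' unconstrained scale (\eqn{\log\beta}, \eqn{\log\sigma},
#' \eqn{\log\sigma_\phi}, logit \eqn{\gamma} for Bertalanffy and
#' \eqn{\gamma = \min(h) - e^{c}} for Gompertz-4) with multiple jittered
#' starts; starting values come from least squares on the deterministic
#' trajectory.  Standard errors are observed-information (negative numeric
#' Hessian on the natural scale).
#'
#' @param data a data frame with columns \code{d_cm}, \code{h_m} and (for
#'   mixed fits) \code{plot_id}; alternatively supply \code{formula}.
#' @param family family code or name, see [hd_family_code()].
#' @param mode \code{"mixed"} (default) or \code{"fixed"}.
#' @param formula optional formula \code{h ~ d | plot} naming the columns of
#'   \code{data} to use.
#' @param start optional named vector of starting values on the natural
#'   scale (\code{alpha}, \code{beta}, \code{gamma} if applicable,
#'   \code{sigma}, \code{sigma_phi} if mixed).
#' @param control list: \code{n_starts} (default 3), \code{jitter} (default
#'   0.1, SD of the start perturbation on the transformed scale),
#'   \code{rel.tol} (optimizer tolerance, default 1e-10), \code{grad_tol}
#'   (gradient max-norm for the convergence flag, default 1e-2),
#'   \code{se} (compute standard errors, default TRUE), \code{se_scale_by_n}
#'   (divide squared SEs by n, default FALSE).
#' @return An object of class \code{"hd_fit"}: coefficients, standard
#'   errors, log-likelihood, AIC (\eqn{-2\,\mathrm{LL} + 2p}), per-plot
#'   random-effect modes (mixed fits), convergence flag and optimizer trace.
#'   Supported methods: \code{print}, \code{summary}, \code{coef},
#'   \code{logLik}, \code{vcov}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{simulate}, \code{plot}.
#' @examples
#' gen <- hd_params("V", alpha = 26.63, beta = 0.0667, sigma = 0.606,
#'                  sigma_phi = 3.94)
#' sim <- hd_simulate(60, "V", gen, seed = 42)
#' fit <- hd_fit(sim, "V", mode = "mixed")
#' summary(fit)
#' @export
hd_fit <- function(data, family, mode = c("mixed", "fixed"),
                   formula = NULL, start = NULL, control = list()) {
  mode <- match.arg(mode)
  code <- hd_family_code(family)
  ctl <- utils::modifyList(list(n_starts = 3L, jitter = 0.1,
                                rel.tol = 1e-10, grad_tol = 1e-2,
                                se = TRUE, se_scale_by_n = FALSE), control)
  if (!is.null(formula)) data <- hd_model_frame(formula, data)
  if (is.null(data$plot_id)) data$plot_id <- 1L
  data <- hd_validate_data(
    if (is.null(data$tree_id)) {
      data$tree_id <- stats::ave(seq_len(nrow(data)), data$plot_id,
                                 FUN = seq_along)
      data
    } else data)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  mixed <- mode == "mixed"
  if (mixed && length(unique(data$plot_id)) < 2L)
    stop("mixed fit needs at least 2 plots", call. = FALSE)
  gmax <- min(min(data$h_m), H0) - 1e-6
  nm <- hd_par_names(code, mixed)
  theta0 <- if (is.null(start)) hd_start_values(code, data, mixed) else {
    if (!all(nm %in% names(start)))
      stop("start must name: ", paste(nm, collapse = ", "), call. = FALSE)
    start[nm]
  }
  if (code == "G4" && theta0[["gamma"]] >= gmax)
    theta0[["gamma"]] <- gmax - 10
  t0 <- hd_to_unconstrained(code, theta0, gmax)

  negll <- function(t) {
    theta <- hd_from_unconstrained(code, t, gmax)
    p <- try(hd_theta_to_params(code, theta), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ll <- if (mixed) hd_loglik_mixed(code, p, data) else
      hd_loglik_fixed(code, p, data)
    if (!is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }

  best <- NULL
  trace <- list()
  set.seed(sum(utf8ToInt(code)) + nrow(data))  # deterministic jitter
  for (s in seq_len(ctl$n_starts)) {
    ts <- if (s == 1) t0 else t0 + stats::rnorm(length(t0), 0, ctl$jitter)
    opt <- try(stats::nlminb(ts, negll,
                             control = list(rel.tol = ctl$rel.tol,
                                            iter.max = 500,
                                            eval.max = 1000)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    trace[[s]] <- list(start = ts, objective = opt$objective,
                       convergence = opt$convergence,
                       iterations = opt$iterations,
                       message = opt$message)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("optimization failed for all starts (family ", code, ", ", mode,
         ")", call. = FALSE)
  grad <- num_gradient(negll, best$par)
  # gradient norm scaled by |LL| (finite-difference noise grows with it)
  gscale <- max(1, abs(best$objective))
  converged <- best$convergence == 0 &&
    max(abs(grad)) / gscale < ctl$grad_tol
  theta <- hd_from_unconstrained(code, best$par, gmax)
  names(theta) <- nm
  p_hat <- hd_theta_to_params(code, theta)
  ll <- if (mixed) hd_loglik_mixed(code, p_hat, data) else
    hd_loglik_fixed(code, p_hat, data)
  phi_hat <- attr(ll, "phi_hat")
  if (!is.null(phi_hat)) names(phi_hat) <- unique(data$plot_id)
  ll <- as.numeric(ll)
  n_par <- length(nm)
  aic <- -2 * ll + 2 * n_par

  se <- rep(NA_real_, n_par); names(se) <- nm
  vc <- matrix(NA_real_, n_par, n_par, dimnames = list(nm, nm))
  if (ctl$se) {
    f_nat <- function(th) {
      names(th) <- nm
      p <- try(hd_theta_to_params(code, th), silent = TRUE)
      if (inherits(p, "try-error")) return(NA_real_)
      v <- if (mixed) hd_loglik_mixed(code, p, data) else
        hd_loglik_fixed(code, p, data)
      as.numeric(v)
    }
    info <- -num_hessian(f_nat, unname(theta),
                         step = 1e-5 * pmax(1, abs(theta)))
    vc_try <- try(solve(info), silent = TRUE)
    if (!inherits(vc_try, "try-error")) {
      dd <- diag(vc_try)
      bad <- !is.finite(dd) | dd <= 0
      if (any(bad))
        warning("observed information not positive definite; NaN SEs for: ",
                paste(nm[bad], collapse = ", "))
      dd[bad] <- NaN
      se <- sqrt(dd)
      if (ctl$se_scale_by_n) se <- se / sqrt(nrow(data))
      names(se) <- nm
      vc[,] <- vc_try
    } else {
      warning("observed information matrix is singular; SEs unavailable")
    }
  }

  structure(list(family = code, mode = mode, coefficients = theta,
                 se = se, vcov = vc, params = p_hat, loglik = ll,
                 aic = aic, ranef = phi_hat, converged = converged,
                 gradient = grad, n_obs = nrow(data),
                 n_plots = length(unique(data$plot_id)),
                 data = data, control = ctl, trace = trace,
                 call = match.call()),
            class = "hd_fit")
}

# h ~ d | plot  ->  standard column names
hd_model_frame <- function(formula, data) {
  rhs <- formula[[3]]
  if (is.call(rhs) && identical(rhs[[1]], as.name("|"))) {
    dvar <- rhs[[2]]; gvar <- rhs[[3]]
  } else {
    dvar <- rhs; gvar <- NULL
  }
  out <- data.frame(
    d_cm = eval(dvar, data, parent.frame()),
    h_m = eval(formula[[2]], data, parent.frame()))
  out$plot_id <- if (is.null(gvar)) 1L else eval(gvar, data, parent.frame())
  out
}
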