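# Independent oracles for the estimation layer. These deliberately avoid
# the package's Laplace code path: quadrature and linear-Gaussian algebra
# built from hd_density / dnorm only.

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' weight e^{-x^2})
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# marginal log-likelihood of one plot by adaptive Gauss-Hermite quadrature:
# nodes centered and scaled at an independently located mode of the log
# integrand (mode and curvature found numerically, not via the package's
# Laplace internals)
gh_plot_loglik <- function(code, params, sigma_phi, plot_data, n_nodes = 64) {
  lg <- function(ph) sum(hd_density(code, params, d = plot_data$d_cm,
                                    h = plot_data$h_m, phi = ph,
                                    log = TRUE)) +
    stats::dnorm(ph, 0, sigma_phi, log = TRUE)
  half <- 10 * sigma_phi
  mode <- stats::optimize(lg, c(-half, half), maximum = TRUE,
                          tol = 1e-12)$maximum
  eps <- 1e-4 * max(sigma_phi, 1e-3)
  curv <- -(lg(mode + eps) - 2 * lg(mode) + lg(mode - eps)) / eps^2
  s <- 1 / sqrt(curv)
  gh <- gauss_hermite(n_nodes)
  phis <- mode + sqrt(2) * s * gh$nodes
  vals <- vapply(phis, lg, numeric(1))
  m <- max(vals)
  # sum w_i e^{x_i^2} f(mode + sqrt(2) s x_i) * sqrt(2) s
  m + log(sum(gh$weights * exp(vals - m + gh$nodes^2))) +
    log(sqrt(2) * s)
}

# marginal log-likelihood of one plot by adaptive quadrature over phi,
# centered on an independently located mode (the integrand is narrow)
quad_plot_loglik <- function(code, params, sigma_phi, plot_data) {
  lg <- function(ph) sum(hd_density(code, params, d = plot_data$d_cm,
                                    h = plot_data$h_m, phi = ph,
                                    log = TRUE)) +
    stats::dnorm(ph, 0, sigma_phi, log = TRUE)
  half <- 10 * sigma_phi
  mode <- stats::optimize(lg, c(-half, half), maximum = TRUE,
                          tol = 1e-12)$maximum
  m <- lg(mode)
  dens <- function(phi) vapply(phi, function(ph) exp(lg(ph) - m),
                               numeric(1))
  m + log(stats::integrate(dens, mode - half, mode + half,
                           rel.tol = 1e-12, subdivisions = 1000L)$value)
}

# exact Vasicek marginal: heights of a plot are jointly Gaussian with
# covariance diag(lambda2) + sigma_phi^2 * b b'
mvn_vasicek_plot_loglik <- function(params, sigma_phi, plot_data) {
  law <- hd_transition_law("V", params, d = plot_data$d_cm)
  e <- exp(-params$beta * plot_data$d_cm)
  b <- 1 - e
  S <- diag(law$lambda2, nrow = length(b)) + sigma_phi^2 * tcrossprod(b)
  r <- plot_data$h_m - law$mu
  -0.5 * (length(b) * log(2 * pi) + determinant(S)$modulus[1] +
            drop(crossprod(r, solve(S, r))))
}
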