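# Likelihoods, Laplace machinery and the fitting function.

test_that("fixed log-likelihood is a brute-force sum of log densities", {
  set.seed(11)
  p <- ref_mixed()$G3
  sim <- hd_simulate(5, "G3", p, trees_per_plot = 4, seed = 2)
  brute <- sum(log(hd_density("G3", p, d = sim$d_cm, h = sim$h_m)))
  expect_equal(hd_loglik_fixed("G3", p, sim), brute, tolerance = 1e-10)
  # single tree
  one <- sim[1, ]
  expect_equal(hd_loglik_fixed("G3", p, one),
               log(hd_density("G3", p, d = one$d_cm, h = one$h_m)))
  # additivity over disjoint datasets
  expect_equal(hd_loglik_fixed("G3", p, sim),
               hd_loglik_fixed("G3", p, sim[1:10, ]) +
                 hd_loglik_fixed("G3", p, sim[-(1:10), ]))
  # out-of-support observation
  bad <- sim; bad$h_m[1] <- -2
  expect_identical(hd_loglik_fixed("G3", p, bad), -Inf)
  expect_error(hd_loglik_fixed("G3", p, sim[0, ]), "empty")
})

test_that("plot objective g matches its definition and handles empty plots", {
  set.seed(12)
  p <- ref_mixed()$B
  sim <- hd_simulate(1, "B", p, trees_per_plot = 5, seed = 9)
  for (phi in stats::rnorm(10, 0, 0.05)) {
    direct <- sum(hd_density("B", p, d = sim$d_cm, h = sim$h_m,
                             phi = phi, log = TRUE)) +
      stats::dnorm(phi, 0, p$sigma_phi, log = TRUE)
    expect_equal(hd_plot_g("B", p, p$sigma_phi, sim, phi), direct,
                 tolerance = 1e-10)
  }
  # zero-tree plot: just the prior, maximized at phi = 0
  empty <- sim[0, ]
  expect_equal(hd_plot_g("B", p, 0.1, empty, 0),
               stats::dnorm(0, 0, 0.1, log = TRUE))
  expect_gt(hd_plot_g("B", p, 0.1, empty, 0),
            hd_plot_g("B", p, 0.1, empty, 0.05))
  # and its marginal contribution is zero (the prior integrates to one)
  expect_equal(hd_laplace_plot("B", p, 0.1, empty)$value, 0)
})

test_that("with a diffuse prior the mode solves the mean-inversion", {
  p <- ref_mixed()$V
  tree <- data.frame(d_cm = 27, h_m = 24.2)
  lap <- hd_laplace_plot("V", p, 1e6, tree)
  expect_equal(hd_mean("V", p, d = 27, phi = lap$phi_hat), 24.2,
               tolerance = 1e-4)
})

test_that("Laplace equals the exact Vasicek marginal and Gauss-Hermite", {
  set.seed(13)
  p <- ref_mixed()$V
  for (r in 1:4) {
    ni <- sample(1:5, 1)
    plot_data <- data.frame(d_cm = stats::runif(ni, 16, 50),
                            h_m = stats::runif(ni, 12, 30))
    lap <- hd_laplace_plot("V", p, p$sigma_phi, plot_data)
    expect_equal(lap$value,
                 mvn_vasicek_plot_loglik(p, p$sigma_phi, plot_data),
                 tolerance = 1e-9)
    expect_equal(lap$value,
                 gh_plot_loglik("V", p, p$sigma_phi, plot_data),
                 tolerance = 1e-9)
    # the mode is a stationary point of g
    eps <- 1e-5
    g1 <- (hd_plot_g("V", p, p$sigma_phi, plot_data, lap$phi_hat + eps) -
             hd_plot_g("V", p, p$sigma_phi, plot_data,
                       lap$phi_hat - eps)) / (2 * eps)
    expect_lt(abs(g1), 1e-6)
  }
})

test_that("Laplace matches adaptive quadrature for the lognormal families", {
  set.seed(14)
  for (k in c("G3", "G4", "B", "G")) {
    p <- ref_mixed()[[k]]
    sim <- hd_simulate(5, k, p, trees_per_plot = 3, seed = 40 + match(k, fams()))
    for (i in unique(sim$plot_id)) {
      pd <- sim[sim$plot_id == i, ]
      lap <- hd_laplace_plot(k, p, p$sigma_phi, pd)$value
      quad <- quad_plot_loglik(k, p, p$sigma_phi, pd)
      expect_equal(lap, quad, tolerance = 1e-4 * max(1, abs(quad)))
    }
  }
})

test_that("mixed log-likelihood sums plot marginals and has the right limits", {
  set.seed(15)
  p <- ref_mixed()$G3
  sim <- hd_simulate(6, "G3", p, seed = 8)
  ll <- hd_loglik_mixed("G3", p, sim)
  by_plot <- sum(vapply(unique(sim$plot_id), function(i)
    hd_laplace_plot("G3", p, p$sigma_phi, sim[sim$plot_id == i, ])$value,
    numeric(1)))
  expect_equal(as.numeric(ll), by_plot, tolerance = 1e-10)
  # sigma_phi -> 0: approaches the fixed-effects likelihood at phi = 0
  p_tiny <- hd_params("G3", p$alpha, p$beta, sigma = p$sigma,
                      sigma_phi = 1e-6)
  expect_equal(as.numeric(hd_loglik_mixed("G3", p_tiny, sim)),
               hd_loglik_fixed("G3", p, sim), tolerance = 1e-3)
  # matches a full numeric double loop on tiny data
  quad <- sum(vapply(unique(sim$plot_id), function(i)
    quad_plot_loglik("G3", p, p$sigma_phi, sim[sim$plot_id == i, ]),
    numeric(1)))
  expect_equal(as.numeric(ll), quad, tolerance = 1e-4 * abs(quad))
})

test_that("fitting recovers parameters and orders likelihoods sanely", {
  p <- ref_mixed()$V
  sim <- hd_simulate(200, "V", p, seed = 77)
  fit <- hd_fit(sim, "V", mode = "mixed")
  expect_true(fit$converged)
  est <- coef(fit)
  expect_lt(abs(est[["alpha"]] - p$alpha) / p$alpha, 0.1)
  expect_lt(abs(est[["beta"]] - p$beta) / p$beta, 0.1)
  expect_lt(abs(est[["sigma"]] - p$sigma) / p$sigma, 0.15)
  expect_lt(abs(est[["sigma_phi"]] - p$sigma_phi) / p$sigma_phi, 0.25)
  # likelihood at the generating values cannot beat the fit
  expect_lte(as.numeric(hd_loglik_mixed("V", p, sim)), fit$loglik + 1e-6)
  # AIC bookkeeping: -2 LL + 2p
  expect_equal(fit$aic, -2 * fit$loglik + 2 * length(coef(fit)))
  expect_length(hd_ranef(fit), fit$n_plots)
  # fixed fit reports no random effects
  ffix <- hd_fit(sim, "V", mode = "fixed")
  expect_null(hd_ranef(ffix))
  expect_gt(ffix$aic, fit$aic)
})

test_that("near-deterministic data pins down the trajectory parameters", {
  p <- hd_params("V", 26.6348, 0.0667, sigma = 0.02)
  sim <- hd_simulate(40, "V", p, seed = 55)
  fit <- hd_fit(sim, "V", mode = "fixed")
  expect_lt(abs(coef(fit)[["alpha"]] - p$alpha) / p$alpha, 0.01)
  expect_lt(abs(coef(fit)[["beta"]] - p$beta) / p$beta, 0.01)
  expect_lt(abs(coef(fit)[["sigma"]] - p$sigma) / p$sigma, 0.2)
})

test_that("fitting is invariant to plot order", {
  p <- ref_mixed()$G
  sim <- hd_simulate(40, "G", p, seed = 19)
  fit1 <- hd_fit(sim, "G", mode = "mixed")
  perm <- sim[order(-sim$plot_id, sim$tree_id), ]
  fit2 <- hd_fit(perm, "G", mode = "mixed")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("standard errors behave like observed information", {
  p <- hd_params("V", 26.6348, 0.0667, sigma = 0.6059)
  sim <- hd_simulate(25, "V", p, trees_per_plot = 2, seed = 91)
  fit <- hd_fit(sim, "V", mode = "fixed")
  # alpha enters the Gaussian model linearly: the (alpha, alpha) element of
  # the observed information is sum(b_j^2 / lambda_j^2) in closed form
  info <- solve(vcov(fit))
  b <- 1 - exp(-coef(fit)[["beta"]] * sim$d_cm)
  l2 <- hd_transition_law("V", fit$params, d = sim$d_cm)$lambda2
  expect_equal(info["alpha", "alpha"], sum(b^2 / l2), tolerance = 0.05)
  # doubling the data halves the variance: SE shrinks by 1/sqrt(2)
  dbl <- rbind(as.data.frame(sim),
               transform(as.data.frame(sim), plot_id = plot_id + 1000))
  fit2 <- hd_fit(dbl, "V", mode = "fixed", start = coef(fit))
  expect_equal(unname(fit2$se / fit$se), rep(1 / sqrt(2), 3),
               tolerance = 0.02)
  # the printed scale-by-n variant divides by sqrt(n)
  fit3 <- hd_fit(sim, "V", mode = "fixed", start = coef(fit),
                 control = list(se_scale_by_n = TRUE))
  expect_equal(unname(fit3$se * sqrt(nrow(sim)) / fit$se), rep(1, 3),
               tolerance = 0.05)
})

test_that("estimation error trends down with the number of plots", {
  p <- ref_mixed()$V
  sizes <- c(50, 200, 800)
  reps <- 10
  err <- array(NA_real_, c(length(sizes), reps, 2),
               dimnames = list(sizes, NULL, c("alpha", "beta")))
  for (si in seq_along(sizes)) for (r in seq_len(reps)) {
    sim <- hd_simulate(sizes[si], "V", p, seed = 1000 * si + r)
    est <- coef(hd_fit(sim, "V", mode = "mixed"))
    err[si, r, "alpha"] <- abs(est[["alpha"]] - p$alpha)
    err[si, r, "beta"] <- abs(est[["beta"]] - p$beta)
  }
  med <- apply(err, c(1, 3), stats::median)
  expect_true(all(diff(med[, "alpha"]) <= 1e-12 + 0))
  expect_true(all(diff(med[, "beta"]) <= 1e-12 + 0))
})

test_that("the formula interface maps columns correctly", {
  p <- ref_mixed()$V
  sim <- hd_simulate(30, "V", p, seed = 4)
  df <- data.frame(height = sim$h_m, dbh = sim$d_cm, stand = sim$plot_id)
  f1 <- hd_fit(sim, "V", mode = "mixed")
  f2 <- hd_fit(df, "V", mode = "mixed", formula = height ~ dbh | stand)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})
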