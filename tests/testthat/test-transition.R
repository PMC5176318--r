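# Transition laws: closed forms, moments, quantiles, sampling.

test_that("deterministic trajectories start at breast height and match frozen values", {
  for (k in fams()) {
    p <- ref_fixed()[[k]]
    d0 <- if (k == "G") 0.001 else 0
    expect_equal(hd_deterministic(k, p, d = d0), 1.3, tolerance = 1e-12)
  }
  # Mitscherlich curve at the mean inventory diameter (independent script)
  expect_equal(hd_deterministic("V", ref_fixed()$V, d = 27.33),
               22.7495461609128, tolerance = 1e-10)
  expect_error(hd_deterministic("V", ref_fixed()$V, d = -1), "d0")
  expect_error(hd_deterministic("G", ref_fixed()$G, d = 0), "d0")
})

test_that("parameter validation enforces family domains", {
  expect_error(hd_params("V", 25, 0.05, sigma = -1), "sigma")
  expect_error(hd_params("V", 25, -0.05, sigma = 1), "beta")
  expect_error(hd_params("B", 0.7, 0.04, gamma = 1.2, sigma = 0.02),
               "gamma")
  expect_error(hd_params("G4", 0.3, 0.07, gamma = 2, sigma = 0.004),
               "1.3")
  expect_error(hd_params("G3", 0.4, 0.1, gamma = 0.5, sigma = 0.04),
               "no 'gamma'")
  # Gamma family admits negative beta
  expect_s3_class(hd_params("G", 0.26, -0.0083, sigma = 0.03), "hd_params")
})

test_that("transition law matches independently computed closed forms", {
  # 3-parameter Gompertz, mixed-effects reference values, d = 25
  law <- hd_transition_law("G3", ref_mixed()$G3, d = 25)
  expect_equal(law$mu, 3.0876347880748902, tolerance = 1e-12)
  expect_equal(law$lambda2, 0.006788396496630482, tolerance = 1e-12)
  expect_equal(hd_mean("G3", ref_mixed()$G3, d = 25),
               21.999703727222535, tolerance = 1e-12)
  expect_equal(hd_variance("G3", ref_mixed()$G3, d = 25),
               3.2966723109451146, tolerance = 1e-12)
  # Bertalanffy conditional mean is the deterministic curve at alpha + phi
  expect_equal(hd_mean("B", ref_mixed()$B, d = 30),
               22.726805326956217, tolerance = 1e-12)
  expect_equal(hd_variance("B", ref_mixed()$B, d = 30),
               4.184456239035124, tolerance = 1e-12)
  # lognormal pdf evaluated independently
  expect_equal(hd_density("G3", ref_fixed()$G3, d = 25, h = 20),
               0.10188759392625672, tolerance = 1e-12)
  # normal mode height
  pV <- ref_mixed()$V
  muV <- hd_mean("V", pV, d = 20)
  expect_equal(hd_density("V", pV, d = 20, h = muV),
               1 / sqrt(2 * pi * hd_variance("V", pV, d = 20)),
               tolerance = 1e-12)
})

test_that("lambda2 vanishes at d0, is nondecreasing, and saturates for Vasicek", {
  for (k in fams()) {
    p <- ref_mixed()[[k]]
    d0 <- if (k == "G") 0.001 else 0
    expect_equal(hd_variance(k, p, d = d0), 0)
    grid <- d0 + seq(0.01, 80, length.out = 120)
    l2 <- hd_transition_law(k, p, d = grid)$lambda2
    expect_true(all(diff(l2) >= -1e-12))
  }
  pV <- ref_mixed()$V
  expect_equal(hd_transition_law("V", pV, d = 1e4)$lambda2,
               pV$sigma^2 / (2 * pV$beta), tolerance = 1e-10)
})

test_that("density integrates to one and matches closed-form moments", {
  set.seed(101)
  for (k in fams()) {
    for (r in 1:3) {
      p <- rand_params(k)
      d <- stats::runif(1, 18, 50)
      b <- quad_bounds(k, p, d)
      mass <- stats::integrate(function(h)
        hd_density(k, p, d = d, h = h), b[1], b[2],
        rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 500L)$value
      expect_equal(mass, 1, tolerance = 1e-8)
      m_q <- quad_moment(k, p, d)
      v_q <- quad_moment(k, p, d, k = 2, about = m_q)
      expect_equal(m_q, hd_mean(k, p, d = d), tolerance = 1e-6)
      expect_equal(v_q, hd_variance(k, p, d = d), tolerance = 1e-6)
    }
  }
})

test_that("quantiles invert the CDF and are monotone in p", {
  set.seed(202)
  ps <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  for (k in fams()) {
    p <- rand_params(k)
    d <- stats::runif(1, 20, 45)
    q <- hd_quantile(k, p, d = d, p_q = ps)
    expect_true(all(diff(q) > 0))
    expect_equal(hd_cdf(k, p, d = d, q = q), ps, tolerance = 1e-10)
  }
  # medians: Vasicek mean, shifted-lognormal gamma + exp(mu)
  pV <- ref_mixed()$V
  expect_equal(hd_quantile("V", pV, d = 30, p_q = 0.5),
               hd_transition_law("V", pV, d = 30)$mu, tolerance = 1e-12)
  pG4 <- ref_mixed()$G4
  law <- hd_transition_law("G4", pG4, d = 30)
  expect_equal(hd_quantile("G4", pG4, d = 30, p_q = 0.5),
               pG4$gamma + exp(law$mu), tolerance = 1e-12)
  expect_error(hd_quantile("V", pV, d = 30, p_q = 1.2), "0, 1")
})

test_that("law degenerates correctly at d0 and as sigma -> 0", {
  pV <- ref_mixed()$V
  expect_error(hd_density("V", pV, d = 0, h = 1.3), "degenerate")
  expect_error(hd_quantile("V", pV, d = 0, p_q = 0.5), "degenerate")
  expect_equal(hd_mean("V", pV, d = 0), 1.3)
  # sigma -> 0: conditional mean collapses onto the deterministic curve
  # with alpha replaced by alpha + phi, and the variance vanishes
  for (k in fams()) {
    p0 <- ref_mixed()[[k]]
    phi <- 0.3 * p0$sigma_phi
    p_small <- hd_params(k, p0$alpha, p0$beta, gamma = p0$gamma,
                         sigma = 1e-9)
    d <- 33
    expect_equal(hd_mean(k, p_small, d = d, phi = phi),
                 hd_deterministic(k, p_small, d = d, phi = phi),
                 tolerance = 1e-10)
    expect_lt(hd_variance(k, p_small, d = d, phi = phi), 1e-12)
  }
})

test_that("exact sampler reproduces the closed-form law", {
  set.seed(303)
  n <- 2e4
  for (k in fams()) {
    p <- ref_mixed()[[k]]
    d <- 28
    x <- hd_sample(n, k, p, d = d)
    ks <- stats::ks.test(x, function(q) hd_cdf(k, p, d = d, q = q))
    expect_gt(ks$p.value, 0.01)
    m <- hd_mean(k, p, d = d)
    se <- sqrt(hd_variance(k, p, d = d) / n)
    expect_lt(abs(mean(x) - m), 3 * se)
  }
})
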