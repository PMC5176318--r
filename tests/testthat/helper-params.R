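# Reference parameter sets typical of mature Scots pine inventories, used
# throughout the tests as generating values.

ref_mixed <- function() list(
  V  = hd_params("V", 26.6348, 0.0667, sigma = 0.6059, sigma_phi = 3.9371),
  G3 = hd_params("G3", 0.4324, 0.1354, sigma = 0.0429, sigma_phi = 0.0238),
  G4 = hd_params("G4", 0.3682, 0.0710, gamma = -152.6744, sigma = 0.0036,
                 sigma_phi = 0.0016),
  B  = hd_params("B", 0.6770, 0.0436, gamma = 0.9893, sigma = 0.0164,
                 sigma_phi = 0.0404),
  G  = hd_params("G", 0.2663, -0.0034, sigma = 0.0165, sigma_phi = 0.0164))

ref_fixed <- function() list(
  V  = hd_params("V", 30.6854, 0.0479, sigma = 1.0568),
  G3 = hd_params("G3", 0.3721, 0.1128, sigma = 0.0786),
  G4 = hd_params("G4", 0.2825, 0.0502, gamma = -245.9571, sigma = 0.0040),
  B  = hd_params("B", 0.9748, 0.0436, gamma = 0.9625, sigma = 0.0335),
  G  = hd_params("G", 0.2557, -0.0083, sigma = 0.0340))

fams <- function() c("V", "G3", "G4", "B", "G")

# randomized valid parameter draw within realistic ranges per family
rand_params <- function(code, mixed = FALSE) {
  runif1 <- function(a, b) stats::runif(1, a, b)
  sp <- if (mixed) switch(code,
    V = runif1(1, 5), G3 = runif1(0.01, 0.04), G4 = runif1(0.001, 0.003),
    B = runif1(0.02, 0.06), G = runif1(0.01, 0.03)) else NULL
  switch(code,
    V  = hd_params("V", runif1(20, 33), runif1(0.04, 0.12),
                   sigma = runif1(0.3, 1.4), sigma_phi = sp),
    G3 = hd_params("G3", runif1(0.32, 0.5), runif1(0.09, 0.18),
                   sigma = runif1(0.02, 0.09), sigma_phi = sp),
    G4 = hd_params("G4", runif1(0.25, 0.45), runif1(0.05, 0.1),
                   gamma = runif1(-220, -80), sigma = runif1(0.002, 0.006),
                   sigma_phi = sp),
    B  = hd_params("B", runif1(0.5, 1.1), runif1(0.035, 0.07),
                   gamma = runif1(0.9, 0.99), sigma = runif1(0.01, 0.04),
                   sigma_phi = sp),
    G  = hd_params("G", runif1(0.22, 0.3), runif1(-0.008, 0.004),
                   sigma = runif1(0.01, 0.04), sigma_phi = sp))
}

# support lower bound of the law (for quadrature in oracles)
law_lower <- function(code, params) {
  if (code == "V") -Inf else if (code == "G4") params$gamma else 0
}

# integration bounds bracketing essentially all mass of the (unimodal) law:
# support intersected with mean +/- 60 conditional SDs
quad_bounds <- function(code, params, d, phi = 0) {
  m <- hd_mean(code, params, d = d, phi = phi)
  s <- sqrt(hd_variance(code, params, d = d, phi = phi))
  c(max(law_lower(code, params), m - 60 * s), m + 60 * s)
}

# independent quadrature moment of h^k under the transition density
quad_moment <- function(code, params, d, phi = 0, k = 1, about = 0) {
  b <- quad_bounds(code, params, d, phi)
  stats::integrate(function(h)
    (h - about)^k * hd_density(code, params, d = d, h = h, phi = phi),
    lower = b[1], upper = b[2],
    rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 500L)$value
}
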