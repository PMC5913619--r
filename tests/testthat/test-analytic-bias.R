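test_that("analytic bias matches the hand-solved 2x2 system", {
  # rho_UE = rho_UC = 0.4, gamma = 0.5, no error, beta = 0:
  # bias_b1 = 0.4 * 0.5 / (1 + 0.16)
  M <- moment_matrices(default_conf())
  b <- analytic_ols_bias(M, structural_params(gamma = 0.5))
  expect_equal(b$bias_b1, 0.4 * 0.5 / 1.16, tolerance = 1e-12)
  expect_equal(b$bias_b2, 0.4 * 0.5 / 1.16, tolerance = 1e-12)
  expect_equal(b$bias_diff, 0, tolerance = 1e-12)
  expect_identical(b$method, "analytic")

  # adjugate-inverse oracle across random scenarios
  set.seed(21)
  for (i in 1:30) {
    r <- runif(2, -0.9, 0.9)
    icc <- runif(2, 0.2, 1)
    gamma <- runif(1, 0, 1)
    beta <- rnorm(2)
    M <- moment_matrices(confounding_structure(r[1], r[2]),
                         continuous_error(icc[1], icc[2]))
    got <- analytic_ols_bias(M, structural_params(beta[1], beta[2], gamma))
    want <- bias_by_hand(r[1], r[2], icc_to_error_variance(icc[1]),
                         icc_to_error_variance(icc[2]), gamma, beta)
    expect_equal(c(got$bias_b1, got$bias_b2), want, tolerance = 1e-12)
  }
})

test_that("no confounding and no error means no bias", {
  M <- moment_matrices(default_conf())
  b <- analytic_ols_bias(M, structural_params(beta1 = 0.7, beta2 = -0.3,
                                              gamma = 0))
  expect_equal(b$bias_b1, 0)
  expect_equal(b$bias_b2, 0)
})

test_that("error-free, equally confounded exposure and control calibrate exactly", {
  set.seed(22)
  for (i in 1:20) {
    rho <- runif(1, -0.9, 0.9)
    sp <- structural_params(rnorm(1), rnorm(1), runif(1, 0, 1))
    M <- moment_matrices(confounding_structure(rho, rho))
    expect_equal(analytic_ols_bias(M, sp)$bias_diff, 0, tolerance = 1e-12)
  }
})

test_that("bias formula reduces exactly to univariate attenuation in the degenerate case", {
  # gamma = 0, rho_EC = 0, error only in the exposure
  expect_equal(univariate_attenuation(0.2, 0), 0.2)
  expect_equal(univariate_attenuation(0.2, 1.0), 0.1)
  expect_equal(univariate_attenuation(0, 5), 0)
  for (beta1 in c(-0.5, 0, 0.2, 1)) {
    for (icc in c(0.3, 0.5, 0.8, 1)) {
      s2 <- icc_to_error_variance(icc)
      M <- moment_matrices(confounding_structure(0, 0),
                           continuous_error(icc_E = icc))
      b <- analytic_ols_bias(M, structural_params(beta1 = beta1))
      expect_equal(b$bias_b1, univariate_attenuation(beta1, s2) - beta1,
                   tolerance = 1e-14)
      expect_equal(b$bias_b2, 0, tolerance = 1e-14)
    }
  }
})

test_that("swapping exposure and control roles swaps the biases", {
  set.seed(23)
  for (i in 1:20) {
    r <- runif(2, -0.9, 0.9)
    icc <- runif(2, 0.2, 1)
    beta <- rnorm(2)
    gamma <- runif(1)
    a <- analytic_ols_bias(
      moment_matrices(confounding_structure(r[1], r[2]),
                      continuous_error(icc[1], icc[2])),
      structural_params(beta[1], beta[2], gamma)
    )
    b <- analytic_ols_bias(
      moment_matrices(confounding_structure(r[2], r[1]),
                      continuous_error(icc[2], icc[1])),
      structural_params(beta[2], beta[1], gamma)
    )
    expect_equal(a$bias_b1, b$bias_b2, tolerance = 1e-12)
    expect_equal(a$bias_b2, b$bias_b1, tolerance = 1e-12)
    expect_equal(a$bias_diff, -b$bias_diff, tolerance = 1e-12)
  }
})

test_that("attenuation bias grows with error variance and drives the slope to zero", {
  beta1 <- 0.8
  iccs <- c(1, 0.8, 0.5, 0.2, 0.05, 0.01)
  biases <- vapply(iccs, function(icc) {
    M <- moment_matrices(confounding_structure(0, 0),
                         continuous_error(icc_E = icc))
    analytic_ols_bias(M, structural_params(beta1 = beta1))$bias_b1
  }, numeric(1))
  expect_true(all(diff(abs(biases)) >= 0))   # |bias| nondecreasing in sigma2_v
  expect_equal(biases[length(biases)], -beta1, tolerance = 0.02) # slope -> 0
})

test_that("bias curves cover the grid in order with correct labelling", {
  curve <- bias_curve(structural_params(beta1 = 0.2), default_conf(),
                      list(continuous_error(), continuous_error(icc_E = 0.7)))
  expect_equal(nrow(curve), 2 * 51)
  expect_equal(curve$gamma[1:51], seq(0, 0.5, length.out = 51))
  expect_setequal(names(curve),
                  c("gamma", "icc_E", "icc_C", "beta1", "beta2",
                    "bias_b1", "bias_b2", "bias_diff", "method"))
  expect_equal(curve$bias_diff, curve$bias_b1 - curve$bias_b2)

  # regression dilution: beta1 > 0, gamma = 0, icc < 1 biases towards the null
  row <- curve[curve$gamma == 0 & curve$icc_E == 0.7, ]
  expect_lt(row$bias_b1, 0)

  # gamma = 0 and beta = 0 kill both bias terms
  null_curve <- bias_curve(structural_params(), default_conf(),
                           continuous_error(icc_E = 0.5, icc_C = 0.9),
                           gamma_grid = 0)
  expect_equal(null_curve$bias_b1, 0)
  expect_equal(null_curve$bias_b2, 0)

  # equal error and equal effects: calibration stays exact along the curve
  sym <- bias_curve(structural_params(beta1 = 0.3, beta2 = 0.3), default_conf(),
                    continuous_error(icc_E = 0.6, icc_C = 0.6))
  expect_equal(sym$bias_diff, rep(0, 51), tolerance = 1e-12)
})
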