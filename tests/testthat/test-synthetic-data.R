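test_that("latent draws are deterministic in the seed and leave the global RNG alone", {
  conf <- default_conf()
  set.seed(999)
  before <- .Random.seed
  a <- draw_latents(100, conf, seed = 42)
  expect_identical(.Random.seed, before)
  b <- draw_latents(100, conf, seed = 42)
  expect_identical(a, b)
  c <- draw_latents(100, conf, seed = 43)
  expect_false(identical(a$U, c$U))
})

test_that("latent sample reproduces the configured correlation structure", {
  n <- 2e5
  ls <- draw_latents(n, default_conf(), seed = 7)
  tol <- 3 / sqrt(n)
  expect_equal(cor(ls$U, ls$E_T), 0.4, tolerance = 2 * tol)
  expect_equal(cor(ls$U, ls$C_T), 0.4, tolerance = 2 * tol)
  expect_equal(cor(ls$E_T, ls$C_T), 0.16, tolerance = 2 * tol)
  expect_equal(sd(ls$E_T), 1, tolerance = 0.02)

  ls0 <- draw_latents(1e5, confounding_structure(0, 0), seed = 8)
  expect_lt(abs(cor(ls0$U, ls0$E_T)), 4 / sqrt(1e5))
})

test_that("continuous measurement error is additive, independent, and ICC-calibrated", {
  ls <- draw_latents(1e5, default_conf(), seed = 9)
  expect_identical(add_continuous_error(ls$E_T, 0, seed = 1), ls$E_T)

  x_obs <- add_continuous_error(ls$E_T, 1, seed = 10)
  v <- x_obs - ls$E_T
  expect_equal(var(ls$E_T) / var(x_obs), 0.5, tolerance = 0.01)
  expect_lt(abs(cor(v, ls$E_T)), 4 / sqrt(1e5))
  expect_error(add_continuous_error(ls$E_T, -1, seed = 1), "nonnegative")
})

test_that("top-quantile dichotomization is rank-based with the right prevalence", {
  expect_identical(dichotomize_top_quantile(c(1, 2, 3, 4, 5)),
                   c(0L, 0L, 0L, 0L, 1L))
  x <- draw_latents(1e5, default_conf(), seed = 11)$E_T
  d <- dichotomize_top_quantile(x)
  expect_equal(mean(d), 0.2, tolerance = 0.005)
  expect_identical(dichotomize_top_quantile(exp(x)), d) # monotone invariance
  expect_equal(mean(dichotomize_top_quantile(x, cut = 0.5)), 0.5,
               tolerance = 0.005)
  expect_error(dichotomize_top_quantile(rep(1, 10)), "constant")
  expect_error(dichotomize_top_quantile(numeric(0)), "nonempty")
  expect_error(dichotomize_top_quantile(x, cut = 0), "inside")
})

test_that("misclassification flips symmetrically at the configured rate", {
  x <- dichotomize_top_quantile(draw_latents(1e5, default_conf(), seed = 12)$E_T)
  expect_identical(misclassify(x, 0, seed = 1), x)

  # p = 0.5 destroys all association with the truth
  y50 <- misclassify(x, 0.5, seed = 13)
  expect_lt(abs(cor(y50, x)), 0.015)

  # P(obs = 1) = 0.2 * 0.9 + 0.8 * 0.1 = 0.26 at p = 0.1
  y10 <- misclassify(x, 0.1, seed = 14)
  expect_equal(mean(y10), 0.26, tolerance = 0.008)

  # same flip rate in both classes
  expect_within(mean(y10[x == 1] == 0), 0.1, 0.01)
  expect_within(mean(y10[x == 0] == 1), 0.1, 0.01)

  expect_error(misclassify(c(0, 1, 2), 0.1, seed = 1), "0 and 1")
  expect_error(misclassify(x, 1.5, seed = 1), "probability")
})

test_that("outcomes follow the structural equation", {
  conf <- default_conf()
  ls <- draw_latents(5000, conf, seed = 15)

  # near-deterministic limit: tiny noise, y tracks the exposure
  sp <- structural_params(beta1 = 1, sigma_eps = 1e-8)
  y <- generate_outcome(ls, sp, ls$E_T, ls$C_T, seed = 16)
  expect_equal(y, ls$E_T, tolerance = 1e-6)

  # pure noise case: no association with the exposure
  y0 <- generate_outcome(ls, structural_params(), ls$E_T, ls$C_T, seed = 17)
  expect_lt(abs(cor(y0, ls$E_T)), 4 / sqrt(5000))

  expect_error(
    generate_outcome(ls, sp, ls$E_T[-1], ls$C_T, seed = 1), "length"
  )
})

test_that("regression including the confounder recovers the binary-design truth", {
  sp <- structural_params(beta1 = 0.2, beta2 = 0, gamma = 0.2)
  d <- simulate_dataset(1e5, sp, default_conf(), binary_error(), seed = 18)
  fit <- lm(d$y ~ d$E_bin + d$C_bin + d$latents$U)
  est <- coef(fit)[2:4]
  se <- sqrt(diag(vcov(fit)))[2:4]
  expect_true(all(abs(est - c(0.2, 0, 0.2)) < 3 * se))
})

test_that("datasets are bit-reproducible and error channels are independent streams", {
  sp <- structural_params(beta1 = 0.2, gamma = 0.2)
  conf <- default_conf()
  a <- simulate_dataset(2000, sp, conf, binary_error(p_E = 0.1, p_C = 0.5),
                        seed = 19)
  b <- simulate_dataset(2000, sp, conf, binary_error(p_E = 0.1, p_C = 0.5),
                        seed = 19)
  expect_identical(a, b)

  # toggling the control's error channel leaves everything else untouched
  c <- simulate_dataset(2000, sp, conf, binary_error(p_E = 0.1, p_C = 0),
                        seed = 19)
  expect_identical(a$E_O, c$E_O)
  expect_identical(a$y, c$y)
  expect_identical(a$latents, c$latents)
  expect_false(identical(a$C_O, c$C_O))

  # outcome is generated from the TRUE values: error never touches y
  d <- simulate_dataset(2000, sp, conf, binary_error(p_E = 0.5, p_C = 0.5),
                        seed = 19)
  expect_identical(a$y, d$y)
  e1 <- simulate_dataset(2000, sp, conf, continuous_error(icc_E = 0.4),
                         seed = 19)
  e2 <- simulate_dataset(2000, sp, conf, continuous_error(), seed = 19)
  expect_identical(e1$y, e2$y)
})

test_that("binary design outputs are 0/1 with the expected marginal rate", {
  d <- simulate_dataset(5000, structural_params(), default_conf(),
                        binary_error(p_E = 0.1, p_C = 0.5), seed = 20)
  expect_true(all(d$E_O %in% c(0L, 1L)))
  expect_true(all(d$C_O %in% c(0L, 1L)))
  expect_equal(mean(d$E_bin), 0.2, tolerance = 0.001) # empirical cut
  expect_equal(mean(d$E_O), 0.26, tolerance = 0.03)
})
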