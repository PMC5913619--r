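#' Derive a deterministic sub-stream seed
#'
#' Mixes a master seed with one or more integer stream identifiers into a
#' new seed, so that the latent draw, each error channel and the outcome
#' noise use independently seeded streams: toggling one channel never
#' perturbs the others, and cells of a scenario grid can be run in any
#' order with identical results. Uses a Lehmer-style multiplicative mix
#' modulo 2^31 - 1 (all arithmetic exact in doubles).
#'
#' @param seed Master seed (integer-valued).
#' @param ... Integer-valued stream identifiers (channel, cell index,
#'   replicate index, ...).
#' @return A single integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  ids <- c(seed, ...)
  if (any(!is.finite(ids)) || any(ids != round(ids))) {
    stop("seeds and stream ids must be integer-valued", call. = FALSE)
  }
  h <- 988463461
  for (v in ids) {
    h <- (h * 48271) %% m
    h <- (h + (v %% m) + 1) %% m
    h <- (h * 16807) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Draw the latent confounder, exposure and control
#'
#' Samples n independent triples (U, E_T, C_T) from a trivariate standard
#' normal with the correlation structure implied by the confounding
#' parameters: corr(U, E_T) = rho_UE, corr(U, C_T) = rho_UC and
#' corr(E_T, C_T) = rho_UE * rho_UC (correlated only through the
#' confounder). Deterministic given the seed; the global RNG state is left
#' untouched.
#'
#' @param n Sample size, at least 2.
#' @param conf A [confounding_structure()].
#' @param seed Integer seed.
#' @return An object of class `latent_sample`: list with numeric vectors
#'   `U`, `E_T`, `C_T` and the `n` and `seed` used.
#' @examples
#' ls <- draw_latents(1000, confounding_structure(0.4, 0.4), seed = 1)
#' cor(ls$E_T, ls$C_T)
#' @export
draw_latents <- function(n, conf, seed) {
  stopifnot(inherits(conf, "confounding_structure"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  X <- withr::with_seed(seed, MASS::mvrnorm(n, mu = rep(0, 3), Sigma = conf$R))
  structure(
    list(U = X[, 1], E_T = X[, 2], C_T = X[, 3], n = as.integer(n),
         seed = seed),
    class = "latent_sample"
  )
}

#' Add classical measurement error to a continuous variable
#'
#' Returns `x_true + v` with `v` i.i.d. mean-zero normal with variance
#' `sigma2_v`, drawn independently of `x_true` (classical, non-differential
#' error). With `sigma2_v = 0` the input is returned unchanged.
#'
#' @param x_true Numeric vector of true values.
#' @param sigma2_v Error variance, nonnegative.
#' @param seed Integer seed for the error draw.
#' @return Numeric vector of observed values, same length as `x_true`.
#' @export
add_continuous_error <- function(x_true, sigma2_v, seed) {
  if (!is.numeric(sigma2_v) || length(sigma2_v) != 1L || !is.finite(sigma2_v) ||
      sigma2_v < 0) {
    stop("`sigma2_v` must be a single nonnegative number", call. = FALSE)
  }
  if (sigma2_v == 0) return(x_true)
  x_true + withr::with_seed(seed, stats::rnorm(length(x_true), 0, sqrt(sigma2_v)))
}

#' Dichotomize at an upper empirical quantile
#'
#' Codes the observations strictly above the empirical `cut` quantile as 1
#' and the rest as 0, so the top `1 - cut` share of values (top 20% by
#' default) forms the exposed/positive class. Rank-based, hence invariant
#' to strictly monotone transformations of the input.
#'
#' @param x Nonempty numeric vector; must not be constant.
#' @param cut Quantile cut point, strictly inside (0, 1); default 0.8.
#' @return An integer 0/1 vector.
#' @examples
#' dichotomize_top_quantile(1:5) # 0 0 0 0 1
#' @export
dichotomize_top_quantile <- function(x, cut = 0.8) {
  if (length(x) == 0L) stop("`x` must be nonempty", call. = FALSE)
  if (!is.numeric(cut) || length(cut) != 1L || cut <= 0 || cut >= 1) {
    stop("`cut` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (max(x) == min(x)) {
    stop("cannot dichotomize a constant vector: the quantile cut is undefined",
         call. = FALSE)
  }
  as.integer(x > stats::quantile(x, cut, names = FALSE))
}

#' Symmetric, non-differential misclassification of a binary variable
#'
#' Flips each observation to the opposite class independently with
#' probability `p`, the same probability in the 1 and the 0 class
#' (symmetric misclassification, independent of the outcome). `p = 0`
#' returns the input unchanged; `p = 0.5` destroys all signal.
#'
#' @param x A 0/1 vector.
#' @param p Misclassification probability, in \[0, 1\].
#' @param seed Integer seed for the flips.
#' @return An integer 0/1 vector of the same length.
#' @export
misclassify <- function(x, p, seed) {
  if (!all(x %in% c(0, 1))) {
    stop("`x` must contain only 0 and 1", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  if (p == 0) return(as.integer(x))
  flip <- withr::with_seed(seed, stats::runif(length(x)) < p)
  as.integer(ifelse(flip, 1L - x, x))
}

#' Generate outcomes from the structural model
#'
#' Computes `y = beta1 * E_for_y + beta2 * C_for_y + gamma * U + eps` with
#' `eps ~ N(0, sigma_eps^2)` independent of everything else. The regressors
#' entering the outcome are always the *true* (error-free) values: in the
#' continuous design the latent `E_T`, `C_T`; in the binary design their
#' dichotomized versions before misclassification. Measurement error only
#' ever affects the regressors handed to estimation, never the outcome.
#'
#' @param ls A [draw_latents()] sample (supplies `U` and `n`).
#' @param sp A [structural_params()].
#' @param E_for_y,C_for_y Numeric vectors of length `n`: the exposure and
#'   control values that causally generate the outcome.
#' @param seed Integer seed for the noise draw.
#' @return Numeric outcome vector of length `n`.
#' @export
generate_outcome <- function(ls, sp, E_for_y, C_for_y, seed) {
  stopifnot(inherits(ls, "latent_sample"), inherits(sp, "structural_params"))
  if (length(E_for_y) != ls$n || length(C_for_y) != ls$n) {
    stop("`E_for_y` and `C_for_y` must have length n = ", ls$n, call. = FALSE)
  }
  eps <- withr::with_seed(seed, stats::rnorm(ls$n, 0, sp$sigma_eps))
  sp$beta1 * E_for_y + sp$beta2 * C_for_y + sp$gamma * ls$U + eps
}

#' Simulate one complete study dataset
#'
#' Runs the full generative pipeline for either design. Continuous design:
#' draw latents, generate the outcome from the true values, then add
#' classical measurement error to exposure and control. Binary design:
#' draw latents, dichotomize exposure and control at the upper quantile,
#' generate the outcome from the *true* binary values, then misclassify
#' each. Six independently seeded sub-streams (latents, two error channels,
#' outcome noise) are derived from `seed` via [derive_seed()], so the whole
#' dataset is bit-reproducible and toggling one error channel leaves the
#' others unchanged.
#'
#' @param n Sample size.
#' @param sp A [structural_params()].
#' @param conf A [confounding_structure()].
#' @param err A [continuous_error()] or [binary_error()] spec; chooses the
#'   design.
#' @param seed Integer master seed for this dataset.
#' @return An object of class `observed_data`: list with `E_O`, `C_O`, `y`,
#'   `design` (`"continuous"` or `"binary"`), the latent sample `latents`,
#'   and for the binary design the true dichotomized `E_bin`, `C_bin`.
#' @examples
#' sp <- structural_params(beta1 = 0.2, gamma = 0.2)
#' conf <- confounding_structure(0.4, 0.4)
#' d <- simulate_dataset(500, sp, conf, binary_error(p_E = 0.1), seed = 7)
#' table(d$E_O)
#' @export
simulate_dataset <- function(n, sp, conf, err, seed) {
  stopifnot(inherits(sp, "structural_params"),
            inherits(conf, "confounding_structure"))
  ls <- draw_latents(n, conf, derive_seed(seed, 1L))
  if (inherits(err, "continuous_error_spec")) {
    y <- generate_outcome(ls, sp, ls$E_T, ls$C_T, derive_seed(seed, 4L))
    out <- list(
      E_O = add_continuous_error(ls$E_T, err$sigma2_vE, derive_seed(seed, 2L)),
      C_O = add_continuous_error(ls$C_T, err$sigma2_vC, derive_seed(seed, 3L)),
      y = y, design = "continuous", latents = ls
    )
  } else if (inherits(err, "binary_error_spec")) {
    E_bin <- dichotomize_top_quantile(ls$E_T, err$quantile_cut)
    C_bin <- dichotomize_top_quantile(ls$C_T, err$quantile_cut)
    y <- generate_outcome(ls, sp, E_bin, C_bin, derive_seed(seed, 4L))
    out <- list(
      E_O = misclassify(E_bin, err$p_E, derive_seed(seed, 5L)),
      C_O = misclassify(C_bin, err$p_C, derive_seed(seed, 6L)),
      y = y, design = "binary", latents = ls,
      E_bin = E_bin, C_bin = C_bin
    )
  } else {
    stop("`err` must be a continuous_error or binary_error spec", call. = FALSE)
  }
  structure(out, class = "observed_data")
}

#' @export
as.data.frame.observed_data <- function(x, ...) {
  data.frame(
    U = x$latents$U, E_T = x$latents$E_T, C_T = x$latents$C_T,
    E_O = x$E_O, C_O = x$C_O, y = x$y
  )
}
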