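#' Fit the misspecified observed-data regression
#'
#' Ordinary least squares of the outcome on an intercept, the observed
#' exposure and the observed negative control -- the regression an analyst
#' would run with the confounder unobserved and the regressors measured
#' with error. The intercept is always included: dichotomized regressors
#' are not mean-zero, and without it even the error-free, unconfounded
#' model would be misspecified.
#'
#' A rank-deficient design (for example a binary regressor that is all one
#' class after misclassification) is flagged as degenerate rather than
#' raising, so the simulation engine can discard and count such replicates.
#'
#' @param data An `observed_data` object from [simulate_dataset()], or any
#'   list with numeric `E_O`, `C_O`, `y` of equal length.
#' @return An object of class `fit_result`: `b1_hat`, `b2_hat`,
#'   `intercept`, `n`, and logical `degenerate`.
#' @examples
#' d <- simulate_dataset(200, structural_params(beta1 = 0.2),
#'                       confounding_structure(0.4, 0.4),
#'                       continuous_error(), seed = 3)
#' fit_observed_regression(d)
#' @export
fit_observed_regression <- function(data) {
  E_O <- data$E_O; C_O <- data$C_O; y <- data$y
  n <- length(y)
  if (length(E_O) != n || length(C_O) != n) {
    stop("E_O, C_O and y must have equal length", call. = FALSE)
  }
  if (n <= 3) stop("need n > 3 observations", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, E_O = E_O, C_O = C_O)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < 3L) {
    return(structure(
      list(b1_hat = NA_real_, b2_hat = NA_real_, intercept = NA_real_,
           n = n, degenerate = TRUE),
      class = "fit_result"
    ))
  }
  b <- fit$coefficients
  structure(
    list(b1_hat = unname(b["E_O"]), b2_hat = unname(b["C_O"]),
         intercept = unname(b["(Intercept)"]), n = n, degenerate = FALSE),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate fit (rank-deficient design), n =", x$n, "\n")
  } else {
    cat(sprintf("OLS fit (n = %d): intercept = %.4f, b1_hat = %.4f, b2_hat = %.4f\n",
                x$n, x$intercept, x$b1_hat, x$b2_hat))
  }
  invisible(x)
}

#' Coefficient errors of a fit relative to the truth
#'
#' Per-replicate estimation errors: `b1_hat - beta1`, `b2_hat - beta2`, and
#' the error of the calibrated estimator, `(b1_hat - b2_hat) - (beta1 -
#' beta2)`. Averaged over replicates these converge to the bias of each
#' estimator. The third component is identically the first minus the
#' second.
#'
#' @param fit A [fit_observed_regression()] result (non-degenerate).
#' @param sp A [structural_params()].
#' @return Named numeric vector `c(err_b1, err_b2, err_diff)`.
#' @export
coefficient_errors <- function(fit, sp) {
  stopifnot(inherits(fit, "fit_result"), inherits(sp, "structural_params"))
  if (fit$degenerate) {
    stop("cannot compute coefficient errors for a degenerate fit",
         call. = FALSE)
  }
  e1 <- fit$b1_hat - sp$beta1
  e2 <- fit$b2_hat - sp$beta2
  c(err_b1 = e1, err_b2 = e2, err_diff = e1 - e2)
}
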