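#' Construct a bias result
#'
#' Container for the bias of the OLS coefficients on exposure and negative
#' control, and of their difference. `bias_diff` is always `bias_b1 -
#' bias_b2` by construction. Monte Carlo results carry standard errors;
#' analytic results do not.
#'
#' @param bias_b1,bias_b2 Bias of the exposure / control coefficient.
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param mc_se_b1,mc_se_b2,mc_se_diff Monte Carlo standard errors
#'   (required iff `method = "monte_carlo"`).
#' @param reps_used Number of non-degenerate replicates (Monte Carlo only).
#' @return An object of class `bias_result`.
#' @keywords internal
#' @export
bias_result <- function(bias_b1, bias_b2, method = c("analytic", "monte_carlo"),
                        mc_se_b1 = NULL, mc_se_b2 = NULL, mc_se_diff = NULL,
                        reps_used = NULL) {
  method <- match.arg(method)
  has_se <- !is.null(mc_se_b1) && !is.null(mc_se_b2) && !is.null(mc_se_diff)
  if (method == "monte_carlo" && !has_se) {
    stop("Monte Carlo bias results require mc_se fields", call. = FALSE)
  }
  if (method == "analytic" && has_se) {
    stop("analytic bias results carry no Monte Carlo standard errors",
         call. = FALSE)
  }
  bias_b1 <- unname(bias_b1)
  bias_b2 <- unname(bias_b2)
  out <- list(
    bias_b1 = bias_b1, bias_b2 = bias_b2, bias_diff = bias_b1 - bias_b2,
    method = method
  )
  if (method == "monte_carlo") {
    out$mc_se_b1 <- mc_se_b1
    out$mc_se_b2 <- mc_se_b2
    out$mc_se_diff <- mc_se_diff
    out$reps_used <- reps_used
  }
  structure(out, class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("Bias (%s): b1 = %.5f, b2 = %.5f, b1 - b2 = %.5f\n",
              x$method, x$bias_b1, x$bias_b2, x$bias_diff))
  if (x$method == "monte_carlo") {
    cat(sprintf("  MC SE:          %.5f       %.5f            %.5f  (%d replicates)\n",
                x$mc_se_b1, x$mc_se_b2, x$mc_se_diff, x$reps_used))
  }
  invisible(x)
}

#' @export
as.data.frame.bias_result <- function(x, ...) {
  d <- data.frame(
    bias_b1 = x$bias_b1, bias_b2 = x$bias_b2, bias_diff = x$bias_diff,
    method = x$method, stringsAsFactors = FALSE
  )
  if (x$method == "monte_carlo") {
    d$mc_se_b1 <- x$mc_se_b1
    d$mc_se_b2 <- x$mc_se_b2
    d$mc_se_diff <- x$mc_se_diff
    d$reps_used <- x$reps_used
  }
  d
}

#' Asymptotic bias of OLS on mismeasured exposure and negative control
#'
#' Closed-form asymptotic bias of the OLS estimator of (beta1, beta2) when
#' the outcome is regressed on the observed (error-laden) exposure and
#' negative control while the confounder is omitted:
#' \deqn{E(\hat\beta - \beta) =
#'   (Q_{XX} + \Sigma_v)^{-1} Q_{XU}\gamma -
#'   (Q_{XX} + \Sigma_v)^{-1} \Sigma_v \beta}
#' The first term is omitted-variable bias transmitted through the
#' confounder; the second is regression-dilution bias from the measurement
#' error. The linear system is solved directly rather than through an
#' explicit inverse, for stability when `Q_XX + Sigma_v` is near singular.
#'
#' @param M A [moment_matrices()] object.
#' @param sp A [structural_params()] object.
#' @return A [bias_result()] with `method = "analytic"`.
#' @examples
#' M <- moment_matrices(confounding_structure(0.4, 0.4))
#' analytic_ols_bias(M, structural_params(gamma = 0.5))
#' @export
analytic_ols_bias <- function(M, sp) {
  stopifnot(inherits(M, "moment_matrices"), inherits(sp, "structural_params"))
  A <- M$Q_XX + M$Sigma_v
  rhs <- M$Q_XU * sp$gamma - M$Sigma_v %*% c(sp$beta1, sp$beta2)
  b <- tryCatch(
    drop(solve(A, rhs)),
    error = function(e) {
      stop("Q_XX + Sigma_v is singular (rho_EC = ", M$Q_XX[1, 2],
           "): ", conditionMessage(e), call. = FALSE)
    }
  )
  bias_result(bias_b1 = b[1], bias_b2 = b[2], method = "analytic")
}

#' Expected OLS slope under classical univariate attenuation
#'
#' Closed-form limit used as an independent check on the matrix bias
#' formula: with no confounding (`gamma = 0`), no exposure-control
#' correlation and error only in the exposure, the expected OLS slope is the
#' true slope shrunk by the reliability ratio,
#' `beta1 * sigma2_true / (sigma2_true + sigma2_v)` -- classical regression
#' dilution. [analytic_ols_bias()] must reduce to this exactly in the
#' degenerate case.
#'
#' @param beta1 True exposure effect.
#' @param sigma2_v Measurement-error variance of the exposure, nonnegative.
#' @param sigma2_true True exposure variance (default 1).
#' @return The expected (attenuated) slope.
#' @examples
#' univariate_attenuation(0.2, 1) # 0.1
#' @export
univariate_attenuation <- function(beta1, sigma2_v, sigma2_true = 1) {
  if (sigma2_v < 0) stop("`sigma2_v` must be nonnegative", call. = FALSE)
  beta1 * sigma2_true / (sigma2_true + sigma2_v)
}

#' Bias curves over a grid of confounder strengths and error configurations
#'
#' Evaluates the analytic bias for every combination of measurement-error
#' configuration and confounder effect gamma, producing the numeric table
#' behind bias-versus-gamma curves (one curve per error configuration).
#'
#' @param sp_base A [structural_params()]; its `gamma` is replaced by each
#'   grid value in turn.
#' @param conf A [confounding_structure()].
#' @param err_grid A list of [continuous_error()] specs (a single spec is
#'   accepted and wrapped).
#' @param gamma_grid Numeric vector of confounder effects; default 51 evenly
#'   spaced points on \[0, 0.5\].
#' @return A data frame with one row per (error configuration, gamma) pair
#'   and columns `gamma`, `icc_E`, `icc_C`, `beta1`, `beta2`, `bias_b1`,
#'   `bias_b2`, `bias_diff`, `method`, ordered by configuration then gamma.
#' @examples
#' bias_curve(structural_params(beta1 = 0.2),
#'            confounding_structure(0.4, 0.4),
#'            list(continuous_error(), continuous_error(icc_E = 0.7)),
#'            gamma_grid = c(0, 0.25, 0.5))
#' @export
bias_curve <- function(sp_base, conf, err_grid,
                       gamma_grid = seq(0, 0.5, length.out = 51)) {
  stopifnot(inherits(sp_base, "structural_params"),
            inherits(conf, "confounding_structure"))
  if (inherits(err_grid, "continuous_error_spec")) err_grid <- list(err_grid)
  if (length(err_grid) == 0L || length(gamma_grid) == 0L) {
    stop("`err_grid` and `gamma_grid` must be nonempty", call. = FALSE)
  }
  rows <- lapply(err_grid, function(err) {
    stopifnot(inherits(err, "continuous_error_spec"))
    M <- moment_matrices(conf, err)
    per_gamma <- lapply(gamma_grid, function(g) {
      sp <- structural_params(sp_base$beta1, sp_base$beta2, g, sp_base$sigma_eps)
      b <- analytic_ols_bias(M, sp)
      data.frame(
        gamma = g, icc_E = err$icc_E, icc_C = err$icc_C,
        beta1 = sp$beta1, beta2 = sp$beta2,
        bias_b1 = b$bias_b1, bias_b2 = b$bias_b2, bias_diff = b$bias_diff,
        method = "analytic", stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_gamma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot bias curves
#'
#' Draws bias versus confounder effect, one panel per bias component, one
#' curve per measurement-error configuration. Requires ggplot2.
#'
#' @param curve A data frame from [bias_curve()].
#' @param component Which bias to plot: the exposure coefficient, the
#'   control coefficient, or their difference.
#' @return A ggplot object.
#' @export
plot_bias_curve <- function(curve,
                            component = c("bias_diff", "bias_b1", "bias_b2")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  component <- match.arg(component)
  curve$config <- sprintf("ICC_E = %g, ICC_C = %g", curve$icc_E, curve$icc_C)
  ggplot2::ggplot(
    curve,
    ggplot2::aes(x = .data$gamma, y = .data[[component]],
                 colour = .data$config)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = expression(gamma ~ "(confounder effect on outcome)"),
      y = switch(component,
                 bias_b1 = "bias of exposure coefficient",
                 bias_b2 = "bias of control coefficient",
                 bias_diff = "bias of calibrated estimate (b1 - b2)"),
      colour = "measurement error"
    ) +
    ggplot2::theme_minimal()
}
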