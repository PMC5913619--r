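#' Structural model parameters
#'
#' Bundles the true causal coefficients of the structural outcome model
#' \deqn{y_i = \beta_1 E_{T,i} + \beta_2 C_{T,i} + \gamma U_i + \epsilon_i}
#' where `E_T` is the true exposure, `C_T` the true negative control and
#' `U` an unmeasured confounder. For a genuine negative control `beta2 = 0`.
#'
#' @param beta1 Causal effect of the exposure on the outcome.
#' @param beta2 Causal effect of the negative control on the outcome
#'   (0 for a valid negative control).
#' @param gamma Effect of the unmeasured confounder on the outcome;
#'   must be nonnegative.
#' @param sigma_eps Standard deviation of the outcome noise term; must be
#'   positive. The asymptotic bias does not depend on it; it only scales
#'   Monte Carlo noise.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(beta1 = 0.2, beta2 = 0, gamma = 0.2)
#' @export
structural_params <- function(beta1 = 0, beta2 = 0, gamma = 0, sigma_eps = 1) {
  for (nm in c("beta1", "beta2", "gamma", "sigma_eps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (gamma < 0) stop("`gamma` must be nonnegative", call. = FALSE)
  if (sigma_eps <= 0) stop("`sigma_eps` must be positive", call. = FALSE)
  structure(
    list(beta1 = beta1, beta2 = beta2, gamma = gamma, sigma_eps = sigma_eps),
    class = "structural_params"
  )
}

#' Confounding structure of exposure, control and confounder
#'
#' The true exposure and the true negative control are assumed to be
#' correlated only through the unmeasured confounder, so their correlation
#' is the product `rho_UE * rho_UC`. All three latent variables have unit
#' variance. Construction validates that the implied 3x3 correlation matrix
#' of (U, E_T, C_T) is positive definite.
#'
#' @param rho_UE Correlation between confounder and true exposure,
#'   strictly inside (-1, 1).
#' @param rho_UC Correlation between confounder and true negative control,
#'   strictly inside (-1, 1).
#' @return An object of class `confounding_structure` with fields `rho_UE`,
#'   `rho_UC`, the derived `rho_EC` and the latent correlation matrix `R`.
#' @examples
#' confounding_structure(0.4, 0.4)$rho_EC # 0.16
#' @export
confounding_structure <- function(rho_UE, rho_UC) {
  rho_EC <- derive_rho_ec(rho_UE, rho_UC)
  R <- matrix(
    c(1, rho_UE, rho_UC,
      rho_UE, 1, rho_EC,
      rho_UC, rho_EC, 1),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("U", "E_T", "C_T"), c("U", "E_T", "C_T"))
  )
  structure(
    list(rho_UE = rho_UE, rho_UC = rho_UC, rho_EC = rho_EC, R = R),
    class = "confounding_structure"
  )
}

#' Correlation between exposure and control induced by the confounder
#'
#' Under the assumption that the true exposure and the true negative control
#' are correlated only through the shared unmeasured confounder,
#' `rho_EC = rho_UE * rho_UC`. The implied (U, E_T, C_T) correlation matrix
#' is checked for positive definiteness.
#'
#' @inheritParams confounding_structure
#' @return The induced correlation, a single number.
#' @examples
#' derive_rho_ec(0.4, 0.4) # 0.16
#' @export
derive_rho_ec <- function(rho_UE, rho_UC) {
  for (nm in c("rho_UE", "rho_UC")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (abs(v) >= 1) stop("`", nm, "` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  rho_EC <- rho_UE * rho_UC
  R <- matrix(
    c(1, rho_UE, rho_UC,
      rho_UE, 1, rho_EC,
      rho_UC, rho_EC, 1),
    nrow = 3, byrow = TRUE
  )
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop("implied (U, E, C) correlation matrix is not positive definite",
         call. = FALSE)
  }
  rho_EC
}

#' Convert an intraclass correlation coefficient to an error variance
#'
#' The ICC is the proportion of observed variance due to true-score
#' variance, `ICC = sigma2_true / (sigma2_true + sigma2_v)`. Solving for the
#' measurement-error variance gives
#' `sigma2_v = sigma2_true * (1 - icc) / icc`. An ICC of 1 means error-free
#' measurement (`sigma2_v = 0`); an ICC of 0 would require infinite error
#' variance and is rejected.
#'
#' @param icc Intraclass correlation coefficient, in (0, 1].
#' @param sigma2_true Variance of the true variable (default 1, matching the
#'   unit-variance latent scale).
#' @return The measurement-error variance, a single nonnegative number.
#' @examples
#' icc_to_error_variance(0.5) # 1
#' icc_to_error_variance(0.8, sigma2_true = 2) # 0.5
#' @export
icc_to_error_variance <- function(icc, sigma2_true = 1) {
  if (!is.numeric(icc) || length(icc) != 1L || !is.finite(icc)) {
    stop("`icc` must be a single finite number", call. = FALSE)
  }
  if (icc <= 0 || icc > 1) {
    stop("`icc` must lie in (0, 1]; icc = 0 implies infinite error variance",
         call. = FALSE)
  }
  if (!is.numeric(sigma2_true) || length(sigma2_true) != 1L ||
      !is.finite(sigma2_true) || sigma2_true <= 0) {
    stop("`sigma2_true` must be a single positive number", call. = FALSE)
  }
  sigma2_true * (1 - icc) / icc
}

#' Convert an error variance back to an ICC
#'
#' Inverse of [icc_to_error_variance()].
#'
#' @param sigma2_v Measurement-error variance, nonnegative.
#' @inheritParams icc_to_error_variance
#' @return The intraclass correlation coefficient.
#' @export
error_variance_to_icc <- function(sigma2_v, sigma2_true = 1) {
  if (!is.numeric(sigma2_v) || length(sigma2_v) != 1L || !is.finite(sigma2_v) ||
      sigma2_v < 0) {
    stop("`sigma2_v` must be a single nonnegative number", call. = FALSE)
  }
  sigma2_true / (sigma2_true + sigma2_v)
}

#' Continuous measurement-error specification
#'
#' Describes additive, mean-zero, normal measurement error on the observed
#' exposure and control in terms of intraclass correlation coefficients.
#' Error variances are derived for the unit true-score variance scale.
#'
#' @param icc_E ICC of the observed exposure, in (0, 1].
#' @param icc_C ICC of the observed negative control, in (0, 1].
#' @param sigma2_true True-score variance used in the ICC conversion
#'   (default 1).
#' @return An object of class `continuous_error_spec` with the ICCs and the
#'   derived error variances `sigma2_vE`, `sigma2_vC`.
#' @examples
#' continuous_error(icc_E = 0.5, icc_C = 1)
#' @export
continuous_error <- function(icc_E = 1, icc_C = 1, sigma2_true = 1) {
  structure(
    list(
      icc_E = icc_E, icc_C = icc_C,
      sigma2_vE = icc_to_error_variance(icc_E, sigma2_true),
      sigma2_vC = icc_to_error_variance(icc_C, sigma2_true)
    ),
    class = "continuous_error_spec"
  )
}

#' Binary misclassification specification
#'
#' Describes the binary design: the true exposure and control are
#' dichotomized at an upper quantile of their latent values (top 20% coded 1
#' by default) and then a proportion of observations is misclassified --
#' flipped to the opposite class, with the same flip probability in both
#' classes (non-differential, symmetric misclassification).
#'
#' @param p_E Proportion of exposure observations misclassified, in \[0, 1\].
#' @param p_C Proportion of control observations misclassified, in \[0, 1\].
#' @param quantile_cut Latent quantile above which observations are coded 1;
#'   strictly inside (0, 1), default 0.8 (top 20%).
#' @return An object of class `binary_error_spec`.
#' @examples
#' binary_error(p_E = 0.1, p_C = 0.5)
#' @export
binary_error <- function(p_E = 0, p_C = 0, quantile_cut = 0.8) {
  for (nm in c("p_E", "p_C")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(quantile_cut) || length(quantile_cut) != 1L ||
      !is.finite(quantile_cut) || quantile_cut <= 0 || quantile_cut >= 1) {
    stop("`quantile_cut` must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(p_E = p_E, p_C = p_C, quantile_cut = quantile_cut),
    class = "binary_error_spec"
  )
}

#' Moment matrices of the asymptotic OLS setup
#'
#' Builds the limiting second-moment matrices that determine the asymptotic
#' behaviour of OLS on the mismeasured regressors:
#' `Q_XX` = plim X_T'X_T / n (unit diagonal, off-diagonal `rho_EC`),
#' `Q_XU` = plim X_T'U / n = (rho_UE, rho_UC)', and the diagonal
#' measurement-error covariance `Sigma_v = diag(sigma2_vE, sigma2_vC)`.
#'
#' @param conf A [confounding_structure()].
#' @param err A [continuous_error()] spec (defaults to error-free).
#' @return An object of class `moment_matrices` with fields `Q_XX` (2x2),
#'   `Q_XU` (length-2 vector) and `Sigma_v` (2x2 diagonal).
#' @examples
#' moment_matrices(confounding_structure(0.4, 0.4),
#'                 continuous_error(icc_E = 0.5))
#' @export
moment_matrices <- function(conf, err = continuous_error()) {
  stopifnot(inherits(conf, "confounding_structure"),
            inherits(err, "continuous_error_spec"))
  nms <- c("E", "C")
  Q_XX <- matrix(c(1, conf$rho_EC, conf$rho_EC, 1), 2, 2,
                 dimnames = list(nms, nms))
  Q_XU <- c(E = conf$rho_UE, C = conf$rho_UC)
  Sigma_v <- diag(c(err$sigma2_vE, err$sigma2_vC))
  dimnames(Sigma_v) <- list(nms, nms)
  structure(
    list(Q_XX = Q_XX, Q_XU = Q_XU, Sigma_v = Sigma_v),
    class = "moment_matrices"
  )
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural parameters: beta1 =", x$beta1, ", beta2 =", x$beta2,
      ", gamma =", x$gamma, ", sigma_eps =", x$sigma_eps, "\n")
  invisible(x)
}

#' @export
print.confounding_structure <- function(x, ...) {
  cat("Confounding structure: rho_UE =", x$rho_UE, ", rho_UC =", x$rho_UC,
      ", rho_EC =", x$rho_EC, "(derived)\n")
  invisible(x)
}
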