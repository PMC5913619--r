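#' Label a misclassification proportion
#'
#' Standard labels for the error levels of the binary simulation grid:
#' 0 is "None (0%)", 0.1 "Low (10%)", 0.5 "High (50%)"; any other
#' proportion is formatted as a percentage.
#'
#' @param p Misclassification proportion in \[0, 1\].
#' @return A character label.
#' @export
misclassification_label <- function(p) {
  vapply(p, function(pi) {
    if (pi == 0) "None (0%)"
    else if (pi == 0.1) "Low (10%)"
    else if (pi == 0.5) "High (50%)"
    else sprintf("%g%%", 100 * pi)
  }, character(1))
}

#' Define one simulation scenario cell
#'
#' A cell fixes everything needed to simulate one configuration: the
#' design, structural parameters, confounding structure, measurement-error
#' spec, per-replicate sample size, replicate count and master seed.
#'
#' @param sp A [structural_params()].
#' @param conf A [confounding_structure()].
#' @param err A [continuous_error()] or [binary_error()] spec (chooses the
#'   design).
#' @param n Per-replicate sample size, at least 10.
#' @param reps Number of replicates, at least 1.
#' @param seed Integer master seed for this cell.
#' @param label_E,label_C Optional labels for the exposure / control error
#'   level; derived from the error spec when omitted.
#' @return An object of class `scenario_cell`.
#' @export
scenario_cell <- function(sp, conf, err, n, reps, seed,
                          label_E = NULL, label_C = NULL) {
  stopifnot(inherits(sp, "structural_params"),
            inherits(conf, "confounding_structure"))
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  if (inherits(err, "binary_error_spec")) {
    design <- "binary"
    if (is.null(label_E)) label_E <- misclassification_label(err$p_E)
    if (is.null(label_C)) label_C <- misclassification_label(err$p_C)
  } else if (inherits(err, "continuous_error_spec")) {
    design <- "continuous"
    if (is.null(label_E)) label_E <- sprintf("ICC = %g", err$icc_E)
    if (is.null(label_C)) label_C <- sprintf("ICC = %g", err$icc_C)
  } else {
    stop("`err` must be a continuous_error or binary_error spec", call. = FALSE)
  }
  structure(
    list(design = design, sp = sp, conf = conf, err = err,
         n = as.integer(n), reps = as.integer(reps), seed = seed,
         label_E = label_E, label_C = label_C),
    class = "scenario_cell"
  )
}

#' Run the Monte Carlo simulation for one scenario cell
#'
#' For each replicate r, simulates a fresh dataset with a seed derived from
#' the cell's master seed and r, fits the observed-data regression and
#' records the coefficient errors. The reported bias is the mean error over
#' non-degenerate replicates; the Monte Carlo standard error is the
#' standard deviation of the per-replicate errors divided by the square
#' root of the replicate count. Degenerate (rank-deficient) replicates are
#' discarded and counted.
#'
#' @param cell A [scenario_cell()].
#' @return A [bias_result()] with `method = "monte_carlo"`, standard errors
#'   and `reps_used`; the number of discarded replicates is attached as
#'   attribute `"degenerate"`.
#' @examples
#' cell <- scenario_cell(structural_params(gamma = 0.2),
#'                       confounding_structure(0.4, 0.4),
#'                       binary_error(p_E = 0.1), n = 500, reps = 20, seed = 1)
#' run_cell(cell)
#' @export
run_cell <- function(cell) {
  stopifnot(inherits(cell, "scenario_cell"))
  errs <- matrix(NA_real_, nrow = cell$reps, ncol = 3)
  for (r in seq_len(cell$reps)) {
    d <- simulate_dataset(cell$n, cell$sp, cell$conf, cell$err,
                          seed = derive_seed(cell$seed, r))
    fit <- fit_observed_regression(d)
    if (!fit$degenerate) errs[r, ] <- coefficient_errors(fit, cell$sp)
  }
  ok <- stats::complete.cases(errs)
  n_used <- sum(ok)
  if (n_used == 0L) {
    stop("all ", cell$reps, " replicates were degenerate", call. = FALSE)
  }
  e <- errs[ok, , drop = FALSE]
  m <- colMeans(e)
  se <- apply(e, 2, stats::sd) / sqrt(n_used)
  res <- bias_result(
    bias_b1 = m[1], bias_b2 = m[2], method = "monte_carlo",
    mc_se_b1 = se[1], mc_se_b2 = se[2],
    mc_se_diff = stats::sd(e[, 1] - e[, 2]) / sqrt(n_used),
    reps_used = n_used
  )
  attr(res, "degenerate") <- cell$reps - n_used
  res
}

#' Reproduce a full bias table over a grid of error levels
#'
#' Runs the Monte Carlo simulation for every pair of exposure and control
#' error levels and assembles the bias table: one row per cell, exposure
#' error as the outer (slowest-varying) factor and control error inner,
#' matching the standard presentation. For the binary design the levels are
#' misclassification proportions (the canonical grid is 0, 0.1, 0.5 with
#' confounder effect 0.2 and confounder correlations 0.4); for the
#' continuous design they are ICCs.
#'
#' Each cell receives a seed derived from the master seed and its cell
#' index, so individual cells rerun in isolation reproduce their table row
#' exactly.
#'
#' @param sp A [structural_params()].
#' @param conf A [confounding_structure()]; default correlations 0.4.
#' @param levels_E,levels_C Error levels for exposure and control:
#'   misclassification proportions (binary) or ICCs (continuous). Default
#'   the canonical 3-level misclassification grid.
#' @param design `"binary"` or `"continuous"`.
#' @param n Per-replicate sample size (default 10000).
#' @param reps Replicates per cell (default 10000; at these settings the
#'   Monte Carlo SE on each bias is around 0.0003 in the binary design).
#' @param seed Integer master seed.
#' @param quantile_cut Dichotomization quantile for the binary design.
#' @return A data frame of class `bias_table` with columns `label_E`,
#'   `label_C`, `err_E`, `err_C`, `bias_b1`, `bias_b2`, `bias_diff`,
#'   `mc_se_b1`, `mc_se_b2`, `mc_se_diff`, `reps_used`. The scenario cells
#'   are attached as attribute `"cells"`.
#' @examples
#' \donttest{
#' tab <- reproduce_table(structural_params(gamma = 0.2),
#'                        n = 1000, reps = 50, seed = 1)
#' }
#' @export
reproduce_table <- function(sp,
                            conf = confounding_structure(0.4, 0.4),
                            levels_E = c(0, 0.1, 0.5),
                            levels_C = c(0, 0.1, 0.5),
                            design = c("binary", "continuous"),
                            n = 10000, reps = 10000, seed = 1,
                            quantile_cut = 0.8) {
  design <- match.arg(design)
  grid <- expand.grid(err_C = levels_C, err_E = levels_E,
                      KEEP.OUT.ATTRS = FALSE)[, c("err_E", "err_C")]
  cells <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    err <- if (design == "binary") {
      binary_error(p_E = grid$err_E[i], p_C = grid$err_C[i],
                   quantile_cut = quantile_cut)
    } else {
      continuous_error(icc_E = grid$err_E[i], icc_C = grid$err_C[i])
    }
    cells[[i]] <- scenario_cell(sp, conf, err, n = n, reps = reps,
                                seed = derive_seed(seed, i))
    res <- run_cell(cells[[i]])
    rows[[i]] <- data.frame(
      label_E = cells[[i]]$label_E, label_C = cells[[i]]$label_C,
      err_E = grid$err_E[i], err_C = grid$err_C[i],
      bias_b1 = res$bias_b1, bias_b2 = res$bias_b2, bias_diff = res$bias_diff,
      mc_se_b1 = res$mc_se_b1, mc_se_b2 = res$mc_se_b2,
      mc_se_diff = res$mc_se_diff, reps_used = res$reps_used,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cells") <- cells
  attr(out, "sp") <- sp
  class(out) <- c("bias_table", class(out))
  out
}

#' @export
print.bias_table <- function(x, digits = 3, ...) {
  sp <- attr(x, "sp")
  if (!is.null(sp)) {
    cat(sprintf("Monte Carlo bias table (beta1 = %g, beta2 = %g, gamma = %g)\n",
                sp$beta1, sp$beta2, sp$gamma))
  }
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits)
  print.data.frame(d, row.names = FALSE, ...)
  invisible(x)
}

#' Validate the analytic bias formula against simulation
#'
#' For a continuous-design scenario, computes the closed-form asymptotic
#' bias and the Monte Carlo bias, and compares them componentwise via
#' z-scores (difference divided by Monte Carlo SE). The scenario passes
#' when all three absolute z-scores are below `z_max`.
#'
#' @param cell A continuous-design [scenario_cell()].
#' @param z_max Pass threshold on absolute z-scores (default 3).
#' @return A list of class `mc_validation`: `analytic` and `monte_carlo`
#'   [bias_result()]s, `z` (named length-3 vector), and logical `pass`.
#' @export
mc_validate_analytic <- function(cell, z_max = 3) {
  stopifnot(inherits(cell, "scenario_cell"))
  if (cell$design != "continuous") {
    stop("analytic validation applies to the continuous design", call. = FALSE)
  }
  ana <- analytic_ols_bias(moment_matrices(cell$conf, cell$err), cell$sp)
  mc <- run_cell(cell)
  z <- c(
    b1 = (mc$bias_b1 - ana$bias_b1) / mc$mc_se_b1,
    b2 = (mc$bias_b2 - ana$bias_b2) / mc$mc_se_b2,
    diff = (mc$bias_diff - ana$bias_diff) / mc$mc_se_diff
  )
  structure(
    list(analytic = ana, monte_carlo = mc, z = z,
         pass = all(is.finite(z)) && all(abs(z) < z_max)),
    class = "mc_validation"
  )
}

#' @export
print.mc_validation <- function(x, ...) {
  cat("Analytic vs Monte Carlo bias\n")
  print(x$analytic)
  print(x$monte_carlo)
  cat(sprintf("z-scores: b1 = %.2f, b2 = %.2f, diff = %.2f -> %s\n",
              x$z["b1"], x$z["b2"], x$z["diff"],
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Run the analytic-vs-simulation validation over a scenario grid
#'
#' Crosses confounder effects with ICC levels (applied to both exposure and
#' control) and validates the closed-form bias against Monte Carlo in every
#' scenario. The default grid spans gamma in \{0, 0.25, 0.5\} and ICC in
#' \{1, 0.7, 0.4\}.
#'
#' @param gammas Confounder effects to scan.
#' @param iccs ICC levels to scan (applied to both variables).
#' @param sp_base Structural parameters; `gamma` is replaced per scenario.
#' @param conf A [confounding_structure()].
#' @param n Per-replicate sample size.
#' @param reps Replicates per scenario.
#' @param seed Integer master seed.
#' @param z_max Pass threshold on absolute z-scores.
#' @return A data frame with one row per scenario: `gamma`, `icc`,
#'   analytic and Monte Carlo biases, Monte Carlo SEs, z-scores and `pass`.
#' @export
validate_analytic_grid <- function(gammas = c(0, 0.25, 0.5),
                                   iccs = c(1, 0.7, 0.4),
                                   sp_base = structural_params(beta1 = 0.2),
                                   conf = confounding_structure(0.4, 0.4),
                                   n = 10000, reps = 200, seed = 1,
                                   z_max = 3) {
  grid <- expand.grid(icc = iccs, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)[, c("gamma", "icc")]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- structural_params(sp_base$beta1, sp_base$beta2, grid$gamma[i],
                            sp_base$sigma_eps)
    cell <- scenario_cell(sp, conf,
                          continuous_error(icc_E = grid$icc[i],
                                           icc_C = grid$icc[i]),
                          n = n, reps = reps, seed = derive_seed(seed, i))
    v <- mc_validate_analytic(cell, z_max = z_max)
    rows[[i]] <- data.frame(
      gamma = grid$gamma[i], icc = grid$icc[i],
      analytic_b1 = v$analytic$bias_b1, analytic_b2 = v$analytic$bias_b2,
      mc_b1 = v$monte_carlo$bias_b1, mc_b2 = v$monte_carlo$bias_b2,
      mc_se_b1 = v$monte_carlo$mc_se_b1, mc_se_b2 = v$monte_carlo$mc_se_b2,
      z_b1 = v$z["b1"], z_b2 = v$z["b2"], z_diff = v$z["diff"],
      pass = v$pass, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
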