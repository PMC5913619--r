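# shared scenario objects for the test suite

default_conf <- function() confounding_structure(0.4, 0.4)

# independent 2x2 oracle for the bias formula: explicit adjugate inverse,
# never the solve() path used by analytic_ols_bias()
bias_by_hand <- function(rho_UE, rho_UC, s2_vE, s2_vC, gamma, beta) {
  rho_EC <- rho_UE * rho_UC
  A <- matrix(c(1 + s2_vE, rho_EC, rho_EC, 1 + s2_vC), 2, 2)
  inv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) /
    (A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  drop(inv %*% (c(rho_UE, rho_UC) * gamma) -
         inv %*% (diag(c(s2_vE, s2_vC)) %*% beta))
}

# brute-force OLS via the normal equations, independent of lm.fit's QR path
ols_by_normal_equations <- function(E_O, C_O, y) {
  X <- cbind(1, E_O, C_O)
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# absolute-tolerance elementwise comparison (expect_equal's tolerance is
# relative, which is the wrong scale for biases near zero)
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
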