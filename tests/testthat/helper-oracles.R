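# Independent oracles, deliberately sharing no code with the package:
# explicit matrix algebra for OLS and the HC sandwich covariance.

brute_ols_hc <- function(y, X, type = c("HC1", "HC0")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  e <- as.numeric(y - X %*% beta)
  meat <- t(X) %*% diag(e^2) %*% X
  V <- XtX_inv %*% meat %*% XtX_inv
  if (type == "HC1") V <- V * n / (n - k)
  list(beta = as.numeric(beta), vcov = V, residuals = e)
}

rel_err <- function(a, b) {
  denom <- max(abs(b), 1e-12)
  max(abs(a - b)) / denom
}

# Random regression design for the sandwich oracle checks.
random_design <- function(n, k, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))
  beta <- rnorm(k)
  # heteroskedastic errors so the sandwich differs from the classical vcov
  y <- as.numeric(X %*% beta) + rnorm(n, sd = 0.5 + abs(X[, min(2, k)]))
  list(y = y, X = X)
}
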