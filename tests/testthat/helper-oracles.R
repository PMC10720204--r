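# Independent oracles used across tests: these deliberately avoid the
# package's own code paths.

# ordinary least squares through the normal equations
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Cox partial log-likelihood (Breslow ties) for a single covariate,
# enumerable risk sets, optional case weights
partial_loglik <- function(beta, time, event, x, w = rep(1, length(time)),
                           start = rep(0, length(time))) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- start < time[i] & time[i] <= time
    ll <- ll + w[i] * (beta * x[i] -
                         log(sum(w[at_risk] * exp(beta * x[at_risk]))))
  }
  ll
}

# closed-form single-predictor elastic net on standardized x, centered y
one_var_enet_oracle <- function(x, y, alpha, lambda) {
  rho <- sum(x * y) / length(y)
  sign(rho) * max(abs(rho) - lambda * alpha, 0) / (1 + lambda * (1 - alpha))
}

# standardize columns to mean 0 and 1/n-variance 1 (as the solver expects)
std_cols <- function(x) {
  xc <- sweep(x, 2, colMeans(x), "-")
  sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
}

# small complete metabolite matrix with named columns
rand_met <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(NULL, sprintf("met_%03d", seq_len(p))))
}
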