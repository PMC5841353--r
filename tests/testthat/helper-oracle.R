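# Independent brute-force oracle for the balanced two-level normal
# -2 log-likelihood: stack each cluster's n*p observations and evaluate
# the multivariate-normal log-density under covariance
# I_n (x) Sigma_W + J_n (x) Sigma_B directly. Deliberately naive; used
# only to cross-check the sufficient-statistics likelihood.
brute_neg2loglik <- function(params, data, mu = params$mu) {
  SW <- implied_within(params)
  SB <- implied_between(params)
  n <- data$n
  p <- data$p
  Om <- diag(n) %x% SW + matrix(1, n, n) %x% SB
  cOm <- chol(Om)
  iOm <- chol2inv(cOm)
  ld <- 2 * sum(log(diag(cOm)))
  tot <- 0
  for (g in levels(data$cluster)) {
    yg <- t(data$scores[data$cluster == g, , drop = FALSE]) # p x n stack
    v <- as.vector(yg) - rep(mu, n)
    tot <- tot + n * p * log(2 * pi) + ld + drop(v %*% iOm %*% v)
  }
  tot
}

# Random admissible parameter set consistent with a spec: fixed entries
# honoured, positive variances.
rand_params_for <- function(spec) {
  p <- spec$n_items
  lam_w <- runif(p, 0.5, 1.5)
  lam_b <- runif(p, 0.5, 1.5)
  lam_w[spec$referent] <- lam_b[spec$referent] <- 1
  sh <- spec$equal_loadings
  if (length(sh)) lam_b[sh] <- lam_w[sh]
  theta_b <- runif(p, 0.05, 0.4)
  theta_b[spec$zero_between_resid] <- 0
  mlcfa_params(lam_w, lam_b, runif(1, 0.5, 2), runif(1, 0.1, 0.8),
               runif(p, 0.3, 1), theta_b, mu = rnorm(p))
}

# Small random balanced dataset.
rand_two_level <- function(G, n, p) {
  two_level_data(matrix(rnorm(G * n * p), G * n, p), rep(seq_len(G), each = n))
}
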