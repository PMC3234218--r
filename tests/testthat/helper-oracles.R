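# Independent oracles used across tests.

# Dense multivariate-normal log-density via determinant + solve (a code path
# independent of the package's Cholesky-based likelihoods).
dmvn_log <- function(r, S) {
  k <- length(r)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * (k * log(2 * pi) + ld + t(r) %*% solve(S) %*% r))
}

# Levene-Haldane exact HWE p by direct enumeration with choose():
# P(j hets) = multinomial(n; hom_r, j, hom_c) * 2^j / choose(2n, n_a).
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * naa + nAa
  if (na == 0 || na == 2 * n) return(1)
  rare <- min(na, 2 * n - na)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(j) {
    hr <- (rare - j) / 2
    hc <- n - j - hr
    choose(n, hr) * choose(n - hr, j) * 2^j / choose(2 * n, rare)
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# Exact lower-tail binomial probability by direct summation.
binom_tail_oracle <- function(k, n) sum(choose(n, 0:k)) / 2^n

# Model-implied covariance of one twin pair, built directly from the ACE
# matrices (matrix-construction oracle for the pair likelihood).
pair_cov_oracle <- function(f1, f2, A, C, E, kappa, sig2) {
  Z1 <- cbind(1, f1); Z2 <- cbind(1, f2)
  W <- A + C + E
  X <- kappa * A + C
  S <- rbind(cbind(Z1 %*% W %*% t(Z1), Z1 %*% X %*% t(Z2)),
             cbind(Z2 %*% X %*% t(Z1), Z2 %*% W %*% t(Z2)))
  S + diag(sig2, nrow(S))
}
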