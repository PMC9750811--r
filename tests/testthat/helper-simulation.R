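# Shared simulation helpers for model tests.

# Observation table from the generating model y = beta*x + u_q + e,
# u_q ~ N(0, sigma_q), e ~ N(0, sigma_e); round-robin quadrat assignment.
sim_hier_table <- function(n_quadrats, n_obs, beta = 0.3,
                           sigma_q = 1, sigma_e = 1, seed = 1) {
  set.seed(seed)
  q <- rep_len(seq_len(n_quadrats), n_obs)
  u <- rnorm(n_quadrats, 0, sigma_q)
  x <- rnorm(n_obs)
  data.frame(
    quadrat_id = sprintf("Q%02d", q),
    x = x,
    y = beta * x + u[q] + rnorm(n_obs, 0, sigma_e)
  )
}

# Brute-force moment oracle: plain sums, no shared code with band_moments.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  dev <- x - mu
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  s <- sqrt(sum(dev^2) / (n - 1))
  list(mean_dn = mu, sd = s, cv = s / mu,
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

quiet_fit <- function(...) suppressWarnings(fit_hierarchical(...))
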