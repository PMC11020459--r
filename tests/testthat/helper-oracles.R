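# Independent oracles and fixture builders shared across tests.
# These deliberately avoid the package's own code paths (and lm/dnorm where
# the package uses them) so agreement is a real cross-check.

# Gaussian log-density written out by hand
ldnorm_hand <- function(x, mean, var) {
  -0.5 * log(2 * pi * var) - (x - mean)^2 / (2 * var)
}

# OLS slope/intercept from the moment formulas, not lm()
ols_hand <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  list(b0 = b0, b1 = b1, sigma2 = sum(res^2) / (length(x) - 2))
}

# Closed-form posterior of beta in the matched linear-Gaussian model with
# sigma2_nu fixed: p ~ N(X beta, diag(psi + s2)), flat prior.
gls_posterior_hand <- function(X, p, psi, s2) {
  W <- diag(1 / (psi + s2))
  cov <- solve(t(X) %*% W %*% X)
  list(mean = drop(cov %*% t(X) %*% W %*% p), cov = cov)
}

# Batch-means Monte-Carlo SE of a chain mean
mcse_batch <- function(x, n_batch = 40) {
  n <- length(x) %/% n_batch * n_batch
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batch))
  sd(bm) / sqrt(n_batch)
}

# Small hand-built area table
tiny_table <- function(n, y, x = NULL, N = 10000L) {
  m <- length(n)
  tab <- data.frame(area_id = sprintf("a%02d", seq_len(m)),
                    n = as.integer(n), y = as.integer(y), N = N,
                    stringsAsFactors = FALSE)
  if (!is.null(x)) tab <- cbind(tab, x)
  tab$sampled <- tab$n > 0L
  class(tab) <- c("area_table", "data.frame")
  tab
}

# Fabricated direct-estimates object (for feeding fit_gvf directly)
fake_direct <- function(p_tilde, psi, n = 50L) {
  m <- length(p_tilde)
  out <- data.frame(area_id = sprintf("a%02d", seq_len(m)),
                    n = rep_len(n, m), p_raw = p_tilde, p_tilde = p_tilde,
                    psi = psi, cv = 100 * sqrt(psi) / p_tilde,
                    adjusted = FALSE, sampled = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("direct_estimates", "data.frame")
  out
}

# Fabricated fit object carrying given draws (for summary/DIC contracts)
fake_fit <- function(theta_draws, p_direct, psi, link = "identity",
                     beta_draws = NULL, sigma2_draws = NULL, X = NULL) {
  ids <- sprintf("a%02d", seq_len(ncol(theta_draws)))
  colnames(theta_draws) <- ids
  lk <- link_spec(link)
  structure(list(
    theta_draws = theta_draws,
    mu_draws = lk$transform(theta_draws),
    beta_draws = beta_draws,
    sigma2_draws = sigma2_draws,
    p_direct = stats::setNames(p_direct, ids),
    psi = stats::setNames(psi, ids),
    area_id = ids, link = lk, X = X,
    config = mcmc_config(n_iter = 10, burn_in = 0, seed = 1)
  ), class = "fh_fit")
}

# One emdhs-like fit at reduced budget, reused by several tests
fit_emdhs_fixture <- function(seed = 42, n_iter = 3000, burn_in = 500,
                              n_chains = 2, variance = "gvf") {
  sim <- simulate_areas(emdhs_config(seed = seed))
  direct <- compute_direct(sim$table)
  gvf <- fit_gvf(direct)
  psi <- select_variance(direct, gvf, mode = variance)
  fit <- run_mcmc(sim$table, link = "logit", psi = psi,
                  config = mcmc_config(n_iter = n_iter, burn_in = burn_in,
                                       n_chains = n_chains, seed = seed))
  list(sim = sim, direct = direct, gvf = gvf, psi = psi, fit = fit)
}
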