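test_that("link transforms invert exactly on the proportion scale", {
  th <- seq(0.001, 0.999, length.out = 101)
  for (lnk in c("identity", "log", "logit")) {
    ls <- link_spec(lnk)
    expect_equal(ls$inverse(ls$transform(th)), th, tolerance = 1e-12)
  }
  expect_error(link_spec("probit"))
})

test_that("log posterior matches hand-computed Gaussian densities", {
  data1 <- list(p = 0.3, psi = 0.01, X = matrix(1, 1, 1))
  # single area, identity link: two Gaussian log densities by hand
  v <- log_unnormalized_posterior(beta = 0.2, sigma2 = 0.04, theta = 0.25,
                                  data = data1, link = "identity",
                                  prior = prior_spec(upper = 1))
  expect_equal(v, ldnorm_hand(0.3, 0.25, 0.01) + ldnorm_hand(0.25, 0.2, 0.04),
               tolerance = 1e-12)
  expect_equal(v, 1.9178959390188006, tolerance = 1e-9)

  # outside the prior support
  expect_identical(log_unnormalized_posterior(0.2, 1.5, 0.25, data1,
                                              "identity", prior_spec(1)),
                   -Inf)
  expect_identical(log_unnormalized_posterior(0.2, -0.1, 0.25, data1,
                                              "identity", prior_spec(1)),
                   -Inf)
  # outside the link domain
  expect_identical(log_unnormalized_posterior(0.2, 0.04, -0.1, data1,
                                              "logit", prior_spec(1)),
                   -Inf)

  # duplicating every area adds exactly the duplicated likelihood
  set.seed(4)
  m <- 6
  data_m <- list(p = runif(m, 0.2, 0.4), psi = runif(m, 0.002, 0.01),
                 X = cbind(1, runif(m)))
  th <- runif(m, 0.2, 0.4)
  beta <- c(0.3, -0.1)
  one <- log_unnormalized_posterior(beta, 0.05, th, data_m, "logit")
  dup <- list(p = rep(data_m$p, 2), psi = rep(data_m$psi, 2),
              X = rbind(data_m$X, data_m$X))
  two <- log_unnormalized_posterior(beta, 0.05, rep(th, 2), dup, "logit")
  expect_equal(two, 2 * one, tolerance = 1e-10)

  expect_error(log_unnormalized_posterior(c(1, 2, 3), 0.05, th, data_m,
                                          "logit"), "ncol")
})

test_that("MCMC matches the closed-form GLS posterior when the model is linear", {
  cfg <- synthetic_config(m = 40, p = 2, beta_true = c(0.3, 0.1, -0.1),
                          sigma2_nu_true = 0.005, link = "identity",
                          n_min = 40, n_max = 160, seed = 11)
  sim <- simulate_areas(cfg)
  d <- compute_direct(sim$table)
  smp <- d$sampled
  psi <- setNames(d$psi[smp], d$area_id[smp])
  s2 <- 0.005
  fit <- run_mcmc(sim$table, link = "identity", psi = psi,
                  prior = prior_spec(sigma2_fixed = s2),
                  config = mcmc_config(n_iter = 10000, burn_in = 2000,
                                       n_chains = 2, seed = 3))
  X <- design_matrix(sim$table)[smp, ]
  o <- gls_posterior_hand(X, d$p_tilde[smp], unname(psi), s2)
  for (j in 1:3) {
    se <- mcse_batch(fit$beta_draws[, j])
    expect_lt(abs(mean(fit$beta_draws[, j]) - o$mean[j]), 3 * se)
    expect_lt(abs(sd(fit$beta_draws[, j]) - sqrt(o$cov[j, j])),
              0.1 * sqrt(o$cov[j, j]))
  }
  # chains mix
  for (j in 1:3)
    expect_lt(split_rhat(fit$beta_draws[, j], fit$chain_id), 1.05)
})

test_that("tiny sampling variances make the data dominate the area means", {
  set.seed(21)
  m <- 12
  p <- round(runif(m, 0.25, 0.45), 3)
  tab <- tiny_table(n = rep(1000L, m), y = as.integer(p * 1000),
                    x = data.frame(x1 = runif(m)))
  psi <- setNames(rep(1e-6, m), tab$area_id)
  fit <- suppressWarnings(run_mcmc(
    tab, link = "identity", psi = psi,
    config = mcmc_config(n_iter = 6000, burn_in = 2000, n_chains = 1,
                         seed = 5, proposal_sd = 0.01)))
  expect_true(all(abs(colMeans(fit$theta_draws) - fit$p_direct) < 1e-3))
})

test_that("matched-model posterior means shrink between data and synthetic part", {
  cfg <- synthetic_config(m = 60, p = 1, beta_true = c(0.35, 0.15),
                          sigma2_nu_true = 0.004, link = "identity",
                          n_min = 30, n_max = 90, seed = 19)
  sim <- simulate_areas(cfg)
  fit <- run_mcmc(sim$table, link = "identity",
                  config = mcmc_config(n_iter = 6000, burn_in = 1000,
                                       n_chains = 1, seed = 7))
  theta_hat <- colMeans(fit$theta_draws)
  synth <- drop(fit$X %*% colMeans(fit$beta_draws))
  lo <- pmin(fit$p_direct, synth) - 0.015
  hi <- pmax(fit$p_direct, synth) + 0.015
  expect_true(all(theta_hat > lo & theta_hat < hi))
})

test_that("posterior means are stable in the MCMC budget", {
  sim <- simulate_areas(emdhs_config(seed = 23))
  fit1 <- run_mcmc(sim$table, link = "logit",
                   config = mcmc_config(n_iter = 4000, burn_in = 1000,
                                        n_chains = 1, seed = 2))
  fit2 <- run_mcmc(sim$table, link = "logit",
                   config = mcmc_config(n_iter = 8000, burn_in = 1000,
                                        n_chains = 1, seed = 2))
  for (j in seq_len(ncol(fit1$beta_draws))) {
    se <- sqrt(mcse_batch(fit1$beta_draws[, j])^2 +
                 mcse_batch(fit2$beta_draws[, j])^2)
    expect_lt(abs(mean(fit1$beta_draws[, j]) - mean(fit2$beta_draws[, j])),
              3 * se)
  }
})

test_that("DIC reproduces hand-computed Gaussian deviances", {
  p <- c(0.3, 0.5); psi <- c(0.01, 0.02)
  draws <- rbind(c(0.25, 0.45), c(0.30, 0.50), c(0.35, 0.55))
  d <- compute_dic(fake_fit(draws, p, psi))
  # frozen from an independent evaluation of the Gaussian deviance
  expect_equal(d$dbar, -4.591439058597547, tolerance = 1e-10)
  expect_equal(d$dhat, -4.841439058597547, tolerance = 1e-10)
  expect_equal(d$pd, 0.25, tolerance = 1e-10)
  expect_equal(d$dic, -4.341439058597547, tolerance = 1e-10)
  expect_equal(d$dic, 2 * d$dbar - d$dhat, tolerance = 1e-12)

  # zero posterior spread: pd = 0, dic = dhat
  d0 <- compute_dic(fake_fit(rbind(c(0.3, 0.5))[rep(1, 4), ], p, psi))
  expect_equal(d0$pd, 0, tolerance = 1e-10)
  expect_equal(d0$dic, d0$dhat, tolerance = 1e-10)

  # duplicating every area doubles dbar and dhat
  d2 <- compute_dic(fake_fit(cbind(draws, draws), rep(p, 2), rep(psi, 2)))
  expect_equal(d2$dbar, 2 * d$dbar, tolerance = 1e-10)
  expect_equal(d2$dhat, 2 * d$dhat, tolerance = 1e-10)
})

test_that("link comparison is deterministic and flags the minimizer", {
  sim <- simulate_areas(emdhs_config(seed = 33))
  cfgm <- mcmc_config(n_iter = 1500, burn_in = 300, n_chains = 1, seed = 6)
  cmp1 <- compare_links(sim$table, config = cfgm, links = c("logit", "log"))
  cmp2 <- compare_links(sim$table, config = cfgm, links = c("logit", "log"))
  expect_identical(cmp1$table$dic, cmp2$table$dic)
  expect_identical(cmp1$table$dic, sort(cmp1$table$dic))
  expect_identical(sum(cmp1$table$best), 1L)

  one <- compare_links(sim$table, config = cfgm, links = "logit")
  expect_identical(one$best_link, "logit")
})

test_that("coefficient summaries follow the credible-interval contract", {
  pm <- fake_fit(rbind(c(0.3, 0.4))[rep(1, 8), ], c(0.3, 0.4), c(0.01, 0.01))
  pm$beta_draws <- matrix(2, 8, 2, dimnames = list(NULL, c("a", "b")))
  s <- summarize_coefficients(pm)
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$lower, c(2, 2))
  expect_true(all(s$significant))

  pm$beta_draws <- cbind(a = seq(-1, 1, length.out = 9),
                         b = rep(0, 9))
  s2 <- summarize_coefficients(pm)
  expect_false(any(s2$significant))
  expect_lt(s2$lower[1], 0)
  expect_gt(s2$upper[1], 0)

  set.seed(1)
  pm$beta_draws <- cbind(g = rnorm(10000, 2, 1))
  s3 <- summarize_coefficients(pm)
  expect_equal(s3$mean, 2, tolerance = 0.05)
  expect_equal(s3$lower, qnorm(0.025, 2, 1), tolerance = 0.08)
  expect_equal(s3$upper, qnorm(0.975, 2, 1), tolerance = 0.08)
})

test_that("run_mcmc validates its preconditions", {
  tab <- tiny_table(n = c(30, 40, 0), y = c(3, 4, 0),
                    x = data.frame(x1 = c(0.1, 0.2, 0.3),
                                   x2 = c(0.3, 0.1, 0.2)))
  # 2 sampled areas < p + 2 = 4
  expect_error(run_mcmc(tab, link = "logit"), "sampled areas")
})
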