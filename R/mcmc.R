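#' Prior specification for the hierarchical Fay-Herriot model
#'
#' The regression coefficients get an improper flat prior, and the
#' area-effect variance `sigma2_nu` a Uniform(0, `upper`) prior on the
#' variance scale.  The default upper bound of 1 reflects the usual scale
#' of link-scale variances for proportions; it is configurable because
#' logit-scale variances above 1 are plausible.  Setting `sigma2_fixed`
#' collapses the variance prior to a point mass, which turns the
#' identity-link model into an exactly linear-Gaussian model (useful for
#' validation against closed-form posteriors).
#'
#' @param upper Upper bound of the Uniform prior on `sigma2_nu` (> 0).
#' @param sigma2_fixed Optional fixed value for `sigma2_nu`; when set, the
#'   variance is not updated.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(upper = 1, sigma2_fixed = NULL) {
  if (!is.numeric(upper) || upper <= 0)
    stop_cfg("upper", "must be a positive variance bound")
  if (!is.null(sigma2_fixed) && (!is.numeric(sigma2_fixed) || sigma2_fixed <= 0))
    stop_cfg("sigma2_fixed", "must be a positive variance when given")
  structure(list(upper = upper, sigma2_fixed = sigma2_fixed),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_iter Total sampling iterations per chain (default 50000).
#' @param burn_in Discarded initial iterations (default 5000).
#' @param thin Keep every `thin`-th retained draw.
#' @param n_chains Number of chains (default 2), each with a seed derived
#'   deterministically from `seed`.
#' @param seed Integer RNG seed for the run.
#' @param proposal_sd Initial random-walk proposal scale for the per-area
#'   link-scale updates.
#' @param adapt Adapt proposal scales during burn-in toward an acceptance
#'   rate of about 0.44 (frozen afterwards so detailed balance holds over
#'   the retained draws).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 50000L, burn_in = 5000L, thin = 1L,
                        n_chains = 2L, seed = 1L,
                        proposal_sd = 0.5, adapt = TRUE) {
  if (burn_in < 0 || burn_in >= n_iter)
    stop_cfg("burn_in", "needs 0 <= burn_in < n_iter")
  if (thin < 1) stop_cfg("thin", "must be >= 1")
  if (n_chains < 1) stop_cfg("n_chains", "must be >= 1")
  structure(list(
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), n_chains = as.integer(n_chains),
    seed = as.integer(seed), proposal_sd = proposal_sd,
    adapt = isTRUE(adapt)
  ), class = "mcmc_config")
}

# log N(x; mean, var) without the 2*pi constant (cancels in MH ratios)
ldnorm_k <- function(x, mean, var) -0.5 * log(var) - 0.5 * (x - mean)^2 / var

#' Log unnormalized posterior of the Fay-Herriot hierarchy
#'
#' Evaluates, up to an additive constant, the joint log posterior of the
#' area means `theta` (proportion scale), coefficients `beta` and
#' area-effect variance `sigma2`: the Normal sampling model of the direct
#' estimates around `theta` with known variances `psi`, the Normal linking
#' model of `link(theta)` around `X beta` with variance `sigma2`, a flat
#' prior on `beta` and a Uniform(0, upper) prior on `sigma2`.  Returns
#' `-Inf` outside the prior support or the link's domain.
#'
#' @param beta Coefficient vector, length `ncol(data$X)`.
#' @param sigma2 Area-effect variance.
#' @param theta Vector of area means on the proportion scale.
#' @param data List with `p` (direct estimates), `psi` (sampling
#'   variances) and `X` (design matrix), all over sampled areas.
#' @param link A `link_spec` or link name.
#' @param prior A [prior_spec()].
#' @return A single finite number, or `-Inf`.
#' @export
log_unnormalized_posterior <- function(beta, sigma2, theta, data,
                                       link = "logit",
                                       prior = prior_spec()) {
  lk <- as_link_spec(link)
  X <- data$X
  if (length(beta) != ncol(X))
    stop("length(beta) must equal ncol(data$X)", call. = FALSE)
  upper <- if (is.null(prior$sigma2_fixed)) prior$upper else Inf
  if (sigma2 <= 0 || sigma2 > upper) return(-Inf)
  if (!all(lk$domain_ok(theta))) return(-Inf)
  mu <- lk$transform(theta)
  eta <- drop(X %*% beta)
  sum(stats::dnorm(data$p, theta, sqrt(data$psi), log = TRUE)) +
    sum(stats::dnorm(mu, eta, sqrt(sigma2), log = TRUE))
}

# One chain of the Metropolis-within-Gibbs sampler.  ph/psi/X over sampled
# areas only; returns kept draws.
run_chain <- function(ph, psi, X, lk, prior, config, chain_seed) {
  set.seed(chain_seed)
  ms <- length(ph); k <- ncol(X)
  XtX <- crossprod(X)
  R <- chol(XtX)
  A <- backsolve(R, backsolve(R, t(X), transpose = TRUE))  # (X'X)^-1 X'

  mu <- lk$transform(ph)
  beta <- drop(A %*% mu)
  sigma2 <- prior$sigma2_fixed %||% (prior$upper / 2)
  eta <- drop(X %*% beta)
  loglik_mu <- function(mu_v) {
    th <- lk$inverse(mu_v)
    ldnorm_k(ph, th, psi)
  }
  ll <- loglik_mu(mu)
  if (!all(is.finite(ll)) || !is.finite(sigma2))
    stop("non-finite posterior at initialization; re-initialize with ",
         "different starting values", call. = FALSE)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  beta_d <- matrix(NA_real_, n_keep, k)
  sig_d <- numeric(n_keep)
  mu_d <- matrix(NA_real_, n_keep, ms)
  s <- rep(config$proposal_sd, ms)
  acc_total <- numeric(ms); acc_batch <- numeric(ms)
  batch_len <- 50L; batch_no <- 0L
  kept <- 0L; post_burn <- 0L

  for (it in seq_len(config$n_iter)) {
    # (a) beta | mu, sigma2: exact Gaussian full conditional (flat prior)
    beta <- drop(A %*% mu) + sqrt(sigma2) * backsolve(R, stats::rnorm(k))
    eta <- drop(X %*% beta)

    # (b) mu_i: independent random-walk Metropolis on the link scale
    mu_star <- mu + s * stats::rnorm(ms)
    ll_star <- loglik_mu(mu_star)
    logr <- (ll_star + ldnorm_k(mu_star, eta, sigma2)) -
            (ll      + ldnorm_k(mu,      eta, sigma2))
    acc <- log(stats::runif(ms)) < logr
    acc[!is.finite(ll_star)] <- FALSE
    mu[acc] <- mu_star[acc]
    ll[acc] <- ll_star[acc]

    # (c) sigma2 | mu, beta: truncated inverse-gamma via inverse CDF
    if (is.null(prior$sigma2_fixed)) {
      ssq <- sum((mu - eta)^2)
      a <- ms / 2 - 1
      plo <- stats::pgamma(1 / prior$upper, shape = a, rate = ssq / 2)
      u <- stats::runif(1, plo, 1)
      w <- stats::qgamma(min(u, 1 - 1e-15), shape = a, rate = ssq / 2)
      sigma2 <- 1 / w
      sigma2 <- min(max(sigma2, 1e-12), prior$upper)
    }

    if (it <= config$burn_in) {
      if (config$adapt) {
        acc_batch <- acc_batch + acc
        if (it %% batch_len == 0L) {
          batch_no <- batch_no + 1L
          delta <- min(0.1, 1 / sqrt(batch_no))
          s <- s * exp(delta * (acc_batch / batch_len - 0.44))
          acc_batch[] <- 0
        }
      }
    } else {
      post_burn <- post_burn + 1L
      acc_total <- acc_total + acc
      if ((it - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        beta_d[kept, ] <- beta
        sig_d[kept] <- sigma2
        mu_d[kept, ] <- mu
      }
    }
  }
  list(beta = beta_d[seq_len(kept), , drop = FALSE],
       sigma2 = sig_d[seq_len(kept)],
       mu = mu_d[seq_len(kept), , drop = FALSE],
       accept = acc_total / post_burn)
}

#' Fit an area-level Fay-Herriot model by hierarchical-Bayes MCMC
#'
#' Metropolis-within-Gibbs sampler for the three-model family: Normal
#' sampling model for the direct proportion with known variance, Normal
#' linking model for `link(theta)` on the covariates with area-effect
#' variance `sigma2_nu`.  Updates: exact Gaussian full conditional for
#' `beta` (flat prior), per-area random-walk Metropolis on the link scale
#' for the area means (proposal scales adapted during burn-in only), and
#' the truncated-inverse-gamma full conditional for `sigma2_nu` under its
#' Uniform(0, upper) prior, drawn by inverse CDF.
#'
#' @param table An `area_table`; direct estimates are computed internally
#'   (continuity-corrected at boundary cells).
#' @param link Link name or `link_spec`.
#' @param psi Optional named vector of sampling variances per sampled area
#'   (e.g. from [select_variance()]); defaults to the raw design variances.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `fh_fit`: retained draws (`beta_draws`,
#'   `sigma2_draws`, `theta_draws`, `mu_draws`), `chain_id`,
#'   per-area `accept_rate`, and the data the fit conditions on
#'   (`area_id`, `p_direct`, `psi`, `X`, plus `link`, `prior`, `config`).
#' @export
run_mcmc <- function(table, link = "logit", psi = NULL,
                     prior = prior_spec(), config = mcmc_config()) {
  validate_area_table(table)
  lk <- as_link_spec(link)
  direct <- compute_direct(table)
  smp <- direct$sampled
  ids <- direct$area_id[smp]
  ph <- direct$p_tilde[smp]
  X <- design_matrix(table)[smp, , drop = FALSE]
  if (sum(smp) < ncol(X) + 1L)
    stop(sprintf("need at least p + 2 = %d sampled areas, have %d",
                 ncol(X) + 1L, sum(smp)), call. = FALSE)
  if (is.null(psi)) {
    psi <- direct$psi[smp]
    names(psi) <- ids
  } else {
    psi <- psi[ids]
    if (anyNA(psi) || any(psi <= 0))
      stop("psi must be strictly positive for every sampled area",
           call. = FALSE)
  }
  if (!all(lk$domain_ok(ph)))
    stop(sprintf("direct estimates outside the domain of the %s link",
                 lk$link), call. = FALSE)

  chains <- lapply(seq_len(config$n_chains), function(cc) {
    run_chain(ph, unname(psi), X, lk, prior, config,
              chain_seed = derive_seed(config$seed, cc))
  })
  beta_draws <- do.call(rbind, lapply(chains, `[[`, "beta"))
  mu_draws <- do.call(rbind, lapply(chains, `[[`, "mu"))
  sigma2_draws <- unlist(lapply(chains, `[[`, "sigma2"))
  chain_id <- rep(seq_len(config$n_chains),
                  vapply(chains, function(ch) length(ch$sigma2), 1L))
  accept_rate <- Reduce(`+`, lapply(chains, `[[`, "accept")) /
    config$n_chains
  if (any(accept_rate < 0.05))
    warning(sprintf("low Metropolis acceptance (< 0.05) for areas: %s",
                    paste(ids[accept_rate < 0.05], collapse = ", ")),
            call. = FALSE)
  colnames(beta_draws) <- colnames(X)
  colnames(mu_draws) <- ids

  structure(list(
    beta_draws = beta_draws,
    sigma2_draws = sigma2_draws,
    mu_draws = mu_draws,
    theta_draws = lk$inverse(mu_draws),
    accept_rate = stats::setNames(accept_rate, ids),
    chain_id = chain_id,
    link = lk, prior = prior, config = config,
    area_id = ids, p_direct = stats::setNames(ph, ids),
    psi = stats::setNames(unname(psi), ids), X = X,
    table = table
  ), class = "fh_fit")
}

#' @export
print.fh_fit <- function(x, ...) {
  cat(sprintf(
    "<fh_fit> %s link, %d sampled areas, %d retained draws (%d chains)\n",
    x$link$link, length(x$area_id), nrow(x$beta_draws),
    x$config$n_chains))
  cat(sprintf("  posterior mean sigma2_nu = %.4f, mean acceptance = %.2f\n",
              mean(x$sigma2_draws), mean(x$accept_rate)))
  invisible(x)
}

#' Deviance information criterion of a fitted model
#'
#' The deviance is that of the Normal sampling model only,
#' `D(theta) = -2 sum_i log N(p_i; theta_i, psi_i)`.  `dbar` averages `D`
#' over retained draws, `dhat` evaluates `D` at the per-area posterior
#' mean of `theta` on the proportion scale, `pd = dbar - dhat`, and
#' `dic = dbar + pd = 2 dbar - dhat`.
#'
#' @param fit An `fh_fit`.
#' @return An object of class `dic_result`: list with `dbar`, `dhat`,
#'   `pd`, `dic`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "fh_fit"))
  th <- fit$theta_draws
  if (nrow(th) == 0L) stop("empty posterior sample", call. = FALSE)
  dev_draws <- -2 * (
    rowSums(-0.5 * sweep(sweep(th, 2, fit$p_direct)^2, 2, fit$psi, `/`)) +
      sum(-0.5 * log(2 * pi * fit$psi)))
  dbar <- mean(dev_draws)
  theta_hat <- colMeans(th)
  dhat <- -2 * sum(stats::dnorm(fit$p_direct, theta_hat, sqrt(fit$psi),
                                log = TRUE))
  pd <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dbar + pd),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("<dic_result> DIC = %.4f (dbar = %.4f, pd = %.4f)\n",
              x$dic, x$dbar, x$pd))
  invisible(x)
}

#' Fit all three linking models and compare by DIC
#'
#' Fits the identity-, log- and logit-link Fay-Herriot models with
#' identical data, priors and MCMC budget and ranks them by DIC
#' (smaller preferred).  A link whose likelihood is undefined on the data
#' is reported as inestimable (`NA` DIC) rather than aborting the
#' comparison.
#'
#' @inheritParams run_mcmc
#' @param links Character vector of links to compare.
#' @return List with `table` (data frame `link`, `dic`, `dbar`, `pd`,
#'   `best`, sorted by DIC ascending, inestimable links last),
#'   `best_link`, and `fits` (named list of `fh_fit`s).
#' @export
compare_links <- function(table, psi = NULL, prior = prior_spec(),
                          config = mcmc_config(),
                          links = c("identity", "log", "logit")) {
  fits <- list(); rows <- list()
  for (lnk in links) {
    fit <- tryCatch(
      run_mcmc(table, link = lnk, psi = psi, prior = prior, config = config),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[lnk]] <- data.frame(link = lnk, dic = NA_real_,
                                dbar = NA_real_, pd = NA_real_,
                                note = conditionMessage(fit),
                                stringsAsFactors = FALSE)
    } else {
      fits[[lnk]] <- fit
      d <- compute_dic(fit)
      rows[[lnk]] <- data.frame(link = lnk, dic = d$dic, dbar = d$dbar,
                                pd = d$pd, note = "",
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(is.na(tab$dic), tab$dic), ]
  rownames(tab) <- NULL
  if (all(is.na(tab$dic)))
    stop("no link was estimable on these data", call. = FALSE)
  tab$best <- !is.na(tab$dic) & tab$dic == min(tab$dic, na.rm = TRUE)
  list(table = tab, best_link = tab$link[which(tab$best)[1]], fits = fits)
}

#' Posterior summaries of the regression coefficients
#'
#' Posterior mean, SD and equal-tailed 95% credible interval per
#' coefficient; a coefficient is flagged significant when its interval
#' excludes zero.
#'
#' @param fit An `fh_fit`.
#' @return Data frame with columns `coefficient`, `mean`, `sd`, `lower`,
#'   `upper`, `significant`.
#' @export
summarize_coefficients <- function(fit) {
  stopifnot(inherits(fit, "fh_fit"))
  b <- fit$beta_draws
  if (nrow(b) == 0L) stop("empty posterior sample", call. = FALSE)
  q <- apply(b, 2, stats::quantile, probs = c(0.025, 0.975))
  data.frame(
    coefficient = colnames(b),
    mean = colMeans(b),
    sd = apply(b, 2, stats::sd),
    lower = q[1, ], upper = q[2, ],
    significant = q[1, ] > 0 | q[2, ] < 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat with each chain split in half, the standard
#' convergence summary for MCMC output.
#'
#' @param x Numeric vector of draws.
#' @param chain Integer chain label per draw.
#' @return A single number; values near 1 indicate mixing.
#' @export
split_rhat <- function(x, chain = rep(1L, length(x))) {
  pieces <- list()
  for (cc in unique(chain)) {
    xc <- x[chain == cc]
    h <- length(xc) %/% 2
    pieces <- c(pieces, list(xc[seq_len(h)], xc[h + seq_len(h)]))
  }
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(p) p[seq_len(n)])
  m <- length(pieces)
  means <- vapply(pieces, mean, 1)
  vars <- vapply(pieces, stats::var, 1)
  b <- n * stats::var(means)
  w <- mean(vars)
  sqrt(((n - 1) / n * w + b / n) / w)
}
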