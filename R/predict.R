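#' Per-area estimates for sampled areas
#'
#' Summarizes the posterior draws of each sampled area's true proportion:
#' posterior mean, SD (the root-MSE surrogate under the hierarchical-Bayes
#' paradigm), equal-tailed 95% credible interval, and percent CV
#' `100 hb_sd / hb_mean`.
#'
#' @param fit An `fh_fit`.
#' @return An `area_estimates` data frame: `area_id`, `hb_mean`, `hb_sd`,
#'   `ci_low`, `ci_high`, `hb_cv`, `sampled`.
#' @export
summarize_sampled <- function(fit) {
  stopifnot(inherits(fit, "fh_fit"))
  th <- fit$theta_draws
  if (nrow(th) == 0L) stop("empty posterior sample", call. = FALSE)
  summarize_theta_draws(th, fit$area_id, sampled = TRUE)
}

summarize_theta_draws <- function(th, ids, sampled) {
  q <- apply(th, 2, stats::quantile, probs = c(0.025, 0.975))
  mu <- colMeans(th)
  sdv <- apply(th, 2, stats::sd)
  out <- data.frame(
    area_id = ids, hb_mean = mu, hb_sd = sdv,
    ci_low = q[1, ], ci_high = q[2, ],
    hb_cv = 100 * sdv / mu,
    sampled = sampled,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("area_estimates", "data.frame")
  out
}

#' Posterior-predictive estimates for non-sampled areas
#'
#' Areas with zero sample size have no direct estimate; their proportions
#' are predicted from the fitted linking model.  For each retained draw
#' `(beta, sigma2_nu)` a fresh area effect `nu* ~ N(0, sigma2_nu)` is
#' drawn and `theta* = inverse-link(x' beta + nu*)` recorded, so the
#' reported spread includes both parameter and area-effect uncertainty —
#' without the predictive `nu*` the CVs of non-sampled areas would be
#' understated.
#'
#' @param fit An `fh_fit`.
#' @param table The `area_table` containing the non-sampled areas'
#'   covariates (defaults to the table the model was fitted to).
#' @return An `area_estimates` data frame with one row per non-sampled
#'   area (zero rows if every area was sampled).
#' @export
predict_nonsampled <- function(fit, table = fit$table) {
  stopifnot(inherits(fit, "fh_fit"))
  validate_area_table(table)
  ns <- which(table$n == 0L)
  if (!length(ns)) {
    out <- summarize_theta_draws(
      matrix(numeric(0), nrow(fit$theta_draws), 0),
      character(0), sampled = logical(0))
    return(out[0, ])
  }
  X_ns <- design_matrix(table)[ns, , drop = FALSE]
  if (ncol(X_ns) != ncol(fit$beta_draws))
    stop("covariates of non-sampled areas do not conform to the fitted ",
         "design: ", paste(table$area_id[ns], collapse = ", "),
         call. = FALSE)
  ndraw <- nrow(fit$beta_draws)
  set.seed(derive_seed(fit$config$seed, 104L))
  eta <- fit$beta_draws %*% t(X_ns)                   # ndraw x n_ns
  nu_star <- matrix(stats::rnorm(ndraw * length(ns)), ndraw) *
    sqrt(fit$sigma2_draws)
  th_star <- fit$link$inverse(eta + nu_star)
  summarize_theta_draws(th_star, table$area_id[ns], sampled = FALSE)
}
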