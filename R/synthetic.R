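#' Configuration for synthetic area-level survey + census data
#'
#' Defines the generative model used to emulate zone-level inputs of an
#' area-level small area analysis: `m` areas each with a census-style
#' covariate vector, a Gaussian area random effect on the link scale, a
#' true proportion obtained by inverse-linking the linear predictor, and a
#' Binomial survey count at the realized area sample size.  A fixed
#' fraction of areas is forced to zero sample size (non-sampled areas),
#' mirroring surveys whose design does not reach every domain.
#'
#' @param m Number of areas (>= 2).
#' @param p Number of auxiliary covariates, excluding the intercept (>= 0).
#' @param beta_true Coefficient vector of length `p + 1`, intercept first,
#'   on the link scale.
#' @param sigma2_nu_true Variance of the Gaussian area random effect on the
#'   link scale (>= 0).
#' @param link Linking transform: `"logit"` (default), `"log"` or
#'   `"identity"`.
#' @param n_min,n_max Bounds of the integer-uniform distribution of area
#'   sample sizes for sampled areas.
#' @param frac_nonsampled Fraction of areas, in `[0, 1)`, forced to
#'   `n_i = 0`; exactly `round(frac_nonsampled * m)` areas are non-sampled.
#' @param pop_size Constant area population size `N_i` (must exceed
#'   `n_max`).
#' @param center_covariates Center non-intercept covariate columns after
#'   generation (keeps the intercept interpretable).
#' @param seed Integer RNG seed; everything downstream is reproducible
#'   given the seed.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [emdhs_config()] for the default survey-like scenario,
#'   [simulate_areas()] to draw data.
#' @export
synthetic_config <- function(m, p, beta_true, sigma2_nu_true,
                             link = "logit",
                             n_min = 15L, n_max = 120L,
                             frac_nonsampled = 0,
                             pop_size = 20000L,
                             center_covariates = TRUE,
                             seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m))
    stop_cfg("m", "must be a single integer >= 2")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p != round(p))
    stop_cfg("p", "must be a single integer >= 0")
  if (length(beta_true) != p + 1L)
    stop_cfg("beta_true", sprintf("must have length p + 1 = %d", p + 1L))
  if (!is.numeric(sigma2_nu_true) || sigma2_nu_true < 0)
    stop_cfg("sigma2_nu_true", "must be a nonnegative variance")
  if (frac_nonsampled < 0 || frac_nonsampled >= 1)
    stop_cfg("frac_nonsampled", "must lie in [0, 1)")
  if (n_min < 1 || n_max < n_min)
    stop_cfg("n_min/n_max", "need 1 <= n_min <= n_max")
  if (pop_size <= n_max)
    stop_cfg("pop_size", "must exceed n_max")
  structure(list(
    m = as.integer(m), p = as.integer(p),
    beta_true = as.numeric(beta_true),
    sigma2_nu_true = as.numeric(sigma2_nu_true),
    link = as_link_spec(link)$link,
    n_min = as.integer(n_min), n_max = as.integer(n_max),
    frac_nonsampled = frac_nonsampled,
    pop_size = as.integer(pop_size),
    center_covariates = isTRUE(center_covariates),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Survey-like default scenario
#'
#' The default generative scenario matches the scale of a national
#' mini-DHS analysed at zone level: 83 zones of which 6 are non-sampled,
#' zone sample sizes integer-uniform on 15..120, 8 census auxiliary
#' covariates, a logit linking model with area-effect variance 0.3243, and
#' coefficients placed so the mean true proportion is close to the 28%
#' national coverage of community-based health insurance.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
emdhs_config <- function(seed = 1L, ...) {
  defaults <- list(
    m = 83L, p = 8L,
    beta_true = c(-1.0, 1.0, -0.8, 0.6, 0.5, -0.5, 0.4, -0.3, 0.2),
    sigma2_nu_true = 0.3243,
    link = "logit",
    n_min = 15L, n_max = 120L,
    frac_nonsampled = 6 / 83,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

#' Generate the covariate design matrix
#'
#' Draws the `m x (p + 1)` design matrix for a synthetic scenario: an
#' intercept column of ones followed by `p` covariates drawn independently
#' uniform on `[0, 1]` (proportions, as census shares are), then centered
#' column-wise when the configuration asks for it.
#'
#' @param config A [synthetic_config()].
#' @return Numeric matrix `m x (p + 1)`, intercept column first, with
#'   column names `(Intercept), x1..xp`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 1L))
  m <- config$m; p <- config$p
  X <- matrix(1, nrow = m, ncol = p + 1L)
  if (p > 0) {
    raw <- matrix(stats::runif(m * p), nrow = m, ncol = p)
    if (config$center_covariates)
      raw <- sweep(raw, 2L, colMeans(raw))
    X[, -1L] <- raw
  }
  colnames(X) <- c("(Intercept)", if (p > 0) paste0("x", seq_len(p)))
  X
}

#' Simulate an area-level survey table and its generating truth
#'
#' Draws, per area: a random effect `nu_i ~ N(0, sigma2_nu_true)`, the true
#' proportion `P_i = inverse-link(x_i' beta + nu_i)`, a sample size `n_i`
#' (integer-uniform, or 0 for the designated non-sampled areas), and the
#' survey count `y_i ~ Binomial(n_i, P_i)`.  Non-sampled areas keep their
#' covariates and population size but carry `n_i = y_i = 0`.
#'
#' For the log and identity links a drawn linear predictor can inverse-link
#' to a value outside `(0, 1)`; the generator then fails listing the
#' offending areas rather than truncating, since silent truncation would
#' corrupt parameter-recovery checks.
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (an `area_table` data frame: `area_id`, `n`,
#'   `y`, `N`, `x1..xp`, `sampled`) and `truth` (data frame: `area_id`,
#'   `p_true`, `nu_true`, `mu_true`).
#' @export
simulate_areas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  X <- generate_covariates(config)
  lk <- link_spec(config$link)
  m <- config$m

  set.seed(derive_seed(config$seed, 2L))
  nu <- stats::rnorm(m, 0, sqrt(config$sigma2_nu_true))
  mu <- drop(X %*% config$beta_true) + nu
  p_true <- lk$inverse(mu)
  bad <- which(!(p_true > 0 & p_true < 1))
  if (length(bad))
    stop(sprintf(
      "simulated true proportions outside (0,1) under the %s link for areas: %s",
      config$link, paste(bad, collapse = ", ")), call. = FALSE)

  n_i <- if (config$n_min == config$n_max) rep(config$n_min, m)
         else sample(seq.int(config$n_min, config$n_max), m, replace = TRUE)
  k_ns <- round(config$frac_nonsampled * m)
  if (k_ns > 0) n_i[sample.int(m, k_ns)] <- 0L
  y_i <- integer(m)
  smp <- n_i > 0L
  y_i[smp] <- stats::rbinom(sum(smp), n_i[smp], p_true[smp])

  tab <- data.frame(
    area_id = sprintf("zone_%02d", seq_len(m)),
    n = as.integer(n_i), y = y_i, N = config$pop_size,
    stringsAsFactors = FALSE
  )
  if (config$p > 0) {
    xs <- as.data.frame(X[, -1L, drop = FALSE])
    names(xs) <- paste0("x", seq_len(config$p))
    tab <- cbind(tab, xs)
  }
  tab$sampled <- smp
  class(tab) <- c("area_table", "data.frame")

  truth <- data.frame(
    area_id = tab$area_id, p_true = p_true, nu_true = nu, mu_true = mu,
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = truth)
}
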