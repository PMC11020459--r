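#' Bias-diagnostic regression
#'
#' Regresses the direct estimates (y-axis) on the model-based estimates
#' (x-axis) by OLS.  Since direct estimates are design-unbiased, a
#' fitted line close to the identity (slope 1, intercept 0) is evidence
#' that the model-based estimates are not systematically biased.
#'
#' @param direct A `direct_estimates` object.
#' @param hb An `area_estimates` data frame (sampled areas).
#' @return List with `slope`, `intercept`, and `points` (data frame
#'   `hb_mean`, `direct`, `fitted`).
#' @export
bias_diagnostic <- function(direct, hb) {
  stopifnot(inherits(direct, "direct_estimates"))
  d <- merge(hb[hb$sampled, c("area_id", "hb_mean")],
             direct[direct$sampled, c("area_id", "p_tilde")],
             by = "area_id")
  if (nrow(d) < 3)
    stop("bias diagnostic needs at least 3 sampled areas", call. = FALSE)
  if (stats::sd(d$hb_mean) == 0)
    stop("zero variance in model-based estimates", call. = FALSE)
  fit <- stats::lm(p_tilde ~ hb_mean, data = d)
  co <- unname(stats::coef(fit))
  list(slope = co[2], intercept = co[1],
       points = data.frame(hb_mean = d$hb_mean, direct = d$p_tilde,
                           fitted = unname(stats::fitted(fit))))
}

#' Normality check of the linking-model residuals
#'
#' Computes per-area residuals `r_i = link(theta_hat_i) - x_i' beta_hat`
#' at the posterior means, applies the Shapiro-Wilk test, and emits
#' normal Q-Q plot coordinates.  The linking model assumes Gaussian area
#' effects, so heavy non-normality here questions the model.
#'
#' @param fit An `fh_fit`.
#' @return List with `shapiro_w`, `shapiro_p`, `residuals` (named), and
#'   `qq` (data frame `theoretical`, `sample`).
#' @export
residual_normality <- function(fit) {
  stopifnot(inherits(fit, "fh_fit"))
  if (length(fit$area_id) < 3)
    stop("normality check needs at least 3 sampled areas", call. = FALSE)
  theta_hat <- colMeans(fit$theta_draws)
  beta_hat <- colMeans(fit$beta_draws)
  r <- fit$link$transform(theta_hat) - drop(fit$X %*% beta_hat)
  if (stats::sd(r) == 0)
    stop("residuals are constant; normality test undefined", call. = FALSE)
  sw <- stats::shapiro.test(r)
  qq <- stats::qqnorm(r, plot.it = FALSE)
  list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       residuals = stats::setNames(r, fit$area_id),
       qq = data.frame(theoretical = qq$x, sample = qq$y))
}

efficiency_gain <- function(direct_cv, hb_cv) 100 * (direct_cv - hb_cv) / direct_cv

#' CV comparison and efficiency-gain table
#'
#' Summarizes the percent CVs of the direct and model-based estimates
#' over sampled areas with the six standard location statistics (Minimum,
#' 1st quartile, Median, Mean, 3rd quartile, Maximum; quartiles by linear
#' interpolation between order statistics) and, row-wise on the summary
#' cells, the efficiency gain `100 (direct - HB) / direct`.  Setting
#' `per_area = TRUE` instead summarizes the per-area gains.
#'
#' @param direct A `direct_estimates` object.
#' @param hb An `area_estimates` data frame over sampled areas.
#' @param per_area Compute the gain per area before summarizing, rather
#'   than on the summary cells (default `FALSE`, the convention the
#'   row-wise summary tables of this literature follow).
#' @return Data frame with columns `quantity`, `direct_cv`, `hb_cv`,
#'   `efficiency_gain`, six rows.
#' @export
cv_comparison_table <- function(direct, hb, per_area = FALSE) {
  stopifnot(inherits(direct, "direct_estimates"))
  d <- merge(hb[hb$sampled, c("area_id", "hb_cv")],
             direct[direct$sampled, c("area_id", "cv")],
             by = "area_id")
  if (!nrow(d)) stop("no sampled areas with both CVs", call. = FALSE)
  six <- function(x) c(min(x), stats::quantile(x, 0.25, names = FALSE),
                       stats::median(x), mean(x),
                       stats::quantile(x, 0.75, names = FALSE), max(x))
  out <- data.frame(
    quantity = c("Minimum", "1st quartile", "Median", "Mean",
                 "3rd quartile", "Maximum"),
    direct_cv = six(d$cv), hb_cv = six(d$hb_cv),
    stringsAsFactors = FALSE
  )
  out$efficiency_gain <- if (per_area)
    six(efficiency_gain(d$cv, d$hb_cv))
  else
    efficiency_gain(out$direct_cv, out$hb_cv)
  out
}

#' Area-keyed estimates table for mapping
#'
#' One row per area — sampled and non-sampled — with the model-based
#' point estimate and credible bounds, suitable for joining onto an
#' external administrative-boundaries file by `area_id`.
#'
#' @param estimates An `area_estimates` data frame covering all areas.
#' @param path Optional CSV output path.
#' @return Data frame `area_id`, `hb_mean`, `ci_low`, `ci_high`,
#'   `sampled`; written to `path` when given.
#' @export
export_map_table <- function(estimates, path = NULL) {
  if (!nrow(estimates)) stop("no estimates to export", call. = FALSE)
  if (any(is.na(estimates$area_id) | estimates$area_id == ""))
    stop("empty area_id in estimates", call. = FALSE)
  if (anyDuplicated(estimates$area_id))
    stop("duplicate area ids: ",
         paste(unique(estimates$area_id[duplicated(estimates$area_id)]),
               collapse = ", "), call. = FALSE)
  out <- estimates[, c("area_id", "hb_mean", "ci_low", "ci_high", "sampled")]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
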