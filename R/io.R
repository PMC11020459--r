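#' Validate an area-level table
#'
#' Checks the schema contract of an area table: unique area ids, integer
#' `n >= 0`, `0 <= y <= n`, `N > 0`, `n <= N`, and a `sampled` flag equal
#' to `n > 0`.  Violations are reported with the offending row numbers.
#'
#' @param table A data frame.
#' @return The table, invisibly, with class `area_table`.
#' @export
validate_area_table <- function(table) {
  req <- c("area_id", "n", "y", "N")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("area table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(table$area_id))
    stop("duplicate area_id values: ",
         paste(unique(table$area_id[duplicated(table$area_id)]),
               collapse = ", "), call. = FALSE)
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(sprintf("area table rows %s: %s",
                   paste(idx, collapse = ", "), what), call. = FALSE)
  }
  bad_row(table$n < 0 | table$n != round(table$n), "n must be integer >= 0")
  bad_row(table$y < 0 | table$y > table$n, "need 0 <= y <= n")
  bad_row(table$N <= 0, "N must be positive")
  bad_row(table$n > table$N, "need n <= N")
  if (!"sampled" %in% names(table)) table$sampled <- table$n > 0L
  bad_row(xor(table$sampled, table$n > 0L), "sampled flag must equal n > 0")
  if (!inherits(table, "area_table"))
    class(table) <- c("area_table", class(table))
  invisible(table)
}

#' Read an area-level table from CSV
#'
#' Expects columns `area_id, n, y, N, x1..xp` (plus optional `sampled` and
#' truth columns `p_true, nu_true` for synthetic data) and validates the
#' schema; the `sampled` flag is derived from `n > 0`.
#'
#' @param path Path to a CSV file with a header row.
#' @return An `area_table` data frame.
#' @export
read_area_table <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$area_id <- as.character(tab$area_id)
  tab$sampled <- tab$n > 0L
  tab <- validate_area_table(tab)
  class(tab) <- c("area_table", "data.frame")
  tab
}

#' Write an area-level table to CSV
#'
#' @param table An `area_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(table, path) {
  validate_area_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Run the full small-area pipeline
#'
#' Composes the stages in analysis order: direct estimation, GVF variance
#' smoothing, hierarchical-Bayes Fay-Herriot fitting (one link or all
#' three with DIC comparison), per-area estimates for sampled and
#' non-sampled areas, and the diagnostic battery.  All tabular artifacts
#' are written as CSV and scalar reports as JSON under `out_dir`; the run
#' is fully determined by the inputs and `seed`.
#'
#' @param table An `area_table`, or a path to one (CSV).
#' @param link `"logit"`, `"log"`, `"identity"`, or `"all"` (fit all three
#'   and also write a DIC comparison, estimates taken from the DIC-best
#'   link).
#' @param variance `"gvf"` (default) or `"raw"` sampling variances.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()]; its seed is overridden by `seed`.
#' @param seed Integer top-level seed; stage seeds derive from it.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return A list with `direct`, `gvf`, `fits` (named by link), `dic`
#'   (comparison table), `best_link`, `estimates` (sampled + non-sampled),
#'   `diagnostics`, and `log` (per-stage notes).
#' @export
run_pipeline <- function(table, link = "logit",
                         variance = c("gvf", "raw"),
                         prior = prior_spec(),
                         config = mcmc_config(),
                         seed = config$seed,
                         out_dir = NULL) {
  variance <- match.arg(variance)
  if (is.character(table) && length(table) == 1L)
    table <- read_area_table(table)
  validate_area_table(table)
  config$seed <- as.integer(seed)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  note("direct estimation: %d areas, %d sampled", nrow(table),
       sum(table$n > 0))
  direct <- compute_direct(table)
  gvf <- fit_gvf(direct)
  note("GVF: log(psi) = %.3f %+.3f log(p), sigma2_hat = %.3f",
       gvf$beta0, gvf$beta1, gvf$sigma2_hat)
  psi <- select_variance(direct, gvf, mode = variance)

  links <- if (identical(link, "all")) c("identity", "log", "logit") else link
  fits <- list(); dic_tab <- NULL
  if (length(links) > 1L) {
    cmp <- compare_links(table, psi = psi, prior = prior, config = config)
    fits <- cmp$fits
    dic_tab <- cmp$table
    best <- cmp$best_link
    note("DIC comparison: best link = %s", best)
  } else {
    fits[[links]] <- run_mcmc(table, link = links, psi = psi,
                              prior = prior, config = config)
    best <- links
  }
  fit <- fits[[best]]
  note("MCMC (%s link): mean acceptance %.2f", best,
       mean(fit$accept_rate))

  est_s <- summarize_sampled(fit)
  est_ns <- predict_nonsampled(fit, table)
  estimates <- rbind(est_s, est_ns)
  estimates <- estimates[order(match(estimates$area_id, table$area_id)), ]
  rownames(estimates) <- NULL

  diag <- list(
    bias = bias_diagnostic(direct, est_s),
    normality = residual_normality(fit),
    cv_table = cv_comparison_table(direct, est_s),
    coefficients = summarize_coefficients(fit)
  )
  note("bias slope %.3f, Shapiro W = %.3f (p = %.3f)",
       diag$bias$slope, diag$normality$shapiro_w, diag$normality$shapiro_p)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    w(as.data.frame(direct), "direct_estimates.csv")
    w(gvf$smoothed, "gvf_smoothed_variances.csv")
    w(estimates, "estimates.csv")
    w(diag$coefficients, "coefficient_summary.csv")
    w(diag$cv_table, "cv_comparison.csv")
    if (!is.null(dic_tab)) w(dic_tab, "dic_comparison.csv")
    jsonlite::write_json(
      list(seed = seed, link = best, variance = variance,
           gvf = list(beta0 = gvf$beta0, beta1 = gvf$beta1,
                      sigma2_hat = gvf$sigma2_hat),
           bias = diag$bias[c("slope", "intercept")],
           shapiro = diag$normality[c("shapiro_w", "shapiro_p")]),
      file.path(out_dir, "diagnostics.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  list(direct = direct, gvf = gvf, fits = fits, dic = dic_tab,
       best_link = best, estimates = estimates, diagnostics = diag,
       log = log_lines)
}
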