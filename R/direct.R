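#' Extract the design matrix from an area table
#'
#' Collects the covariate columns `x1..xp` of an area table into a numeric
#' design matrix with a leading intercept column of ones.
#'
#' @param table An `area_table` data frame.
#' @return Numeric matrix with `nrow(table)` rows and `p + 1` columns.
#' @export
design_matrix <- function(table) {
  xcols <- grep("^x[0-9]+$", names(table), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  X <- cbind(1, as.matrix(table[, xcols, drop = FALSE]))
  colnames(X) <- c("(Intercept)", xcols)
  rownames(X) <- table$area_id
  X
}

#' Design-based direct estimates per area
#'
#' Computes, for every sampled area, the direct survey proportion
#' `p_i = y_i / n_i`, its design variance `psi_i = p_i (1 - p_i) / n_i`,
#' and the percent coefficient of variation `100 sqrt(psi_i) / p_i`.
#' Boundary cells (`y_i = 0` or `y_i = n_i`) would give a zero variance and
#' an infinite log-transform downstream, so they are replaced by the
#' continuity-corrected proportion `(y_i + 0.5) / (n_i + 1)` before the
#' variance and CV are formed, and flagged.  Non-sampled areas (`n_i = 0`)
#' carry `NA` estimates.
#'
#' @param table An `area_table` (see [read_area_table()] or
#'   [simulate_areas()]).
#' @param correction Continuity-correction rule for boundary cells; a
#'   function of `(y, n)` returning the corrected proportion.  The default
#'   is `(y + 0.5) / (n + 1)`.
#' @return An object of class `direct_estimates`: a data frame with
#'   columns `area_id`, `n`, `p_raw`, `p_tilde`, `psi`, `cv`, `adjusted`,
#'   `sampled`.
#' @export
compute_direct <- function(table,
                           correction = function(y, n) (y + 0.5) / (n + 1)) {
  validate_area_table(table)
  if (!any(table$n > 0))
    stop("no sampled areas: every row has n = 0", call. = FALSE)

  n <- table$n; y <- table$y
  smp <- n > 0L
  p_raw <- ifelse(smp, y / n, NA_real_)
  boundary <- smp & (y == 0L | y == n)
  p_tilde <- p_raw
  p_tilde[boundary] <- correction(y[boundary], n[boundary])
  psi <- ifelse(smp, p_tilde * (1 - p_tilde) / n, NA_real_)
  cv <- ifelse(smp, 100 * sqrt(psi) / p_tilde, NA_real_)

  out <- data.frame(
    area_id = table$area_id, n = n,
    p_raw = p_raw, p_tilde = p_tilde, psi = psi, cv = cv,
    adjusted = boundary, sampled = smp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("direct_estimates", "data.frame")
  out
}

#' Fit the generalized variance function
#'
#' Regresses the log design variance on the log direct proportion by
#' ordinary least squares, `log(psi_i) = b0 + b1 log(p_i) + e_i`, and
#' back-transforms with the smearing factor `exp(sigma2_hat / 2)` to give a
#' smoothed variance per area:
#' `gvf_i = exp(sigma2_hat / 2) exp(b0 + b1 log(p_i))`.
#' `sigma2_hat` is the residual variance with the residual
#' degrees-of-freedom divisor `n - 2`.
#'
#' @param direct A `direct_estimates` object from [compute_direct()].
#' @return An object of class `gvf_fit`: list with `beta0`, `beta1`,
#'   `sigma2_hat`, `residuals`, and `smoothed` (data frame `area_id`,
#'   `psi`, `smoothed_var` over the fitted areas).
#' @export
fit_gvf <- function(direct) {
  stopifnot(inherits(direct, "direct_estimates"))
  use <- direct$sampled & direct$p_tilde > 0 & direct$p_tilde < 1 &
    direct$psi > 0
  use[is.na(use)] <- FALSE
  if (sum(use) < 3)
    stop("GVF fit needs at least 3 sampled areas with p in (0,1) and psi > 0",
         call. = FALSE)
  lx <- log(direct$p_tilde[use])
  ly <- log(direct$psi[use])
  if (stats::sd(lx) == 0)
    stop("GVF slope unidentifiable: no spread in log(p)", call. = FALSE)

  fit <- stats::lm(ly ~ lx)
  b <- unname(stats::coef(fit))
  res <- unname(stats::residuals(fit))
  s2 <- sum(res^2) / (length(res) - 2L)
  smoothed_var <- exp(s2 / 2) * exp(b[1] + b[2] * lx)

  structure(list(
    beta0 = b[1], beta1 = b[2], sigma2_hat = s2,
    residuals = res,
    smoothed = data.frame(
      area_id = direct$area_id[use],
      psi = direct$psi[use],
      smoothed_var = smoothed_var,
      stringsAsFactors = FALSE
    )
  ), class = "gvf_fit")
}

#' @export
print.gvf_fit <- function(x, ...) {
  cat(sprintf(
    "<gvf_fit> log(psi) = %.4f %+.4f log(p), sigma2_hat = %.4f, %d areas\n",
    x$beta0, x$beta1, x$sigma2_hat, nrow(x$smoothed)))
  invisible(x)
}

#' Choose the sampling variances fed to the Fay-Herriot model
#'
#' Returns the per-sampled-area variance vector for the FH sampling model:
#' either the raw design variances `psi_i` or the GVF-smoothed ones.
#'
#' @param direct A `direct_estimates` object.
#' @param gvf A `gvf_fit`, required when `mode = "gvf"`.
#' @param mode `"gvf"` (default) or `"raw"`.
#' @return Named numeric vector (names = area ids) of strictly positive
#'   variances, one per sampled area in `direct`.
#' @export
select_variance <- function(direct, gvf = NULL, mode = c("gvf", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(direct, "direct_estimates"))
  ids <- direct$area_id[direct$sampled]
  if (mode == "raw") {
    v <- direct$psi[direct$sampled]
    names(v) <- ids
  } else {
    if (is.null(gvf))
      stop("mode = \"gvf\" requires a fitted gvf_fit", call. = FALSE)
    v <- gvf$smoothed$smoothed_var[match(ids, gvf$smoothed$area_id)]
    names(v) <- ids
    if (anyNA(v))
      stop("GVF fit lacks smoothed variances for some sampled areas",
           call. = FALSE)
  }
  if (any(v <= 0))
    stop("selected variance vector must be strictly positive", call. = FALSE)
  v
}
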