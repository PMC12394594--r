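#' REML estimate of the between-study variance tau^2
#'
#' Random-effects model `y_j ~ N(mu, v_j + tau^2)`.  The restricted
#' likelihood is maximized by the standard fixed-point iteration
#' `tau2 <- sum(w^2 ((y - mu)^2 - v)) / sum(w^2) + 1 / sum(w)` with
#' `w = 1/(v + tau2)` and `mu` the weighted mean, truncated at zero,
#' started from the DerSimonian-Laird estimate.
#'
#' @param estimates Study effect estimates `y_j`.
#' @param variances Within-study sampling variances `v_j > 0`.
#' @param tol Convergence tolerance on tau^2.
#' @param maxit Maximum iterations.
#' @return Scalar tau^2 (attribute `single_study = TRUE` when k = 1).
#' @export
reml_tau2 <- function(estimates, variances, tol = 1e-10, maxit = 1000L) {
  k <- length(estimates)
  stopifnot(length(variances) == k)
  if (any(variances <= 0)) stop("all sampling variances must be positive")
  if (k < 2L) {
    return(structure(0, single_study = TRUE))
  }
  tau2 <- max(0, dersimonian_laird(estimates, variances))
  for (it in seq_len(maxit)) {
    w <- 1 / (variances + tau2)
    mu <- sum(w * estimates) / sum(w)
    new <- sum(w^2 * ((estimates - mu)^2 - variances)) / sum(w^2) +
      1 / sum(w)
    new <- max(0, new)
    if (abs(new - tau2) < tol) return(new)
    tau2 <- new
  }
  stop("REML tau^2 iteration failed to converge after ", maxit, " steps")
}

#' DerSimonian-Laird moment estimator of tau^2
#'
#' Classical cross-check for the REML estimate.
#'
#' @inheritParams reml_tau2
#' @return Scalar tau^2 (truncated at 0).
#' @export
dersimonian_laird <- function(estimates, variances) {
  w <- 1 / variances
  mu <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - mu)^2)
  k <- length(estimates)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' I-squared heterogeneity percentage
#'
#' `I^2 = 100 tau2 / (tau2 + s2)` with the Higgins "typical" within-study
#' variance `s2 = (k-1) sum(w) / ((sum(w))^2 - sum(w^2))`, `w = 1/v`.
#'
#' @param tau2 Between-study variance.
#' @param variances Within-study variances.
#' @return Percentage in \[0, 100\]; `NA` when fewer than 2 studies.
#' @export
i_squared <- function(tau2, variances) {
  k <- length(variances)
  if (k < 2L) return(NA_real_)
  if (any(variances <= 0)) stop("variances must be positive")
  w <- 1 / variances
  s2 <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  100 * tau2 / (tau2 + s2)
}

#' Random-effects pooling of one analysis family
#'
#' Inverse-variance weights `w_j = 1/(v_j + tau2)`; pooled estimate,
#' standard error, Wald z / p and a 1.96-SE confidence interval.
#' Fisher-z effects are back-transformed (tanh) for reporting.
#'
#' @param effects Effect-size data.frame (columns `study_id`, `analysis`,
#'   `estimate`, `variance`, `n`, `scale`) sharing one analysis label and
#'   scale.
#' @param tau2 Optional fixed tau^2 (e.g. a DerSimonian-Laird value for
#'   cross-checks); default: REML estimate.
#' @return Object of class `meta_result`.
#' @export
pool_effects <- function(effects, tau2 = NULL) {
  k <- nrow(effects)
  if (is.null(k) || k < 1L) stop("no effects to pool")
  if (length(unique(effects$analysis)) != 1L) {
    stop("effects must share one analysis label")
  }
  if (length(unique(effects$scale)) != 1L) {
    stop("effects must share one scale; got mixed scales")
  }
  y <- effects$estimate
  v <- effects$variance
  if (is.null(tau2)) tau2 <- as.numeric(reml_tau2(y, v))
  w <- 1 / (v + tau2)
  pooled <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- pooled / se
  res <- list(
    analysis = effects$analysis[1L], k = k, pooled = pooled, se = se,
    ci_lo = pooled - 1.96 * se, ci_hi = pooled + 1.96 * se,
    z = z, p = 2 * pnorm(-abs(z)), tau2 = tau2,
    i2 = i_squared(tau2, v), scale = effects$scale[1L],
    weights = w, study_id = effects$study_id
  )
  if (res$scale == "fisher_z") {
    res$back_transformed <- tanh(pooled)
    res$back_ci <- tanh(c(res$ci_lo, res$ci_hi))
  }
  structure(res, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %s: k=%d pooled=%.4f SE=%.4f [%.4f, %.4f] p=%.3g tau2=%.4g I2=%.1f%%\n",
    x$analysis, x$k, x$pooled, x$se, x$ci_lo, x$ci_hi, x$p, x$tau2,
    ifelse(is.na(x$i2), NaN, x$i2)))
  if (!is.null(x$back_transformed)) {
    cat(sprintf("  back-transformed r = %.4f [%.4f, %.4f]\n",
                x$back_transformed, x$back_ci[1L], x$back_ci[2L]))
  }
  invisible(x)
}

#' Pool every analysis family in an effects table
#'
#' @param effects Stacked effect-size rows from [study_effects()].
#' @return Named list of `meta_result`, one per analysis label.
#' @export
pool_all <- function(effects) {
  fams <- unique(effects$analysis)
  out <- lapply(fams, function(a) {
    pool_effects(effects[effects$analysis == a, , drop = FALSE])
  })
  names(out) <- fams
  out
}

#' Forest-plot-ready table for one pooled family
#'
#' @param meta A `meta_result`.
#' @param effects The effect rows it pooled.
#' @return data.frame of per-study rows (estimate, CI, relative weight)
#'   plus a final `pooled` row.
#' @export
forest_table <- function(meta, effects) {
  stopifnot(inherits(meta, "meta_result"))
  se_j <- sqrt(effects$variance)
  rows <- data.frame(
    study_id = effects$study_id,
    estimate = effects$estimate,
    ci_lo = effects$estimate - 1.96 * se_j,
    ci_hi = effects$estimate + 1.96 * se_j,
    weight = meta$weights / sum(meta$weights),
    stringsAsFactors = FALSE
  )
  rbind(rows, data.frame(
    study_id = "pooled", estimate = meta$pooled,
    ci_lo = meta$ci_lo, ci_hi = meta$ci_hi, weight = 1,
    stringsAsFactors = FALSE))
}
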