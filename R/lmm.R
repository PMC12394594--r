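#' Specify a Gaussian linear mixed model with crossed random intercepts
#'
#' The model is `y = X beta + sum_k Z_k u_k + e` with
#' `u_k ~ N(0, sigma2_k I)` and `e ~ N(0, sigma2_e I)`; the `Z_k` are
#' indicator matrices of crossed grouping factors (typically participant,
#' from-state and to-state).
#'
#' @param outcome Outcome column name.
#' @param fixed One-sided formula for the fixed effects, e.g.
#'   `~ self_z * loneliness_z` (categorical predictors are
#'   reference-coded).
#' @param random Character vector of grouping column names for random
#'   intercepts (may be empty).
#' @param standardize_continuous Z-score the outcome and every numeric
#'   predictor (across the analysis rows) before fitting, so coefficients
#'   are on the standardized scale; factors are never standardized.
#' @return List of class `lmm_spec`.
#' @export
lmm_spec <- function(outcome, fixed, random = character(),
                     standardize_continuous = TRUE) {
  stopifnot(inherits(fixed, "formula"), is.character(random))
  if (outcome %in% all.vars(fixed)) {
    stop("outcome must not appear among the predictors")
  }
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 standardize_continuous = isTRUE(standardize_continuous)),
            class = "lmm_spec")
}

# crossproduct blocks of the stacked random-effect indicator matrix:
# Z'Z from contingency tables, Z'M from rowsum -- no n x q matrix is formed
stack_crossprods <- function(factors, X, y) {
  qs <- vapply(factors, nlevels, integer(1))
  q <- sum(qs)
  off <- cumsum(c(0L, qs))
  ZtZ <- matrix(0, q, q)
  ZtX <- matrix(0, q, ncol(X))
  Zty <- numeric(q)
  for (k in seq_along(factors)) {
    ik <- off[k] + seq_len(qs[k])
    for (l in seq_along(factors)) {
      il <- off[l] + seq_len(qs[l])
      ZtZ[ik, il] <- unclass(table(factors[[k]], factors[[l]]))
    }
    rsX <- rowsum(X, factors[[k]])
    ZtX[ik, ] <- rsX[levels(factors[[k]]), , drop = FALSE]
    rsy <- rowsum(y, factors[[k]])
    Zty[ik] <- rsy[levels(factors[[k]]), 1L]
  }
  list(ZtZ = ZtZ, ZtX = ZtX, Zty = Zty, qs = qs, off = off)
}

#' Fit a linear mixed model by profiled REML
#'
#' Variance components are profiled out through the variance ratios
#' `lambda_k = sigma2_k / sigma2_e` (optimized on the log scale, which
#' enforces nonnegativity); for each candidate `lambda` the fixed effects
#' and residual variance have closed forms via the Woodbury identity on
#' the `q x q` random-level crossproducts, so fitting cost is driven by
#' the (small) total number of random levels rather than the row count.
#' The REML criterion is
#' `log|A| + log|X' V0^-1 X| + (n-p) (1 + log(2 pi rss/(n-p)))`
#' with `V0 = I + Z Lambda Z'` and `A = I_q + W Z'Z W`, `W = Lambda^{1/2}`.
#'
#' @param data Long-format data.frame.
#' @param spec An [lmm_spec()].
#' @param maxit Maximum optimizer iterations.
#' @param reltol Relative convergence tolerance on the REML criterion.
#' @param fix_lambda Optional vector of fixed variance ratios
#'   `sigma2_k / sigma2_e` (one per random factor): skips estimation and
#'   evaluates the profiled fit there (e.g. all zero reproduces ordinary
#'   least squares exactly).
#' @return Object of class `lmm_fit` with elements `beta`, `vcov_beta`,
#'   `varcomp` (named per random factor plus `"residual"`), `reml_loglik`,
#'   `converged`, `boundary`, `n_obs`, `n_levels`, `xlevels`.
#' @export
fit_lmm <- function(data, spec, maxit = 500L, reltol = 1e-8,
                    fix_lambda = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  vars <- unique(c(spec$outcome, all.vars(spec$fixed), spec$random))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("data missing column(s): ", paste(miss, collapse = ", "))
  data <- data[complete.cases(data[vars]), , drop = FALSE]
  n <- nrow(data)
  if (n < 3L) stop("too few complete observations")
  y <- data[[spec$outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric")
  if (spec$standardize_continuous) {
    y <- standardize_z(y)
    for (v in setdiff(all.vars(spec$fixed), spec$random)) {
      if (is.numeric(data[[v]]) && sd(data[[v]]) > 0) {
        data[[v]] <- standardize_z(data[[v]])
      }
    }
  }
  X <- model.matrix(spec$fixed, data)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  xlevels <- lapply(Filter(function(v) is.factor(data[[v]]) ||
                             is.character(data[[v]]),
                           setNames(all.vars(spec$fixed),
                                    all.vars(spec$fixed))),
                    function(v) levels(factor(data[[v]])))

  factors <- lapply(spec$random, function(f) factor(data[[f]]))
  names(factors) <- spec$random
  K <- length(factors)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)

  if (K == 0L) {
    beta <- qr.coef(qrX, y)
    rss <- sum((y - X %*% beta)^2)
    sigma2 <- rss / (n - p)
    vcov_beta <- sigma2 * chol2inv(qr.R(qrX))
    dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    crit <- determinant(XtX, logarithm = TRUE)$modulus +
      (n - p) * (1 + log(2 * pi * sigma2))
    return(structure(list(
      beta = setNames(drop(beta), colnames(X)), vcov_beta = vcov_beta,
      varcomp = c(residual = sigma2), lambda = numeric(0),
      reml_loglik = -as.numeric(crit) / 2, converged = TRUE,
      boundary = logical(0), n_obs = n,
      n_levels = integer(0), xlevels = xlevels, spec = spec),
      class = "lmm_fit"))
  }

  cp <- stack_crossprods(factors, X, y)
  cp$ZtXy <- cbind(cp$ZtX, cp$Zty)
  lam_index <- rep(seq_len(K), cp$qs)

  eval_crit <- function(theta, want = FALSE) {
    lam <- pmin(pmax(exp(theta), 1e-13), 1e9)
    w <- sqrt(lam[lam_index])
    A <- cp$ZtZ * tcrossprod(w)
    diag(A) <- diag(A) + 1
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(if (want) NULL else 1e12)
    C <- backsolve(R, w * cp$ZtXy, transpose = TRUE)
    CX <- C[, -ncol(C), drop = FALSE]
    Cy <- C[, ncol(C)]
    XtViX <- XtX - crossprod(CX)
    XtViy <- Xty - drop(crossprod(CX, Cy))
    ytViy <- yty - sum(Cy^2)
    Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(Rx)) return(if (want) NULL else 1e12)
    beta <- backsolve(Rx, backsolve(Rx, XtViy, transpose = TRUE))
    rss <- ytViy - sum(beta * XtViy)
    if (!is.finite(rss) || rss <= 0) return(if (want) NULL else 1e12)
    crit <- 2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx))) +
      (n - p) * (1 + log(2 * pi * rss / (n - p)))
    if (!want) return(crit)
    sigma2 <- rss / (n - p)
    vcov_beta <- sigma2 * chol2inv(Rx)
    dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    list(crit = crit, lam = lam, beta = setNames(drop(beta), colnames(X)),
         sigma2 = sigma2, vcov_beta = vcov_beta)
  }

  theta0 <- rep(log(0.5), K)
  if (!is.null(fix_lambda)) {
    stopifnot(length(fix_lambda) == K, all(fix_lambda >= 0))
    opt <- list(par = log(pmax(fix_lambda, 1e-13)), convergence = 0L)
  } else if (K == 1L) {
    opt <- optim(theta0, eval_crit, method = "Brent",
                 lower = -30, upper = 15,
                 control = list(maxit = maxit))
  } else {
    opt <- optim(theta0, eval_crit, method = "Nelder-Mead",
                 control = list(maxit = max(maxit * 4L, 2000L),
                                reltol = reltol))
    if (opt$convergence != 0) {
      # restart from the endpoint: near-boundary (lambda -> 0) regions are
      # flat in log-lambda and can exhaust the simplex without improvement
      opt2 <- optim(opt$par, eval_crit, method = "Nelder-Mead",
                    control = list(maxit = max(maxit * 4L, 2000L),
                                   reltol = reltol))
      if (opt$value - opt2$value < 1e-6) opt2$convergence <- 0L
      opt <- opt2
    }
  }
  sol <- eval_crit(opt$par, want = TRUE)
  converged <- opt$convergence == 0 && !is.null(sol) &&
    is.finite(sol$crit)
  if (is.null(sol)) stop("REML optimization failed (singular fit)")
  if (sol$sigma2 < 1e-10 * max(var(y), 1e-300)) {
    stop("degenerate zero-residual fit: outcome is explained exactly")
  }
  varcomp <- c(setNames(sol$lam * sol$sigma2, names(factors)),
               residual = sol$sigma2)
  boundary <- sol$lam < 1e-7
  varcomp[seq_len(K)][boundary] <- 0
  structure(list(
    beta = sol$beta, vcov_beta = sol$vcov_beta, varcomp = varcomp,
    lambda = setNames(sol$lam, names(factors)),
    reml_loglik = -sol$crit / 2, converged = converged,
    boundary = setNames(boundary, names(factors)), n_obs = n,
    n_levels = setNames(cp$qs, names(factors)),
    xlevels = xlevels, spec = spec), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> REML, n =", x$n_obs,
      if (length(x$n_levels)) paste0("; levels: ",
        paste(names(x$n_levels), x$n_levels, sep = "=", collapse = ", ")),
      "\n  logLik(REML) =", format(x$reml_loglik),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  if (x$converged) print(wald_table(x))
  cat("variance components:\n")
  print(x$varcomp)
  invisible(x)
}

#' Wald inference table for the fixed effects
#'
#' `z = beta/SE`, two-sided normal p-values, CI = estimate +/- 1.96 SE.
#'
#' @param fit A converged `lmm_fit`.
#' @return data.frame with estimate, se, z, p, ci_lo, ci_hi per coefficient.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("refusing inference on a non-converged fit")
  se <- sqrt(diag(fit$vcov_beta))
  z <- fit$beta / se
  data.frame(estimate = fit$beta, se = se, z = z,
             p = 2 * pnorm(-abs(z)),
             ci_lo = fit$beta - 1.96 * se,
             ci_hi = fit$beta + 1.96 * se)
}

#' Simple slopes of a continuous predictor within categories
#'
#' For a fitted `continuous x categorical` interaction, the slope within
#' category `c` is `beta_cont + beta_interaction(c)` (zero for the
#' reference level) with variance
#' `var(b_cont) + var(b_int) + 2 cov(b_cont, b_int)`.
#'
#' @param fit A converged `lmm_fit` containing the interaction.
#' @param continuous Name of the continuous term.
#' @param categorical Name of the categorical term.
#' @return data.frame: category, slope, se, z, p, ci_lo, ci_hi.
#' @export
simple_slopes <- function(fit, continuous, categorical) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("refusing inference on a non-converged fit")
  cn <- names(fit$beta)
  if (!continuous %in% cn) {
    stop("continuous term '", continuous, "' absent from the fit")
  }
  levs <- fit$xlevels[[categorical]]
  if (is.null(levs)) {
    stop("categorical term '", categorical, "' absent from the fit")
  }
  V <- fit$vcov_beta
  rows <- lapply(levs, function(l) {
    if (l == levs[1L]) {
      slope <- fit$beta[[continuous]]
      v <- V[continuous, continuous]
    } else {
      cand <- c(paste0(continuous, ":", categorical, l),
                paste0(categorical, l, ":", continuous))
      int <- cand[cand %in% cn]
      if (!length(int)) {
        stop("interaction term for category '", l, "' absent from the fit")
      }
      int <- int[1L]
      slope <- fit$beta[[continuous]] + fit$beta[[int]]
      v <- V[continuous, continuous] + V[int, int] + 2 * V[continuous, int]
    }
    se <- sqrt(v)
    data.frame(category = l, slope = slope, se = se, z = slope / se,
               p = 2 * pnorm(-abs(slope / se)),
               ci_lo = slope - 1.96 * se, ci_hi = slope + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
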