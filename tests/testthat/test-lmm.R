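# simulated crossed-design table with known structure
sim_crossed <- function(seed, np = 30, nf = 5, nt = 5,
                        sig_p = 2, sig_f = 1.5, sig_t = 1, sig_e = 3,
                        beta = c(1, 0.5, -0.3, 0.2)) {
  set.seed(seed)
  d <- expand.grid(p = factor(seq_len(np)), f = factor(seq_len(nf)),
                   t = factor(seq_len(nt)))
  d$x <- rnorm(nrow(d))
  d$g <- rnorm(nrow(d))
  d$y <- beta[1] + beta[2] * d$x + beta[3] * d$g + beta[4] * d$x * d$g +
    rnorm(np, 0, sig_p)[d$p] + rnorm(nf, 0, sig_f)[d$f] +
    rnorm(nt, 0, sig_t)[d$t] + rnorm(nrow(d), 0, sig_e)
  d
}

test_that("with zero random variance the fit collapses to OLS", {
  d <- sim_crossed(1, sig_p = 0, sig_f = 0, sig_t = 0)
  spec <- lmm_spec("y", ~ x * g, c("p", "f", "t"),
                   standardize_continuous = FALSE)
  # at the boundary the GLS identity is exact
  fit0 <- fit_lmm(d, spec, fix_lambda = c(0, 0, 0))
  ols <- lm(y ~ x * g, data = d)
  expect_lt(max(abs(fit0$beta - coef(ols))), 1e-8)
  # the free fit stays close (variance estimates carry sampling noise)
  fit <- fit_lmm(d, spec)
  expect_lt(max(abs(fit$beta - coef(ols))), 1e-2)
})

test_that("balanced one-factor REML matches the ANOVA closed form", {
  set.seed(2)
  g <- 25; m <- 6
  y <- rep(rnorm(g, 0, 2), each = m) + rnorm(g * m, 5, 1.7)
  d <- data.frame(y = y, grp = factor(rep(seq_len(g), each = m)))
  fit <- fit_lmm(d, lmm_spec("y", ~ 1, "grp",
                             standardize_continuous = FALSE))
  msw <- sum((y - ave(y, d$grp))^2) / (g * (m - 1))
  msb <- m * var(tapply(y, d$grp, mean))
  expect_equal(fit$varcomp[["residual"]], msw, tolerance = 1e-6)
  expect_equal(fit$varcomp[["grp"]], (msb - msw) / m, tolerance = 1e-6)
})

test_that("intercept-only fit gives the REML identities", {
  set.seed(3)
  y <- rnorm(40, 10, 2)
  d <- data.frame(y = y)
  fit <- fit_lmm(d, lmm_spec("y", ~ 1, character(),
                             standardize_continuous = FALSE))
  expect_equal(unname(fit$beta), mean(y))
  expect_equal(fit$varcomp[["residual"]], var(y))
})

test_that("fit agrees with the reference implementation", {
  skip_if_not_installed("lme4")
  d <- sim_crossed(4, np = 40, nf = 6, nt = 6)
  spec <- lmm_spec("y", ~ x * g, c("p", "f", "t"),
                   standardize_continuous = FALSE)
  fit <- fit_lmm(d, spec, reltol = 1e-12)
  ref <- lme4::lmer(y ~ x * g + (1 | p) + (1 | f) + (1 | t), data = d,
                    REML = TRUE)
  expect_lt(max(abs(fit$beta - lme4::fixef(ref))), 1e-5)
  expect_lt(max(abs(sqrt(diag(fit$vcov_beta)) -
                      sqrt(diag(as.matrix(vcov(ref)))))), 1e-3)
  vc <- as.data.frame(lme4::VarCorr(ref))
  ref_vc <- vc$vcov[match(c("p", "f", "t", "Residual"), vc$grp)]
  expect_lt(max(abs(fit$varcomp - ref_vc) / pmax(ref_vc, 0.5)), 1e-3)
  expect_lt(abs(-2 * fit$reml_loglik - lme4::REMLcrit(ref)), 1e-3)
})

test_that("wald_table implements the normal-approximation contract", {
  fit <- structure(list(
    beta = c(a = 0, b = 1.96 * 0.5), vcov_beta = diag(c(0.25, 0.25)),
    converged = TRUE), class = "lmm_fit")
  dimnames(fit$vcov_beta) <- list(c("a", "b"), c("a", "b"))
  wt <- wald_table(fit)
  expect_equal(wt["a", "p"], 1)
  expect_equal(wt["b", "p"], 0.05, tolerance = 1e-3)
  expect_equal(wt["b", "ci_lo"], 1.96 * 0.5 - 1.96 * 0.5)
  fit$converged <- FALSE
  expect_error(wald_table(fit), "non-converged")
})

test_that("simple slopes reproduce hand-computed linear combinations", {
  nm <- c("(Intercept)", "catB", "x", "x:catB")
  V <- matrix(0.001, 4, 4, dimnames = list(nm, nm))
  diag(V) <- c(0.01, 0.02, 0.03, 0.05)
  fit <- structure(list(beta = setNames(c(1, 0.3, 0.5, -0.2), nm),
                        vcov_beta = V, converged = TRUE,
                        xlevels = list(cat = c("A", "B"))),
                   class = "lmm_fit")
  ss <- simple_slopes(fit, "x", "cat")
  expect_equal(ss$slope, c(0.5, 0.3))
  expect_equal(ss$se, c(sqrt(0.03), sqrt(0.03 + 0.05 + 2 * 0.001)))
  expect_equal(ss$ci_lo, ss$slope - 1.96 * ss$se)
  expect_error(simple_slopes(fit, "z", "cat"), "absent")
  expect_error(simple_slopes(fit, "x", "dog"), "absent")
})

test_that("slopes are invariant to the reference category", {
  set.seed(5)
  n <- 600
  d <- data.frame(x = rnorm(n),
                  cat = factor(sample(c("PP", "PN", "NP"), n, TRUE)),
                  p = factor(sample(20, n, TRUE)))
  d$y <- 2 + 0.4 * d$x + 0.3 * (d$cat == "PN") * d$x -
    0.2 * (d$cat == "NP") * d$x + rnorm(20, 0, 1)[d$p] + rnorm(n)
  spec <- lmm_spec("y", ~ cat * x, "p", standardize_continuous = FALSE)
  f1 <- fit_lmm(d, spec)
  s1 <- simple_slopes(f1, "x", "cat")
  d2 <- d
  d2$cat <- relevel(d$cat, "PP")
  f2 <- fit_lmm(d2, spec)
  s2 <- simple_slopes(f2, "x", "cat")
  s1 <- s1[order(s1$category), ]
  s2 <- s2[order(s2$category), ]
  expect_equal(s1$slope, s2$slope, tolerance = 1e-6)
  expect_equal(s1$se, s2$se, tolerance = 1e-6)
})

test_that("zero interaction means every slope equals the main effect", {
  set.seed(6)
  n <- 500
  d <- data.frame(x = rnorm(n),
                  cat = factor(sample(c("A", "B"), n, TRUE)))
  d$y <- 1 + 0.5 * d$x + rnorm(n, 0, 0.1)
  fit <- fit_lmm(d, lmm_spec("y", ~ cat * x, character(),
                             standardize_continuous = FALSE))
  ss <- simple_slopes(fit, "x", "cat")
  expect_equal(ss$slope[1], ss$slope[2], tolerance = 0.05)
  expect_equal(ss$slope, rep(fit$beta[["x"]], 2) +
                 c(0, fit$beta[["catB:x"]]))
})

test_that("estimates are equivariant under predictor rescaling", {
  d <- sim_crossed(7)
  spec <- lmm_spec("y", ~ x * g, c("p", "f", "t"),
                   standardize_continuous = FALSE)
  f1 <- fit_lmm(d, spec)
  d2 <- d
  d2$x <- d2$x * 10
  f2 <- fit_lmm(d2, spec)
  expect_equal(f2$beta[["x"]], f1$beta[["x"]] / 10, tolerance = 1e-4)
  expect_equal(f2$beta[["x:g"]], f1$beta[["x:g"]] / 10, tolerance = 1e-4)
  expect_equal(f2$beta[["g"]], f1$beta[["g"]], tolerance = 1e-4)
})

test_that("rank-deficient designs fail with the aliased column named", {
  d <- sim_crossed(8)
  d$x2 <- d$x
  expect_error(fit_lmm(d, lmm_spec("y", ~ x + x2, "p",
                                   standardize_continuous = FALSE)),
               "x2")
})

test_that("standardization yields standardized-scale coefficients", {
  d <- sim_crossed(9)
  fit <- fit_lmm(d, lmm_spec("y", ~ x * g, c("p", "f", "t"),
                             standardize_continuous = TRUE))
  raw <- fit_lmm(d, lmm_spec("y", ~ x * g, c("p", "f", "t"),
                             standardize_continuous = FALSE))
  # after centering g, the x main effect absorbs beta_xg * mean(g)
  expect_equal(fit$beta[["x"]],
               (raw$beta[["x"]] + raw$beta[["x:g"]] * mean(d$g)) *
                 sd(d$x) / sd(d$y),
               tolerance = 1e-4)
})
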