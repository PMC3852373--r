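make_two_factor_data <- function(seed = 42, n = 250) {
  withr::with_seed(seed, {
    g <- factor(sample(1:30, n, TRUE))
    b <- factor(sample(1:8, n, TRUE))
    y <- rnorm(30, 0, 1.1)[g] + rnorm(8, 0, 0.6)[b] + rnorm(n, 0, 0.9)
    list(y = y, g = g, b = b)
  })
}

test_that("REML estimates, BLUPs and restricted likelihood match lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  d <- make_two_factor_data()
  fit <- reml_fit(d$y, random = list(genotype = d$g, block = d$b))
  lf <- lme4::lmer(y ~ 1 + (1 | g) + (1 | b), REML = TRUE,
                   data = data.frame(y = d$y, g = d$g, b = d$b))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomps$sigma2[match("genotype", fit$varcomps$term)],
               vc$vcov[vc$grp == "g"], tolerance = 1e-4)
  expect_equal(fit$varcomps$sigma2[match("block", fit$varcomps$term)],
               vc$vcov[vc$grp == "b"], tolerance = 1e-4)
  expect_equal(fit$varcomps$sigma2[match("residual", fit$varcomps$term)],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  expect_equal(fit$loglik_restricted, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
  expect_gt(cor(fit$blups$genotype, lme4::ranef(lf)$g[, 1]), 0.99999)

  # single-term profile path agrees too
  fit1 <- reml_fit(d$y, random = list(genotype = d$g))
  lf1 <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE,
                    data = data.frame(y = d$y, g = d$g))
  vc1 <- as.data.frame(lme4::VarCorr(lf1))
  expect_equal(fit1$varcomps$sigma2, vc1$vcov, tolerance = 1e-5)
  expect_equal(fit1$loglik_restricted, as.numeric(stats::logLik(lf1)),
               tolerance = 1e-6)
})

test_that("fixed-only and balanced one-way models reproduce closed-form REML", {
  withr::with_seed(1, {
    y <- rnorm(50, 3, 2)
    f0 <- reml_fit(y, random = list())
    expect_equal(f0$varcomps$sigma2, var(y), tolerance = 1e-12)

    # balanced one-way: REML == ANOVA expected-mean-squares estimators
    a <- 12; r <- 5
    g <- factor(rep(1:a, each = r))
    yy <- rnorm(a, 0, 1.3)[g] + rnorm(a * r, 0, 0.8)
    fit <- reml_fit(yy, random = list(genotype = g))
    msa <- r * var(tapply(yy, g, mean))
    mse <- sum((yy - ave(yy, g))^2) / (a * (r - 1))
    expect_equal(fit$varcomps$sigma2[2], mse, tolerance = 1e-6)
    expect_equal(fit$varcomps$sigma2[1], (msa - mse) / r, tolerance = 1e-5)

    # negative ANOVA estimate: REML clamps the component near zero
    y0 <- rnorm(a * r)
    g0 <- factor(rep(1:a, each = r))
    while ((r * var(tapply(y0, g0, mean))) >=
           sum((y0 - ave(y0, g0))^2) / (a * (r - 1))) {
      y0 <- rnorm(a * r)
    }
    fit0 <- reml_fit(y0, random = list(genotype = g0))
    expect_lt(fit0$varcomps$sigma2[1], 1e-6)
  })
})

test_that("EM iterations never decrease the restricted likelihood", {
  d <- make_two_factor_data(seed = 9)
  fit <- reml_fit(d$y, random = list(genotype = d$g, block = d$b),
                  method = "em")
  expect_gt(length(fit$trace), 3)
  expect_true(all(diff(fit$trace) <= 1e-8))
})

test_that("REML is invariant to observation order and equivariant to shifts", {
  d <- make_two_factor_data(seed = 5, n = 150)
  fit <- reml_fit(d$y, random = list(g = d$g, b = d$b))
  perm <- withr::with_seed(1, sample(150))
  fitp <- reml_fit(d$y[perm], random = list(g = d$g[perm], b = d$b[perm]))
  expect_equal(fit$varcomps$sigma2, fitp$varcomps$sigma2, tolerance = 1e-6)
  expect_equal(fit$blups$g, fitp$blups$g, tolerance = 1e-6)

  fits <- reml_fit(d$y + 100, random = list(g = d$g, b = d$b))
  expect_equal(unname(fits$beta_hat[1]), unname(fit$beta_hat[1]) + 100,
               tolerance = 1e-5)
  expect_equal(fits$varcomps$sigma2, fit$varcomps$sigma2, tolerance = 1e-5)
  expect_equal(fits$blups$g, fit$blups$g, tolerance = 1e-5)
})

test_that("aliased fixed columns are dropped left-to-right and residuals decompose exactly", {
  d <- make_two_factor_data(seed = 3, n = 120)
  X <- cbind(1, x = rnorm(120), x_dup = 0)
  X[, 3] <- X[, 2]  # aliased
  fit <- reml_fit(d$y, X = X, random = list(g = d$g))
  expect_equal(fit$p, 2)
  expect_named(fit$beta_hat, c("", "x"), ignore.order = FALSE)

  Z <- matrix(0, 120, nlevels(d$g))
  Z[cbind(1:120, as.integer(d$g))] <- 1
  recon <- d$y - X[, 1:2] %*% fit$beta_hat - Z %*% fit$blups$g
  expect_equal(unname(fit$residuals), drop(recon), tolerance = 1e-10)
})

test_that("GBLUP equals the multi-term REML engine and the ridge-regression solution", {
  dat <- quick_kernel_data(n = 50, m = 200, seed = 2)
  K <- build_kernel(dat$G, kernel_spec("RR"))
  fit_g <- gblup_fit(dat$y, K)
  fit_r <- reml_fit(unname(dat$y),
                    random = list(g = list(Z = diag(50), K = K)))
  expect_equal(fit_g$varcomps$sigma2, fit_r$varcomps$sigma2, tolerance = 1e-5)
  expect_lt(max(abs(fit_g$gebv - fit_r$blups$g)), 1e-6)

  # ridge oracle on a training subset, matched penalty c * lambda
  train <- names(dat$y)[1:40]
  fit_t <- gblup_fit(dat$y[train], K)
  p <- (colMeans(dat$G) + 1) / 2
  c0 <- sum(2 * p * (1 - p))
  Mc <- sweep(dat$G, 2, colMeans(dat$G))
  alpha <- solve(tcrossprod(Mc[train, ]) / c0 + diag(fit_t$lambda, 40),
                 dat$y[train] - fit_t$mu)
  ridge_pred <- drop(Mc %*% crossprod(Mc[train, ], alpha)) / c0
  expect_lt(max(abs(fit_t$gebv - ridge_pred)), 1e-6)
})

test_that("GBLUP limits: identity kernel, infinite shrinkage, noiseless data, non-PSD error", {
  dat <- quick_kernel_data(n = 40, m = 150, seed = 6)
  ids <- names(dat$y)
  KI <- diag(40); dimnames(KI) <- list(ids, ids)
  fi <- gblup_fit(dat$y[1:30], KI)
  expect_equal(fi$predictions$predicted[!fi$predictions$in_training],
               rep(fi$mu, 10), tolerance = 1e-10)

  K <- build_kernel(dat$G, kernel_spec("RR"))
  fl <- gblup_fit(dat$y[1:30], K, lambda = 1e10)
  expect_lt(max(abs(fl$predictions$predicted - fl$mu)), 1e-6)

  # noiseless kernel-distributed phenotype: fitted values converge to y
  g_true <- withr::with_seed(3, {
    ev <- eigen(K, symmetric = TRUE)
    drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(40)))
  })
  names(g_true) <- ids
  fn <- gblup_fit(g_true, K)
  expect_gt(cor(fn$predictions$predicted, g_true), 0.999)

  Kbad <- K
  Kbad[1, 2] <- Kbad[2, 1] <- 10  # breaks PSD
  expect_error(gblup_fit(dat$y, Kbad), "positive semi-definite")
})

test_that("the profiled variance ratio matches a dense grid search", {
  for (s in 1:3) {
    dat <- quick_kernel_data(n = 40, m = 150, seed = 10 + s)
    K <- build_kernel(dat$G, kernel_spec("RR"))
    fit <- gblup_fit(dat$y, K)
    grid <- seq(-6, 6, length.out = 101)
    ll <- vapply(grid, function(t) gblup_fit(dat$y, K, lambda = exp(t))$loglik_restricted,
                 numeric(1))
    best <- grid[which.max(ll)]
    # clamp into the grid range: a boundary optimum matches a boundary grid point
    expect_lte(abs(min(max(log(fit$lambda), -6), 6) - best),
               diff(grid[1:2]) + 1e-9)
  }
})

test_that("tidy and glance methods return well-formed summaries", {
  d <- make_two_factor_data(seed = 8, n = 100)
  fit <- reml_fit(d$y, random = list(genotype = d$g, block = d$b))
  expect_named(tidy(fit), c("term", "sigma2"))
  expect_equal(nrow(tidy(fit, effects = "genotype")), nlevels(d$g))
  expect_equal(nrow(glance(fit)), 1)

  dat <- quick_kernel_data(n = 30, m = 100, seed = 1)
  K <- build_kernel(dat$G, kernel_spec("RR"))
  gf <- gblup_fit(dat$y, K)
  expect_true(all(c("line_id", "gebv", "predicted") %in% names(tidy(gf))))
  expect_equal(nrow(glance(gf)), 1)
})
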