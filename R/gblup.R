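#' Genomic BLUP from a kernel (relationship) matrix
#'
#' Fits the single-kernel mixed model `y = mu + g + e` with
#' `g ~ N(0, sigma2_u K)` and `e ~ N(0, sigma2_e I)` on the lines with
#' observed phenotypes, profiling the restricted likelihood over the variance
#' ratio `lambda = sigma2_e / sigma2_u` in one dimension via the spectral
#' decomposition of the training submatrix of `K`. Genetic values are
#' returned for every line in `K`; unobserved lines are predicted as
#' `K[test, train] (K[train, train] + lambda I)^-1 (y - mu)`.
#'
#' @param y Named numeric vector of phenotypes (names are line ids present in
#'   `K`); lines absent from `y` or with `NA` are predicted, not trained on.
#' @param K Symmetric positive semi-definite kernel matrix with line ids as
#'   dimnames.
#' @param lambda Optional fixed variance ratio; when `NULL` (default) the
#'   ratio is estimated by bounded minimisation of the restricted
#'   -2 log-likelihood over `log(lambda)`.
#' @param bounds Search interval for `log(lambda)`.
#' @return An object of class `gblup_fit`: `mu`, `lambda`, `varcomps`
#'   (genetic and residual variances), `h2_ratio`, `gebv` (named vector over
#'   all lines of `K`), `predictions` tibble, `loglik_restricted`,
#'   `train_ids`.
#' @export
gblup_fit <- function(y, K, lambda = NULL, bounds = c(-20, 20)) {
  K <- as.matrix(K)
  lines <- rownames(K)
  if (is.null(lines)) abort("gblup_fit: K must have line ids as dimnames.")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    abort("gblup_fit: K must be symmetric.")
  }
  if (is.data.frame(y)) y <- setNames(y[[2]], y[[1]])
  if (is.null(names(y))) abort("gblup_fit: y must be named by line id.")
  train <- lines[lines %in% names(y)[!is.na(y)]]
  nt <- length(train)
  if (nt < 3L) abort("gblup_fit: need at least 3 phenotyped lines in K.")
  yt_raw <- y[train]

  eg <- eigen(K[train, train, drop = FALSE], symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d))) {
    abort("gblup_fit: K is not positive semi-definite beyond jitter tolerance.")
  }
  d <- pmax(d, 0) + 1e-8
  U <- eg$vectors
  yr <- drop(crossprod(U, yt_raw))
  xr <- drop(crossprod(U, rep(1, nt)))

  neg2ll_at <- function(log_lam) {
    lam <- exp(log_lam)
    w <- d + lam
    a <- sum(xr^2 / w)
    mu <- sum(xr * yr / w) / a
    rss <- sum((yr - xr * mu)^2 / w)
    s2u <- rss / (nt - 1)
    (nt - 1) * log(s2u) + sum(log(w)) + log(a)
  }

  if (is.null(lambda)) {
    opt <- optimize(neg2ll_at, bounds, tol = 1e-8)
    log_lam <- opt$minimum
  } else {
    stopifnot(lambda > 0)
    log_lam <- log(lambda)
  }
  lam <- exp(log_lam)
  w <- d + lam
  a <- sum(xr^2 / w)
  mu <- sum(xr * yr / w) / a
  rss <- sum((yr - xr * mu)^2 / w)
  s2u <- rss / (nt - 1)
  s2e <- lam * s2u
  alpha <- drop(U %*% ((yr - xr * mu) / w))
  gebv <- drop(K[, train, drop = FALSE] %*% alpha)
  names(gebv) <- lines
  nll <- neg2ll_at(log_lam) + (nt - 1) * (1 + log(2 * pi))

  out <- list(
    mu = mu, lambda = lam,
    varcomps = tibble(term = c("genetic", "residual"),
                      sigma2 = c(s2u, s2e)),
    h2_ratio = 1 / (1 + lam),
    gebv = gebv,
    predictions = tibble(
      line_id = lines,
      gebv = unname(gebv),
      predicted = unname(mu + gebv),
      observed = unname(y[match(lines, names(y))]),
      in_training = lines %in% train
    ),
    loglik_restricted = -0.5 * nll,
    train_ids = train
  )
  class(out) <- "gblup_fit"
  out
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit: ", length(x$train_ids), " training lines, lambda = ",
      format(x$lambda, digits = 4), ", variance ratio h2 = ",
      format(x$h2_ratio, digits = 3), "\n", sep = "")
  invisible(x)
}
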