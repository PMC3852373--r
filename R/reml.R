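#' Fit a Gaussian linear mixed model by REML
#'
#' Estimates variance components for a model
#' `y = X beta + sum_k Z_k u_k + e`, with independent random vectors
#' `u_k ~ N(0, sigma2_k K_k)` and `e ~ N(0, sigma2_e I)`, by restricted
#' maximum likelihood. Multi-term models are fitted by EM-REML iterations on
#' Henderson's mixed-model equations followed by a derivative-free polish of
#' the restricted likelihood; single-random-term models use an exact
#' one-dimensional profile of the restricted likelihood over the variance
#' ratio. Fixed-effect columns that are aliased are dropped left-to-right.
#'
#' @param y Numeric response vector (no missing values).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param random Named list of random terms. Each term is either a
#'   factor/character vector of length `length(y)` (an iid random factor), a
#'   design matrix `Z`, or a list with elements `Z` (or `factor`) and
#'   optionally `K`, a known covariance matrix among the term's levels.
#' @param tol Relative convergence tolerance on variance components.
#' @param max_iter Maximum EM iterations.
#' @param method `"auto"` (profile when a single random term, EM otherwise),
#'   `"em"`, or `"profile"` (single-term only).
#' @return An object of class `reml_fit` with elements `varcomps` (tibble of
#'   `term`, `sigma2`, including the `"residual"` row), `beta_hat`, `blups`
#'   (named list of named vectors), `residuals` (equal to
#'   `y - X beta - sum Z_k blup_k` exactly), `fitted`, `loglik_restricted`,
#'   `converged`, `n_iter` and `trace` (restricted -2 log-likelihood per EM
#'   iteration).
#' @export
#' @examples
#' set.seed(1)
#' g <- factor(rep(1:20, each = 4))
#' y <- rnorm(20)[g] + rnorm(80)
#' fit <- reml_fit(y, random = list(genotype = g))
#' tidy(fit)
reml_fit <- function(y, X = NULL, random, tol = 1e-6, max_iter = 200L,
                     method = c("auto", "em", "profile")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) abort("reml_fit: y must not contain missing values.")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) != n) abort("reml_fit: nrow(X) must equal length(y).")

  # drop aliased fixed columns left-to-right
  keep <- logical(ncol(X))
  r <- 0L
  for (j in seq_len(ncol(X))) {
    if (qr(X[, c(which(keep), j), drop = FALSE])$rank > r) {
      keep[j] <- TRUE
      r <- r + 1L
    }
  }
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  if (p == 0L) abort("reml_fit: fixed design has rank zero.")
  if (n <= p) abort("reml_fit: need more observations than fixed effects.")

  if (missing(random) || is.null(random)) random <- list()
  if (!is.list(random)) abort("reml_fit: random must be a list of terms.")
  if (length(random) == 0L) {
    # fixed-effects-only model: residual REML variance in closed form
    fitlm <- stats::lm.fit(X, y)
    se <- sum(fitlm$residuals^2) / (n - p)
    nll <- (n - p) * log(se) + log(det(crossprod(X))) + (n - p)
    out <- list(
      varcomps = tibble(term = "residual", sigma2 = se),
      beta_hat = setNames(fitlm$coefficients, colnames(X)),
      blups = list(),
      residuals = fitlm$residuals,
      fitted = drop(X %*% fitlm$coefficients),
      loglik_restricted = -0.5 * (nll + (n - p) * log(2 * pi)),
      n = n, p = p, q = integer(0),
      converged = TRUE, n_iter = 0L, trace = numeric(0),
      method = "closed-form"
    )
    class(out) <- "reml_fit"
    return(out)
  }
  if (is.null(names(random)) || any(names(random) == "")) {
    names(random) <- paste0("term", seq_along(random))
  }
  terms <- lapply(seq_along(random), function(k) {
    normalize_random_term(random[[k]], n, names(random)[k])
  })
  K <- length(terms)
  q_k <- vapply(terms, function(t) ncol(t$Z), integer(1))
  if (any(q_k < 2L)) abort("reml_fit: each random term needs >= 2 levels.")
  q <- sum(q_k)

  W <- cbind(X, do.call(cbind, lapply(terms, `[[`, "Zt")))
  idx <- split(p + seq_len(q), rep(seq_len(K), q_k))
  WtW <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y^2)
  diag_pos <- p + seq_len(q)

  mme <- function(lambda) {
    C <- WtW
    for (k in seq_len(K)) {
      ii <- idx[[k]]
      C[cbind(ii, ii)] <- C[cbind(ii, ii)] + lambda[k]
    }
    R <- chol(C)
    sol <- backsolve(R, backsolve(R, Wty, transpose = TRUE))
    SSR <- max(yty - sum(Wty * sol), 1e-300)
    list(sol = sol, SSR = SSR, logdet = 2 * sum(log(diag(R))), R = R)
  }

  # -2 * restricted log-likelihood, constants in n and p only dropped
  neg2ll <- function(s2) {
    se <- s2[K + 1]
    lam <- se / s2[seq_len(K)]
    m <- mme(lam)
    (n - p - q) * log(se) + sum(q_k * log(s2[seq_len(K)])) +
      m$logdet + m$SSR / se
  }

  floor_s2 <- 1e-10
  trace_ll <- numeric(0)
  n_iter <- 0L
  converged <- TRUE

  if ((method == "auto" && K == 1L) || method == "profile") {
    if (K != 1L) abort("reml_fit: method 'profile' needs exactly one random term.")
    prof <- function(t) {
      m <- mme(exp(t))
      se <- m$SSR / (n - p)
      (n - p) * log(se) - q * log(exp(t)) + m$logdet
    }
    opt <- optimize(prof, c(-30, 30), tol = 1e-8)
    lam_hat <- exp(opt$minimum)
    m <- mme(lam_hat)
    se <- m$SSR / (n - p)
    s2 <- c(max(se / lam_hat, floor_s2), se)
    used_method <- "profile"
  } else {
    v0 <- var(stats::lm.fit(X, y)$residuals)
    s2 <- c(rep(v0 / (2 * K), K), v0 / 2)
    em_converged <- FALSE
    for (it in seq_len(min(max_iter, 40L))) {
      se <- s2[K + 1]
      lam <- pmin(se / pmax(s2[seq_len(K)], floor_s2), 1e12)
      m <- mme(lam)
      trace_ll <- c(trace_ll, neg2ll(s2))
      Cinv_diag <- diag(chol2inv(m$R))
      s2_new <- s2
      for (k in seq_len(K)) {
        uk <- m$sol[idx[[k]]]
        s2_new[k] <- (sum(uk^2) + se * sum(Cinv_diag[idx[[k]]])) / q_k[k]
      }
      s2_new[K + 1] <- m$SSR / (n - p)
      s2_new <- pmax(s2_new, floor_s2)
      delta <- max(abs(s2_new - s2) / (s2 + 1e-12))
      s2 <- s2_new
      n_iter <- it
      if (delta < tol) {
        em_converged <- TRUE
        break
      }
    }
    # derivative-free polish on the log-variance scale
    opt <- optim(log(pmax(s2, floor_s2)), function(lp) neg2ll(exp(lp)),
                 method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12))
    if (opt$value < neg2ll(s2)) s2 <- pmax(exp(opt$par), floor_s2)
    converged <- em_converged || opt$convergence == 0L
    used_method <- "em"
  }

  se <- s2[K + 1]
  lam <- pmin(se / pmax(s2[seq_len(K)], floor_s2), 1e12)
  m <- mme(lam)
  beta_hat <- setNames(m$sol[seq_len(p)], colnames(X))
  blups <- vector("list", K)
  names(blups) <- vapply(terms, `[[`, "", "name")
  for (k in seq_len(K)) {
    v <- m$sol[idx[[k]]]
    u <- if (is.null(terms[[k]]$L)) v else drop(terms[[k]]$L %*% v)
    blups[[k]] <- setNames(u, terms[[k]]$levels)
  }
  fitted <- drop(W %*% m$sol)
  nll <- neg2ll(s2)
  out <- list(
    varcomps = tibble(term = c(names(blups), "residual"), sigma2 = unname(s2)),
    beta_hat = beta_hat,
    blups = blups,
    residuals = y - fitted,
    fitted = fitted,
    loglik_restricted = -0.5 * (nll + (n - p) * log(2 * pi)),
    n = n, p = p, q = unname(q_k),
    converged = converged, n_iter = n_iter, trace = trace_ll,
    method = used_method
  )
  if (!converged) {
    warn("reml_fit: EM did not converge within max_iter; returning best iterate.")
  }
  class(out) <- "reml_fit"
  out
}

normalize_random_term <- function(term, n, name) {
  Kmat <- NULL
  if (is.list(term) && !is.data.frame(term)) {
    Kmat <- term$K
    term <- if (!is.null(term$Z)) term$Z else term$factor
    if (is.null(term)) abort("reml_fit: random term list needs 'Z' or 'factor'.")
  }
  if (is.factor(term) || is.character(term)) {
    f <- factor(term)
    if (length(f) != n) abort("reml_fit: random factor length must equal length(y).")
    Z <- matrix(0, n, nlevels(f))
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    levels <- levels(f)
  } else {
    Z <- as.matrix(term)
    if (nrow(Z) != n) abort("reml_fit: random design rows must equal length(y).")
    levels <- colnames(Z)
    if (is.null(levels)) levels <- paste0(name, seq_len(ncol(Z)))
  }
  L <- NULL
  if (!is.null(Kmat)) {
    Kmat <- as.matrix(Kmat)
    if (!all(dim(Kmat) == ncol(Z))) {
      abort("reml_fit: K dimensions must match the number of term levels.")
    }
    jit <- 1e-8 * max(diag(Kmat), 1)
    L <- t(chol(Kmat + diag(jit, ncol(Kmat))))
    Zt <- Z %*% L
  } else {
    Zt <- Z
  }
  list(Z = Z, Zt = Zt, L = L, levels = levels, name = name)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (", x$method, "): n = ", x$n, ", restricted logLik = ",
      format(x$loglik_restricted, digits = 6), "\n", sep = "")
  print(x$varcomps)
  invisible(x)
}
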