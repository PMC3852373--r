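#' Filter markers on allele frequency, missingness and heterozygosity
#'
#' Retains biallelic markers with minor allele frequency at least `maf_min`
#' (computed on non-missing calls, heterozygotes counted as half an allele),
#' missing fraction at most `max_missing`, and an estimated inbreeding
#' coefficient `F = 1 - Hobs/Hexp` of at least `min_inbreeding` — i.e.
#' observed heterozygosity no more than `(1 - min_inbreeding)` times the
#' Hardy-Weinberg expectation, the filter used to purge spurious
#' heterozygote calls in highly homozygous inbred panels.
#'
#' @param G Genotype matrix (lines x markers) in \{-1, 0, +1\} with `NA`
#'   allowed.
#' @param maf_min Minimum minor allele frequency (default 0.01; the boundary
#'   is kept).
#' @param max_missing Maximum missing-call fraction (default 0.8).
#' @param min_inbreeding Minimum per-marker inbreeding coefficient
#'   (default 0.9).
#' @return A list with `genotypes` (the retained columns of `G`) and
#'   `report`, a per-marker tibble with the computed statistics, a `keep`
#'   flag and the first applicable `drop_reason`
#'   (`"missingness"`, `"maf"`, `"inbreeding"` or `NA`).
#' @export
filter_markers <- function(G, maf_min = 0.01, max_missing = 0.8,
                           min_inbreeding = 0.9) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1,
            min_inbreeding >= 0, min_inbreeding <= 1)
  G <- as.matrix(G)
  n <- nrow(G)
  n_miss <- colSums(is.na(G))
  n_calls <- n - n_miss
  n_het <- colSums(G == 0, na.rm = TRUE)
  n_pos <- colSums(G == 1, na.rm = TRUE)
  p <- ifelse(n_calls > 0, (n_pos + 0.5 * n_het) / n_calls, NA_real_)
  maf <- pmin(p, 1 - p)
  missing_frac <- n_miss / n
  het_obs <- ifelse(n_calls > 0, n_het / n_calls, NA_real_)
  het_exp <- 2 * p * (1 - p)
  f_hat <- ifelse(!is.na(het_exp) & het_exp > 0, 1 - het_obs / het_exp, 1)

  fail_miss <- missing_frac > max_missing
  fail_maf <- is.na(maf) | maf < maf_min
  fail_inb <- f_hat < min_inbreeding
  keep <- !(fail_miss | fail_maf | fail_inb)
  drop_reason <- rep(NA_character_, length(keep))
  drop_reason[fail_inb] <- "inbreeding"
  drop_reason[fail_maf] <- "maf"
  drop_reason[fail_miss] <- "missingness"

  report <- tibble(
    marker_id = colnames(G) %||% paste0("M", seq_len(ncol(G))),
    n_calls = as.integer(n_calls), missing_frac = missing_frac,
    maf = maf, het_obs = het_obs, het_exp = het_exp, inbreeding_f = f_hat,
    keep = keep, drop_reason = drop_reason
  )
  if (!any(keep)) warn("filter_markers: no markers pass the filters.")
  list(genotypes = G[, keep, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing genotypes by multivariate-normal EM
#'
#' Fills missing calls with their conditional expectations under a
#' multivariate-normal model across lines whose covariance is the realized
#' relationship matrix, iterating between imputation (E-step, conditional
#' means given the current relationship matrix) and re-estimation of the
#' relationship matrix from the completed data (M-step) until the largest
#' absolute change in any imputed value falls below `tol`. Observed calls
#' are never altered; imputed values are clamped to `[-1, 1]`.
#'
#' @param G Genotype matrix (lines x markers) with `NA` for missing calls;
#'   per-marker missingness should already satisfy the missingness filter.
#' @param tol Convergence tolerance on imputed values.
#' @param max_iter Maximum EM iterations.
#' @return A list with `genotypes` (complete matrix), `kinship` (the
#'   converged realized relationship matrix, VanRaden-scaled, with a 1e-6
#'   diagonal regularization), `iterations` and `converged`.
#' @export
impute_mvn_em <- function(G, tol = 1e-4, max_iter = 100L) {
  G <- as.matrix(G)
  n <- nrow(G)
  miss <- which(colSums(is.na(G)) > 0L)
  if (length(miss) == 0L) {
    return(list(genotypes = G, kinship = realized_relationship(G),
                iterations = 1L, converged = TRUE))
  }
  if (any(colSums(is.na(G)) == n)) {
    abort("impute_mvn_em: markers with all calls missing cannot be imputed.")
  }
  miss_idx <- lapply(miss, function(j) which(is.na(G[, j])))
  mu_j <- vapply(miss, function(j) mean(G[, j], na.rm = TRUE), numeric(1))
  Gc <- G
  for (k in seq_along(miss)) Gc[miss_idx[[k]], miss[k]] <- mu_j[k]

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- realized_relationship(Gc)
    P <- chol2inv(chol(A))
    delta <- 0
    for (k in seq_along(miss)) {
      j <- miss[k]
      m <- miss_idx[[k]]
      o <- seq_len(n)[-m]
      mu <- mean(G[o, j])
      # conditional mean via the precision matrix:
      # E[x_m | x_o] = mu - P_mm^{-1} P_mo (x_o - mu)
      rhs <- P[m, o, drop = FALSE] %*% (G[o, j] - mu)
      xm <- drop(mu - solve(P[m, m, drop = FALSE], rhs))
      xm <- pmin(pmax(xm, -1), 1)
      delta <- max(delta, max(abs(xm - Gc[m, j])))
      Gc[m, j] <- xm
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("impute_mvn_em: EM did not converge within max_iter; returning best iterate.")
  }
  list(genotypes = Gc, kinship = realized_relationship(Gc),
       iterations = it, converged = converged)
}

# VanRaden-scaled realized relationship matrix from a complete {-1,0,1}
# matrix, with a small diagonal regularization so it is safely invertible.
realized_relationship <- function(G) {
  p <- (colMeans(G) + 1) / 2
  Mc <- sweep(G, 2, colMeans(G))
  c0 <- sum(2 * p * (1 - p))
  if (c0 <= 0) abort("realized_relationship: all markers are monomorphic.")
  A <- tcrossprod(Mc) / c0
  A + diag(1e-6, nrow(A))
}
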