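#' Allele-sharing similarity (kinship) and dissimilarity matrices
#'
#' The similarity between two lines is the proportion of markers at which
#' they carry the same allele. For complete \{-1, +1\} coding this is the
#' affine transform `(1 + G G' / M) / 2` of the genotype cross-product; the
#' diagonal is 1 by definition. The dissimilarity matrix is
#' `1 - similarity`, with a zero diagonal.
#'
#' @param G Complete genotype matrix (lines x markers).
#' @return `kinship_similarity()`: an `n x n` similarity matrix with
#'   line ids as dimnames; `dissimilarity()`: the corresponding
#'   dissimilarity matrix.
#' @export
kinship_similarity <- function(G) {
  G <- as.matrix(G)
  if (anyNA(G)) abort("kinship_similarity: G must be complete (impute first).")
  S <- (1 + tcrossprod(G) / ncol(G)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(G), rownames(G))
  attr(S, "kind") <- "similarity"
  S
}

#' @rdname kinship_similarity
#' @param S A similarity matrix.
#' @export
dissimilarity <- function(S) {
  D <- 1 - S
  diag(D) <- 0
  attr(D, "kind") <- NULL
  D
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric multidimensional scaling: the squared dissimilarities
#' are double-centred (`-D^2/2`), eigendecomposed, and coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues,
#' sorted by decreasing eigenvalue. Negative eigenvalues are discarded and
#' per-axis percentages of variance are taken over the positive eigenvalues
#' only.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes Maximum number of axes to return (default: all positive).
#' @return An object of class `spatgs_pcoa`: `coordinates` (tibble with
#'   `line_id` and `PCo1`, `PCo2`, ...), `eigenvalues` (positive only) and
#'   `pct_variance`.
#' @export
pcoa_dissimilarity <- function(D, n_axes = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (max(abs(D - t(D))) > 1e-8) abort("pcoa_dissimilarity: D must be symmetric.")
  if (max(abs(diag(D))) > 1e-8) abort("pcoa_dissimilarity: D must have a zero diagonal.")
  ids <- rownames(D) %||% paste0("L", seq_len(n))
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  pos <- which(eg$values > 1e-9 * max(abs(eg$values), 1e-12))
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 1, dimnames = list(ids, "PCo1"))
    out <- list(coordinates = bind_coords(ids, coords),
                eigenvalues = numeric(0), pct_variance = numeric(0))
    class(out) <- "spatgs_pcoa"
    return(out)
  }
  if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
  vals <- eg$values[pos]
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), length(pos))
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- ids
  pct <- 100 * eg$values[eg$values > 0][seq_along(pos)] /
    sum(eg$values[eg$values > 0])
  out <- list(coordinates = bind_coords(ids, coords),
              eigenvalues = vals, pct_variance = pct)
  class(out) <- "spatgs_pcoa"
  out
}

bind_coords <- function(ids, coords) {
  dplyr::bind_cols(tibble(line_id = ids), as_tibble(coords))
}

#' @export
print.spatgs_pcoa <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("PCoA with", k, "positive axes")
  if (k >= 2) {
    cat(sprintf("; first two explain %.1f%% of variance",
                sum(x$pct_variance[1:2])))
  }
  cat("\n")
  invisible(x)
}

#' Linkage disequilibrium between marker pairs
#'
#' Computes `r^2`, the squared Pearson correlation of genotype codes, for
#' caller-supplied marker pairs, using only the lines non-missing for both
#' markers of a pair. For inbred biallelic data this equals the standard LD
#' `r^2`. Pairs involving a marker that is monomorphic (on the jointly
#' observed lines) get `NA`.
#'
#' @param G Genotype matrix (lines x markers).
#' @param pairs Data frame with columns `marker_1` and `marker_2` (marker
#'   ids or column indices).
#' @return A tibble with `marker_1`, `marker_2`, `n` (lines used) and `r2`.
#' @export
ld_r2 <- function(G, pairs) {
  G <- as.matrix(G)
  pairs <- as.data.frame(pairs)
  resolve <- function(x) {
    if (is.numeric(x)) {
      if (any(x < 1 | x > ncol(G))) abort("ld_r2: marker index out of range.")
      return(as.integer(x))
    }
    i <- match(as.character(x), colnames(G))
    if (anyNA(i)) {
      abort(paste0("ld_r2: unknown markers: ",
                   paste(unique(x[is.na(i)]), collapse = ", ")))
    }
    i
  }
  i1 <- resolve(pairs[[1]])
  i2 <- resolve(pairs[[2]])
  res <- purrr::map2_dfr(i1, i2, function(a, b) {
    ok <- complete.cases(G[, a], G[, b])
    xa <- G[ok, a]
    xb <- G[ok, b]
    r2 <- if (sum(ok) < 2 || sd(xa) == 0 || sd(xb) == 0) NA_real_ else
      cor(xa, xb)^2
    tibble(n = sum(ok), r2 = r2)
  })
  ids <- colnames(G) %||% paste0("M", seq_len(ncol(G)))
  tibble(marker_1 = ids[i1], marker_2 = ids[i2], n = res$n, r2 = res$r2)
}
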