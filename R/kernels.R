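#' Kernel specification for genomic prediction
#'
#' @param kind `"RR"` (additive / ridge-regression kernel) or `"GAUSS"`
#'   (Gaussian kernel on Euclidean marker distances).
#' @param theta Gaussian bandwidth (> 0) on the mean-scaled distance, or
#'   `"profile"` (the default) to select it per training set by restricted
#'   likelihood over a 21-point log-grid on `[0.1, 10]`. Ignored for `"RR"`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("RR", "GAUSS"), theta = "profile") {
  kind <- match.arg(kind)
  if (kind == "GAUSS") {
    if (is.character(theta)) {
      if (!identical(theta, "profile")) {
        abort("kernel_spec: theta must be a positive number or \"profile\".")
      }
    } else if (!is.numeric(theta) || theta <= 0) {
      abort("kernel_spec: theta must be > 0.")
    }
  }
  out <- list(kind = kind, theta = theta)
  class(out) <- "kernel_spec"
  out
}

#' Build a genomic relationship kernel from markers
#'
#' For `"RR"`, the additive (VanRaden-scaled) relationship matrix
#' `A = (G - P)(G - P)' / c` with column-mean centring `P` and
#' `c = sum(2 p_k (1 - p_k))`, so the mean diagonal is about `1 + f` for
#' lines with inbreeding `f`. For `"GAUSS"`,
#' `K_ij = exp(-(d_ij / theta)^2)` where `d_ij` is the Euclidean marker
#' distance scaled by its mean off-diagonal value, making `theta` unitless.
#'
#' @param G Complete genotype matrix (lines x markers); missing genotypes
#'   are an error — impute first.
#' @param spec A [kernel_spec()] with numeric `theta`
#'   (`theta = "profile"` is resolved at fitting time, see
#'   [cross_validate()]).
#' @return An `n x n` kernel matrix with line ids as dimnames and a
#'   `"kind"` attribute.
#' @export
build_kernel <- function(G, spec = kernel_spec("RR")) {
  stopifnot(inherits(spec, "kernel_spec"))
  G <- as.matrix(G)
  if (anyNA(G)) abort("build_kernel: G has missing genotypes; impute first.")
  if (spec$kind == "RR") {
    p <- (colMeans(G) + 1) / 2
    c0 <- sum(2 * p * (1 - p))
    if (c0 <= 0) abort("build_kernel: all markers are monomorphic.")
    Mc <- sweep(G, 2, colMeans(G))
    K <- tcrossprod(Mc) / c0
  } else {
    if (identical(spec$theta, "profile")) {
      abort("build_kernel: theta = \"profile\" is resolved during fitting; supply a numeric theta.")
    }
    Ds <- marker_distances(G)
    K <- exp(-(Ds / spec$theta)^2)
  }
  dimnames(K) <- list(rownames(G), rownames(G))
  attr(K, "kind") <- if (spec$kind == "RR") "additive" else "gaussian"
  K
}

#' Mean-scaled Euclidean marker distances
#'
#' @param G Complete genotype matrix.
#' @return Symmetric matrix of Euclidean distances divided by their mean
#'   off-diagonal value.
#' @export
marker_distances <- function(G) {
  D <- as.matrix(stats::dist(as.matrix(G)))
  md <- mean(D[upper.tri(D)])
  if (md <= 0) abort("marker_distances: all lines are identical.")
  D / md
}

theta_grid_default <- function() exp(seq(log(0.1), log(10), length.out = 21))

# Select the Gaussian bandwidth on a training set by restricted likelihood.
# Returns the winning theta, its gblup fit, and the likelihood per grid point.
profile_theta <- function(y_train, Ds, theta_grid = theta_grid_default()) {
  best <- NULL
  ll <- numeric(length(theta_grid))
  for (i in seq_along(theta_grid)) {
    K <- exp(-(Ds / theta_grid[i])^2)
    fit <- gblup_fit(y_train, K)
    ll[i] <- fit$loglik_restricted
    if (is.null(best) || ll[i] > best$loglik) {
      best <- list(theta = theta_grid[i], fit = fit, loglik = ll[i])
    }
  }
  best$grid <- tibble(theta = theta_grid, loglik_restricted = ll)
  best
}
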