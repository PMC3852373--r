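#' Neighbourhood grid for the moving-means covariate
#'
#' Defines which plots count as neighbours of a plot on the field grid. The
#' default is the six-plot neighbourhood used for the moving-means
#' covariate: the two plots in the same row plus the four diagonal plots of
#' the adjacent rows. Offsets are `(delta_row, delta_col)` pairs and are
#' user-configurable because plot geometry (long thin plots) dictates which
#' neighbours are informative.
#'
#' @param offsets Two-column matrix (or list of length-2 vectors) of
#'   `(delta_row, delta_col)` offsets; `(0, 0)` is not allowed.
#' @param min_neighbors Minimum number of phenotyped neighbours required to
#'   compute the covariate for a plot; plots below the minimum get a neutral
#'   covariate value and are flagged.
#' @return An object of class `moving_grid`.
#' @export
moving_grid <- function(offsets = rbind(c(0, -1), c(0, 1),
                                        c(-1, -1), c(-1, 1),
                                        c(1, -1), c(1, 1)),
                        min_neighbors = 2L) {
  if (is.list(offsets)) offsets <- do.call(rbind, offsets)
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2L || nrow(offsets) == 0L) {
    abort("moving_grid: offsets must be a non-empty two-column matrix.")
  }
  if (any(offsets[, 1] == 0 & offsets[, 2] == 0)) {
    abort("moving_grid: the focal plot (0, 0) cannot be its own neighbour.")
  }
  out <- list(offsets = offsets, min_neighbors = as.integer(min_neighbors))
  class(out) <- "moving_grid"
  out
}

#' Moving-means spatial covariate
#'
#' Computes a per-plot covariate from the phenotypes of the plot's grid
#' neighbours, within replicate boundaries (a neighbour position belonging
#' to another replicate is excluded, as are unplanted or unphenotyped
#' positions). Two definitions are available: `"neighbor_mean"` (default)
#' uses the mean phenotype of the available neighbours — the classical
#' moving-means covariate; `"deviation"` uses the plot value minus that
#' neighbour mean. Plots with fewer than `min_neighbors` available
#' neighbours get a neutral value (the replicate mean for
#' `"neighbor_mean"`, 0 for `"deviation"`) and are flagged.
#'
#' @param trial Field-trial data frame with columns `rep`, `row`, `col` and
#'   the trait column.
#' @param trait Name of the trait column (default `"y"`).
#' @param grid A [moving_grid()].
#' @param covariate `"neighbor_mean"` or `"deviation"`.
#' @return The trial tibble with added columns `x` (covariate),
#'   `x_neighbors` (number of neighbours used) and `x_fallback` (logical).
#' @export
moving_mean_covariate <- function(trial, trait = "y", grid = moving_grid(),
                                  covariate = c("neighbor_mean", "deviation")) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(grid, "moving_grid"))
  trial <- as_tibble(trial)
  for (cn in c("rep", "row", "col", trait)) {
    if (!cn %in% names(trial)) {
      abort(paste0("moving_mean_covariate: missing column '", cn, "'."))
    }
  }
  y <- trial[[trait]]
  key <- paste(trial$rep, trial$row, trial$col, sep = ":")
  if (anyDuplicated(key)) {
    abort("moving_mean_covariate: duplicated (rep, row, col) positions.")
  }
  n <- nrow(trial)
  nb_sum <- numeric(n)
  nb_cnt <- integer(n)
  for (k in seq_len(nrow(grid$offsets))) {
    nb_key <- paste(trial$rep, trial$row + grid$offsets[k, 1],
                    trial$col + grid$offsets[k, 2], sep = ":")
    j <- match(nb_key, key)
    ok <- !is.na(j) & !is.na(y[j])
    nb_sum[ok] <- nb_sum[ok] + y[j[ok]]
    nb_cnt[ok] <- nb_cnt[ok] + 1L
  }
  enough <- nb_cnt >= grid$min_neighbors & !is.na(y)
  if (!any(enough)) {
    abort("moving_mean_covariate: no plot has enough neighbours; layout is not gridded.")
  }
  nb_mean <- ifelse(enough, nb_sum / pmax(nb_cnt, 1L), NA_real_)
  rep_mean <- stats::ave(y, trial$rep, FUN = function(v) mean(v, na.rm = TRUE))
  if (covariate == "neighbor_mean") {
    x <- ifelse(enough, nb_mean, rep_mean)
  } else {
    x <- ifelse(enough, y - nb_mean, 0)
  }
  trial$x <- x
  trial$x_neighbors <- nb_cnt
  trial$x_fallback <- !enough
  trial
}

#' Fit a phenotypic adjustment model to a field trial
#'
#' Fits one of four competing models for plot-level phenotypes and returns
#' per-genotype adjusted values (BLUPs), variance components, broad-sense
#' heritability and per-plot residuals:
#' \describe{
#'   \item{IB}{incomplete blocks (the field design): random genotype,
#'     replicate and block-within-replicate effects.}
#'   \item{RC}{row-by-column: random genotype, replicate,
#'     row-within-replicate and column-within-replicate effects.}
#'   \item{RCB_MVNG}{randomized complete blocks with the moving-means
#'     covariate as a fixed regression: random genotype and replicate.}
#'   \item{MVNG}{two stages — (1) ordinary regression of the phenotype on
#'     the moving-means covariate; the spatially adjusted plot value is the
#'     intercept plus the stage-1 residual; (2) a random-genotype model on
#'     the adjusted values yields BLUPs and heritability.}
#' }
#'
#' @param trial Field-trial data frame (`plot`, `genotype`, `rep`, `block`,
#'   `row`, `col`, trait column).
#' @param trait Trait column name.
#' @param model One of `"IB"`, `"RC"`, `"RCB_MVNG"`, `"MVNG"`.
#' @param grid [moving_grid()]; required for the covariate models.
#' @param covariate Covariate definition, see [moving_mean_covariate()].
#' @param n_reps Number of replicates for the heritability denominator
#'   (default: distinct values of `rep` in the trial).
#' @return An object of class `spatial_fit`: `model`, `genotype_blups`
#'   (tibble `genotype`, `blup`, `adjusted`), `varcomps`, `H2`, `residuals`
#'   (tibble keyed by plot/row/col), and the underlying fits.
#' @export
fit_spatial_model <- function(trial, trait = "y",
                              model = c("IB", "RC", "RCB_MVNG", "MVNG"),
                              grid = moving_grid(),
                              covariate = c("neighbor_mean", "deviation"),
                              n_reps = NULL) {
  if (length(model) == 1L && !model %in% c("IB", "RC", "RCB_MVNG", "MVNG")) {
    abort(paste0("fit_spatial_model: unknown model '", model, "'."))
  }
  model <- match.arg(model)
  covariate <- match.arg(covariate)
  trial <- as_tibble(trial)
  for (cn in c("genotype", "rep", "row", "col", trait)) {
    if (!cn %in% names(trial)) {
      abort(paste0("fit_spatial_model: missing column '", cn, "'."))
    }
  }
  trial <- trial[!is.na(trial[[trait]]), , drop = FALSE]
  y <- trial[[trait]]
  if (is.null(n_reps)) n_reps <- length(unique(trial$rep))
  geno <- factor(trial$genotype)
  rep_f <- factor(trial$rep)

  stage1 <- NULL
  if (model %in% c("RCB_MVNG", "MVNG")) {
    trial <- moving_mean_covariate(trial, trait, grid, covariate)
    x <- trial$x
  }

  if (model == "IB") {
    if (!"block" %in% names(trial)) abort("fit_spatial_model: IB needs a 'block' column.")
    fit <- reml_fit(y, random = list(
      genotype = geno, rep = rep_f,
      block = interaction(trial$rep, trial$block, drop = TRUE)))
    resid <- fit$residuals
    vc <- fit$varcomps
    blup_g <- fit$blups$genotype
    mu <- fit$beta_hat[["(Intercept)"]]
  } else if (model == "RC") {
    fit <- reml_fit(y, random = list(
      genotype = geno, rep = rep_f,
      row = interaction(trial$rep, trial$row, drop = TRUE),
      col = interaction(trial$rep, trial$col, drop = TRUE)))
    resid <- fit$residuals
    vc <- fit$varcomps
    blup_g <- fit$blups$genotype
    mu <- fit$beta_hat[["(Intercept)"]]
  } else if (model == "RCB_MVNG") {
    X <- cbind(`(Intercept)` = 1, x = x)
    fit <- reml_fit(y, X = X, random = list(genotype = geno, rep = rep_f))
    resid <- fit$residuals
    vc <- fit$varcomps
    blup_g <- fit$blups$genotype
    mu <- fit$beta_hat[["(Intercept)"]]
  } else { # MVNG
    stage1 <- lm(y ~ x)
    adjusted <- coef(stage1)[1] + residuals(stage1)
    fit <- reml_fit(adjusted, random = list(genotype = geno))
    resid <- fit$residuals
    vc <- fit$varcomps
    blup_g <- fit$blups$genotype
    mu <- fit$beta_hat[["(Intercept)"]]
  }

  H2 <- heritability(vc, n_reps)
  out <- list(
    model = model, trait = trait, n_reps = n_reps, covariate = covariate,
    genotype_blups = tibble(genotype = names(blup_g),
                            blup = unname(blup_g),
                            adjusted = unname(mu + blup_g)),
    varcomps = vc, H2 = H2, mu = unname(mu),
    residuals = tibble(plot = trial$plot %||% seq_len(nrow(trial)),
                       rep = trial$rep, row = trial$row, col = trial$col,
                       residual = resid),
    fit = fit, stage1 = stage1
  )
  class(out) <- "spatial_fit"
  out
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / n_reps)`, clamped to `[0, 1]`.
#'
#' @param varcomps A `spatial_fit`, `reml_fit`, or data frame with columns
#'   `term` and `sigma2` containing a `"genotype"` and a `"residual"` row.
#' @param n_reps Number of replicates (entry means average this many plots).
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(varcomps, n_reps) {
  if (n_reps <= 0) abort("heritability: n_reps must be positive.")
  if (inherits(varcomps, "spatial_fit")) varcomps <- varcomps$varcomps
  if (inherits(varcomps, "reml_fit")) varcomps <- varcomps$varcomps
  vc <- as.data.frame(varcomps)
  s_g <- vc$sigma2[match("genotype", vc$term)]
  s_e <- vc$sigma2[match("residual", vc$term)]
  if (is.na(s_g) || is.na(s_e)) {
    abort("heritability: varcomps must contain 'genotype' and 'residual' terms.")
  }
  if (s_g <= 0) return(0)
  min(max(s_g / (s_g + s_e / n_reps), 0), 1)
}

#' Residual field map and spatial-autocorrelation diagnostic
#'
#' Arranges a fitted model's plot residuals on the (row, column) grid, with
#' `NA` at unplanted positions, and reports Moran's I with a permutation
#' p-value as a scalar diagnostic of residual spatial autocorrelation.
#'
#' @param fit A `spatial_fit` (or a data frame with `row`, `col`,
#'   `residual`).
#' @param n_perm Number of permutations for the Moran test.
#' @param seed Seed for the permutation test.
#' @return An object of class `field_map`: `map` (rows x cols matrix),
#'   `moran` (list with `I`, `p_value`, `n_perm`) and the residual tibble.
#' @export
residual_field_map <- function(fit, n_perm = 999L, seed = 1L) {
  res <- if (inherits(fit, "spatial_fit")) fit$residuals else as_tibble(fit)
  stopifnot(all(c("row", "col", "residual") %in% names(res)))
  nr <- max(res$row)
  nc <- max(res$col)
  map <- matrix(NA_real_, nr, nc,
                dimnames = list(paste0("row", seq_len(nr)),
                                paste0("col", seq_len(nc))))
  map[cbind(res$row, res$col)] <- res$residual
  moran <- moran_test(res$residual, res$row, res$col,
                      n_perm = n_perm, seed = seed)
  out <- list(map = map, moran = moran, residuals = res,
              model = if (inherits(fit, "spatial_fit")) fit$model else NULL)
  class(out) <- "field_map"
  out
}

#' Moran's I for values on a grid, with a permutation p-value
#'
#' Uses rook (edge-sharing) adjacency between occupied grid cells and binary
#' weights. The p-value is one-sided for positive autocorrelation,
#' `(1 + #\{I_perm >= I_obs\}) / (n_perm + 1)`.
#'
#' @param values Numeric vector of cell values.
#' @param row,col Integer grid coordinates of each value.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @return A list with `I`, `expected` (`-1/(n-1)`), `p_value` and `n_perm`.
#' @export
moran_test <- function(values, row, col, n_perm = 999L, seed = 1L) {
  ok <- !is.na(values)
  values <- values[ok]
  row <- row[ok]
  col <- col[ok]
  n <- length(values)
  if (n < 4L) abort("moran_test: need at least 4 values.")
  key <- paste(row, col, sep = ":")
  right <- match(paste(row, col + 1L, sep = ":"), key)
  down <- match(paste(row + 1L, col, sep = ":"), key)
  i_idx <- c(which(!is.na(right)), which(!is.na(down)))
  j_idx <- c(right[!is.na(right)], down[!is.na(down)])
  if (length(i_idx) == 0L) abort("moran_test: no adjacent cells on the grid.")
  s0 <- 2 * length(i_idx)
  z <- values - mean(values)
  denom <- sum(z^2)
  stat <- function(zz) (n / s0) * (2 * sum(zz[i_idx] * zz[j_idx])) / sum(zz^2)
  I_obs <- (n / s0) * (2 * sum(z[i_idx] * z[j_idx])) / denom
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat(z[sample.int(n)]), numeric(1))
  })
  list(I = I_obs, expected = -1 / (n - 1),
       p_value = (1 + sum(perms >= I_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat("Spatial adjustment model ", x$model, ": H2 = ",
      format(x$H2, digits = 3), ", ", nrow(x$genotype_blups),
      " genotypes\n", sep = "")
  print(x$varcomps)
  invisible(x)
}

#' @export
print.field_map <- function(x, ...) {
  cat("Residual field map ", if (!is.null(x$model)) paste0("(", x$model, ") "),
      dim(x$map)[1], " x ", dim(x$map)[2],
      "; Moran's I = ", format(x$moran$I, digits = 3),
      " (p = ", format(x$moran$p_value, digits = 3), ")\n", sep = "")
  invisible(x)
}
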