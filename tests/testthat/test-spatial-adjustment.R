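grid_trial <- function(y_mat, rep_id = 1L) {
  # build a one-replicate trial from a matrix of plot values
  idx <- which(!is.na(y_mat), arr.ind = TRUE)
  tibble::tibble(
    plot = seq_len(nrow(idx)),
    genotype = paste0("g", seq_len(nrow(idx))),
    rep = rep_id, block = 1L,
    row = idx[, 1], col = idx[, 2],
    y = y_mat[idx]
  )
}

test_that("the printed deviation covariate evaluates exactly on hand-built neighbourhoods", {
  m <- matrix(10, 3, 3)
  m[2, 2] <- 12
  tr <- moving_mean_covariate(grid_trial(m), covariate = "deviation")
  centre <- tr$row == 2 & tr$col == 2
  expect_equal(tr$x[centre], 2)        # y = 12, six neighbours all 10
  expect_equal(tr$x_neighbors[centre], 6L)

  m2 <- matrix(c(4, 10, 6, 8, 10, 12, 14, 10, 16), 3, 3)
  m2[2, 2] <- 10                       # neighbours (4,6,8,12,14,16): mean 10
  tr2 <- moving_mean_covariate(grid_trial(m2), covariate = "deviation")
  expect_equal(tr2$x[tr2$row == 2 & tr2$col == 2], 0)

  # uniform field: deviation covariate is zero everywhere it is defined
  tru <- moving_mean_covariate(grid_trial(matrix(7, 4, 5)),
                               covariate = "deviation")
  expect_true(all(tru$x == 0))

  # adding a constant leaves the deviation covariate unchanged
  trl <- grid_trial(m2)
  shift <- trl
  shift$y <- shift$y + 55
  expect_equal(moving_mean_covariate(shift, covariate = "deviation")$x,
               moving_mean_covariate(trl, covariate = "deviation")$x)
})

test_that("neighbourhoods respect replicate boundaries and the minimum-neighbour fallback", {
  tr1 <- grid_trial(matrix(rnorm(12), 3, 4), rep_id = 1L)
  tr2 <- grid_trial(matrix(rnorm(12), 3, 4), rep_id = 2L)
  tr2$row <- tr2$row + 3  # second replicate band directly below the first
  tr2$plot <- tr2$plot + 12
  both <- dplyr::bind_rows(tr1, tr2)
  out <- moving_mean_covariate(both)
  # a plot on the boundary row must not borrow neighbours across the band
  boundary <- out[out$rep == 1 & out$row == 3, ]
  expect_true(all(boundary$x_neighbors <= 4L))

  # raising min_neighbors forces the corner plots onto the neutral fallback
  g <- moving_grid(min_neighbors = 4L)
  out4 <- moving_mean_covariate(tr1, grid = g)
  corner <- out4[out4$row == 1 & out4$col == 1, ]
  expect_true(corner$x_fallback)
  expect_equal(corner$x, mean(tr1$y))  # replicate mean is the neutral value

  # ungridded layout (single row, diagonal-only offsets): hard error
  one_row <- grid_trial(matrix(rnorm(6), 1, 6))
  expect_error(
    moving_mean_covariate(one_row, grid = moving_grid(rbind(c(1, 0), c(-1, 0)),
                                                      min_neighbors = 1L)),
    "not gridded")
  expect_error(moving_grid(rbind(c(0, 0))), "own neighbour")
})

test_that("heritability follows the entry-mean formula and is clamped", {
  vc <- tibble::tibble(term = c("genotype", "residual"), sigma2 = c(1, 2))
  expect_equal(heritability(vc, 2), 0.5)
  expect_equal(heritability(tibble::tibble(term = c("genotype", "residual"),
                                           sigma2 = c(1, 0)), 2), 1)
  expect_equal(heritability(tibble::tibble(term = c("genotype", "residual"),
                                           sigma2 = c(0, 1)), 2), 0)
  expect_error(heritability(vc, 0), "n_reps")
})

test_that("all four adjustment models fit, centre their BLUPs, and report H2 in range", {
  cfg <- quick_cfg(n_lines = 60, n_blocks = 6, n_rows = 12, n_cols = 10,
                   seed = 4)
  ft <- simulate_field_trial(quick_tbv(60, seed = 4), cfg)
  for (m in c("IB", "RC", "RCB_MVNG", "MVNG")) {
    fit <- suppressWarnings(fit_spatial_model(ft$trial, model = m))
    expect_s3_class(fit, "spatial_fit")
    expect_lt(abs(mean(fit$genotype_blups$blup)), 0.05)
    expect_gte(fit$H2, 0)
    expect_lte(fit$H2, 1)
    expect_equal(nrow(fit$genotype_blups), 60)
    expect_equal(nrow(fit$residuals), nrow(ft$trial))
  }
  expect_error(fit_spatial_model(ft$trial, model = "SPLINES"), "unknown model")
})

test_that("genotype rankings agree across models when there is no spatial trend", {
  rho <- vapply(1:3, function(s) {
    cfg <- quick_cfg(n_lines = 96, spatial_var_ratio = 0, h2_plot = 0.55,
                     n_blocks = 8, block_size = 12, n_rows = 12, n_cols = 16,
                     seed = s)
    tbv <- quick_tbv(96, seed = s)
    ft <- simulate_field_trial(tbv, cfg)
    b <- sapply(c("IB", "RC", "RCB_MVNG", "MVNG"), function(m) {
      f <- suppressWarnings(fit_spatial_model(ft$trial, model = m))
      setNames(f$genotype_blups$blup, f$genotype_blups$genotype)[names(tbv)]
    })
    min(cor(b, method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
})

test_that("Moran's I matches a dense-matrix oracle, flags gradients, and is calibrated under the null", {
  set.seed(2)
  nr <- 8; nc <- 10
  vals <- rnorm(nr * nc)
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  mine <- moran_test(vals, rows, cols, n_perm = 99)
  # textbook computation with an explicit binary rook-adjacency matrix
  W <- matrix(0, nr * nc, nr * nc)
  for (i in seq_along(vals)) {
    for (j in seq_along(vals)) {
      W[i, j] <- as.integer(abs(rows[i] - rows[j]) + abs(cols[i] - cols[j]) == 1)
    }
  }
  z <- vals - mean(vals)
  I_oracle <- length(vals) / sum(W) * sum(W * outer(z, z)) / sum(z^2)
  expect_equal(mine$I, I_oracle, tolerance = 1e-12)

  # a pure row gradient is maximally autocorrelated
  grad <- moran_test(as.numeric(rows), rows, cols, n_perm = 999, seed = 3)
  expect_gt(grad$I, 0.5)
  expect_lte(grad$p_value, 0.001)

  # iid values: permutation p roughly uniform across seeds
  ps <- vapply(1:40, function(s) {
    v <- withr::with_seed(100 + s, rnorm(48))
    moran_test(v, rep(1:6, 8), rep(1:8, each = 6), n_perm = 99, seed = s)$p_value
  }, numeric(1))
  # discrete permutation p-values tie; the KS test still flags miscalibration
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("residual maps show the trend surviving RC but removed by the moving-means model", {
  cfg <- sim_config(n_markers = 10, seed = 2)  # default strong-trend study layout
  ft <- simulate_field_trial(quick_tbv(384, seed = 2), cfg)
  rc <- suppressWarnings(fit_spatial_model(ft$trial, model = "RC"))
  mv <- suppressWarnings(fit_spatial_model(ft$trial, model = "MVNG"))
  map_rc <- residual_field_map(rc, n_perm = 499, seed = 2)
  map_mv <- residual_field_map(mv, n_perm = 499, seed = 2)
  expect_equal(dim(map_rc$map), c(max(ft$trial$row), max(ft$trial$col)))
  expect_equal(sum(!is.na(map_rc$map)), nrow(ft$trial))
  expect_gt(map_rc$moran$I, 0.1)
  expect_lte(map_rc$moran$p_value, 0.01)
  expect_lt(abs(map_mv$moran$I), 0.1)
  expect_lt(map_mv$moran$I, map_rc$moran$I)
})

test_that("under a strong trend the moving-means model recovers truth better than the design model", {
  wins <- vapply(1:5, function(s) {
    cfg <- quick_cfg(n_lines = 96, n_blocks = 8, block_size = 12,
                     n_rows = 12, n_cols = 16, h2_plot = 0.55,
                     spatial_var_ratio = 4, seed = 20 + s)
    tbv <- quick_tbv(96, seed = 20 + s)
    ft <- simulate_field_trial(tbv, cfg)
    ib <- suppressWarnings(fit_spatial_model(ft$trial, model = "IB"))
    mv <- suppressWarnings(fit_spatial_model(ft$trial, model = "MVNG"))
    bi <- setNames(ib$genotype_blups$blup, ib$genotype_blups$genotype)
    bm <- setNames(mv$genotype_blups$blup, mv$genotype_blups$genotype)
    cor(bm[names(tbv)], tbv) >= cor(bi[names(tbv)], tbv)
  }, logical(1))
  expect_gte(sum(wins), 4)
})
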