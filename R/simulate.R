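#' Simulate inbred-line genotypes with subpopulation structure
#'
#' Draws fully homozygous biallelic genotypes (coded -1/+1) for a panel of
#' inbred lines split across breeding-program subpopulations. Ancestral
#' allele frequencies are uniform above `maf_floor`; each subpopulation's
#' frequencies drift away from the ancestral ones under a Balding-Nichols
#' model with drift parameter `subpop_divergence`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (an `n_lines x n_markers` matrix in
#'   \{-1, +1\} with line/marker dimnames) and `subpops`, a tibble with
#'   columns `line_id` and `subpop`.
#' @export
#' @examples
#' sim <- simulate_genotypes(sim_config(n_lines = 20, n_markers = 50,
#'                                      n_blocks = 2, n_rows = 5, n_cols = 8))
#' table(sim$genotypes[1, ])
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_lines
    m <- cfg$n_markers
    line_ids <- sprintf("L%04d", seq_len(n))
    marker_ids <- sprintf("M%05d", seq_len(m))
    subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
    subpop <- sort(subpop)
    p_anc <- runif(m, cfg$maf_floor, 1 - cfg$maf_floor)
    G <- matrix(0L, n, m, dimnames = list(line_ids, marker_ids))
    f <- cfg$subpop_divergence
    for (s in seq_len(cfg$n_subpops)) {
      idx <- which(subpop == s)
      if (f > 0 && cfg$n_subpops > 1L) {
        p_s <- stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      } else {
        p_s <- p_anc
      }
      draws <- rbinom(length(idx) * m, 1L, rep(p_s, each = length(idx)))
      G[idx, ] <- matrix(2L * draws - 1L, nrow = length(idx))
    }
    list(
      genotypes = G,
      subpops = tibble(line_id = line_ids, subpop = factor(subpop))
    )
  })
}

#' Simulate additive (and optionally epistatic) genetic values
#'
#' Assigns normal effects to all markers and, when `epistasis_fraction > 0`,
#' adds additive-by-additive interaction variance under a multiplicative
#' model: the effect of a marker pair is the product of the two markers'
#' additive effects, so the epistatic deviation is the centred and
#' standardized quadratic component of the additive score (the sum of
#' centred-code products over all marker pairs). Components are scaled so
#' the additive part carries `1 - epistasis_fraction` and the epistatic part
#' `epistasis_fraction` of a unit total genetic variance (empirical
#' variances over the panel).
#'
#' @param G Complete genotype matrix in \{-1, +1\} (lines x markers).
#' @param cfg A [sim_config()].
#' @param effects Optional fixed per-marker additive effects (bypasses the
#'   random draw; no rescaling is applied when all effects are zero).
#' @return A list with `values` (tibble: `line_id`, `tbv`, `additive`,
#'   `epistatic`) and `marker_effects` (named numeric, scaled so that the
#'   additive part equals `G %*% marker_effects` exactly).
#' @export
simulate_genetic_values <- function(G, cfg, effects = NULL) {
  validate_sim_config(cfg)
  if (anyNA(G)) abort("G must be complete (no missing genotypes).")
  n <- nrow(G)
  m <- ncol(G)
  f_epi <- cfg$epistasis_fraction
  withr::with_seed(cfg$seed + 1000L, {
    if (is.null(effects)) effects <- rnorm(m)
    stopifnot(length(effects) == m)
    additive <- drop(G %*% effects)
    s_add <- sd(additive)
    if (s_add > 0) {
      target_sd <- sqrt(1 - f_epi)
      effects <- effects * target_sd / s_add
      additive <- additive * target_sd / s_add
    }
    if (f_epi > 0 && s_add > 0) {
      # multiplicative add-by-add epistasis: pair effect = product of the two
      # additive effects, so the epistatic deviation is the quadratic
      # component of the (centred) additive score. On centred codes this is
      # a sum over all marker pairs and is orthogonal to the additive part.
      Gc <- sweep(G, 2, colMeans(G))
      z <- drop(Gc %*% effects)
      z <- (z - mean(z)) / sd(z)
      epi <- z^2 - mean(z^2)
      s_epi <- sd(epi)
      if (s_epi > 0) epi <- epi * sqrt(f_epi) / s_epi
    } else {
      epi <- rep(0, n)
    }
    names(effects) <- colnames(G)
    list(
      values = tibble(line_id = rownames(G), tbv = additive + epi,
                      additive = additive, epistatic = epi),
      marker_effects = effects
    )
  })
}

ar1_chol_field <- function(n_rows, n_cols, rho = 0.6) {
  cr <- rho^abs(outer(seq_len(n_rows), seq_len(n_rows), "-"))
  cc <- rho^abs(outer(seq_len(n_cols), seq_len(n_cols), "-"))
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  t(chol(cr)) %*% z %*% chol(cc)
}

#' Simulate an alpha-lattice field trial with spatial trend
#'
#' Lays `n_reps` replicates of all lines onto the field grid row-major, each
#' replicate randomized into incomplete blocks of (nearly) equal size, and
#' generates plot phenotypes as mean + breeding value + replicate effect +
#' block-within-replicate effect + spatial trend + iid error. The spatial
#' trend is an equal-variance mix of a smooth second-order polynomial in the
#' scaled (row, column) coordinates (all five terms with equal variance and
#' random signs) and a separable AR(1) x AR(1) Gaussian field (correlation
#' 0.6 per step on both axes), scaled so its variance is
#' `spatial_var_ratio` times the iid plot-error variance.
#'
#' @param tbv True breeding values: the `values` tibble from
#'   [simulate_genetic_values()], or a named numeric vector per line.
#' @param cfg A [sim_config()].
#' @return A list with `trial` (tibble: `plot`, `genotype`, `rep`, `block`,
#'   `row`, `col`, `y`) and `truth` (list: `spatial` tibble keyed by plot,
#'   `sigma2_e`, `sigma2_g`, `rep_effects`, `block_effects`, `mu`).
#' @export
simulate_field_trial <- function(tbv, cfg) {
  validate_sim_config(cfg)
  if (is.data.frame(tbv)) tbv <- setNames(tbv$tbv, tbv$line_id)
  if (is.null(names(tbv))) names(tbv) <- sprintf("L%04d", seq_along(tbv))
  if (length(tbv) != cfg$n_lines) {
    abort("length(tbv) must equal cfg$n_lines.", class = "spatgs_config_error")
  }
  n <- cfg$n_lines
  withr::with_seed(cfg$seed + 2000L, {
    sigma2_g <- var(tbv)
    sigma2_e <- sigma2_g * (1 - cfg$h2_plot) / cfg$h2_plot
    mu <- 10

    # layout: plots numbered row-major over the grid, one contiguous band per rep
    n_plots <- n * cfg$n_reps
    plot_id <- seq_len(n_plots)
    row <- (plot_id - 1L) %/% cfg$n_cols + 1L
    col <- (plot_id - 1L) %% cfg$n_cols + 1L
    rep_id <- rep(seq_len(cfg$n_reps), each = n)

    # block sizes: lines dealt as evenly as possible over n_blocks
    base <- n %/% cfg$n_blocks
    extra <- n %% cfg$n_blocks
    sizes <- c(rep(base + 1L, extra), rep(base, cfg$n_blocks - extra))
    stopifnot(max(sizes) <= cfg$block_size)
    block_within <- rep(seq_len(cfg$n_blocks), times = sizes)

    genotype <- character(n_plots)
    block <- integer(n_plots)
    for (r in seq_len(cfg$n_reps)) {
      idx <- which(rep_id == r)
      genotype[idx] <- sample(names(tbv))
      block[idx] <- block_within
    }

    rep_eff <- rnorm(cfg$n_reps, 0, sqrt(cfg$rep_var_ratio * sigma2_e))
    blk_eff <- matrix(rnorm(cfg$n_reps * cfg$n_blocks, 0,
                            sqrt(cfg$block_var_ratio * sigma2_e)),
                      cfg$n_reps, cfg$n_blocks)

    # spatial surface over the full grid; the five second-order polynomial
    # terms enter with equal variance and random signs so every realization
    # carries both row- and column-direction gradients
    u <- (row - 0.5 * (cfg$n_rows + 1)) / cfg$n_rows
    v <- (col - 0.5 * (cfg$n_cols + 1)) / cfg$n_cols
    std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    terms <- cbind(std(u), std(v), std(u^2), std(v^2), std(u * v))
    signs <- sample(c(-1, 1), 5, replace = TRUE)
    poly <- drop(terms %*% signs)
    fld <- ar1_chol_field(cfg$n_rows, cfg$n_cols, rho = 0.6)
    ar <- fld[cbind(row, col)]
    spatial <- sqrt(0.5) * std(poly) + sqrt(0.5) * std(ar)
    spatial <- std(spatial) * sqrt(cfg$spatial_var_ratio * sigma2_e)

    e <- rnorm(n_plots, 0, sqrt(sigma2_e))
    y <- mu + unname(tbv[genotype]) + rep_eff[rep_id] +
      blk_eff[cbind(rep_id, block)] + spatial + e

    trial <- tibble(
      plot = plot_id, genotype = genotype, rep = rep_id, block = block,
      row = row, col = col, y = y
    )
    truth <- list(
      spatial = tibble(plot = plot_id, row = row, col = col, value = spatial),
      sigma2_e = sigma2_e, sigma2_g = sigma2_g, mu = mu,
      rep_effects = rep_eff, block_effects = blk_eff
    )
    list(trial = trial, truth = truth)
  })
}

#' Simulate a complete study: genotypes, genetic values and a field trial
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_genetic_values()] and [simulate_field_trial()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes`, `subpops`, `values`, `marker_effects`,
#'   `trial` and `truth`.
#' @export
simulate_trial_data <- function(cfg) {
  g <- simulate_genotypes(cfg)
  gv <- simulate_genetic_values(g$genotypes, cfg)
  ft <- simulate_field_trial(gv$values, cfg)
  list(genotypes = g$genotypes, subpops = g$subpops, values = gv$values,
       marker_effects = gv$marker_effects, trial = ft$trial, truth = ft$truth)
}

#' Mask genotype calls as missing or heterozygous
#'
#' Sets exactly `floor(rate * n_cells)` entries to `NA` and, disjointly,
#' `floor(het_rate * n_cells)` entries to 0 (the heterozygous/ambiguous
#' code), uniformly at random.
#'
#' @param G Genotype matrix.
#' @param rate Proportion of cells to mask missing.
#' @param het_rate Proportion of cells to set heterozygous.
#' @param seed Integer seed.
#' @return The modified genotype matrix.
#' @export
inject_missing <- function(G, rate, het_rate = 0, seed = 1L) {
  if (rate < 0 || het_rate < 0 || rate > 1 || het_rate > 1) {
    abort("rate and het_rate must be in [0, 1].", class = "spatgs_config_error")
  }
  if (rate + het_rate > 1) {
    abort("rate + het_rate must not exceed 1.", class = "spatgs_config_error")
  }
  n_cells <- length(G)
  n_miss <- floor(rate * n_cells)
  n_het <- floor(het_rate * n_cells)
  if (n_miss + n_het == 0L) return(G)
  withr::with_seed(seed, {
    idx <- sample.int(n_cells, n_miss + n_het)
    G[idx[seq_len(n_miss)]] <- NA
    if (n_het > 0L) G[idx[n_miss + seq_len(n_het)]] <- 0
    G
  })
}
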