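#' Simulation configuration for synthetic field-trial and genotype data
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study conditions the package targets: 384 inbred wheat lines
#' drawn from two breeding-program subpopulations, genotyped at thousands of
#' biallelic SNPs, and phenotyped in an alpha-lattice field trial with 20
#' incomplete blocks of 20 genotypes and two replicates (768 plots), with a
#' smooth two-dimensional spatial trend superimposed on iid plot error.
#'
#' @param n_lines Number of inbred lines.
#' @param n_markers Number of biallelic markers (scaled down from the
#'   ~1e5 of a genotyping-by-sequencing panel; marker density only matters
#'   for kinship resolution, not for the field-trial machinery).
#' @param n_subpops Number of breeding-program subpopulations.
#' @param subpop_divergence Allele-frequency drift between subpopulations in
#'   `[0, 1]`; used as the drift parameter of a Balding-Nichols model, so it
#'   plays the role of an Fst-like divergence. 0 means no structure.
#' @param maf_floor Lower bound for ancestral minor-allele frequencies.
#' @param n_rows,n_cols Field grid dimensions (plots).
#' @param n_reps Number of complete replicates.
#' @param n_blocks Number of incomplete blocks per replicate.
#' @param block_size Maximum genotypes per incomplete block.
#' @param h2_plot Plot-basis heritability in `(0, 1]`: the ratio
#'   `var(genetic) / (var(genetic) + var(iid plot error))`, spatial trend and
#'   design effects excluded.
#' @param spatial_var_ratio Ratio of spatial-trend variance to iid plot-error
#'   variance (0 = no trend; 1 = trend as strong as the plot error).
#' @param epistasis_fraction Proportion of genetic variance contributed by
#'   pairwise marker-product (additive-by-additive) interactions, in `[0, 1]`.
#' @param rep_var_ratio,block_var_ratio Variance of the replicate and
#'   block-within-replicate effects, as ratios of the iid plot-error variance.
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return A list of class `sim_config`.
#' @export
#'
#' @examples
#' cfg <- sim_config(n_lines = 40, n_markers = 200, n_blocks = 4,
#'                   block_size = 10, n_rows = 8, n_cols = 10)
#' cfg$n_lines
sim_config <- function(n_lines = 384,
                       n_markers = 5000,
                       n_subpops = 2,
                       subpop_divergence = 0.2,
                       maf_floor = 0.05,
                       n_rows = 32,
                       n_cols = 24,
                       n_reps = 2,
                       n_blocks = 20,
                       block_size = 20,
                       h2_plot = 0.55,
                       spatial_var_ratio = 4,
                       epistasis_fraction = 0,
                       rep_var_ratio = 0.05,
                       block_var_ratio = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    n_subpops = as.integer(n_subpops),
    subpop_divergence = subpop_divergence, maf_floor = maf_floor,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_reps = as.integer(n_reps), n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), h2_plot = h2_plot,
    spatial_var_ratio = spatial_var_ratio,
    epistasis_fraction = epistasis_fraction,
    rep_var_ratio = rep_var_ratio, block_var_ratio = block_var_ratio,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_lines < 2L || cfg$n_markers < 1L || cfg$n_subpops < 1L) {
    abort("sim_config: n_lines >= 2, n_markers >= 1 and n_subpops >= 1 required.",
          class = "spatgs_config_error")
  }
  if (cfg$subpop_divergence < 0 || cfg$subpop_divergence > 1) {
    abort("sim_config: subpop_divergence must be in [0, 1].",
          class = "spatgs_config_error")
  }
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.5) {
    abort("sim_config: maf_floor must be in [0, 0.5).",
          class = "spatgs_config_error")
  }
  if (cfg$n_blocks * cfg$block_size < cfg$n_lines) {
    abort("sim_config: n_blocks * block_size must be >= n_lines.",
          class = "spatgs_config_error")
  }
  if (cfg$n_rows * cfg$n_cols < cfg$n_lines * cfg$n_reps) {
    abort("sim_config: field grid too small (n_rows * n_cols < n_lines * n_reps).",
          class = "spatgs_config_error")
  }
  if (cfg$h2_plot <= 0 || cfg$h2_plot > 1) {
    abort("sim_config: h2_plot must be in (0, 1].", class = "spatgs_config_error")
  }
  if (cfg$spatial_var_ratio < 0 || cfg$rep_var_ratio < 0 || cfg$block_var_ratio < 0) {
    abort("sim_config: variance ratios must be >= 0.", class = "spatgs_config_error")
  }
  if (cfg$epistasis_fraction < 0 || cfg$epistasis_fraction > 1) {
    abort("sim_config: epistasis_fraction must be in [0, 1].",
          class = "spatgs_config_error")
  }
  invisible(cfg)
}
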