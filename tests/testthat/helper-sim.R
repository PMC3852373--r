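# Small simulation configurations shared across tests.

quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_lines = 40, n_markers = 120, n_subpops = 2,
                   n_blocks = 4, block_size = 10, n_rows = 8, n_cols = 10,
                   n_reps = 2, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# named breeding values without simulating markers
quick_tbv <- function(n = 384, seed = 1) {
  withr::with_seed(seed, setNames(rnorm(n), sprintf("L%04d", seq_len(n))))
}

# genotype matrix + K-distributed phenotype for kernel tests
quick_kernel_data <- function(n = 50, m = 200, seed = 1, h2 = 0.7) {
  cfg <- sim_config(n_lines = n, n_markers = m, n_blocks = ceiling(n / 10),
                    block_size = 10, n_rows = ceiling(2 * n / 10), n_cols = 10,
                    seed = seed)
  G <- simulate_genotypes(cfg)$genotypes
  gv <- simulate_genetic_values(G, cfg)
  tbv <- setNames(gv$values$tbv, gv$values$line_id)
  y <- withr::with_seed(seed + 7, tbv + rnorm(n, 0, sqrt(var(tbv) * (1 - h2) / h2)))
  list(G = G, tbv = tbv, y = y)
}
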