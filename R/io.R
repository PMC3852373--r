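#' Read and write genotype matrices as TSV
#'
#' The on-disk format is one row per line (first column `line_id`), one
#' column per marker, values in \{-1, 0, 1\} with `NA` for missing calls.
#' The round trip `read(write(G))` is lossless on values and ids.
#'
#' @param G Genotype matrix with line and marker dimnames.
#' @param path File path.
#' @return `write_genotype_tsv()` returns `path` invisibly;
#'   `read_genotype_tsv()` returns the genotype matrix.
#' @export
write_genotype_tsv <- function(G, path) {
  G <- as.matrix(G)
  df <- dplyr::bind_cols(
    tibble(line_id = rownames(G) %||% sprintf("L%04d", seq_len(nrow(G)))),
    as_tibble(G, .name_repair = "minimal"))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), .default = readr::col_double()))
  if (!"line_id" %in% names(df)) {
    abort(paste0("read_genotype_tsv: ", path, ": missing 'line_id' column."))
  }
  G <- as.matrix(df[, setdiff(names(df), "line_id"), drop = FALSE])
  rownames(G) <- df$line_id
  bad <- which(!(G %in% c(-1, 0, 1) | is.na(G)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(G))
    abort(sprintf(
      "read_genotype_tsv: %s: invalid genotype code %s at data line %d (marker '%s'); expected -1, 0, 1 or NA.",
      path, format(G[bad[1]]), rc[1], colnames(G)[rc[2]]))
  }
  if (anyDuplicated(rownames(G))) {
    abort(paste0("read_genotype_tsv: ", path, ": duplicated line ids."))
  }
  G
}

#' Read and write plot-level phenotype tables as CSV
#'
#' Columns: `plot`, `genotype`, `rep`, `block`, `row`, `col`, `value`
#' (1-based field-book coordinates). In memory the trait column is named
#' `y`. Duplicated `(row, col, rep)` positions are an error.
#'
#' @param trial Field-trial tibble with a `y` column.
#' @param path File path.
#' @param trait Name of the trait column to write as `value`.
#' @return `write_phenotype_csv()` returns `path` invisibly;
#'   `read_phenotype_csv()` returns the trial tibble.
#' @export
write_phenotype_csv <- function(trial, path, trait = "y") {
  trial <- as_tibble(trial)
  stopifnot(all(c("plot", "genotype", "rep", "block", "row", "col", trait)
                %in% names(trial)))
  out <- trial[, c("plot", "genotype", "rep", "block", "row", "col", trait)]
  names(out)[7] <- "value"
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    plot = readr::col_integer(), genotype = readr::col_character(),
    rep = readr::col_integer(), block = readr::col_integer(),
    row = readr::col_integer(), col = readr::col_integer(),
    value = readr::col_double()))
  need <- c("plot", "genotype", "rep", "block", "row", "col", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("read_phenotype_csv: ", path, ": missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  key <- paste(df$row, df$col, df$rep, sep = ":")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("read_phenotype_csv: ", path,
                 ": duplicated (row, col, rep) positions: ",
                 paste(head(dup, 5), collapse = "; ")))
  }
  names(df)[names(df) == "value"] <- "y"
  as_tibble(df)
}

#' Read and write per-genotype BLUP tables as CSV
#'
#' Two columns: `genotype`, `value`.
#'
#' @param blups Data frame with `genotype` and a value column, or a named
#'   vector.
#' @param path File path.
#' @return `write_blup_csv()` returns `path` invisibly; `read_blup_csv()`
#'   returns a tibble with `genotype` and `value`.
#' @export
write_blup_csv <- function(blups, path) {
  if (!is.data.frame(blups)) {
    blups <- tibble(genotype = names(blups), value = unname(blups))
  } else {
    vcol <- setdiff(names(blups), "genotype")[1]
    blups <- tibble(genotype = blups$genotype, value = blups[[vcol]])
  }
  readr::write_csv(blups, path)
  invisible(path)
}

#' @rdname write_blup_csv
#' @export
read_blup_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(), value = readr::col_double()))
  if (!all(c("genotype", "value") %in% names(df))) {
    abort(paste0("read_blup_csv: ", path, ": needs columns genotype, value."))
  }
  as_tibble(df)
}

#' Import genotypes from a VCF file
#'
#' Converts unphased or phased diploid GT calls of biallelic SNPs into the
#' package's -1/0/+1 coding (homozygous reference -1, heterozygous 0,
#' homozygous alternate +1, missing `NA`). Multiallelic sites are skipped
#' with a warning reporting their count.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return Genotype matrix, lines (samples) x markers.
#' @export
import_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("import_vcf: the 'vcfR' package is required.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    warn(sprintf("import_vcf: skipped %d multiallelic site(s).", n_skip))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- -1
    out[g %in% c("0/1", "1/0")] <- 0
    out[g %in% c("1/1")] <- 1
    out
  }
  G <- apply(gt, 2, code)
  if (is.null(dim(G))) G <- matrix(G, nrow = nrow(gt))
  G <- t(G)
  colnames(G) <- rownames(gt)
  rownames(G) <- colnames(gt)
  G
}

#' Check that phenotyped genotypes are all genotyped
#'
#' @param G Genotype matrix.
#' @param trial Field-trial tibble.
#' @return Invisibly `TRUE`; errors listing offenders otherwise.
#' @export
check_line_consistency <- function(G, trial) {
  missing <- setdiff(unique(trial$genotype), rownames(G))
  if (length(missing) > 0) {
    abort(paste0("Genotypes present in the trial but absent from the marker matrix: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) " ..."))
  }
  invisible(TRUE)
}

#' Write an accuracy comparison as a wide CSV report
#'
#' One row per kernel, one column per adjustment model, cells
#' `mean +/- SD` over cross-validation replicates.
#'
#' @param comparison An `adjustment_comparison`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(comparison, path) {
  stopifnot(inherits(comparison, "adjustment_comparison"))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(comparison$summary,
                  value = sprintf("%.3f +/- %.3f", .data$mean_accuracy,
                                  .data$sd_accuracy)),
    id_cols = "kernel", names_from = "model", values_from = "value")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Write simulation truth as a JSON sidecar
#'
#' @param sim Output of [simulate_trial_data()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sim, path) {
  jsonlite::write_json(list(
    subpops = sim$subpops,
    values = sim$values,
    spatial = sim$truth$spatial,
    sigma2_e = sim$truth$sigma2_e,
    sigma2_g = sim$truth$sigma2_g
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
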