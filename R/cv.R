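#' Random fold partitions for replicated cross-validation
#'
#' Each replicate partitions the lines into `n_folds` validation sets whose
#' sizes differ by at most one, so with 384 lines and 7 folds the training
#' sets hold 6/7 = 86% of the lines and the validation sets 14%.
#'
#' @param line_ids Character vector of line ids.
#' @param n_folds Number of folds per replicate.
#' @param n_cv_reps Number of independent randomizations.
#' @param seed Integer seed; partitions are deterministic given it.
#' @return A list of length `n_cv_reps`; each element is an integer vector
#'   of fold labels named by line id.
#' @export
make_cv_partitions <- function(line_ids, n_folds = 7L, n_cv_reps = 100L,
                               seed = 1L) {
  n <- length(line_ids)
  if (n_folds > n) abort("make_cv_partitions: more folds than lines.")
  if (n_folds < 2L) abort("make_cv_partitions: need at least 2 folds.")
  sizes <- rep(n %/% n_folds, n_folds) +
    as.integer(seq_len(n_folds) <= n %% n_folds)
  withr::with_seed(seed, {
    lapply(seq_len(n_cv_reps), function(r) {
      setNames(sample(rep.int(seq_len(n_folds), sizes)), line_ids)
    })
  })
}

#' Replicated k-fold cross-validation of GBLUP accuracy
#'
#' For each replicate, lines are partitioned into `n_folds` similar sets;
#' each set in turn is held out while the remaining sets train a
#' [gblup_fit()], and the fold accuracy is the Pearson correlation between
#' predicted genetic values and the observed (adjusted) phenotypes of the
#' held-out lines. The replicate accuracy is the mean over folds; the
#' report gives the mean and SD of replicate accuracies.
#'
#' With `spec$theta = "profile"`, the Gaussian bandwidth is re-selected on
#' every training fold by restricted likelihood (no information from the
#' held-out lines is used).
#'
#' @param y Per-genotype adjusted values: a data frame with columns
#'   `genotype` and a value column, or a named numeric vector.
#' @param G Complete genotype matrix (needed unless `K` is supplied).
#' @param spec A [kernel_spec()].
#' @param K Optional precomputed kernel (overrides `G`/`spec` kernel
#'   construction; still requires `spec` for bookkeeping).
#' @param n_folds Folds per replicate (default 7).
#' @param n_cv_reps Replicates (default 100).
#' @param seed Seed for the partitions.
#' @param partitions Optional partitions from [make_cv_partitions()], used
#'   to pair randomizations across calls.
#' @return An object of class `cv_report`: `folds` (tibble with `replicate`,
#'   `fold`, `accuracy`, `theta`), `replicates` (per-replicate means),
#'   `mean_accuracy`, `sd_accuracy`, `n_folds`, `n_cv_reps`,
#'   `train_fraction` and `partition_hash`.
#' @export
cross_validate <- function(y, G = NULL, spec = kernel_spec("RR"), K = NULL,
                           n_folds = 7L, n_cv_reps = 100L, seed = 1L,
                           partitions = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.data.frame(y)) {
    vcol <- setdiff(names(y), "genotype")[1]
    y <- setNames(y[[vcol]], y$genotype)
  }
  if (is.null(names(y))) abort("cross_validate: y must be named by genotype.")
  profile <- spec$kind == "GAUSS" && identical(spec$theta, "profile")
  Ds <- NULL
  if (is.null(K)) {
    if (is.null(G)) abort("cross_validate: supply G or a precomputed K.")
    G <- as.matrix(G)
    if (profile) Ds <- marker_distances(G) else K <- build_kernel(G, spec)
  }
  lines <- if (profile) rownames(G) else rownames(K)
  y <- y[!is.na(y)]
  missing_geno <- setdiff(names(y), lines)
  if (length(missing_geno) > 0) {
    abort(paste0("cross_validate: genotypes absent from the kernel: ",
                 paste(head(missing_geno, 5), collapse = ", ")))
  }
  lines <- lines[lines %in% names(y)]
  if (profile) Ds <- Ds[lines, lines] else K <- K[lines, lines]
  y <- y[lines]
  if (is.null(partitions)) {
    partitions <- make_cv_partitions(lines, n_folds, n_cv_reps, seed)
  } else {
    n_cv_reps <- length(partitions)
    n_folds <- max(partitions[[1]])
    if (!setequal(names(partitions[[1]]), lines)) {
      abort("cross_validate: partitions do not cover the phenotyped lines.")
    }
  }

  rows <- vector("list", n_cv_reps)
  for (r in seq_len(n_cv_reps)) {
    fold_of <- partitions[[r]][lines]
    acc <- numeric(n_folds)
    theta_used <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      valid <- lines[fold_of == f]
      train <- setdiff(lines, valid)
      if (profile) {
        sel <- profile_theta(y[train], Ds)
        fit <- sel$fit
        theta_used[f] <- sel$theta
      } else {
        fit <- gblup_fit(y[train], K)
      }
      acc[f] <- cor(fit$gebv[valid], y[valid])
    }
    rows[[r]] <- tibble(replicate = r, fold = seq_len(n_folds),
                        accuracy = acc, theta = theta_used)
  }
  folds <- dplyr::bind_rows(rows)
  reps <- dplyr::summarise(dplyr::group_by(folds, .data$replicate),
                           accuracy = mean(.data$accuracy), .groups = "drop")
  out <- list(
    folds = folds, replicates = reps,
    mean_accuracy = mean(reps$accuracy), sd_accuracy = sd(reps$accuracy),
    n_folds = n_folds, n_cv_reps = n_cv_reps,
    train_fraction = 1 - 1 / n_folds,
    kernel = spec$kind,
    partition_hash = partition_hash(partitions)
  )
  class(out) <- "cv_report"
  out
}

partition_hash <- function(partitions) {
  v <- unlist(lapply(partitions, function(p) p[sort(names(p))]),
              use.names = FALSE)
  sum(v * (seq_along(v) %% 97 + 1)) %% 1e9
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Cross-validation (%s): %d reps x %d folds, train fraction %.0f%%\n",
    x$kernel, x$n_cv_reps, x$n_folds, 100 * x$train_fraction))
  cat(sprintf("  accuracy %.3f +/- %.3f (mean +/- SD over replicates)\n",
              x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Cross-validated accuracy for several adjustment models, paired by folds
#'
#' Fits each requested spatial adjustment model, then cross-validates GBLUP
#' on each model's genotype BLUPs with shared fold randomizations (the same
#' partitions for every model and kernel), so accuracy columns are paired
#' replicate by replicate.
#'
#' @param trial Field-trial data frame.
#' @param trait Trait column name.
#' @param models Character vector of adjustment models.
#' @param G Complete genotype matrix over the trial's genotypes.
#' @param specs List of [kernel_spec()]s (default RR and GAUSS).
#' @param grid [moving_grid()] for the covariate models.
#' @param covariate Covariate definition, see [moving_mean_covariate()].
#' @inheritParams cross_validate
#' @return An object of class `adjustment_comparison`: `results` (tibble
#'   `model`, `kernel`, `replicate`, `accuracy`), `summary` (mean and SD per
#'   model x kernel), `H2` (per model), `fits`, `partition_hash`.
#' @export
compare_adjustments <- function(trial, trait = "y",
                                models = c("IB", "RC", "RCB_MVNG", "MVNG"),
                                G, specs = list(kernel_spec("RR"),
                                                kernel_spec("GAUSS")),
                                grid = moving_grid(),
                                covariate = c("neighbor_mean", "deviation"),
                                n_folds = 7L, n_cv_reps = 100L, seed = 1L) {
  covariate <- match.arg(covariate)
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  G <- as.matrix(G)
  fits <- lapply(models, function(m) {
    fit_spatial_model(trial, trait, m, grid = grid, covariate = covariate)
  })
  names(fits) <- models
  lines <- rownames(G)
  lines <- lines[lines %in% fits[[1]]$genotype_blups$genotype]
  partitions <- make_cv_partitions(lines, n_folds, n_cv_reps, seed)
  rows <- list()
  reports <- list()
  for (m in models) {
    b <- fits[[m]]$genotype_blups
    yv <- setNames(b$adjusted, b$genotype)[lines]
    for (sp in specs) {
      cvr <- cross_validate(yv, G = G, spec = sp, partitions = partitions)
      kern_lab <- kernel_label(sp)
      reports[[paste(m, kern_lab, sep = ".")]] <- cvr
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(cvr$replicates, model = m, kernel = kern_lab,
                      .before = 1)
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$model, .data$kernel),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = sd(.data$accuracy), .groups = "drop")
  out <- list(
    results = results, summary = summary,
    H2 = tibble(model = models,
                H2 = vapply(fits, function(f) f$H2, numeric(1))),
    fits = fits, reports = reports,
    partition_hash = partition_hash(partitions)
  )
  class(out) <- "adjustment_comparison"
  out
}

kernel_label <- function(spec) {
  if (spec$kind == "GAUSS" && identical(spec$theta, "profile")) {
    "GAUSS"
  } else if (spec$kind == "GAUSS") {
    "GAUSS"
  } else {
    "RR"
  }
}

#' @export
print.adjustment_comparison <- function(x, ...) {
  cat("Paired cross-validation accuracy by adjustment model and kernel:\n")
  print(tidyr::pivot_wider(
    dplyr::mutate(x$summary,
                  value = sprintf("%.3f +/- %.3f", .data$mean_accuracy,
                                  .data$sd_accuracy)),
    id_cols = "kernel", names_from = "model", values_from = "value"))
  invisible(x)
}

#' Train in some environments, predict another
#'
#' Standardizes each training environment's per-genotype adjusted values to
#' zero mean and unit variance, averages them per genotype into a single
#' training response, fits GBLUP on all genotypes, and reports the Pearson
#' correlation between predicted genetic values and the test environment's
#' adjusted values, for each kernel.
#'
#' @param train_envs A list of per-genotype values (data frames with
#'   `genotype` + value column, or named vectors), one per training
#'   environment.
#' @param test_env Per-genotype values for the test environment.
#' @param G Complete genotype matrix.
#' @param specs List of [kernel_spec()]s.
#' @return A tibble with `kernel`, `accuracy`, `n_genotypes` and
#'   `n_train_envs`.
#' @export
cross_env_predict <- function(train_envs, test_env, G,
                              specs = list(kernel_spec("RR"),
                                           kernel_spec("GAUSS"))) {
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  as_named <- function(v) {
    if (is.data.frame(v)) {
      vcol <- setdiff(names(v), "genotype")[1]
      v <- setNames(v[[vcol]], v$genotype)
    }
    v[!is.na(v)]
  }
  if (!is.list(train_envs) || is.data.frame(train_envs)) {
    train_envs <- list(train_envs)
  }
  train_envs <- lapply(train_envs, as_named)
  test_env <- as_named(test_env)
  G <- as.matrix(G)
  shared <- Reduce(intersect, c(lapply(train_envs, names),
                                list(names(test_env), rownames(G))))
  if (length(shared) == 0L) {
    abort("cross_env_predict: no genotype is shared across environments and G.")
  }
  train_y <- rowMeans(do.call(cbind, lapply(train_envs, function(v) {
    scale(v[shared])[, 1]
  })))
  names(train_y) <- shared
  Gs <- G[shared, , drop = FALSE]
  purrr::map_dfr(specs, function(sp) {
    if (sp$kind == "GAUSS" && identical(sp$theta, "profile")) {
      sel <- profile_theta(train_y, marker_distances(Gs))
      fit <- sel$fit
    } else {
      fit <- gblup_fit(train_y, build_kernel(Gs, sp))
    }
    tibble(kernel = kernel_label(sp),
           accuracy = cor(fit$gebv[shared], test_env[shared]),
           n_genotypes = length(shared),
           n_train_envs = length(train_envs))
  })
}
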