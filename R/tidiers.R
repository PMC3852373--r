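#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns the per-term (or per-genotype, per-replicate) detail of
#' a fit as a tibble; `glance()` returns a one-row model summary.
#'
#' @param x A fitted object.
#' @param effects For `tidy.reml_fit`, `"varcomps"` (default) or the name of
#'   a random term whose BLUPs to return.
#' @param ... Unused.
#' @return A tibble.
#' @name spatgs-tidiers
NULL

#' @rdname spatgs-tidiers
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, effects = "varcomps", ...) {
  if (identical(effects, "varcomps")) return(x$varcomps)
  if (!effects %in% names(x$blups)) {
    abort(paste0("tidy.reml_fit: no random term '", effects, "'."))
  }
  b <- x$blups[[effects]]
  tibble(level = names(b), blup = unname(b))
}

#' @rdname spatgs-tidiers
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(loglik_restricted = x$loglik_restricted, n = x$n,
         n_fixed = x$p, converged = x$converged, n_iter = x$n_iter,
         method = x$method)
}

#' @rdname spatgs-tidiers
#' @method tidy spatial_fit
#' @export
tidy.spatial_fit <- function(x, ...) x$genotype_blups

#' @rdname spatgs-tidiers
#' @method glance spatial_fit
#' @export
glance.spatial_fit <- function(x, ...) {
  vc <- x$varcomps
  tibble(
    model = x$model, H2 = x$H2,
    sigma2_g = vc$sigma2[match("genotype", vc$term)],
    sigma2_e = vc$sigma2[match("residual", vc$term)],
    loglik_restricted = x$fit$loglik_restricted,
    n_genotypes = nrow(x$genotype_blups)
  )
}

#' @rdname spatgs-tidiers
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) x$predictions

#' @rdname spatgs-tidiers
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble(mu = x$mu, lambda = x$lambda, h2_ratio = x$h2_ratio,
         sigma2_g = x$varcomps$sigma2[1], sigma2_e = x$varcomps$sigma2[2],
         loglik_restricted = x$loglik_restricted,
         n_train = length(x$train_ids))
}

#' @rdname spatgs-tidiers
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$replicates

#' @rdname spatgs-tidiers
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
         n_folds = x$n_folds, n_cv_reps = x$n_cv_reps,
         train_fraction = x$train_fraction, kernel = x$kernel)
}

#' @rdname spatgs-tidiers
#' @method tidy adjustment_comparison
#' @export
tidy.adjustment_comparison <- function(x, ...) x$results

#' @rdname spatgs-tidiers
#' @method glance adjustment_comparison
#' @export
glance.adjustment_comparison <- function(x, ...) x$summary

#' @rdname spatgs-tidiers
#' @method tidy spatgs_pcoa
#' @export
tidy.spatgs_pcoa <- function(x, ...) x$coordinates
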