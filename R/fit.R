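#' Fit the Bayesian NB GLMM to every gene
#'
#' End-to-end differential expression workflow for clustered or longitudinal
#' count data: low-expression filtering, median-of-ratios offsets, empirical
#' dispersion prior, per-gene MCMC, convergence screening, contour-probability
#' inference and per-contrast BH adjustment across genes. Genes flagged as
#' convergence failures are reported but excluded from the BH pool by default
#' (their adjusted values are `NA`).
#'
#' @param counts raw count matrix (genes x samples) with dimnames.
#' @param metadata sample metadata (data.frame or TSV path) with `sample_id`
#'   and `subject_id` columns; aligned via [read_metadata()].
#' @param fixed one-sided fixed-effects formula over metadata columns.
#' @param random `"intercept"` (default) or `"none"`.
#' @param contrasts named list of length-p numeric vectors; default one per
#'   coefficient.
#' @param n_iter,burn_in chain length and burn-in fraction.
#' @param seed master seed; every chain seed derives from it and the gene id.
#' @param n_workers forked workers for the per-gene loop.
#' @param filter apply the CPM > 1 low-expression filter.
#' @param filter_min_samples `m` for [filter_low_expression()]; default the
#'   smallest cross-classified cell of the categorical fixed-effect
#'   covariates ([smallest_unit_size()]).
#' @param offsets per-sample log offsets; default `log` median-of-ratios size
#'   factors.
#' @param priors `"empirical"` (default) or an `nbglmm_priors` object.
#' @param prior_k dispersion-prior inflation factor.
#' @param exclude_failed_from_bh drop convergence failures from the BH pool.
#' @param keep_chains retain full chains on the returned object.
#' @return object of class `"nbglmm_fit"`: list with `results` (data.frame:
#'   gene_id, contrast, estimate, ci_lower, ci_upper, p_contour, p_adj,
#'   converged), `convergence` (per-gene report), `design`, `priors`,
#'   `size_factors`, `kept_genes`, `settings`, and `chains` if requested.
#' @export
fit_nbglmm <- function(counts, metadata, fixed, random = c("intercept", "none"),
                       contrasts = NULL, n_iter = 30000, burn_in = 0.1,
                       seed = 1, n_workers = 1, filter = TRUE,
                       filter_min_samples = NULL, offsets = NULL,
                       priors = "empirical", prior_k = 2,
                       exclude_failed_from_bh = TRUE, keep_chains = FALSE) {
  random <- match.arg(random)
  counts <- validate_counts(counts)
  metadata <- read_metadata(metadata, counts)

  if (filter) {
    if (is.null(filter_min_samples)) {
      vars <- intersect(all.vars(fixed), names(metadata))
      cat_vars <- vars[!vapply(metadata[vars], is.numeric, TRUE)]
      filter_min_samples <- smallest_unit_size(metadata, cat_vars)
    }
    flt <- filter_low_expression(counts, filter_min_samples)
    kept <- flt$keep
    counts_f <- flt$counts
  } else {
    kept <- stats::setNames(rep(TRUE, nrow(counts)), rownames(counts))
    counts_f <- counts
  }
  if (nrow(counts_f) == 0) stop("no genes pass the low-expression filter")

  size_factors <- NULL
  if (is.null(offsets)) {
    norm <- median_of_ratios_size_factors(counts_f)
    offsets <- norm$offsets
    size_factors <- norm$size_factors
  }
  design <- build_design(metadata, fixed, random, offsets = offsets)

  if (identical(priors, "empirical"))
    priors <- default_priors(counts_f, design, k = prior_k)
  if (!inherits(priors, "nbglmm_priors")) stop("invalid priors object")

  fits <- fit_all_genes(counts_f, design, priors, contrasts = contrasts,
                        n_iter = n_iter, burn_in = burn_in,
                        master_seed = seed, n_workers = n_workers,
                        keep_chains = keep_chains)
  convergence <- flag_convergence(fits$summaries)

  res <- do.call(rbind, lapply(fits$genes, function(g) {
    tab <- fits$summaries[[g]]$table
    tab$gene_id <- g
    tab
  }))
  res$converged <- !convergence$failed[match(res$gene_id, convergence$gene_id)]
  res$p_adj <- NA_real_
  for (nm in names(fits$contrasts)) {
    sel <- res$contrast == nm & (res$converged | !exclude_failed_from_bh)
    res$p_adj[sel] <- bh_adjust(res$p_contour[sel])
  }
  res <- res[, c("gene_id", "contrast", "estimate", "ci_lower", "ci_upper",
                 "p_contour", "p_adj", "converged")]
  rownames(res) <- NULL

  structure(list(
    results = res, convergence = convergence, design = design,
    priors = priors, size_factors = size_factors, kept_genes = kept,
    contrasts = fits$contrasts,
    chains = if (keep_chains) lapply(fits$summaries, `[[`, "chain"),
    settings = list(n_iter = n_iter, burn_in = burn_in, seed = seed,
                    filter_min_samples = if (filter) filter_min_samples else NA,
                    prior_k = prior_k)
  ), class = "nbglmm_fit")
}

#' @export
print.nbglmm_fit <- function(x, ...) {
  ng <- length(unique(x$results$gene_id))
  cat(sprintf("Bayesian NB GLMM fit: %d genes, %d contrasts, %d iterations\n",
              ng, length(x$contrasts), x$settings$n_iter))
  cat(sprintf("  convergence failures: %d (%.2f%%)\n",
              sum(x$convergence$failed),
              100 * mean(x$convergence$failed)))
  for (nm in names(x$contrasts)) {
    sel <- x$results$contrast == nm
    cat(sprintf("  %-28s %4d genes with BH-adjusted p < 0.05\n", nm,
                sum(x$results$p_adj[sel] < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}
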