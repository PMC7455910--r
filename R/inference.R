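#' Draw-wise contrast chain
#'
#' Evaluates `c' beta` for every retained draw.
#'
#' @param chains `nbglmm_chains` object or an R x p matrix of beta draws.
#' @param contrast numeric vector of length p.
#' @return numeric vector of length R.
#' @export
contrast_chain <- function(chains, contrast) {
  beta <- if (inherits(chains, "nbglmm_chains")) chains$beta else chains
  if (length(contrast) != ncol(beta))
    stop("contrast has length ", length(contrast), ", expected ", ncol(beta))
  as.numeric(beta %*% contrast)
}

#' Contour probability
#'
#' The Bayesian analogue of a two-sided p-value: twice the proportion of MCMC
#' draws on the opposite side of 0 from the posterior median,
#' `p_c = min(1, 2/R * #\{ draws * median < 0 \})`. Draws exactly at 0 never
#' count as opposite side (strict inequality). The resolution is `2/R`; fully
#' one-sided chains give exactly 0. When the median is essentially 0 and the
#' two tails are balanced the statistic degenerates to 0; a warning flags
#' that edge case.
#'
#' @param samples numeric chain of a scalar quantity (R draws; warns below
#'   100).
#' @return contour probability in `[0, 1]`.
#' @export
contour_probability <- function(samples) {
  R <- length(samples)
  if (R < 100) warning("fewer than 100 draws; contour probability is coarse")
  med <- stats::median(samples)
  opp <- sum(samples * med < 0)
  if (abs(med) < 1e-12) {
    lo <- sum(samples < 0); hi <- sum(samples > 0)
    if (abs(lo - hi) < 2)
      warning("posterior median is essentially 0 with balanced tails; ",
              "contour probability degenerates to 0")
  }
  min(1, 2 * opp / R)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values (a thin wrapper over
#' `stats::p.adjust(method = "BH")` with input validation), returned in input
#' order. Applied per contrast across genes.
#'
#' @param p raw values in `[0, 1]` (contour probabilities here).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Summarize one gene's chain over a set of contrasts
#'
#' Per contrast: posterior median, equal-tailed 95% credible interval and
#' contour probability; plus the diagnostic raw material (acceptance rates
#' and Geweke tests on every beta element, `log(alpha)` and `log(sigma2)`).
#'
#' @param chains `nbglmm_chains` object.
#' @param contrasts named list of length-p contrast vectors.
#' @param ci_level credible-interval level.
#' @return list with `table` (data.frame: contrast, estimate, ci_lower,
#'   ci_upper, p_contour), `accept_beta`, `accept_alpha`, `geweke`
#'   (data.frame: parameter, z, p), `failed`.
#' @export
summarize_chain <- function(chains, contrasts, ci_level = 0.95) {
  R <- nrow(chains$beta)
  if (R < 100) warning("fewer than 100 retained draws")
  a <- (1 - ci_level) / 2
  rows <- lapply(names(contrasts), function(nm) {
    cc <- contrast_chain(chains, contrasts[[nm]])
    qs <- stats::quantile(cc, c(a, 0.5, 1 - a), names = FALSE)
    data.frame(contrast = nm, estimate = qs[2], ci_lower = qs[1],
               ci_upper = qs[3],
               p_contour = suppressWarnings(contour_probability(cc)),
               stringsAsFactors = FALSE)
  })
  # post-burn-in acceptance rates; the always-accepted sigma2 Gibbs step is
  # excluded from this diagnostic by construction
  keep <- (chains$n_burn + 1):chains$n_iter
  params <- cbind(chains$beta, log_alpha = chains$log_alpha)
  if (chains$q == 1) params <- cbind(params, log_sigma2 = log(chains$sigma2))
  gw <- t(apply(params, 2, geweke_test))
  list(table = do.call(rbind, rows),
       accept_beta = mean(chains$accept_beta[keep]),
       accept_alpha = mean(chains$accept_alpha[keep]),
       geweke = data.frame(parameter = colnames(params),
                           z = gw[, 1], p = gw[, 2], row.names = NULL),
       failed = isTRUE(chains$failed))
}

#' Write a per-gene, per-contrast results table
#'
#' One TSV row per gene x contrast: posterior median, 95% equal-tailed
#' credible interval, contour probability, BH-adjusted value and the
#' convergence flag.
#'
#' @param results data.frame as found in `fit$results` from [fit_nbglmm()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  need <- c("gene_id", "contrast", "estimate", "ci_lower", "ci_upper",
            "p_contour", "p_adj", "converged")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0) stop("results lack columns: ", paste(miss, collapse = ", "))
  utils::write.table(results[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
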