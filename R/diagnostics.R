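#' Acceptance rate of a Metropolis block
#'
#' Mean of per-iteration acceptance flags.
#'
#' @param flags logical/0-1 vector, one entry per iteration.
#' @return proportion in `[0, 1]`.
#' @export
acceptance_rate <- function(flags) {
  if (length(flags) == 0) stop("no iterations recorded")
  mean(as.numeric(flags))
}

#' Geweke mean-equality screen
#'
#' Compares the first 20% of the retained chain to the final 50% with the
#' z statistic `z = (mean_A - mean_B) / sqrt(s0_A/n_A + s0_B/n_B)` and a
#' two-sided normal p-value. The segment variances `s0` are spectral density
#' estimates at frequency zero obtained from an autoregressive fit, so the
#' autocorrelation inherent in MCMC output does not overstate the statistic;
#' for independent draws `s0` reduces to the ordinary variance and the
#' statistic coincides with a two-sample (Welch) t-type test. A chain that is
#' constant in both segments gives z = 0, p = 1; zero variance with unequal
#' means gives p = 0 with a warning.
#'
#' @param chain retained draws of one scalar parameter (length >= 100).
#' @return named vector `c(z, p)`.
#' @export
geweke_test <- function(chain) {
  R <- length(chain)
  if (R < 100) stop("at least 100 retained draws are required")
  a <- chain[1:floor(0.2 * R)]
  b <- chain[(R - floor(0.5 * R) + 1):R]
  s0a <- spectrum0_ar(a); s0b <- spectrum0_ar(b)
  se2 <- s0a / length(a) + s0b / length(b)
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(c(z = 0, p = 1))
    warning("degenerate chain: zero variance with unequal segment means")
    return(c(z = Inf, p = 0))
  }
  z <- (mean(a) - mean(b)) / sqrt(se2)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Spectral density at frequency zero from an AR fit with AIC order selection;
# equals the chain variance for white noise. Falls back to the plain variance
# if the AR fit is unavailable.
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(20, floor(length(x) / 10))),
                  error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Composite convergence screen across genes
#'
#' A gene fails when any Metropolis acceptance rate (regression block or
#' dispersion) is below `min_accept`, or any of its Geweke p-values — BH
#' adjusted across genes separately for each model parameter — falls below
#' `geweke_alpha`. Genes whose sampler aborted are always failures.
#'
#' @param summaries per-gene summaries from [fit_all_genes()].
#' @param min_accept acceptance-rate threshold (default 0.10).
#' @param geweke_alpha adjusted Geweke p threshold (default 0.05).
#' @return data.frame with one row per gene: acceptance rates, minimum
#'   adjusted Geweke p, `failed` flag and semicolon-separated `reasons`.
#' @export
flag_convergence <- function(summaries, min_accept = 0.10,
                             geweke_alpha = 0.05) {
  genes <- names(summaries)
  acc_b <- vapply(summaries, function(s) s$accept_beta, 0)
  acc_a <- vapply(summaries, function(s) s$accept_alpha, 0)
  aborted <- vapply(summaries, function(s) isTRUE(s$failed), TRUE)
  gw <- lapply(summaries, function(s) s$geweke)
  params <- unique(unlist(lapply(gw, function(g) g$parameter)))
  # BH across genes, one family per model parameter
  min_adj <- rep(1, length(genes))
  for (pp in params) {
    praw <- vapply(gw, function(g) {
      i <- match(pp, g$parameter)
      if (is.na(i)) NA_real_ else g$p[i]
    }, 0)
    padj <- bh_adjust(praw)
    min_adj <- pmin(min_adj, ifelse(is.na(padj), 1, padj))
  }
  failed <- aborted | acc_b < min_accept | acc_a < min_accept |
    min_adj < geweke_alpha
  reasons <- vapply(seq_along(genes), function(i) {
    r <- c(if (aborted[i]) "aborted",
           if (acc_b[i] < min_accept) "acceptance_beta",
           if (acc_a[i] < min_accept) "acceptance_alpha",
           if (min_adj[i] < geweke_alpha) "geweke")
    paste(r, collapse = ";")
  }, "")
  data.frame(gene_id = genes, accept_beta = acc_b, accept_alpha = acc_a,
             min_adj_geweke_p = min_adj, failed = failed, reasons = reasons,
             row.names = NULL, stringsAsFactors = FALSE)
}
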