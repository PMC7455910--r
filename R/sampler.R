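#' Negative binomial log-likelihood
#'
#' Log pmf of the NB distribution parameterized by mean `mu` and dispersion
#' `alpha`, so that `Var(Y) = mu + alpha * mu^2` (size = 1/alpha). Computed
#' through log-gamma functions; as `alpha -> 0` it approaches the Poisson
#' log pmf.
#'
#' @param y nonnegative counts.
#' @param mu positive means (recycled).
#' @param alpha positive dispersion.
#' @return vector of log-probabilities.
#' @export
nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  if (any(mu <= 0)) stop("mu must be positive")
  n <- max(length(y), length(mu))
  as.numeric(.nb_loglik_cpp(rep_len(as.numeric(y), n),
                            rep_len(as.numeric(mu), n), alpha))
}

#' One-step weighted least squares proposal
#'
#' The Gamerman-style proposal for the joint update of `(beta, b)`: a single
#' iteratively-reweighted-least-squares step from the current state, with the
#' prior entering as a ridge. With combined design `C = [X | Z]`,
#' `eta = C theta + rho`, `mu = exp(eta)`, weights `w = mu / (1 + alpha mu)`,
#' working response `z = (eta - rho) + (y - mu)/mu` and prior precision
#' `P = blockdiag(T^-1, I/sigma2)` with prior mean `m0 = (M, 0)`, the
#' proposal is normal with covariance `(C'WC + P)^-1` and mean
#' `cov (C'Wz + P m0)`.
#'
#' @param y gene counts.
#' @param design object from [build_design()].
#' @param theta current `(beta, b)` vector of length `p + I*q`.
#' @param alpha current dispersion.
#' @param sigma2 current random-intercept variance (ignored when q = 0).
#' @param M,Tmat prior mean and covariance of `beta`.
#' @return list with `mean` and `cov`.
#' @export
wls_proposal <- function(y, design, theta, alpha, sigma2 = 1, M, Tmat) {
  C <- combined_design(design)
  if (length(theta) != ncol(C)) stop("theta has wrong length")
  out <- .wls_proposal_cpp(as.numeric(y), C, design$offsets,
                           as.numeric(theta), alpha, solve(Tmat),
                           as.numeric(M), sigma2, design$p)
  list(mean = as.numeric(out$mean), cov = out$cov)
}

#' Deterministic per-gene seed stream
#'
#' Derives the chain seed from the master seed and the *gene id* (not its
#' index), so fitting a subset of genes, reordering the input, or changing
#' the worker count never changes any gene's chain.
#'
#' @param master_seed integer master seed.
#' @param gene_id character gene identifier.
#' @return numeric seed in `[0, 2^53)`.
#' @export
gene_seed <- function(master_seed, gene_id) {
  .gene_seed_cpp(as.integer(master_seed), as.character(gene_id))
}

#' Run the MCMC chain for a single gene
#'
#' Per iteration: joint Metropolis-Hastings update of `(beta, b)` with the
#' asymmetric one-step WLS proposal, random-walk update of `log(alpha)`
#' (step size tuned by Robbins-Monro towards 40% acceptance during burn-in
#' only, then frozen), and an exact inverse-gamma Gibbs draw of `sigma2`.
#' Initialization: intercept at `log(mean(y))` adjusted by the mean offset,
#' other coefficients and random effects 0, `log(alpha) = A_g`,
#' `sigma2 = 0.1`.
#'
#' A zero-length `y` (with a 0-row design) removes the likelihood, in which
#' case the sampler draws from the joint prior; this is used to verify
#' correctness.
#'
#' @param y gene counts (length `design$n_samples`).
#' @param design object from [build_design()].
#' @param prior per-gene prior: list with `M` (length p), `Tmat`, `A`, `B`,
#'   `U`, `V`.
#' @param n_iter total iterations (default 30000).
#' @param burn_in fraction discarded as burn-in (default 0.1).
#' @param seed chain seed (e.g. from [gene_seed()]).
#' @param step_sd0 initial random-walk sd for `log(alpha)`.
#' @param save_b keep (thinned) random-effect draws.
#' @param thin_b thinning interval for saved random effects.
#' @return object of class `"nbglmm_chains"`: retained draws `beta`
#'   (R x p), `log_alpha` (R), `sigma2` (R, q = 1 only), optional `b`;
#'   per-iteration acceptance flags `accept_beta`, `accept_alpha`; `failed`
#'   flag set when over half the iterations were numerically unusable.
#' @export
run_chain <- function(y, design, prior, n_iter = 30000, burn_in = 0.1,
                      seed = 1, step_sd0 = 0.5, save_b = FALSE, thin_b = 10) {
  stopifnot(n_iter >= 10, burn_in > 0, burn_in < 1)
  n_burn <- floor(n_iter * burn_in)
  if (n_iter - n_burn < 1000)
    warning("fewer than 1000 retained draws; contour probabilities will be coarse")
  C <- combined_design(design)
  if (length(y) != nrow(C)) stop("y has wrong length")
  d <- ncol(C)
  theta0 <- numeric(d)
  theta0[1] <- if (length(y) > 0 && mean(y) > 0)
    log(mean(y)) - mean(design$offsets) else prior$M[1]
  res <- .fit_gene_cpp(as.numeric(y), C, design$offsets, design$p,
                       design$n_subjects, as.numeric(prior$M),
                       solve(prior$Tmat), prior$A, prior$B, prior$U, prior$V,
                       as.integer(n_iter), as.integer(n_burn), theta0,
                       prior$A, 0.1, step_sd0, 0.40, seed, save_b,
                       as.integer(thin_b))
  colnames(res$beta) <- colnames(design$X)
  res$n_iter <- n_iter
  res$n_burn <- n_burn
  res$q <- design$q
  class(res) <- "nbglmm_chains"
  res
}

#' Fit chains for every gene
#'
#' Runs [run_chain()] independently per gene with per-gene seeds from
#' [gene_seed()] and immediately reduces each chain to the summaries needed
#' downstream (posterior medians, credible intervals, contour probabilities,
#' acceptance rates, Geweke screens), so memory stays flat in the number of
#' genes. Results are identical for any worker count.
#'
#' @param counts filtered count matrix.
#' @param design object from [build_design()].
#' @param priors object from [default_priors()].
#' @param contrasts named list of length-p numeric vectors; default: one
#'   identity contrast per fixed-effect coefficient.
#' @param n_iter,burn_in chain settings.
#' @param master_seed integer master seed.
#' @param n_workers forked workers via `parallel::mclapply` when > 1.
#' @param keep_chains also return the full `nbglmm_chains` objects (memory!).
#' @return list with `summaries` (list per gene), `chains` (if requested) and
#'   `genes`.
#' @export
fit_all_genes <- function(counts, design, priors, contrasts = NULL,
                          n_iter = 30000, burn_in = 0.1, master_seed = 1,
                          n_workers = 1, keep_chains = FALSE) {
  counts <- validate_counts(counts)
  if (is.null(contrasts)) {
    contrasts <- lapply(seq_len(design$p), function(j) {
      v <- numeric(design$p); v[j] <- 1; v
    })
    names(contrasts) <- colnames(design$X)
  }
  validate_contrasts(contrasts, design$p)
  genes <- rownames(counts)
  one <- function(g) {
    prior_g <- list(M = priors$M[g, ], Tmat = priors$Tmat,
                    A = priors$A[match(g, genes)], B = priors$B,
                    U = priors$U, V = priors$V)
    ch <- run_chain(counts[g, ], design, prior_g, n_iter = n_iter,
                    burn_in = burn_in, seed = gene_seed(master_seed, g))
    s <- summarize_chain(ch, contrasts)
    if (keep_chains) s$chain <- ch
    s
  }
  summaries <- if (n_workers > 1) {
    parallel::mclapply(genes, one, mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(genes, one)
  }
  names(summaries) <- genes
  list(summaries = summaries, genes = genes, contrasts = contrasts)
}

validate_contrasts <- function(contrasts, p) {
  if (is.null(names(contrasts)) || any(names(contrasts) == ""))
    stop("contrasts must be a named list")
  for (nm in names(contrasts)) {
    v <- contrasts[[nm]]
    if (length(v) != p)
      stop("contrast '", nm, "' has length ", length(v), ", expected ", p)
    if (all(v == 0)) stop("contrast '", nm, "' is all zero")
  }
  invisible(TRUE)
}

#' @export
print.nbglmm_chains <- function(x, ...) {
  cat(sprintf("NB GLMM chain: %d retained draws (%d iterations, %d burn-in), p = %d%s\n",
              nrow(x$beta), x$n_iter, x$n_burn, ncol(x$beta),
              if (isTRUE(x$failed)) " [FAILED]" else ""))
  invisible(x)
}
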