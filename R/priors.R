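#' Method-of-moments dispersion estimates
#'
#' Counts are first scaled to the median library size; for each gene the mean
#' `m_g` and sample variance `v_g` (denominator S - 1) of the scaled counts
#' give the naive dispersion estimate `(v_g - m_g) / m_g^2`. Estimates may be
#' nonpositive (under-dispersed genes); genes with `m_g = 0` return `NA`.
#' These naive estimates over-state the true dispersion because fixed and
#' random effects explaining part of the variance are ignored, which is why
#' the prior built from them is widened by the inflation factor `k`.
#'
#' @param counts validated count matrix with at least 2 samples.
#' @return named numeric vector of per-gene estimates.
#' @export
mom_dispersion <- function(counts) {
  counts <- validate_counts(counts)
  if (ncol(counts) < 2) stop("at least two samples are required")
  libs <- colSums(counts)
  scaled <- sweep(counts, 2, stats::median(libs) / libs, "*")
  m <- rowMeans(scaled)
  v <- apply(scaled, 1, stats::var)
  est <- (v - m) / m^2
  est[m == 0] <- NA_real_
  est
}

#' Fit the information-sharing dispersion prior
#'
#' LOESS regression of `log` method-of-moments dispersion on mean log(CPM),
#' using only genes with strictly positive estimates. The prior mean `A_g` is
#' the fitted trend evaluated at every gene's mean log(CPM) (clamped to the
#' fitted range), and the shared prior variance is `B = (k * tau)^2` with
#' `tau` the residual standard deviation of the fit. With `k > 1` the prior
#' admits a wider range of dispersions than the (upward-biased) naive
#' estimates suggest; `k = 2` is the default throughout.
#'
#' @param mom per-gene naive dispersion estimates ([mom_dispersion()]).
#' @param mean_logcpm per-gene mean log(CPM), same length/order as `mom`.
#' @param k inflation factor (> 0).
#' @param span,degree LOESS settings.
#' @param min_genes minimum number of usable (positive) estimates.
#' @return list with `A` (per gene), `B`, `tau`, and `trend` (function over
#'   mean log(CPM), clamped outside the fitted range).
#' @export
fit_dispersion_prior <- function(mom, mean_logcpm, k = 2, span = 0.75,
                                 degree = 2, min_genes = 20) {
  if (length(mom) != length(mean_logcpm))
    stop("mom and mean_logcpm must have equal length")
  use <- is.finite(mom) & mom > 0 & is.finite(mean_logcpm)
  if (sum(use) < min_genes)
    stop("fewer than ", min_genes, " genes with positive dispersion ",
         "estimates; set A and B manually")
  x <- mean_logcpm[use]
  yv <- log(mom[use])
  if (stats::var(yv) < 1e-24) {
    # all usable log-dispersions identical: flat trend, floored variance
    cval <- yv[1]
    trend <- function(z) rep(cval, length(z))
    tau <- 0
  } else {
    fit <- stats::loess(yv ~ x, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    rng <- range(x)
    trend <- function(z) as.numeric(stats::predict(
      fit, newdata = data.frame(x = pmin(pmax(z, rng[1]), rng[2]))))
    tau <- stats::sd(stats::residuals(fit))
  }
  B <- max((k * tau)^2, (k * 0.1)^2)  # floor avoids a point-mass prior
  A <- trend(mean_logcpm)
  list(A = A, B = B, tau = tau, trend = trend)
}

#' Assemble default priors for the Bayesian NB GLMM
#'
#' Per gene, the prior mean vector `M_g` has first element
#' `log(mean raw count)` and zeros elsewhere; the fixed-effect prior
#' covariance is `T = diag(49)` (sd 7, effectively uninformative on the log
#' scale); the random-intercept variance gets an inverse-gamma(U, V) prior
#' with `U = V = 0.01`; and `(A_g, B)` come from [fit_dispersion_prior()].
#'
#' @param counts filtered count matrix.
#' @param design design from [build_design()].
#' @param k dispersion-prior inflation factor.
#' @param t_var diagonal value of `T`.
#' @param U,V inverse-gamma hyper-parameters for the random-intercept
#'   variance (shape `U`, scale `V`; density proportional to
#'   `x^-(U+1) exp(-V/x)`).
#' @param A,B optional overrides: fixed `A` (scalar or per-gene) and/or `B`.
#' @param span LOESS span passed through.
#' @return object of class `"nbglmm_priors"`: list with `M` (G x p), `Tmat`,
#'   `A` (per gene), `B`, `U`, `V`, `k`, `tau`, `trend`.
#' @export
default_priors <- function(counts, design, k = 2, t_var = 49, U = 0.01,
                           V = 0.01, A = NULL, B = NULL, span = 0.75) {
  counts <- validate_counts(counts)
  p <- design$p
  gm <- rowMeans(counts)
  if (any(gm == 0))
    stop("genes with zero mean count cannot be fit; apply filter_low_expression first")
  M <- matrix(0, nrow(counts), p,
              dimnames = list(rownames(counts), colnames(design$X)))
  M[, 1] <- log(gm)
  tau <- NA_real_; trend <- NULL
  if (is.null(A) || is.null(B)) {
    mlc <- rowMeans(log(cpm(counts) + 0.5))
    fitp <- fit_dispersion_prior(mom_dispersion(counts), mlc, k = k, span = span)
    if (is.null(A)) A <- fitp$A
    if (is.null(B)) B <- fitp$B
    tau <- fitp$tau; trend <- fitp$trend
  }
  if (length(A) == 1) A <- rep(A, nrow(counts))
  if (length(A) != nrow(counts)) stop("A must be scalar or one value per gene")
  if (B <= 0) stop("B must be positive")
  structure(list(M = M, Tmat = diag(t_var, p), A = as.numeric(A), B = B,
                 U = U, V = V, k = k, tau = tau, trend = trend),
            class = "nbglmm_priors")
}
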