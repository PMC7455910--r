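#' Gamma parameters from mode and standard deviation
#'
#' Solves `(shape - 1) * scale = mode` and `sqrt(shape) * scale = sd` for the
#' effect-size distribution. In `s = sqrt(shape)` the system reduces to
#' `sd * s^2 - mode * s - sd = 0`, whose positive root gives the solution.
#'
#' @param mode,sd positive reals.
#' @return named vector `c(shape, scale)`.
#' @export
es_gamma_params <- function(mode, sd) {
  if (mode <= 0 || sd <= 0) stop("mode and sd must be positive")
  s <- (mode + sqrt(mode^2 + 4 * sd^2)) / (2 * sd)
  c(shape = s^2, scale = sd / s)
}

#' Default per-gene parameter source for simulations
#'
#' Parametric stand-ins emulating bulk RNA-seq: mean log(CPM) normal around
#' `log(16)` (sd 1.5, truncated to `[log 1, log 4000]`) mapped to a baseline
#' log mean count through a nominal library size of 25 million; log
#' dispersion decreasing in mean log(CPM) with lognormal scatter (so the
#' mean-dispersion trend the empirical prior exploits is present); gamma
#' random-intercept variances (shape 2, scale 0.25).
#'
#' @param n_genes number of genes.
#' @return data.frame with `beta0`, `alpha`, `sigma2`, `mean_log_cpm`.
#' @export
default_parameter_source <- function(n_genes) {
  lcpm <- pmin(pmax(stats::rnorm(n_genes, log(16), 1.5), log(1)), log(4000))
  beta0 <- lcpm + log(25)  # CPM * 25e6 / 1e6
  lalpha <- -1.8 - 0.3 * (lcpm - log(16)) + stats::rnorm(n_genes, 0, 0.6)
  sigma2 <- stats::rgamma(n_genes, shape = 2, scale = 0.25)
  data.frame(beta0 = beta0, alpha = exp(lalpha), sigma2 = sigma2,
             mean_log_cpm = lcpm)
}

#' Simulate a paired two-group NB repeated-measures dataset
#'
#' Subjects are split evenly into control and treatment groups, each with a
#' baseline and a follow-up sample (4 * n_per_group samples). Per gene, the
#' log mean is `beta0 + beta1 I_trt + beta2 I_fup + beta3 I_trt I_fup + b_i`
#' with `b_i ~ N(0, sigma2)` shared by a subject's two samples and counts
#' drawn NB with dispersion `alpha`. Both group main effects are 0 for all
#' genes; the interaction `beta3` is 0 for `prop_null` of genes and
#' `+/-ES` otherwise, with ES drawn per gene from the gamma distribution
#' parameterized by mode and sd. Consequently the between-subject
#' (`beta1 + beta3`), within-subject (`beta2 + beta3`) and interaction
#' (`beta3`) contrasts share the same null/up/down labels.
#'
#' @param n_per_group subjects per group.
#' @param n_genes genes.
#' @param prop_null,prop_up,prop_down mixture over `beta3` (must sum to 1).
#' @param es_mode,es_sd effect-size gamma parameters (defaults: mode
#'   `log(2)`, sd 0.5).
#' @param parameter_source function `n -> data.frame(beta0, alpha, sigma2)`;
#'   default [default_parameter_source()].
#' @param libsize_log_sd sd of lognormal library-size variation entering the
#'   true offsets (default 0: equal depths, offsets 0).
#' @param all_null force `beta3 = 0` for every gene.
#' @param seed integer seed (R RNG).
#' @return list with `counts`, `metadata` (sample_id, subject_id, group,
#'   time), and `truth` (per gene: beta0..beta3, alpha, sigma2, label_between,
#'   label_within, label_interaction).
#' @export
simulate_dataset <- function(n_per_group, n_genes, prop_null = 0.8,
                             prop_up = 0.1, prop_down = 0.1,
                             es_mode = log(2), es_sd = 0.5,
                             parameter_source = default_parameter_source,
                             libsize_log_sd = 0, all_null = FALSE, seed = 1) {
  if (abs(prop_null + prop_up + prop_down - 1) > 1e-8)
    stop("proportions must sum to 1")
  set.seed(seed)
  n_subj <- 2L * n_per_group
  subjects <- sprintf("subj%02d", seq_len(n_subj))
  group <- rep(c("control", "treatment"), each = n_per_group)
  metadata <- data.frame(
    sample_id = paste0(rep(subjects, each = 2), "_", c("baseline", "followup")),
    subject_id = rep(subjects, each = 2),
    group = rep(group, each = 2),
    time = rep(c("baseline", "followup"), n_subj),
    stringsAsFactors = FALSE)

  pars <- parameter_source(n_genes)
  gp <- es_gamma_params(es_mode, es_sd)
  lab <- if (all_null) rep("null", n_genes) else
    sample(c("null", "up", "down"), n_genes, replace = TRUE,
           prob = c(prop_null, prop_up, prop_down))
  es <- stats::rgamma(n_genes, shape = gp["shape"], scale = gp["scale"])
  beta3 <- ifelse(lab == "null", 0, ifelse(lab == "up", es, -es))

  rho <- if (libsize_log_sd > 0)
    rep(stats::rnorm(n_subj * 2, 0, libsize_log_sd)) else numeric(nrow(metadata))
  i_trt <- as.numeric(metadata$group == "treatment")
  i_fup <- as.numeric(metadata$time == "followup")
  subj_idx <- match(metadata$subject_id, subjects)

  counts <- matrix(0, n_genes, nrow(metadata),
                   dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                   metadata$sample_id))
  for (g in seq_len(n_genes)) {
    b <- stats::rnorm(n_subj, 0, sqrt(pars$sigma2[g]))
    log_mu <- pars$beta0[g] + beta3[g] * i_trt * i_fup + b[subj_idx] + rho
    counts[g, ] <- stats::rnbinom(nrow(metadata), mu = exp(log_mu),
                                  size = 1 / pars$alpha[g])
  }
  truth <- data.frame(
    gene_id = rownames(counts), beta0 = pars$beta0, beta1 = 0, beta2 = 0,
    beta3 = beta3, alpha = pars$alpha, sigma2 = pars$sigma2,
    label_between = lab, label_within = lab, label_interaction = lab,
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Standard contrasts for the paired two-group design
#'
#' Between-subject (`beta1 + beta3`: group difference at follow-up),
#' within-subject (`beta2 + beta3`: change over time in the treatment group)
#' and interaction (`beta3`) contrasts for the
#' `~ group * time` design matrix.
#'
#' @return named list of length-4 numeric vectors.
#' @export
paired_design_contrasts <- function() {
  list(between = c(0, 1, 0, 1), within = c(0, 0, 1, 1),
       interaction = c(0, 0, 0, 1))
}

#' Type-1 error, FDR and power from results plus truth
#'
#' Type-1 error = FP / #null genes at unadjusted thresholds; FDR =
#' FP / #significant (0 when nothing is significant) and power = TP / #DE at
#' BH-adjusted thresholds. Genes with missing p-values (convergence
#' failures) are excluded from every denominator and counted.
#'
#' @param results fit results data.frame (`gene_id`, `contrast`, `p_contour`,
#'   `p_adj`).
#' @param truth truth data.frame from [simulate_dataset()].
#' @param contrast_labels named character vector mapping contrast name to the
#'   truth label column; default the [paired_design_contrasts()] names.
#' @param raw_thresholds,adj_thresholds significance thresholds.
#' @return data.frame: contrast, metric, threshold, value, n_missing.
#' @export
evaluate_testing_characteristics <- function(
    results, truth,
    contrast_labels = c(between = "label_between", within = "label_within",
                        interaction = "label_interaction"),
    raw_thresholds = c(1e-4, 0.01, 0.05, 0.1),
    adj_thresholds = c(0.01, 0.05, 0.1)) {
  out <- list()
  for (nm in names(contrast_labels)) {
    res <- results[results$contrast == nm, ]
    if (nrow(res) == 0) next
    lab <- truth[[contrast_labels[[nm]]]][match(res$gene_id, truth$gene_id)]
    if (anyNA(lab)) stop("results and truth are not aligned by gene")
    ok_raw <- !is.na(res$p_contour)
    ok_adj <- !is.na(res$p_adj)
    for (t in raw_thresholds) {
      is_null <- lab == "null" & ok_raw
      fp <- sum(res$p_contour[is_null] < t)
      out[[length(out) + 1]] <- data.frame(
        contrast = nm, metric = "type1_error", threshold = t,
        value = if (sum(is_null) > 0) fp / sum(is_null) else NA_real_,
        n_missing = sum(!ok_raw))
    }
    for (t in adj_thresholds) {
      sig <- ok_adj & res$p_adj < t
      fp <- sum(sig & lab == "null")
      tp <- sum(sig & lab != "null")
      nde <- sum(lab != "null" & ok_adj)
      out[[length(out) + 1]] <- data.frame(
        contrast = nm, metric = "fdr", threshold = t,
        value = if (sum(sig) > 0) fp / sum(sig) else 0,
        n_missing = sum(!ok_adj))
      out[[length(out) + 1]] <- data.frame(
        contrast = nm, metric = "power", threshold = t,
        value = if (nde > 0) tp / nde else NA_real_,
        n_missing = sum(!ok_adj))
    }
  }
  do.call(rbind, out)
}

#' Run the scaled simulation study end to end
#'
#' For each dataset: simulate a paired two-group experiment, filter, fit the
#' Bayesian NB GLMM with the three standard contrasts, evaluate testing
#' characteristics, then average the per-dataset metrics (unweighted).
#'
#' @param n_per_group,n_genes,n_datasets study dimensions.
#' @param n_iter,burn_in chain settings for the fits.
#' @param seed master seed; per-dataset simulation and fitting seeds derive
#'   from it.
#' @param all_null simulate with every effect null (calibration runs).
#' @param n_workers forwarded to [fit_nbglmm()].
#' @param ... forwarded to [simulate_dataset()].
#' @return list with `per_dataset` (list of metric tables), `average`
#'   (metrics averaged across datasets), `convergence_failure_rate`.
#' @export
run_simulation_study <- function(n_per_group, n_genes, n_datasets = 1,
                                 n_iter = 10000, burn_in = 0.1, seed = 1,
                                 all_null = FALSE, n_workers = 1, ...) {
  per <- vector("list", n_datasets)
  fail_rates <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    seed_d <- (seed + 104729L * d) %% .Machine$integer.max
    sim <- simulate_dataset(n_per_group, n_genes, all_null = all_null,
                            seed = seed_d, ...)
    fit <- fit_nbglmm(sim$counts, sim$metadata, ~ group * time,
                      random = "intercept",
                      contrasts = paired_design_contrasts(),
                      n_iter = n_iter, burn_in = burn_in, seed = seed_d,
                      n_workers = n_workers)
    per[[d]] <- evaluate_testing_characteristics(fit$results, sim$truth)
    fail_rates[d] <- mean(fit$convergence$failed)
  }
  avg <- per[[1]][, c("contrast", "metric", "threshold")]
  avg$value <- rowMeans(vapply(per, function(x) x$value, numeric(nrow(avg))))
  list(per_dataset = per, average = avg,
       convergence_failure_rate = mean(fail_rates))
}
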