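test_that("nb log-likelihood has the right closed forms and limits", {
  # y = 0: log pmf is -(1/alpha) log(1 + alpha mu)
  expect_equal(nb_loglik(0, 3.5, 0.7), -(1 / 0.7) * log(1 + 0.7 * 3.5))
  # Poisson limit
  expect_equal(nb_loglik(3, 2, 1e-8), dpois(3, 2, log = TRUE),
               tolerance = 1e-5)
  # agrees with the stock NB density in the size = 1/alpha parameterization
  ys <- c(0, 1, 7, 250)
  expect_equal(nb_loglik(ys, 5, 0.5),
               dnbinom(ys, size = 2, mu = 5, log = TRUE))
  # proper distribution: probabilities sum to one
  expect_equal(sum(exp(nb_loglik(0:2000, 5, 0.5))), 1, tolerance = 1e-8)
  expect_error(nb_loglik(1, -2, 0.5), "mu")
  expect_error(nb_loglik(1, 2, 0), "alpha")
})

test_that("WLS proposal hits the Poisson IRLS fixed point", {
  y <- c(4, 7, 9)
  des <- iid_design(3)
  # flat prior, Poisson limit, current state at the MLE: proposal centred
  # there with variance 1/sum(mu)
  pr <- wls_proposal(y, des, theta = log(mean(y)), alpha = 1e-8,
                     M = 0, Tmat = matrix(1e10))
  expect_equal(pr$mean, log(mean(y)), tolerance = 1e-6)
  expect_equal(pr$cov[1, 1], 1 / sum(y), tolerance = 1e-6)
})

test_that("iterated WLS proposal converges to the penalized-likelihood maximizer", {
  y <- c(1, 2, 3)
  des <- iid_design(3)
  alpha <- 0.5; M <- 0.3; Tmat <- matrix(2.0)
  th <- 0
  for (i in 1:200) th <- wls_proposal(y, des, th, alpha, 1, M, Tmat)$mean
  obj <- function(b)
    -(sum(nb_loglik(y, rep(exp(b), 3), alpha)) - 0.5 * (b - M)^2 / 2.0)
  opt <- stats::optimize(obj, c(-5, 5), tol = 1e-12)$minimum
  expect_equal(th, opt, tolerance = 1e-6)
})

test_that("WLS weights approach Poisson weights as alpha -> 0", {
  y <- c(3, 8)
  des <- iid_design(2)
  th <- 1.1
  mu <- exp(th)
  # with a flat prior the proposal precision is sum of weights; compare the
  # alpha -> 0 precision to sum(mu)
  pr <- wls_proposal(y, des, th, 1e-10, M = 0, Tmat = matrix(1e12))
  expect_equal(1 / pr$cov[1, 1], 2 * mu, tolerance = 1e-4)
})

test_that("sigma2 Gibbs draws follow the closed-form conditional", {
  # U = V = 0.01, I = 20, sum b^2 = 2 -> IG(10.01, 1.01), mean 1.01/9.01
  dr <- bnbglmm:::.draw_sigma2_cpp(100000, 0.01, 0.01, 2.0, 20, 42)
  truth <- 1.01 / 9.01
  ig_sd <- sqrt(1.01^2 / (9.01^2 * 8.01))
  expect_lt(abs(mean(dr) - truth), 3 * ig_sd / sqrt(100000))
  # all-zero random effects, I = 4 -> IG(2.01, 0.01), mean 0.01/1.01
  dr0 <- bnbglmm:::.draw_sigma2_cpp(200000, 0.01, 0.01, 0, 4, 43)
  expect_equal(mean(dr0), 0.01 / 1.01, tolerance = 0.01)
})

test_that("chains are deterministic and sized by the burn-in rule", {
  sim <- simulate_dataset(3, 5, seed = 9)
  md <- read_metadata(sim$metadata, sim$counts)
  des <- build_design(md, ~ group * time, "intercept")
  pr <- list(M = c(log(mean(sim$counts[1, ])), 0, 0, 0), Tmat = diag(49, 4),
             A = -1, B = 1, U = 0.01, V = 0.01)
  ch1 <- run_chain(sim$counts[1, ], des, pr, n_iter = 3000, seed = 11)
  ch2 <- run_chain(sim$counts[1, ], des, pr, n_iter = 3000, seed = 11)
  expect_identical(ch1$beta, ch2$beta)
  expect_identical(ch1$log_alpha, ch2$log_alpha)
  ch3 <- run_chain(sim$counts[1, ], des, pr, n_iter = 3000, seed = 12)
  expect_false(identical(ch1$beta, ch3$beta))

  # default 30,000 iterations with 10% burn-in retain 27,000 draws
  expect_equal(30000 - floor(30000 * 0.1), 27000)
  expect_equal(nrow(ch1$beta), 3000 - 300)
  expect_equal(length(ch1$accept_beta), 3000)

  # healthy acceptance on a well-behaved gene
  expect_gt(mean(ch1$accept_beta), 0.10)
  expect_gt(mean(ch1$accept_alpha), 0.10)
})

test_that("a zero-data chain reproduces its joint prior", {
  des0 <- empty_design(2)
  pr <- list(M = c(1, -2), Tmat = diag(c(4, 9)), A = -1, B = 0.25,
             U = 0.01, V = 0.01)
  ch <- run_chain(numeric(0), des0, pr, n_iter = 30000, seed = 13)
  # with no likelihood the WLS proposal is the prior itself and every
  # proposal is accepted, so draws are iid from N(M, T)
  expect_gt(mean(ch$accept_beta), 0.999)
  R <- nrow(ch$beta)
  for (j in 1:2) {
    expect_lt(abs(mean(ch$beta[, j]) - pr$M[j]),
              3 * sqrt(pr$Tmat[j, j] / R))
    expect_equal(sd(ch$beta[, j]), sqrt(pr$Tmat[j, j]), tolerance = 0.03)
  }
  expect_lt(abs(mean(ch$log_alpha) - pr$A), 4 * mcse_mean(ch$log_alpha))
  expect_equal(sd(ch$log_alpha), 0.5, tolerance = 0.03)
})

test_that("per-gene seeds depend on the id, not position or worker count", {
  expect_identical(gene_seed(1, "geneA"), gene_seed(1, "geneA"))
  expect_false(identical(gene_seed(1, "geneA"), gene_seed(1, "geneB")))
  expect_false(identical(gene_seed(1, "geneA"), gene_seed(2, "geneA")))

  sim <- simulate_dataset(3, 10, seed = 15)
  md <- read_metadata(sim$metadata, sim$counts)
  des <- build_design(md, ~ group * time, "intercept")
  pri <- default_priors(sim$counts, des, A = -1, B = 1)
  f1 <- fit_all_genes(sim$counts, des, pri, n_iter = 1500, master_seed = 4)
  f4 <- fit_all_genes(sim$counts, des, pri, n_iter = 1500, master_seed = 4,
                      n_workers = 4)
  expect_identical(f1$summaries, f4$summaries)

  # fitting a subset leaves each gene's results untouched
  sub <- fit_all_genes(sim$counts[c(3, 7), ], des,
                       list(M = pri$M[c(3, 7), , drop = FALSE],
                            Tmat = pri$Tmat, A = pri$A[c(3, 7)], B = pri$B,
                            U = pri$U, V = pri$V),
                       n_iter = 1500, master_seed = 4)
  expect_identical(sub$summaries[[1]], f1$summaries[[3]])

  # empty input gives empty output
  f0 <- fit_all_genes(sim$counts[0, ], des,
                      list(M = pri$M[0, , drop = FALSE], Tmat = pri$Tmat,
                           A = numeric(0), B = pri$B, U = pri$U, V = pri$V),
                      n_iter = 1500, master_seed = 4)
  expect_length(f0$summaries, 0)
})

test_that("posterior widths reflect dispersion uncertainty", {
  # pinning alpha at the posterior median removes the dispersion-uncertainty
  # contribution, so the free-dispersion posterior of beta must be at least
  # as wide
  set.seed(21)
  y <- rnbinom(8, mu = 30, size = 1)
  des <- iid_design(8)
  pr_free <- list(M = log(mean(y)), Tmat = matrix(49), A = 0, B = 1,
                  U = 0.01, V = 0.01)
  ch_free <- run_chain(y, des, pr_free, n_iter = 60000, seed = 31)
  pr_fixed <- pr_free
  pr_fixed$A <- median(ch_free$log_alpha)
  pr_fixed$B <- 1e-10
  ch_fixed <- run_chain(y, des, pr_fixed, n_iter = 60000, seed = 131)
  expect_gte(sd(ch_free$beta[, 1]), sd(ch_fixed$beta[, 1]))
})

test_that("differential expression calls are stable across master seeds", {
  sim <- simulate_dataset(5, 150, seed = 19)
  fits <- lapply(c(101, 202), function(s)
    fit_nbglmm(sim$counts, sim$metadata, ~ group * time,
               contrasts = paired_design_contrasts(), n_iter = 4000,
               seed = s))
  r1 <- fits[[1]]$results[fits[[1]]$results$contrast == "interaction", ]
  r2 <- fits[[2]]$results[fits[[2]]$results$contrast == "interaction", ]
  call1 <- !is.na(r1$p_adj) & r1$p_adj < 0.05
  call2 <- !is.na(r2$p_adj) & r2$p_adj < 0.05
  expect_gte(mean(call1 == call2), 0.95)
  expect_gte(cor(r1$p_contour, r2$p_contour, method = "spearman"), 0.9)
})
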