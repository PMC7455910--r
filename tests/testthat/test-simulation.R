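test_that("effect-size gamma parameters solve the mode/sd system", {
  gp <- es_gamma_params(log(2), 0.5)
  expect_equal(unname((gp["shape"] - 1) * gp["scale"]), log(2),
               tolerance = 1e-9)
  expect_equal(unname(sqrt(gp["shape"]) * gp["scale"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(gp["shape"]), 3.6477, tolerance = 1e-4)
  expect_equal(unname(gp["scale"]), 0.2618, tolerance = 1e-4)
  set.seed(3)
  draws <- rgamma(1e6, shape = gp["shape"], scale = gp["scale"])
  expect_lt(abs(sd(draws) - 0.5), 3 * 0.5 / sqrt(2 * 1e6) + 0.002)
  expect_error(es_gamma_params(-1, 0.5), "positive")
})

test_that("simulated counts have the negative binomial mean-variance law", {
  # constant parameters, no random intercept: 10,000 iid samples per cell
  src <- function(n) data.frame(beta0 = rep(log(100), n), alpha = 0.4,
                                sigma2 = 0)
  sim <- simulate_dataset(2500, 1, parameter_source = src, all_null = TRUE,
                          seed = 10)
  y <- as.numeric(sim$counts[1, ])
  mu <- 100
  v <- mu + 0.4 * mu^2
  expect_lt(abs(mean(y) - mu), 3 * sqrt(v / length(y)))
  expect_lt(abs(var(y) - v), 4 * v * sqrt(2 / length(y)))
})

test_that("the mean structure follows the two-group paired design", {
  src <- function(n) data.frame(beta0 = rep(log(200), n), alpha = 1e-6,
                                sigma2 = 0)
  sim <- simulate_dataset(4000, 1, parameter_source = src,
                          prop_null = 0, prop_up = 1, prop_down = 0,
                          seed = 12)
  b3 <- sim$truth$beta3[1]
  md <- sim$metadata
  y <- as.numeric(sim$counts[1, ])
  cell <- function(g, t) mean(y[md$group == g & md$time == t])
  # only the treatment/follow-up cell moves, by exp(beta3)
  expect_equal(cell("control", "baseline"), 200, tolerance = 0.05)
  expect_equal(cell("treatment", "baseline"), 200, tolerance = 0.05)
  expect_equal(cell("control", "followup"), 200, tolerance = 0.05)
  expect_equal(cell("treatment", "followup") / cell("treatment", "baseline"),
               exp(b3), tolerance = 0.05)
  expect_gt(b3, 0)
})

test_that("null/up/down labels follow the configured proportions", {
  sim <- simulate_dataset(3, 15000, seed = 14)
  tab <- table(sim$truth$label_interaction) / 15000
  se3 <- 3 * sqrt(0.8 * 0.2 / 15000)
  expect_lt(abs(tab[["null"]] - 0.8), se3)
  expect_lt(abs(tab[["up"]] - 0.1), se3)
  expect_lt(abs(tab[["down"]] - 0.1), se3)
  # signs consistent with labels
  expect_true(all(sim$truth$beta3[sim$truth$label_interaction == "up"] > 0))
  expect_true(all(sim$truth$beta3[sim$truth$label_interaction == "down"] < 0))
  expect_true(all(sim$truth$beta3[sim$truth$label_interaction == "null"] == 0))
  expect_true(all(sim$truth$beta1 == 0) && all(sim$truth$beta2 == 0))
})

test_that("between-subject variability grows with the random-intercept variance", {
  vars <- sapply(c(0, 0.25, 1, 4), function(s2) {
    src <- function(n) data.frame(beta0 = rep(log(500), n), alpha = 1e-6,
                                  sigma2 = s2)
    sim <- simulate_dataset(40, 1, parameter_source = src, all_null = TRUE,
                            seed = 16)
    md <- sim$metadata
    subj_means <- tapply(log(as.numeric(sim$counts[1, ]) + 1), md$subject_id,
                         mean)
    var(subj_means)
  })
  expect_true(all(diff(vars) > 0))
})

test_that("datasets are reproducible from the seed", {
  s1 <- simulate_dataset(3, 20, seed = 5)
  s2 <- simulate_dataset(3, 20, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_dataset(3, 20, seed = 6)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("testing characteristics implement the standard confusion ratios", {
  # 90 null / 10 DE; 5 false and 8 true calls at every threshold
  truth <- data.frame(gene_id = paste0("g", 1:100),
                      label_interaction = rep(c("null", "up"), c(90, 10)),
                      label_between = rep(c("null", "up"), c(90, 10)),
                      label_within = rep(c("null", "up"), c(90, 10)))
  p <- rep(1, 100)
  p[c(1:5, 91:98)] <- 1e-6  # 5 FP + 8 TP
  results <- data.frame(gene_id = truth$gene_id, contrast = "interaction",
                        p_contour = p, p_adj = p)
  m <- evaluate_testing_characteristics(
    results, truth, contrast_labels = c(interaction = "label_interaction"))
  t1 <- m$value[m$metric == "type1_error" & m$threshold == 0.05]
  expect_equal(t1, 5 / 90)
  expect_equal(m$value[m$metric == "fdr" & m$threshold == 0.05], 5 / 13)
  expect_equal(m$value[m$metric == "power" & m$threshold == 0.05], 0.8)

  # no rejections: all three metrics are zero at every threshold
  none <- results; none$p_contour <- 1; none$p_adj <- 1
  m0 <- evaluate_testing_characteristics(
    none, truth, contrast_labels = c(interaction = "label_interaction"))
  expect_true(all(m0$value == 0))

  # perfect calls
  perfect <- results
  perfect$p_contour <- perfect$p_adj <- ifelse(truth$label_interaction == "up",
                                               1e-6, 1)
  mp <- evaluate_testing_characteristics(
    perfect, truth, contrast_labels = c(interaction = "label_interaction"))
  expect_equal(mp$value[mp$metric == "fdr" & mp$threshold == 0.05], 0)
  expect_equal(mp$value[mp$metric == "power" & mp$threshold == 0.05], 1)

  # missing p-values drop out of the denominators and are counted
  miss <- results
  miss$p_contour[1] <- miss$p_adj[1] <- NA  # one of the FPs
  mm <- evaluate_testing_characteristics(
    miss, truth, contrast_labels = c(interaction = "label_interaction"))
  expect_equal(mm$value[mm$metric == "type1_error" & mm$threshold == 0.05],
               4 / 89)
  expect_equal(unique(mm$n_missing), 1)
})

test_that("the simulation study driver is deterministic and complete", {
  st1 <- run_simulation_study(3, 40, n_datasets = 2, n_iter = 1200, seed = 8)
  st2 <- run_simulation_study(3, 40, n_datasets = 2, n_iter = 1200, seed = 8)
  expect_identical(st1$average, st2$average)
  expect_length(st1$per_dataset, 2)
  expect_setequal(unique(st1$average$contrast),
                  c("between", "within", "interaction"))
  expect_setequal(unique(st1$average$metric), c("type1_error", "fdr", "power"))
  expect_true(all(st1$average$value >= 0 & st1$average$value <= 1, na.rm = TRUE))
  expect_gte(st1$convergence_failure_rate, 0)
})
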