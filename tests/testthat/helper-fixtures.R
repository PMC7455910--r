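# Small fixtures built in code, shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10, 20, 30,
                5,  0, 15), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  m
}

# paired two-group metadata for 2n subjects, two samples each
paired_metadata <- function(n_per_group) {
  n_subj <- 2L * n_per_group
  subjects <- sprintf("subj%02d", seq_len(n_subj))
  data.frame(
    sample_id = paste0(rep(subjects, each = 2), "_", c("baseline", "followup")),
    subject_id = rep(subjects, each = 2),
    group = rep(rep(c("control", "treatment"), each = n_per_group), each = 2),
    time = rep(c("baseline", "followup"), n_subj),
    stringsAsFactors = FALSE)
}

# independent-sample design (no clustering) over the given counts
iid_design <- function(n, fixed = ~ 1, random = "none") {
  md <- data.frame(sample_id = paste0("s", seq_len(n)),
                   subject_id = paste0("u", seq_len(n)),
                   stringsAsFactors = FALSE)
  build_design(md, fixed, random)
}

# zero-observation design used to sample from the prior (no likelihood term)
empty_design <- function(p) {
  structure(list(
    X = matrix(numeric(0), 0, p,
               dimnames = list(NULL, paste0("x", seq_len(p) - 1))),
    q = 0L, subject = NULL, offsets = numeric(0), p = as.integer(p),
    n_subjects = 0L, n_samples = 0L), class = "nbglmm_design")
}

# log joint posterior on a (beta0, log alpha) grid for an intercept-only
# NB model without random effects; returns normalized cell probabilities
grid_posterior_q0 <- function(y, bg, lg, M, t_var, A, B) {
  out <- matrix(0, length(bg), length(lg))
  mu <- exp(bg)
  for (j in seq_along(lg)) {
    r <- exp(-lg[j])
    ll <- 0
    for (yy in y)
      ll <- ll + lgamma(yy + r) - lgamma(r) - lgamma(yy + 1) +
        r * log(r / (r + mu)) + yy * log(mu / (r + mu))
    out[, j] <- ll - 0.5 * (bg - M)^2 / t_var - 0.5 * (lg[j] - A)^2 / B
  }
  w <- exp(out - max(out))
  w / sum(w)
}

grid_moments <- function(w, grid_vals, margin) {
  g <- apply(w, margin, sum)
  m <- sum(g * grid_vals)
  list(mean = m, sd = sqrt(sum(g * grid_vals^2) - m^2))
}

# Monte Carlo standard error of a chain mean, accounting for autocorrelation
mcse_mean <- function(chain) {
  sqrt(bnbglmm:::spectrum0_ar(chain) / length(chain))
}

# batch-based Monte Carlo standard error of a chain standard deviation
mcse_sd <- function(chain, n_batches = 20) {
  b <- split(chain, cut(seq_along(chain), n_batches, labels = FALSE))
  stats::sd(vapply(b, stats::sd, 0)) / sqrt(n_batches)
}
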