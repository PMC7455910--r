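#' Build the fixed/random design for the NB mixed model
#'
#' Constructs the S x p fixed-effect matrix `X` from a formula over the
#' metadata covariates (intercept first; character covariates become factors
#' with levels sorted so the reference level is the lexicographically first),
#' the subject index for the optional random intercept, and the per-sample
#' offsets entering the linear predictor.
#'
#' @param metadata aligned metadata from [read_metadata()].
#' @param fixed one-sided formula over metadata columns, e.g.
#'   `~ group * time`.
#' @param random `"intercept"` for one random intercept per subject (q = 1) or
#'   `"none"` for a fixed-effects NB GLM (q = 0).
#' @param offsets per-sample offsets on the natural-log scale (default all 0;
#'   usually `log` size factors from [median_of_ratios_size_factors()]).
#' @return an object of class `"nbglmm_design"`: list with `X`, `q`,
#'   `subject` (factor, `NULL` when q = 0), `offsets`, and dimensions `p`,
#'   `n_subjects`, `n_samples`.
#' @export
build_design <- function(metadata, fixed, random = c("intercept", "none"),
                         offsets = NULL) {
  random <- match.arg(random)
  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(metadata))
  if (length(miss) > 0)
    stop("variables in fixed formula not found in metadata: ",
         paste(miss, collapse = ", "))
  df <- metadata
  for (v in vars)
    if (is.character(df[[v]]) || is.logical(df[[v]]))
      df[[v]] <- factor(df[[v]], levels = sort(unique(df[[v]])))
  X <- stats::model.matrix(fixed, data = df)
  attr(X, "assign") <- NULL
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  if (is.null(offsets)) offsets <- rep(0, nrow(df))
  if (length(offsets) != nrow(df) || !all(is.finite(offsets)))
    stop("offsets must be ", nrow(df), " finite values")
  subject <- NULL
  if (random == "intercept") {
    subject <- factor(df$subject_id, levels = unique(df$subject_id))
    if (any(table(subject) < 1)) stop("every subject needs at least one sample")
  }
  structure(list(
    X = X, q = if (random == "intercept") 1L else 0L, subject = subject,
    offsets = as.numeric(offsets), p = ncol(X),
    n_subjects = if (is.null(subject)) 0L else nlevels(subject),
    n_samples = nrow(X)
  ), class = "nbglmm_design")
}

# combined design [X | Z] with Z the subject indicator block (q = 1)
combined_design <- function(design) {
  if (design$q == 0L) return(design$X)
  Z <- stats::model.matrix(~ 0 + design$subject)
  colnames(Z) <- paste0("b:", levels(design$subject))
  cbind(design$X, Z)
}

#' @export
print.nbglmm_design <- function(x, ...) {
  cat(sprintf("NB GLMM design: %d samples, p = %d fixed effects, q = %d%s\n",
              x$n_samples, x$p, x$q,
              if (x$q == 1) sprintf(" (%d subjects)", x$n_subjects) else ""))
  invisible(x)
}
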