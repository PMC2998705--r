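# Redundancy-variate calibration: the linear combination of logcontrast
# gene-expression measures maximizing correlation with known age, and the
# regression of that variate on age. With a univariate response the first
# redundancy variate has a closed form: the fitted values of the least
# squares regression of (centered) age on the standardized gene matrix,
# rescaled to unit variance. The achieved correlation is the multiple
# correlation R of age on the genes.

# Core fitting engine, shared by the user-facing fits, the bootstrap and
# LOOCV. Deliberately lean: called O(10^5-10^6) times per validation run.
# Returns NULL for degenerate inputs (constant age, no age association)
# instead of raising, so resampling loops can redraw cheaply.
#
# Rank-deficient normal equations (e.g. noise-free data where every gene is
# an exact linear function of age) are solved by SVD minimum-norm least
# squares: the fitted variate -- the only quantity that matters downstream --
# is invariant to which solution of the normal equations is taken.
.chain_fit <- function(X, age, tol = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = n)
  s <- sqrt(.colSums(Xc * Xc, n, p) / (n - 1))
  zero_col <- s <= 0
  s1 <- ifelse(zero_col, 1, s)
  Z <- Xc / rep(s1, each = n)
  if (any(zero_col)) Z[, zero_col] <- 0
  abar <- sum(age) / n
  ac <- age - abar
  ssa <- sum(ac * ac)
  if (ssa <= 0) return(NULL)                       # constant age
  G <- crossprod(Z)
  b <- crossprod(Z, ac)
  w0 <- tryCatch(solve(G, b), error = function(e) NULL)
  rank <- p
  if (is.null(w0) || !all(is.finite(w0))) {
    sv <- svd(G)
    keep <- sv$d > tol * max(sv$d, tol)
    if (!any(keep)) return(NULL)                   # all gene columns constant
    rank <- sum(keep)
    w0 <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep])
  }
  v0 <- Z %*% w0
  ssv0 <- sum(v0 * v0)
  if (ssv0 <= tol) return(NULL)                    # no age association
  scale_v <- sqrt(ssv0 / (n - 1))
  w <- as.numeric(w0) / scale_v
  v <- as.numeric(v0) / scale_v
  cov_va <- sum(v * ac)
  if (cov_va < 0) {                                # sign convention corr(v, age) >= 0
    w <- -w
    v <- -v
    cov_va <- -cov_va
  }
  r <- cov_va / sqrt((n - 1) * ssa)
  beta <- cov_va / ssa
  alpha <- -beta * abar                            # training variate has mean 0
  list(mu = mu, s = s1, w = w, v = v, canonical_correlation = r,
       alpha = alpha, beta = beta, rank = rank,
       residuals = v - alpha - beta * age)
}

.as_logcontrast_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  .check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix of logcontrast values")
  .check(all(is.finite(X)), "X contains missing or non-finite values", "mozage_data_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("gene", seq_len(ncol(X)))
  X
}

#' Fit the redundancy variate of gene expression on age
#'
#' Finds the linear combination of standardized logcontrast measures that
#' maximizes the Pearson correlation with known age (the first redundancy
#' variate of a canonical correlation analysis with a univariate response).
#' Each gene column is standardized with its training mean and SD; the
#' weights are rescaled so the training variate has mean 0 and variance 1,
#' and the sign is fixed so that the variate correlates positively with age.
#' The achieved correlation equals the multiple correlation R of age on the
#' gene matrix.
#'
#' @param X numeric matrix (or data frame) of logcontrast values,
#'   individuals in rows, genes in columns (see [logcontrast()]).
#' @param ages numeric vector of known ages in days, one per row of `X`.
#' @return An object of class `redundancy_model`: a list with elements
#'   `gene_ids`, `mu`, `s` (standardization constants, cycles), `w`
#'   (loadings applied to standardized values), `canonical_correlation`,
#'   `variate` (training scores), `n`.
#' @details Exactly collinear gene columns (which arise, e.g., in noise-free
#'   simulated data where every gene is a linear function of age) are
#'   tolerated: the minimum-norm least squares solution is used and a
#'   warning names the dependent columns. Constant gene columns and
#'   constant ages are errors.
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_config(seed = 1))
#' lc <- logcontrast(aggregate_replicates(sim$ct))
#' fem <- sim$samples$sex == "F"
#' fit_redundancy(lc[sim$samples$sample_id[fem], ], sim$samples$age_days[fem])
#' @seealso [fit_calibration()], [score_variate()], [rank_genes()]
#' @export
fit_redundancy <- function(X, ages) {
  X <- .as_logcontrast_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  .check(is.numeric(ages) && length(ages) == n && all(is.finite(ages)),
         "ages must be a finite numeric vector with one entry per row of X")
  .check(n > p + 1, sprintf("need n > p + 1 individuals (n = %d, p = %d)", n, p),
         "mozage_model_error")
  if (stats::var(ages) == 0) .err("ages are constant; no calibration is possible",
                                  "mozage_model_error")
  csd <- apply(X, 2, stats::sd)
  if (any(csd == 0)) {
    .err(sprintf("constant gene column(s): %s",
                 paste(colnames(X)[csd == 0], collapse = ", ")),
         "mozage_model_error")
  }
  qrz <- qr(scale(X))
  if (qrz$rank < p) {
    dep <- colnames(X)[qrz$pivot[(qrz$rank + 1L):p]]
    warning(sprintf(
      "gene columns are collinear (rank %d < %d); minimum-norm solution used; dependent column(s): %s",
      qrz$rank, p, paste(dep, collapse = ", ")))
  }
  fit <- .chain_fit(X, ages)
  if (is.null(fit)) .err("no association between genes and age (degenerate fit)",
                         "mozage_model_error")
  structure(
    list(gene_ids = colnames(X), mu = unname(fit$mu), s = unname(fit$s),
         w = unname(fit$w), canonical_correlation = fit$canonical_correlation,
         variate = fit$v, n = n),
    class = "redundancy_model")
}

#' Score individuals on a fitted redundancy variate
#'
#' Computes `v = sum_g w_g * (x_g - mu_g) / s_g` using the *training*
#' standardization constants, for one sample (named vector) or several
#' (matrix with genes in columns).
#'
#' @param model a [fit_redundancy()] model (or the `redundancy` element of
#'   an `age_model`).
#' @param x named numeric vector of one individual's logcontrast values, or
#'   a matrix/data frame with one row per individual and the model's genes
#'   in columns.
#' @return numeric vector of variate scores.
#' @export
score_variate <- function(model, x) {
  if (inherits(model, "age_model")) model <- model$redundancy
  .check(inherits(model, "redundancy_model"), "model must be a redundancy_model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing_g <- setdiff(model$gene_ids, colnames(x))
    if (length(missing_g) > 0) {
      .err(sprintf("missing gene value(s): %s", paste(missing_g, collapse = ", ")),
           "mozage_data_error")
    }
    x <- x[, model$gene_ids, drop = FALSE]
  } else {
    .check(ncol(x) == length(model$gene_ids),
           "unnamed input must have one column per model gene", "mozage_data_error")
  }
  .check(all(is.finite(x)), "missing gene value(s) in input", "mozage_data_error")
  z <- (x - rep(model$mu, each = nrow(x))) / rep(model$s, each = nrow(x))
  as.numeric(z %*% model$w)
}

#' Fit the calibration line of the redundancy variate on age
#'
#' Ordinary least squares fit `v = alpha + beta * age` of the training
#' variate scores on known age. Under the sign convention of
#' [fit_redundancy()] the slope is positive, and the coefficient of
#' determination equals the squared canonical correlation.
#'
#' @param variates numeric vector of training variate scores (from
#'   [fit_redundancy()]'s `variate` element or [score_variate()]).
#' @param ages numeric vector of known ages (days).
#' @param redundancy the fitted `redundancy_model`.
#' @param sex_label optional label ("F"/"M") recording which sex the model
#'   was calibrated for; sexes are calibrated separately.
#' @return An object of class `age_model`: list with `redundancy`, `alpha`
#'   (variate units), `beta` (variate units per day), `r_squared`, `n`,
#'   `sex_label`.
#' @export
fit_calibration <- function(variates, ages, redundancy, sex_label = NA_character_) {
  .check(inherits(redundancy, "redundancy_model"), "redundancy must be a redundancy_model")
  n <- length(variates)
  .check(is.numeric(ages) && length(ages) == n && all(is.finite(ages)),
         "ages must match variates in length")
  if (stats::var(ages) == 0) .err("ages are constant; calibration undefined",
                                  "mozage_model_error")
  abar <- mean(ages)
  ac <- ages - abar
  beta <- sum(variates * ac) / sum(ac * ac)
  alpha <- mean(variates) - beta * abar
  r2 <- stats::cor(variates, ages)^2
  structure(
    list(redundancy = redundancy, alpha = alpha, beta = beta,
         r_squared = r2, n = n, sex_label = sex_label),
    class = "age_model")
}

#' Fit the full age-calibration model in one call
#'
#' Convenience chain: [fit_redundancy()] then [fit_calibration()] on the
#' training variate.
#'
#' @inheritParams fit_redundancy
#' @param sex_label optional sex label carried by the model.
#' @return an `age_model` (see [fit_calibration()]).
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_config(seed = 42))
#' lc <- logcontrast(aggregate_replicates(sim$ct))
#' fem <- sim$samples[sim$samples$sex == "F", ]
#' m <- fit_age_model(lc[fem$sample_id, ], fem$age_days, sex_label = "F")
#' m$r_squared
#' @export
fit_age_model <- function(X, ages, sex_label = NA_character_) {
  red <- fit_redundancy(X, ages)
  fit_calibration(red$variate, ages, red, sex_label = sex_label)
}

#' Rank genes by loading magnitude
#'
#' Orders the model's genes by decreasing absolute loading `|w_g|`; more
#' informative genes have larger absolute loadings (of either sign,
#' depending on the direction of the gene's relationship with age). Ties
#' are broken by lexicographic gene id.
#'
#' @param model a `redundancy_model` or `age_model`.
#' @return data frame with columns `gene_id`, `loading`, ordered by
#'   decreasing `abs(loading)`.
#' @export
rank_genes <- function(model) {
  if (inherits(model, "age_model")) model <- model$redundancy
  .check(inherits(model, "redundancy_model"), "model must be a fitted redundancy_model")
  ord <- order(-abs(model$w), model$gene_ids)
  data.frame(gene_id = model$gene_ids[ord], loading = model$w[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the most informative genes and refit
#'
#' Fits the redundancy model on all genes, keeps the `k` genes with the
#' largest absolute loadings, and refits the calibration model on that
#' subset (the strategy used to reduce the nine qPCR candidates to the
#' four-transcript assay panel).
#'
#' @inheritParams fit_redundancy
#' @param k number of genes to retain (1 <= k <= ncol(X)).
#' @param sex_label optional sex label for the refitted model.
#' @return list with `gene_ids` (the selected subset, in loading order) and
#'   `model` (the refitted `age_model`).
#' @export
select_informative_genes <- function(X, ages, k, sex_label = NA_character_) {
  X <- .as_logcontrast_matrix(X)
  .check(.is_count(k) && k <= ncol(X),
         sprintf("k must be an integer in [1, %d]", ncol(X)))
  full <- fit_redundancy(X, ages)
  keep <- rank_genes(full)$gene_id[seq_len(k)]
  list(gene_ids = keep,
       model = fit_age_model(X[, keep, drop = FALSE], ages, sex_label = sex_label))
}

#' @export
print.redundancy_model <- function(x, ...) {
  cat("Redundancy variate model\n")
  cat(sprintf("  genes: %s\n", paste(x$gene_ids, collapse = ", ")))
  cat(sprintf("  canonical correlation: %.4f  (n = %d)\n",
              x$canonical_correlation, x$n))
  cat("  loadings (standardized):\n")
  print(round(stats::setNames(x$w, x$gene_ids), 4))
  invisible(x)
}

#' @export
print.age_model <- function(x, ...) {
  cat("Age calibration model")
  if (!is.na(x$sex_label)) cat(sprintf(" (sex: %s)", x$sex_label))
  cat("\n")
  cat(sprintf("  variate = %.4f + %.4f * age,  R^2 = %.4f,  n = %d\n",
              x$alpha, x$beta, x$r_squared, x$n))
  cat(sprintf("  genes: %s\n", paste(x$redundancy$gene_ids, collapse = ", ")))
  invisible(x)
}
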