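# Microarray screening: normalization chain, raw-signal filter, per-gene
# two-way ANOVA with BH correction, age-only selection, and the
# correlation / fold-change candidate filters.

.validate_expr <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  .check(is.matrix(expr) && is.numeric(expr) && length(expr) > 0,
         "expression matrix must be a non-empty numeric matrix (genes x arrays)",
         "mozage_input_error")
  .check(!is.null(rownames(expr)) && !anyDuplicated(rownames(expr)),
         "expression matrix needs unique gene ids as rownames", "mozage_input_error")
  .check(!is.null(colnames(expr)) && !anyDuplicated(colnames(expr)),
         "expression matrix needs unique array ids as colnames", "mozage_input_error")
  .check(all(is.finite(expr)), "expression matrix contains non-finite values",
         "mozage_input_error")
  expr
}

.validate_array_meta <- function(expr, meta) {
  .check(is.data.frame(meta) && all(c("array_id", "age_days", "sex") %in% names(meta)),
         "array metadata needs columns array_id, age_days, sex", "mozage_input_error")
  missing_m <- setdiff(colnames(expr), meta$array_id)
  .check(length(missing_m) == 0,
         sprintf("no metadata for array(s): %s", paste(missing_m, collapse = ", ")),
         "mozage_input_error")
  .check(!anyDuplicated(meta$array_id), "duplicated array_id in metadata",
         "mozage_input_error")
  meta[match(colnames(expr), meta$array_id), , drop = FALSE]
}

#' Filter genes on raw signal
#'
#' Computes the given percentile of all raw fluorescence values pooled
#' across the whole matrix and retains a gene iff its raw value strictly
#' exceeds that cutoff in at least `min_arrays_above` arrays (GeneSpring
#' style "at least one sample" semantics by default). The screening default
#' excludes data at or below the 20th percentile.
#'
#' @param expr raw expression matrix, genes x arrays.
#' @param percentile pooled percentile in (0, 100) defining the cutoff
#'   (default 20).
#' @param min_arrays_above minimum number of arrays in which a gene must
#'   exceed the cutoff (default 1).
#' @return character vector of retained gene ids, input order preserved.
#' @export
filter_low_signal <- function(expr, percentile = 20, min_arrays_above = 1) {
  expr <- .validate_expr(expr)
  .check(.is_number(percentile) && percentile > 0 && percentile < 100,
         "percentile must lie strictly between 0 and 100")
  .check(.is_count(min_arrays_above), "min_arrays_above must be an integer >= 1")
  cutoff <- stats::quantile(as.numeric(expr), percentile / 100, names = FALSE)
  keep <- rowSums(expr > cutoff) >= min_arrays_above
  rownames(expr)[keep]
}

#' Normalize raw fluorescence signals
#'
#' The one-colour processing chain: raw values below 1.0 are thresholded to
#' 1.0; values are log2-transformed; each array is shifted by its own 75th
#' percentile of log2 values (percentile-shift normalization, removing
#' array-scale differences); each gene is baseline-transformed by
#' subtracting its median across all arrays.
#'
#' @param expr raw expression matrix (non-negative fluorescence), genes x
#'   arrays.
#' @return normalized log2-scale matrix of the same shape.
#' @export
normalize_signals <- function(expr) {
  expr <- .validate_expr(expr)
  .check(all(expr >= 0), "raw fluorescence must be non-negative", "mozage_input_error")
  m <- log2(pmax(expr, 1))
  m <- sweep(m, 2, apply(m, 2, stats::quantile, probs = 0.75, names = FALSE))
  sweep(m, 1, apply(m, 1, stats::median))
}

# Balanced-design classical two-way decomposition, vectorized over genes.
# Y: genes x arrays; age/sex: factors of length ncol(Y).
.anova_balanced <- function(Y, age, sex) {
  N <- ncol(Y)
  a <- nlevels(age)
  b <- nlevels(sex)
  cell <- interaction(age, sex, drop = FALSE, lex.order = TRUE)
  n_cell <- N / (a * b)
  grand <- rowMeans(Y)
  agg <- function(f) {
    idx <- split(seq_len(N), f)
    vapply(idx, function(j) rowMeans(Y[, j, drop = FALSE]), numeric(nrow(Y)))
  }
  m_age <- agg(age)                       # genes x a
  m_sex <- agg(sex)                       # genes x b
  m_cell <- agg(cell)                     # genes x (a*b), age fastest? lex.order=TRUE -> age varies slowest
  ss_age <- (N / a) * rowSums((m_age - grand)^2)
  ss_sex <- (N / b) * rowSums((m_sex - grand)^2)
  # expected cell mean under additivity, matching m_cell's column order
  lev <- strsplit(colnames(m_cell), ".", fixed = TRUE)
  ai <- match(vapply(lev, `[`, "", 1), levels(age))
  bi <- match(vapply(lev, `[`, "", 2), levels(sex))
  add <- m_age[, ai, drop = FALSE] + m_sex[, bi, drop = FALSE] - grand
  ss_int <- n_cell * rowSums((m_cell - add)^2)
  fitted_cell <- m_cell[, match(as.character(cell), colnames(m_cell)), drop = FALSE]
  ss_res <- rowSums((Y - fitted_cell)^2)
  df <- c(age = a - 1, sex = b - 1, int = (a - 1) * (b - 1), res = N - a * b)
  list(ss = cbind(age = ss_age, sex = ss_sex, interaction = ss_int, residual = ss_res),
       df = df)
}

.anova_pvalues <- function(ss, df, total_scale) {
  ms_res <- ss[, "residual"] / df[["res"]]
  eff <- c("age", "sex", "interaction")
  dfe <- c(df[["age"]], df[["sex"]], df[["int"]])
  p <- matrix(NA_real_, nrow(ss), 3, dimnames = list(NULL, eff))
  tol <- 1e-12 * pmax(total_scale, 1)
  for (k in seq_along(eff)) {
    Fv <- (ss[, eff[k]] / dfe[k]) / ms_res
    pk <- stats::pf(Fv, dfe[k], df[["res"]], lower.tail = FALSE)
    # residual variance numerically zero: exact effect -> p = 0, no effect -> p = 1
    zero_res <- ss[, "residual"] <= tol
    pk[zero_res & ss[, eff[k]] > tol] <- 0
    pk[zero_res & ss[, eff[k]] <= tol] <- 1
    p[, k] <- pk
  }
  # fully degenerate genes (no variation at all): p = 1 everywhere
  degen <- total_scale <= 0
  p[degen, ] <- 1
  p
}

#' Per-gene two-way ANOVA for age, sex and their interaction
#'
#' Fits, for every gene, a fixed-effects two-way analysis of variance with
#' factors age and sex and their interaction, and applies Benjamini-
#' Hochberg adjustment per effect across all tested genes. Balanced designs
#' use the classical sums-of-squares decomposition (all SS types coincide);
#' unbalanced designs fall back to per-gene type-II tests. Genes with no
#' variation return p = 1 for all effects so they can never be selected.
#'
#' @param norm normalized expression matrix (genes x arrays), e.g. from
#'   [normalize_signals()].
#' @param meta array metadata: `array_id`, `age_days`, `sex`.
#' @return data frame of class `screen_anova`: `gene_id`, `p_age`, `p_sex`,
#'   `p_interaction`, `q_age`, `q_sex`, `q_interaction`.
#' @export
two_way_anova <- function(norm, meta) {
  norm <- .validate_expr(norm)
  meta <- .validate_array_meta(norm, meta)
  age <- factor(meta$age_days)
  sex <- factor(meta$sex)
  .check(nlevels(age) >= 2 && nlevels(sex) >= 2,
         "need >= 2 levels of both age and sex", "mozage_design_error")
  counts <- table(age, sex)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    .err(sprintf("empty design cell: age %s, sex %s",
                 levels(age)[bad[1]], levels(sex)[bad[2]]),
         "mozage_design_error")
  }
  if (any(counts == 1)) {
    bad <- which(counts == 1, arr.ind = TRUE)[1, ]
    .err(sprintf("single replicate in cell (age %s, sex %s); the interaction term needs >= 2",
                 levels(age)[bad[1]], levels(sex)[bad[2]]),
         "mozage_design_error")
  }
  total_scale <- apply(norm, 1, function(y) sum((y - mean(y))^2))
  if (length(unique(as.numeric(counts))) == 1) {
    dec <- .anova_balanced(norm, age, sex)
    p <- .anova_pvalues(dec$ss, dec$df, total_scale)
  } else {
    p <- t(apply(norm, 1, function(y) .anova_type2_gene(y, age, sex, sum((y - mean(y))^2))))
    colnames(p) <- c("age", "sex", "interaction")
  }
  out <- data.frame(gene_id = rownames(norm),
                    p_age = p[, "age"], p_sex = p[, "sex"],
                    p_interaction = p[, "interaction"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q_age <- bh_adjust(out$p_age)
  out$q_sex <- bh_adjust(out$p_sex)
  out$q_interaction <- bh_adjust(out$p_interaction)
  class(out) <- c("screen_anova", "data.frame")
  out
}

# Type-II tests for one gene on an unbalanced (but full) design.
.anova_type2_gene <- function(y, age, sex, tss) {
  if (tss <= 0) return(c(1, 1, 1))
  fit <- stats::lm(y ~ age * sex)
  tab <- car::Anova(fit, type = 2)
  p <- tab[c("age", "sex", "age:sex"), "Pr(>F)"]
  p[is.na(p)] <- 1
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a vector of p-values: sort ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j` clipped to 1, returned in the
#' original order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  .check(is.numeric(pvalues) && length(pvalues) > 0, "pvalues must be non-empty numeric")
  .check(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
         "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select genes regulated by age only
#'
#' Keeps genes with significant differential expression across age and no
#' significant sex or age-sex interaction effect, on BH-adjusted q-values:
#' `q_age <= alpha` and `q_sex > alpha` and `q_interaction > alpha`.
#'
#' @param anova a [two_way_anova()] result (q-values filled).
#' @param alpha significance threshold (default 0.01, the screening
#'   setting).
#' @return character vector of selected gene ids.
#' @export
select_age_only <- function(anova, alpha = 0.01) {
  .check(is.data.frame(anova) &&
           all(c("gene_id", "q_age", "q_sex", "q_interaction") %in% names(anova)),
         "anova must be a two_way_anova() result with q-values")
  .check(.is_number(alpha) && alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  sel <- anova$q_age <= alpha & anova$q_sex > alpha & anova$q_interaction > alpha
  anova$gene_id[sel]
}

#' Per-gene age-correlation and fold-change profile statistics
#'
#' For each gene, `r_age` is the Pearson correlation between the per-age
#' mean normalized expression and age (one point per age class, profile-
#' level correlation), and `max_fold_change` is the linear-scale ratio
#' between the highest and lowest per-age mean: `2^(max - min)` on the log2
#' scale. Genes whose per-age means have zero variance get `r_age = 0` (and
#' fold change 1).
#'
#' @param norm normalized log2-scale matrix, genes x arrays.
#' @param meta array metadata (`array_id`, `age_days`, `sex`).
#' @param method `"per_age_means"` (default; the profile-level reading) or
#'   `"per_array"` (correlation over individual arrays).
#' @return data frame: `gene_id`, `r_age`, `max_fold_change`.
#' @export
profile_stats <- function(norm, meta, method = c("per_age_means", "per_array")) {
  norm <- .validate_expr(norm)
  meta <- .validate_array_meta(norm, meta)
  method <- match.arg(method)
  ages <- sort(unique(meta$age_days))
  .check(length(ages) >= 3, "need >= 3 distinct ages for profile correlation",
         "mozage_design_error")
  idx <- split(seq_len(ncol(norm)), meta$age_days)
  m_age <- vapply(idx, function(j) rowMeans(norm[, j, drop = FALSE]),
                  numeric(nrow(norm)))                  # genes x ages (sorted names)
  m_age <- m_age[, as.character(ages), drop = FALSE]
  safe_cor <- function(y, x) {
    if (stats::sd(y) == 0 || stats::sd(x) == 0) 0 else stats::cor(y, x)
  }
  r_age <- if (method == "per_age_means") {
    apply(m_age, 1, safe_cor, x = ages)
  } else {
    apply(norm, 1, safe_cor, x = meta$age_days)
  }
  fc <- 2^(apply(m_age, 1, max) - apply(m_age, 1, min))
  data.frame(gene_id = rownames(norm), r_age = unname(r_age),
             max_fold_change = unname(fc), stringsAsFactors = FALSE)
}

#' Candidate selection on age-only genes
#'
#' Flags age-only genes whose profile correlation with age is strictly
#' above `r_up` (up-regulated candidates) or strictly below `r_down`
#' (down-regulated candidates). Fold change is recorded as an annotation
#' (`meets_fold_change`), not a hard gate: in the screening protocol
#' fourfold changes received attention but did not exclude genes.
#'
#' @param stats data frame with `gene_id`, `r_age`, `max_fold_change` (from
#'   [profile_stats()]).
#' @param age_only_genes character vector of age-only gene ids (from
#'   [select_age_only()]).
#' @param r_up positive-correlation threshold (default 0.8).
#' @param r_down negative-correlation threshold (default -0.4).
#' @param fc_min fold-change annotation threshold (default 4).
#' @return data frame of candidates: `gene_id`, `direction` ("up"/"down"),
#'   `r_age`, `max_fold_change`, `meets_fold_change`.
#' @export
select_candidates <- function(stats, age_only_genes, r_up = 0.8, r_down = -0.4,
                              fc_min = 4) {
  .check(is.data.frame(stats) &&
           all(c("gene_id", "r_age", "max_fold_change") %in% names(stats)),
         "stats must come from profile_stats()")
  .check(.is_number(r_up) && .is_number(r_down) && r_down < r_up,
         "need r_down < r_up")
  .check(.is_number(fc_min) && fc_min >= 1, "fc_min must be >= 1")
  s <- stats[stats$gene_id %in% age_only_genes, , drop = FALSE]
  up <- s$r_age > r_up
  down <- s$r_age < r_down
  out <- s[up | down, c("gene_id", "r_age", "max_fold_change"), drop = FALSE]
  out$direction <- ifelse(out$r_age > r_up, "up", "down")
  out$meets_fold_change <- out$max_fold_change >= fc_min
  rownames(out) <- NULL
  out[, c("gene_id", "direction", "r_age", "max_fold_change", "meets_fold_change")]
}

#' Run the full microarray screening pipeline
#'
#' Normalizes the raw matrix, filters genes on raw signal (and optional
#' feature-extraction flags), runs the per-gene two-way ANOVA with BH
#' correction on the retained genes, computes profile statistics, and
#' assembles the per-gene screening report with selection verdicts.
#'
#' @param expr raw expression matrix (genes x arrays).
#' @param meta array metadata (`array_id`, `age_days`, `sex`).
#' @param alpha BH-adjusted significance threshold (default 0.01).
#' @param percentile raw-signal filter percentile (default 20).
#' @param flags optional logical matrix (genes x arrays), TRUE where the
#'   instrument flagged the feature as usable; a gene is retained iff
#'   flagged usable in at least one array. Flags are accepted as input
#'   only, never generated.
#' @param r_up,r_down,fc_min candidate thresholds (see
#'   [select_candidates()]).
#' @param min_arrays_above signal-filter knob (see [filter_low_signal()]).
#' @return list of class `screen_result` with elements `genes` (per-gene
#'   report: p/q-values, `r_age`, `max_fold_change`, and flags
#'   `passed_signal_filter`, `age_only`, `candidate_up`, `candidate_down`,
#'   `meets_fold_change`) and `candidates` (the candidate table).
#' @examples
#' sim <- simulate_microarray(array_sim_config(n_genes = 200, seed = 3))
#' res <- screen_arrays(sim$expr, sim$arrays)
#' head(res$candidates)
#' @export
screen_arrays <- function(expr, meta, alpha = 0.01, percentile = 20,
                          flags = NULL, r_up = 0.8, r_down = -0.4, fc_min = 4,
                          min_arrays_above = 1) {
  expr <- .validate_expr(expr)
  meta <- .validate_array_meta(expr, meta)
  keep <- filter_low_signal(expr, percentile, min_arrays_above)
  if (!is.null(flags)) {
    .check(is.matrix(flags) && is.logical(flags) &&
             identical(dim(flags), dim(expr)),
           "flags must be a logical matrix matching expr", "mozage_input_error")
    keep <- intersect(keep, rownames(expr)[rowSums(flags) >= 1])
  }
  norm <- normalize_signals(expr)
  .check(length(keep) > 0, "no genes passed the signal filter", "mozage_data_error")
  norm_kept <- norm[keep, , drop = FALSE]
  anova <- two_way_anova(norm_kept, meta)
  ps <- profile_stats(norm_kept, meta)
  age_only <- select_age_only(anova, alpha)
  cand <- select_candidates(ps, age_only, r_up, r_down, fc_min)
  genes <- data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE)
  genes$passed_signal_filter <- genes$gene_id %in% keep
  for (col in c("p_age", "p_sex", "p_interaction", "q_age", "q_sex", "q_interaction")) {
    genes[[col]] <- anova[[col]][match(genes$gene_id, anova$gene_id)]
  }
  genes$r_age <- ps$r_age[match(genes$gene_id, ps$gene_id)]
  genes$max_fold_change <- ps$max_fold_change[match(genes$gene_id, ps$gene_id)]
  genes$age_only <- genes$gene_id %in% age_only
  genes$candidate_up <- genes$gene_id %in% cand$gene_id[cand$direction == "up"]
  genes$candidate_down <- genes$gene_id %in% cand$gene_id[cand$direction == "down"]
  genes$meets_fold_change <- !is.na(genes$max_fold_change) &
    genes$max_fold_change >= fc_min
  structure(list(genes = genes, candidates = cand,
                 settings = list(alpha = alpha, percentile = percentile,
                                 r_up = r_up, r_down = r_down, fc_min = fc_min)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  g <- x$genes
  cat("Microarray screen\n")
  cat(sprintf("  genes: %d; passed signal filter: %d\n",
              nrow(g), sum(g$passed_signal_filter)))
  cat(sprintf("  age-only (q <= %g): %d; candidates: %d up, %d down\n",
              x$settings$alpha, sum(g$age_only),
              sum(g$candidate_up), sum(g$candidate_down)))
  invisible(x)
}
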