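# Microarray screening: signal filter, normalization chain, per-gene
# two-way ANOVA, BH adjustment, and candidate selection.

test_that("low-signal filter matches a brute-force percentile oracle", {
  set.seed(1)
  # 10 genes x 4 arrays; 2 genes pinned at the global minimum
  m <- matrix(runif(40, 50, 100), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), paste0("a", 1:4)))
  m[c(3, 7), ] <- 10
  keep <- filter_low_signal(m, percentile = 20)
  expect_setequal(keep, rownames(m)[-c(3, 7)])

  for (s in 1:10) {
    set.seed(s)
    r <- matrix(rexp(60, 1 / 50), 12, 5,
                dimnames = list(sprintf("g%02d", 1:12), paste0("a", 1:5)))
    cutoff <- quantile(as.numeric(r), 0.2)
    expected <- rownames(r)[apply(r, 1, function(x) any(x > cutoff))]
    expect_identical(filter_low_signal(r, 20), expected)
  }

  # degenerate: all values identical -> nothing strictly exceeds the cutoff
  flat <- matrix(5, 3, 3, dimnames = list(paste0("g", 1:3), paste0("a", 1:3)))
  expect_length(filter_low_signal(flat, 20), 0)
})

test_that("normalization thresholds, percentile-shifts and centres gene medians", {
  m <- matrix(c(0.5, 4, 16, 64, 1, 8, 32, 128), 4, 2,
              dimnames = list(paste0("g", 1:4), c("a1", "a2")))
  norm <- normalize_signals(m)
  # raw 0.5 thresholded to 1 -> log2 = 0 before the shifts
  expect_equal(log2(pmax(m, 1))[1, 1], 0)
  # arrays differing by a multiplicative constant become identical columns
  set.seed(2)
  v <- 2^runif(10, 1, 10)
  base <- matrix(rep(v, 4), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("a", 1:4)))
  scaled <- sweep(base, 2, c(1, 2.5, 7, 0.9), `*`)
  ns <- normalize_signals(scaled)
  expect_lt(max(abs(ns - rowMeans(ns))), 1e-10)
  # every gene's median across arrays is zero after baseline transformation
  expect_equal(unname(apply(norm, 1, median)), rep(0, 4))
  expect_error(normalize_signals(m - 10), "non-negative", class = "mozage_input_error")
})

test_that("two-way ANOVA matches the explicit sums-of-squares oracle and aov", {
  set.seed(7)
  meta <- expand.grid(rep = 1:2, age_days = c(0, 10, 20, 30), sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  meta$array_id <- sprintf("a%02d", seq_len(nrow(meta)))
  Y <- matrix(rnorm(20 * nrow(meta)), 20,
              dimnames = list(sprintf("g%02d", 1:20), meta$array_id))
  Y[1:5, ] <- Y[1:5, ] + outer(runif(5, 1, 2), meta$age_days / 30)
  res <- two_way_anova(Y, meta)
  for (g in rownames(Y)) {
    orc <- oracle_anova_ss(Y[g, ], meta$age_days, meta$sex)
    row <- res[res$gene_id == g, ]
    expect_equal(row$p_age, unname(orc$p["age"]), tolerance = 1e-10)
    expect_equal(row$p_sex, unname(orc$p["sex"]), tolerance = 1e-10)
    expect_equal(row$p_interaction, unname(orc$p["interaction"]), tolerance = 1e-10)
    a <- summary(aov(Y[g, ] ~ factor(meta$age_days) * factor(meta$sex)))[[1]]
    expect_equal(unname(unlist(row[c("p_age", "p_sex", "p_interaction")])),
                 a[["Pr(>F)"]][1:3], tolerance = 1e-10)
  }
  # effect + residual SS conserve the total SS (balanced decomposition)
  dec <- mozage:::.anova_balanced(Y, factor(meta$age_days), factor(meta$sex))
  total <- apply(Y, 1, function(y) sum((y - mean(y))^2))
  expect_equal(unname(rowSums(dec$ss)), unname(total), tolerance = 1e-8)
})

test_that("degenerate genes return p = 1 and design errors name the cell", {
  meta <- expand.grid(rep = 1:2, age_days = c(0, 10), sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  meta$array_id <- sprintf("a%d", seq_len(nrow(meta)))
  Y <- matrix(3.2, 2, 8, dimnames = list(c("g1", "g2"), meta$array_id))
  res <- two_way_anova(Y, meta)
  expect_true(all(unlist(res[, c("p_age", "p_sex", "p_interaction")]) == 1))

  meta_bad <- meta[meta$array_id != "a1", ]
  expect_error(two_way_anova(Y[, meta_bad$array_id], meta_bad), "age 0",
               class = "mozage_design_error")
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("age-only selection applies the q-value rule", {
  res <- data.frame(gene_id = c("gA", "gB", "gC"),
                    q_age = c(0.005, 0.005, 0.2),
                    q_sex = c(0.5, 0.005, 0.5),
                    q_interaction = c(0.5, 0.5, 0.5))
  expect_identical(select_age_only(res, 0.01), "gA")
})

test_that("profile statistics follow the per-age-mean definitions", {
  meta <- expand.grid(rep = 1:2, age_days = c(0, 10, 20, 30), sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  meta$array_id <- sprintf("a%02d", seq_len(nrow(meta)))
  per_age <- c(0, 1, 2, 2)[match(meta$age_days, c(0, 10, 20, 30))]
  Y <- rbind(g1 = meta$age_days / 10,        # exactly linear increasing
             g2 = per_age,                   # log2 means {0,1,2,2}
             g3 = rep(1, nrow(meta)))        # constant
  colnames(Y) <- meta$array_id
  ps <- profile_stats(Y, meta)
  expect_equal(ps$r_age[ps$gene_id == "g1"], 1)
  expect_equal(ps$max_fold_change[ps$gene_id == "g2"], 4)  # 2^(2-0)
  expect_equal(ps$r_age[ps$gene_id == "g3"], 0)
  expect_equal(ps$max_fold_change[ps$gene_id == "g3"], 1)
})

test_that("candidate thresholds are strict inequalities", {
  stats <- data.frame(gene_id = c("up", "edge", "down", "mid"),
                      r_age = c(0.85, 0.80, -0.5, 0.2),
                      max_fold_change = c(5, 5, 2, 10))
  cand <- select_candidates(stats, stats$gene_id)
  expect_setequal(cand$gene_id, c("up", "down"))
  expect_equal(cand$direction[cand$gene_id == "up"], "up")
  expect_equal(cand$direction[cand$gene_id == "down"], "down")
  # fold change is an annotation, not a gate
  expect_false(cand$meets_fold_change[cand$gene_id == "down"])
})

test_that("screening is invariant to gene and array order", {
  sim <- simulate_microarray(array_sim_config(n_genes = 120, seed = 13))
  res <- screen_arrays(sim$expr, sim$arrays)
  set.seed(5)
  gperm <- sample(nrow(sim$expr))
  aperm <- sample(ncol(sim$expr))
  res2 <- screen_arrays(sim$expr[gperm, aperm], sim$arrays)
  g1 <- res$genes[order(res$genes$gene_id), ]
  g2 <- res2$genes[order(res2$genes$gene_id), ]
  rownames(g1) <- rownames(g2) <- NULL
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("null-gene ANOVA p-values are uniform", {
  sim <- simulate_microarray(array_sim_config(
    n_genes = 500, frac_age_only = 0, frac_sex_only = 0, frac_interaction = 0,
    sigma = 0.25, seed = 19))
  an <- two_way_anova(normalize_signals(sim$expr), sim$arrays)
  expect_gt(ks.test(an$p_age, "punif")$p.value, 0.001)
  expect_gt(ks.test(an$p_interaction, "punif")$p.value, 0.001)
})
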