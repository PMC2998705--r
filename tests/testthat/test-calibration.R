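# Redundancy-variate calibration: oracle equivalence, invariances,
# gene ranking and model serialization.

test_that("with one gene the variate reduces to the standardized gene", {
  X <- make_lc(ages34(), slopes = -0.1, sigma = 0.4, seed = 1)
  red <- fit_redundancy(X, ages34())
  r <- cor(X[, 1], ages34())
  expect_equal(red$canonical_correlation, abs(r), tolerance = 1e-12)
  expect_equal(red$variate, sign(r) * as.numeric(scale(X[, 1])), tolerance = 1e-10)
})

test_that("the canonical correlation equals the multiple correlation R (OLS oracle)", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:50, 1)
    p <- sample(1:6, 1)
    while (n <= p + 1) n <- n + p
    ages <- sample(seq(0, 30, 5), n, replace = TRUE)
    while (sd(ages) == 0) ages <- sample(seq(0, 30, 5), n, replace = TRUE)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p))) +
      outer(ages, runif(p, -0.1, 0.1))
    red <- fit_redundancy(X, ages)
    r_lm <- sqrt(summary(lm(ages ~ X))$r.squared)
    expect_equal(red$canonical_correlation, r_lm, tolerance = 1e-10)
    # independent CCA route
    cc <- cancor(X, ages)$cor
    expect_equal(red$canonical_correlation, cc, tolerance = 1e-10)
    # training variate is standardized and positively correlated with age
    expect_equal(mean(red$variate), 0, tolerance = 1e-8)
    expect_equal(var(red$variate), 1, tolerance = 1e-8)
    expect_gte(cor(red$variate, ages), 0)
  }
})

test_that("genes independent of age give a small canonical correlation", {
  ccs <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 200
    ages <- rep(c(0, 5, 10, 15, 20, 25, 30), length.out = n)
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
    fit_redundancy(X, ages)$canonical_correlation
  }, numeric(1))
  expect_lt(max(ccs), 0.3)
})

test_that("scoring uses training constants and is affine-invariant", {
  X <- make_lc(ages34(), c(-0.1, 0.07, -0.06), 0.5, seed = 3)
  red <- fit_redundancy(X, ages34())
  # x at the training mean scores zero
  expect_equal(score_variate(red, colMeans(X)), 0, tolerance = 1e-10)
  # training samples scored by their own model reproduce the variate
  expect_equal(score_variate(red, X), red$variate, tolerance = 1e-10)
  # per-gene affine transform with refit leaves variates unchanged
  a <- c(2, 0.5, 3)
  b <- c(-1, 4, 10)
  X2 <- sweep(sweep(X, 2, a, `*`), 2, b, `+`)
  red2 <- fit_redundancy(X2, ages34())
  expect_equal(red2$variate, red$variate, tolerance = 1e-10)
  expect_error(score_variate(red, c(g01 = 1, g02 = 2)), "g03",
               class = "mozage_data_error")
})

test_that("calibration line satisfies the R^2 identity and sign convention", {
  for (s in 1:10) {
    lc <- sim_female_lc(40 + s)
    red <- fit_redundancy(lc$X, lc$ages)
    cal <- fit_calibration(red$variate, lc$ages, red, sex_label = "F")
    expect_equal(cal$r_squared, red$canonical_correlation^2, tolerance = 1e-10)
    expect_gt(cal$beta, 0)
    # age-unit invariance of R^2; slope rescales exactly
    cal_w <- fit_calibration(red$variate, lc$ages / 7, red)
    expect_equal(cal_w$r_squared, cal$r_squared, tolerance = 1e-12)
    expect_equal(cal_w$beta, cal$beta * 7, tolerance = 1e-10)
  }
  # noise-free data: R^2 = 1 and zero residuals
  Xz <- make_lc(ages34(), c(-0.1, 0.07), 0, seed = 1)
  mz <- suppressWarnings(fit_age_model(Xz, ages34()))
  expect_equal(mz$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict_age(mz, Xz), ages34(), tolerance = 1e-8)
})

test_that("degenerate inputs raise informative model errors", {
  X <- make_lc(ages34(), c(-0.1, 0.07), 0.5, seed = 5)
  expect_error(fit_redundancy(X, rep(10, 34)), "constant", class = "mozage_model_error")
  Xc <- X
  Xc[, 2] <- 3
  expect_error(fit_redundancy(Xc, ages34()), "g02", class = "mozage_model_error")
  expect_error(fit_redundancy(X[1:3, ], ages34()[1:3]), "n > p",
               class = "mozage_model_error")
  # exact collinearity: warns naming a dependent column, still fits exactly
  Xd <- cbind(X[, 1, drop = FALSE], g99 = 2 * X[, 1])
  expect_warning(red <- fit_redundancy(Xd, ages34()), "g99")
  expect_equal(red$canonical_correlation, abs(cor(X[, 1], ages34())),
               tolerance = 1e-10)
})

test_that("gene ranking orders by absolute loading with lexicographic ties", {
  red <- structure(list(gene_ids = c("A", "B", "C"), mu = c(0, 0, 0),
                        s = c(1, 1, 1), w = c(-0.9, 0.2, 0.5),
                        canonical_correlation = 0.9, variate = NULL, n = 10),
                   class = "redundancy_model")
  expect_identical(rank_genes(red)$gene_id, c("A", "C", "B"))
  red$gene_ids <- c("B", "A", "C")
  red$w <- c(-0.5, 0.5, 0.1)
  expect_identical(rank_genes(red)$gene_id, c("A", "B", "C"))
})

test_that("informative-gene selection recovers a planted panel and k = p is the identity", {
  ages <- rep(c(0, 5, 10, 15, 20, 25, 30), each = 20)
  hits <- 0
  for (s in 1:50) {
    Y <- make_lc(ages, c(-0.10, -0.08, 0.07, -0.06, 0, 0, 0, 0, 0), 0.72,
                 seed = 1000 + s)
    sel <- select_informative_genes(Y, ages, 4)
    hits <- hits + setequal(sel$gene_ids, paste0("g0", 1:4))
  }
  expect_gte(hits, 45)

  X <- make_lc(ages34(), c(-0.1, 0.07, -0.06), 0.5, seed = 2)
  sel_full <- select_informative_genes(X, ages34(), k = 3)
  full <- fit_age_model(X[, sel_full$gene_ids], ages34())
  expect_equal(sel_full$model$r_squared, fit_age_model(X, ages34())$r_squared,
               tolerance = 1e-10)
  expect_equal(sel_full$model$r_squared, full$r_squared, tolerance = 1e-10)
  expect_error(select_informative_genes(X, ages34(), 0), "k must",
               class = "mozage_input_error")
})

test_that("a planted strong gene ranks first almost always", {
  ages <- ages34()
  firsts <- 0
  for (s in 1:50) {
    X <- make_lc(ages, c(0.30, 0.05, -0.04, 0.05, 0), 0.7, seed = 2000 + s)
    firsts <- firsts + (rank_genes(fit_redundancy(X, ages))$gene_id[1] == "g01")
  }
  expect_gte(firsts, 45)
})

test_that("adding a pure-noise gene never decreases the training correlation", {
  for (s in 1:10) {
    lc <- sim_female_lc(60 + s)
    cc1 <- fit_redundancy(lc$X, lc$ages)$canonical_correlation
    set.seed(s)
    X2 <- cbind(lc$X, noise = rnorm(nrow(lc$X)))
    cc2 <- fit_redundancy(X2, lc$ages)$canonical_correlation
    expect_gte(cc2 + 1e-12, cc1)
  }
})

test_that("model serialization round-trips losslessly", {
  lc <- sim_female_lc(77)
  m <- fit_age_model(lc$X, lc$ages, sex_label = "F")
  f <- tempfile(fileext = ".model")
  write_age_model(m, f)
  m2 <- read_age_model(f)
  expect_equal(m2$alpha, m$alpha, tolerance = 1e-12)
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
  expect_equal(m2$r_squared, m$r_squared, tolerance = 1e-12)
  expect_identical(m2$redundancy$gene_ids, m$redundancy$gene_ids)
  expect_equal(m2$redundancy$w, m$redundancy$w, tolerance = 1e-12)
  expect_identical(m2$sex_label, "F")
  # restored model reproduces predictions exactly
  expect_equal(predict_age(m2, lc$X), predict_age(m, lc$X), tolerance = 1e-12)
})
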