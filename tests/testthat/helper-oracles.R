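# Independent oracles and fixture builders used across the suite. These
# deliberately share no code with the package internals.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Explicit balanced two-way sums-of-squares decomposition for one response.
oracle_anova_ss <- function(y, age, sex) {
  age <- as.character(age)
  sex <- as.character(sex)
  grand <- mean(y)
  ss_age <- 0
  for (a in unique(age)) ss_age <- ss_age + sum(age == a) * (mean(y[age == a]) - grand)^2
  ss_sex <- 0
  for (b in unique(sex)) ss_sex <- ss_sex + sum(sex == b) * (mean(y[sex == b]) - grand)^2
  ss_int <- 0
  ss_res <- 0
  for (a in unique(age)) for (b in unique(sex)) {
    cell <- age == a & sex == b
    ss_int <- ss_int + sum(cell) *
      (mean(y[cell]) - mean(y[age == a]) - mean(y[sex == b]) + grand)^2
    ss_res <- ss_res + sum((y[cell] - mean(y[cell]))^2)
  }
  dfa <- length(unique(age)) - 1
  dfb <- length(unique(sex)) - 1
  dfi <- dfa * dfb
  dfr <- length(y) - length(unique(age)) * length(unique(sex))
  f <- c(age = (ss_age / dfa), sex = (ss_sex / dfb), interaction = (ss_int / dfi)) /
    (ss_res / dfr)
  p <- stats::pf(f, c(dfa, dfb, dfi), dfr, lower.tail = FALSE)
  list(ss = c(age = ss_age, sex = ss_sex, interaction = ss_int, residual = ss_res),
       f = f, p = p)
}

# Ages of a full 7-class design with one female dropped (n = 34).
ages34 <- function() rep(c(0, 5, 10, 15, 20, 25, 30), each = 5)[1:34]

# Direct logcontrast matrix: x_g = slope_g * age + noise.
make_lc <- function(ages, slopes, sigma, seed, intercepts = rep(0, length(slopes))) {
  set.seed(seed)
  n <- length(ages)
  X <- vapply(seq_along(slopes),
              function(g) intercepts[g] + slopes[g] * ages + rnorm(n, 0, sigma),
              numeric(n))
  colnames(X) <- sprintf("g%02d", seq_along(slopes))
  rownames(X) <- sprintf("s%03d", seq_len(n))
  X
}

# Female logcontrast matrix + ages from the default simulated study.
sim_female_lc <- function(seed, ...) {
  sim <- simulate_qpcr(qpcr_sim_config(seed = seed, ...))
  lc <- suppressWarnings(logcontrast(aggregate_replicates(sim$ct)))
  fem <- sim$samples[sim$samples$sex == "F", ]
  list(X = lc[fem$sample_id, , drop = FALSE], ages = fem$age_days, sim = sim)
}
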