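# Synthetic-data generators. These define the study conditions under which
# the pipeline is validated: a 7-age x 2-sex qRT-PCR design with triplicate
# Ct measurements and a 4-age x 2-sex factorial microarray design with
# planted differential-expression classes.

#' Default qRT-PCR assay gene panel
#'
#' The four-transcript assay panel with per-gene logcontrast (delta-Ct)
#' baselines and age slopes used as simulation defaults. Up-regulated
#' transcripts have negative delta-Ct slopes (more template, earlier
#' crossing); down-regulated transcripts have positive slopes. The slope
#' magnitudes (0.06-0.10 cycles/day) were chosen so that, together with the
#' default noise level, the population calibration R^2 is approximately
#' 0.82 (see the methods vignette for the closed-form derivation).
#'
#' @return data frame with columns `gene_id`, `baseline_delta` (cycles at
#'   age 0), `slope` (cycles/day).
#' @export
default_assay_genes <- function() {
  data.frame(
    gene_id = c("AGAP006187-RA", "AGAP010398-RA", "AGAP007963-RA", "AGAP012936-RA"),
    baseline_delta = c(2, 5, 3, 6),
    slope = c(-0.10, -0.08, 0.07, -0.06),
    stringsAsFactors = FALSE)
}

#' Configuration for the qRT-PCR simulator
#'
#' Defaults mirror the laboratory design: ages 0, 5, ..., 30 days
#' post-eclosion, both sexes, 5 individuals per age x sex cell with one
#' random female dropped (n = 34 females, 35 males), triplicate Ct
#' measurements, a stable reference gene, and candidate genes with linear
#' logcontrast-age relationships of either sign.
#'
#' @param ages integer ages in days; non-empty, non-negative, strictly
#'   increasing.
#' @param n_per_cell individuals per age x sex cell.
#' @param genes data frame with columns `gene_id`, `baseline_delta`,
#'   `slope` (see [default_assay_genes()]).
#' @param ref_gene_id reference gene identifier.
#' @param ref_mu mean reference-gene Ct (cycles).
#' @param sigma_biological between-individual SD on the logcontrast scale
#'   (cycles); also used for the global per-individual Ct shift that
#'   cancels in the logcontrast.
#' @param sigma_technical between-replicate SD on the Ct scale (cycles).
#' @param n_replicates technical replicates per (sample, gene).
#' @param drop_one_female drop one random female from the full grid so the
#'   totals match the study (34 F / 35 M with the defaults)?
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(ages = c(0, 5, 10, 15, 20, 25, 30),
                            n_per_cell = 5,
                            genes = default_assay_genes(),
                            ref_gene_id = "AGAP010592-RA",
                            ref_mu = 20,
                            sigma_biological = 0.72,
                            sigma_technical = 0.2,
                            n_replicates = 3,
                            drop_one_female = TRUE,
                            seed = 1L) {
  .check(is.numeric(ages) && length(ages) >= 1 && all(is.finite(ages)),
         "ages: must be a non-empty numeric vector", "mozage_config_error")
  .check(all(ages >= 0), "ages: must be non-negative", "mozage_config_error")
  .check(length(ages) < 2 || all(diff(ages) > 0),
         "ages: must be strictly increasing", "mozage_config_error")
  .check(.is_count(n_per_cell), "n_per_cell: must be an integer >= 1",
         "mozage_config_error")
  .check(is.data.frame(genes) &&
           all(c("gene_id", "baseline_delta", "slope") %in% names(genes)) &&
           nrow(genes) >= 1,
         "genes: need columns gene_id, baseline_delta, slope", "mozage_config_error")
  .check(!anyDuplicated(genes$gene_id) && !ref_gene_id %in% genes$gene_id,
         "genes: gene ids must be unique and distinct from the reference",
         "mozage_config_error")
  .check(.is_number(ref_mu) && ref_mu > 0, "ref_mu: must be a positive number",
         "mozage_config_error")
  .check(.is_number(sigma_biological) && sigma_biological >= 0,
         "sigma_biological: must be >= 0", "mozage_config_error")
  .check(.is_number(sigma_technical) && sigma_technical >= 0,
         "sigma_technical: must be >= 0", "mozage_config_error")
  .check(.is_count(n_replicates), "n_replicates: must be an integer >= 1",
         "mozage_config_error")
  .check(.is_count(seed, min = 0L), "seed: must be a non-negative integer",
         "mozage_config_error")
  structure(list(ages = as.numeric(ages), n_per_cell = as.integer(n_per_cell),
                 genes = genes, ref_gene_id = ref_gene_id, ref_mu = ref_mu,
                 sigma_biological = sigma_biological,
                 sigma_technical = sigma_technical,
                 n_replicates = as.integer(n_replicates),
                 drop_one_female = isTRUE(drop_one_female),
                 seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a qRT-PCR Ct table with known ground truth
#'
#' For individual `i` of age `a`, each reference-gene replicate Ct is
#' `Normal(ref_mu + b_i, sigma_technical^2)` where `b_i ~ Normal(0,
#' sigma_biological^2)` is a global shift shared by all genes of the
#' individual (laboratory input-amount variation; it cancels in the
#' logcontrast). Each candidate-gene replicate Ct is `Normal(ref_mu + b_i +
#' baseline_delta_g + slope_g * a + e_ig, sigma_technical^2)` with `e_ig ~
#' Normal(0, sigma_biological^2)` an individual-by-gene biological
#' deviation — the component that survives normalization and sets the
#' between-individual spread of the logcontrast. With all SDs zero the
#' logcontrast is exactly `baseline_delta_g + slope_g * a`.
#'
#' @param config a [qpcr_sim_config()].
#' @return list of class `qpcr_simulation` with elements
#'   \describe{
#'     \item{ct}{long-format Ct table: `sample_id`, `gene_id`, `replicate`,
#'       `ct` (includes the reference gene).}
#'     \item{samples}{metadata: `sample_id`, `sex`, `age_days`.}
#'     \item{truth}{per-gene ground truth: `gene_id`, `slope`,
#'       `intercept` (logcontrast at age 0).}
#'   }
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_config(seed = 7))
#' table(sim$samples$sex)
#' @export
simulate_qpcr <- function(config) {
  .check(inherits(config, "qpcr_sim_config"), "config must come from qpcr_sim_config()",
         "mozage_config_error")
  withr::with_seed(config$seed, {
    grid <- expand.grid(rep = seq_len(config$n_per_cell),
                        age = config$ages, sex = c("F", "M"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (config$drop_one_female && sum(grid$sex == "F") > 1) {
      drop <- sample(which(grid$sex == "F"), 1L)
      grid <- grid[-drop, , drop = FALSE]
    }
    grid$sample_id <- sprintf("%s_d%02d_i%d", grid$sex, grid$age, grid$rep)
    n <- nrow(grid)
    genes <- config$genes
    p <- nrow(genes)
    b <- rnorm(n, 0, config$sigma_biological)
    e <- matrix(rnorm(n * p, 0, config$sigma_biological), n, p)
    gene_ids <- c(config$ref_gene_id, genes$gene_id)
    # mean Ct per (individual, gene), reference first
    mean_ct <- cbind(config$ref_mu + b,
                     config$ref_mu + b +
                       outer(rep(1, n), genes$baseline_delta) +
                       outer(grid$age, genes$slope) + e)
    reps <- config$n_replicates
    ct <- data.frame(
      sample_id = rep(grid$sample_id, times = (p + 1) * reps),
      gene_id = rep(rep(gene_ids, each = n), times = reps),
      replicate = rep(seq_len(reps), each = n * (p + 1)),
      ct = as.numeric(mean_ct)[rep(seq_len(n * (p + 1)), times = reps)] +
        rnorm(n * (p + 1) * reps, 0, config$sigma_technical),
      stringsAsFactors = FALSE)
    ct <- ct[order(ct$sample_id, ct$gene_id, ct$replicate), , drop = FALSE]
    rownames(ct) <- NULL
    samples <- data.frame(sample_id = grid$sample_id, sex = grid$sex,
                          age_days = grid$age, stringsAsFactors = FALSE)
    samples <- samples[order(samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
    truth <- data.frame(gene_id = genes$gene_id, slope = genes$slope,
                        intercept = genes$baseline_delta, stringsAsFactors = FALSE)
    structure(list(ct = ct, samples = samples, truth = truth,
                   config = config),
              class = "qpcr_simulation")
  })
}

#' Configuration for the microarray simulator
#'
#' Defaults mirror the factorial screening design: pooled samples of both
#' sexes at 0, 10, 20 and 30 days post-eclosion, with planted
#' differential-expression classes (age-only trend, sex-only offset,
#' sex-dependent age trend) among null genes.
#'
#' @param n_genes number of genes.
#' @param ages design ages (days).
#' @param sexes sex levels.
#' @param n_reps arrays per age x sex cell (>= 2: the interaction test
#'   needs within-cell replication).
#' @param frac_age_only,frac_sex_only,frac_interaction fractions of genes
#'   in each planted class (non-negative, sum <= 1; remainder are null).
#' @param effect_size total planted effect span in log2 units (2 =
#'   fourfold).
#' @param sigma log2-scale noise SD.
#' @param baseline_mu multiplicative raw-signal scale.
#' @param seed integer seed.
#' @return an object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_genes = 1000,
                             ages = c(0, 10, 20, 30),
                             sexes = c("F", "M"),
                             n_reps = 3,
                             frac_age_only = 0.10,
                             frac_sex_only = 0.05,
                             frac_interaction = 0.05,
                             effect_size = 2,
                             sigma = 0.25,
                             baseline_mu = 1,
                             seed = 1L) {
  .check(.is_count(n_genes), "n_genes: must be an integer >= 1", "mozage_config_error")
  .check(is.numeric(ages) && length(ages) >= 2 && all(diff(ages) > 0),
         "ages: need >= 2 strictly increasing ages", "mozage_config_error")
  .check(length(sexes) >= 2 && !anyDuplicated(sexes),
         "sexes: need >= 2 distinct levels", "mozage_config_error")
  .check(.is_count(n_reps, min = 2L), "n_reps: must be >= 2 (interaction needs replication)",
         "mozage_config_error")
  fr <- c(frac_age_only, frac_sex_only, frac_interaction)
  .check(all(is.finite(fr)) && all(fr >= 0) && sum(fr) <= 1,
         "class fractions must be >= 0 and sum to <= 1", "mozage_config_error")
  .check(.is_number(effect_size) && effect_size >= 0, "effect_size: must be >= 0",
         "mozage_config_error")
  .check(.is_number(sigma) && sigma >= 0, "sigma: must be >= 0", "mozage_config_error")
  .check(.is_number(baseline_mu) && baseline_mu > 0, "baseline_mu: must be > 0",
         "mozage_config_error")
  .check(.is_count(seed, min = 0L), "seed: must be a non-negative integer",
         "mozage_config_error")
  structure(list(n_genes = as.integer(n_genes), ages = as.numeric(ages),
                 sexes = as.character(sexes), n_reps = as.integer(n_reps),
                 frac_age_only = frac_age_only, frac_sex_only = frac_sex_only,
                 frac_interaction = frac_interaction,
                 effect_size = effect_size, sigma = sigma,
                 baseline_mu = baseline_mu, seed = as.integer(seed)),
            class = "array_sim_config")
}

#' Simulate a one-colour expression matrix with planted effects
#'
#' Generates a genes x arrays matrix of raw fluorescence values. On the
#' log2 scale each gene's signal is a gene-specific baseline plus a
#' class-specific effect plus `Normal(0, sigma^2)` noise:
#' * `age_only` — a monotone linear trend across the design ages with total
#'   span `effect_size` (random sign per gene);
#' * `sex_only` — an offset of `effect_size` for the second sex level
#'   (random sign);
#' * `interaction` — an age trend of span `effect_size` with opposite sign
#'   in the two sexes (no marginal age effect);
#' * `null` — baseline only.
#' Raw signal is `baseline_mu * 2^log2signal`.
#'
#' @param config an [array_sim_config()].
#' @return list of class `array_simulation` with elements `expr` (raw
#'   matrix, gene ids in rownames, array ids in colnames), `arrays`
#'   (metadata: `array_id`, `age_days`, `sex`), and `truth` (`gene_id`,
#'   `class`, `sign`).
#' @export
simulate_microarray <- function(config) {
  .check(inherits(config, "array_sim_config"), "config must come from array_sim_config()",
         "mozage_config_error")
  withr::with_seed(config$seed, {
    ng <- config$n_genes
    n_age <- round(config$frac_age_only * ng)
    n_sex <- round(config$frac_sex_only * ng)
    n_int <- round(config$frac_interaction * ng)
    .check(n_age + n_sex + n_int <= ng, "class fractions exceed the gene count",
           "mozage_config_error")
    classes <- sample(rep(c("age_only", "sex_only", "interaction", "null"),
                          c(n_age, n_sex, n_int, ng - n_age - n_sex - n_int)))
    gene_ids <- sprintf("gene%05d", seq_len(ng))
    arrays <- expand.grid(rep = seq_len(config$n_reps), age = config$ages,
                          sex = config$sexes,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    arrays$array_id <- sprintf("arr_%s_d%02d_r%d", arrays$sex, arrays$age, arrays$rep)
    na <- nrow(arrays)
    baseline <- runif(ng, 2, 10)
    sgn <- sample(c(-1, 1), ng, replace = TRUE)
    u <- (arrays$age - min(config$ages)) / diff(range(config$ages))  # 0..1
    is_sex2 <- as.numeric(arrays$sex == config$sexes[2])
    sex_dir <- 1 - 2 * is_sex2                                      # +1 / -1
    eff <- matrix(0, ng, na)
    for (cls in c("age_only", "sex_only", "interaction")) {
      idx <- which(classes == cls)
      if (length(idx) == 0) next
      per_array <- switch(cls,
        age_only = u,
        sex_only = is_sex2,
        interaction = u * sex_dir)
      eff[idx, ] <- outer(sgn[idx] * config$effect_size, per_array)
    }
    log2sig <- baseline + eff +
      matrix(rnorm(ng * na, 0, config$sigma), ng, na)
    expr <- config$baseline_mu * 2^log2sig
    dimnames(expr) <- list(gene_ids, arrays$array_id)
    meta <- data.frame(array_id = arrays$array_id, age_days = arrays$age,
                       sex = arrays$sex, stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_ids, class = classes, sign = sgn,
                        stringsAsFactors = FALSE)
    structure(list(expr = expr, arrays = meta, truth = truth, config = config),
              class = "array_simulation")
  })
}
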