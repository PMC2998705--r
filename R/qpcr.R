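# qRT-PCR stage: triplicate Ct values -> mean Ct -> logcontrast (delta-Ct)
# matrix relative to the reference gene. A low Ct means the amplification
# curve crossed threshold early, i.e. high transcript abundance.

.validate_ct_table <- function(ct, max_cycles = 45) {
  .check(is.data.frame(ct) && all(c("sample_id", "gene_id", "replicate", "ct") %in% names(ct)),
         "Ct table needs columns sample_id, gene_id, replicate, ct",
         "mozage_input_error")
  .check(nrow(ct) > 0, "Ct table is empty", "mozage_input_error")
  .check(is.numeric(ct$ct) && all(is.finite(ct$ct)), "ct values must be finite numbers",
         "mozage_input_error")
  .check(all(ct$ct > 0 & ct$ct <= max_cycles),
         sprintf("ct values must lie in (0, %g] cycles", max_cycles),
         "mozage_input_error")
  key <- paste(ct$sample_id, ct$gene_id, ct$replicate, sep = "\r")
  dup <- anyDuplicated(key)
  .check(dup == 0,
         sprintf("duplicate replicate index for (%s, %s)",
                 ct$sample_id[dup], ct$gene_id[dup]),
         "mozage_input_error")
  invisible(ct)
}

#' Aggregate technical replicates to mean Ct values
#'
#' Computes the arithmetic mean and SD of the replicate Ct values for every
#' (sample, gene) pair. Pairs whose replicate SD exceeds `qc_sd_max` are
#' flagged for quality review but never dropped.
#'
#' @param ct long-format Ct table with columns `sample_id`, `gene_id`,
#'   `replicate`, `ct` (cycles), e.g. from [simulate_qpcr()] or
#'   [read_ct_table()].
#' @param qc_sd_max replicate-SD QC threshold in cycles (default 0.5).
#' @param max_cycles maximum valid Ct (default 45, the assay's cycle count).
#' @return data frame of class `mean_ct`: `sample_id`, `gene_id`,
#'   `mean_ct`, `sd_ct`, `n_replicates`, `qc_flag`.
#' @examples
#' ct <- data.frame(sample_id = "s1", gene_id = "g1", replicate = 1:3,
#'                  ct = c(20.0, 20.2, 20.4))
#' aggregate_replicates(ct)
#' @export
aggregate_replicates <- function(ct, qc_sd_max = 0.5, max_cycles = 45) {
  .validate_ct_table(ct, max_cycles)
  .check(.is_number(qc_sd_max) && qc_sd_max >= 0, "qc_sd_max must be >= 0")
  key <- interaction(ct$sample_id, ct$gene_id, drop = TRUE, sep = "\r")
  mean_ct <- tapply(ct$ct, key, mean)
  sd_ct <- tapply(ct$ct, key, function(x) if (length(x) > 1) stats::sd(x) else 0)
  nrep <- tapply(ct$ct, key, length)
  parts <- do.call(rbind, strsplit(names(mean_ct), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1], gene_id = parts[, 2],
                    mean_ct = as.numeric(mean_ct), sd_ct = as.numeric(sd_ct),
                    n_replicates = as.integer(nrep),
                    stringsAsFactors = FALSE)
  out$qc_flag <- out$sd_ct > qc_sd_max
  out <- out[order(out$sample_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mean_ct", "data.frame")
  out
}

#' Logcontrast (delta-Ct) normalization against the reference gene
#'
#' Normalizes mean Ct values to the reference gene as logcontrasts:
#' `x[i, g] = meanCt[i, g] - meanCt[i, ref]`. Because Ct is (under full
#' amplification efficiency) the negative log2 of starting template, this
#' difference is a log-scale contrast of the gene's expression against the
#' reference; it cancels any per-sample additive Ct shift (input-amount /
#' pipetting variation). The reference gene is excluded from the output.
#'
#' @param mean_ct output of [aggregate_replicates()] (or any data frame
#'   with `sample_id`, `gene_id`, `mean_ct`).
#' @param reference_gene_id id of the stable reference gene (default the
#'   40S ribosomal protein S7 transcript, AGAP010592-RA).
#' @return numeric matrix (samples x genes) of logcontrast values with the
#'   reference gene id stored in `attr(, "reference_gene_id")`.
#' @examples
#' ct <- data.frame(sample_id = "s1", gene_id = c("g1", "ref"),
#'                  replicate = 1, ct = c(25, 20))
#' logcontrast(aggregate_replicates(ct), reference_gene_id = "ref")
#' @export
logcontrast <- function(mean_ct, reference_gene_id = "AGAP010592-RA") {
  .check(is.data.frame(mean_ct) &&
           all(c("sample_id", "gene_id", "mean_ct") %in% names(mean_ct)),
         "mean_ct needs columns sample_id, gene_id, mean_ct", "mozage_input_error")
  samples <- unique(mean_ct$sample_id)
  genes <- setdiff(unique(mean_ct$gene_id), reference_gene_id)
  .check(length(genes) >= 1, "no target genes besides the reference",
         "mozage_input_error")
  ref <- mean_ct[mean_ct$gene_id == reference_gene_id, , drop = FALSE]
  missing_ref <- setdiff(samples, ref$sample_id)
  if (length(missing_ref) > 0) {
    .err(sprintf("reference gene %s missing for sample(s): %s", reference_gene_id,
                 paste(missing_ref, collapse = ", ")),
         "mozage_data_error")
  }
  X <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  tgt <- mean_ct[mean_ct$gene_id != reference_gene_id, , drop = FALSE]
  X[cbind(match(tgt$sample_id, samples), match(tgt$gene_id, genes))] <- tgt$mean_ct
  miss <- which(is.na(X), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    .err(sprintf("missing Ct for (sample %s, gene %s)",
                 samples[miss[1, 1]], genes[miss[1, 2]]),
         "mozage_data_error")
  }
  X <- X - ref$mean_ct[match(samples, ref$sample_id)]
  attr(X, "reference_gene_id") <- reference_gene_id
  X
}
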