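#' Estimate negative-binomial dispersions
#'
#' Per-gene method-of-moments dispersion from within-condition normalized
#' counts, pooled across conditions:
#' `alpha_raw = sum_c (n_c - 1) (v_c - m_c) / sum_c (n_c - 1) m_c^2`
#' (NB variance = m + alpha m^2). A mean-dispersion trend is obtained by
#' regressing log raw dispersion on log base mean over sufficiently expressed
#' genes, and the final dispersion shrinks the raw estimate toward the trend
#' in log space with weight `df / (df + 8)` (raw estimates dominate with many
#' replicates, the trend dominates at typical 2-3 replicate designs), floored
#' at 1e-8.
#'
#' @param table A [count_table()].
#' @param design data.frame with columns `sample_id`, `condition`.
#' @param sf [spike_size_factors()] for the table.
#' @param min_count Genes with base mean below this are excluded from the
#'   trend fit (their trend value is still predicted).
#' @return data.frame of class `dispersions` with columns `gene_id`,
#'   `base_mean`, `raw`, `trend`, `final`.
#' @export
estimate_dispersions_one <- function(table, design, sf, min_count = 10) {
  stopifnot(inherits(table, "count_table"))
  norm <- normalize_counts(table, sf)
  conds <- unique(design$condition)
  reps <- vapply(conds, function(cc) sum(design$condition == cc), integer(1))
  if (any(reps < 2)) {
    stop("fewer than 2 replicates in some condition; supply a fixed ",
         "dispersion_alpha from configuration instead of estimating it")
  }
  num <- 0; den <- 0; df <- 0
  for (cc in conds) {
    cols <- design$sample_id[design$condition == cc]
    x <- norm[, cols, drop = FALSE]
    m <- rowMeans(x)
    v <- rowVars(x)
    w <- length(cols) - 1L
    num <- num + w * (v - m)
    den <- den + w * m^2
    df <- df + w
  }
  base_mean <- rowMeans(norm)
  raw <- ifelse(den > 0, num / den, 0)
  raw_fl <- pmax(raw, 1e-8)

  fit_idx <- which(base_mean >= min_count)
  if (length(fit_idx) >= 10) {
    fit <- stats::lm(log(raw_fl[fit_idx]) ~ log(base_mean[fit_idx]))
    trend <- exp(cbind(1, log(pmax(base_mean, 1e-8))) %*% stats::coef(fit))[, 1]
  } else {
    trend <- rep(exp(mean(log(raw_fl))), length(raw_fl))
  }
  trend <- pmax(trend, 1e-8)
  w_shrink <- df / (df + 8)
  final <- pmax(exp(w_shrink * log(raw_fl) + (1 - w_shrink) * log(trend)), 1e-8)

  structure(data.frame(gene_id = rownames(table$counts),
                       base_mean = base_mean, raw = raw,
                       trend = trend, final = final,
                       stringsAsFactors = FALSE),
            class = c("dispersions", "data.frame"))
}

#' @describeIn estimate_dispersions_one Estimate dispersions for both assays
#'   of a TE experiment.
#' @param rpf,rna [count_table()]s for the two assays.
#' @param sf_list list with elements `rpf` and `rna` of size factors.
#' @export
estimate_dispersions <- function(rpf, rna, design, sf_list, min_count = 10) {
  list(rpf = estimate_dispersions_one(rpf, design, sf_list$rpf, min_count),
       rna = estimate_dispersions_one(rna, design, sf_list$rna, min_count))
}
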