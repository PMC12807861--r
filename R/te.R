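#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), as behind
#' every adjusted p-value in the analysis. Wraps [stats::p.adjust()] after
#' validating the inputs.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
adjust_bh <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!is.numeric(pvals) || any(!ok)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# lower-median convention: deterministic for even-length vectors
lower_median <- function(x) {
  x <- sort(x)
  if (!length(x)) return(NA_real_)
  unname(x[floor((length(x) + 1) / 2)])
}

cond_means <- function(norm, design, contrast) {
  lapply(stats::setNames(contrast, contrast), function(cc) {
    cols <- design$sample_id[design$condition == cc]
    rowMeans(norm[, cols, drop = FALSE])
  })
}

log2_ratio <- function(mB, mA) {
  log2(ifelse(mB == 0, 0.5, mB)) - log2(ifelse(mA == 0, 0.5, mA))
}

final_alpha <- function(disp, gene_ids) {
  if (is.numeric(disp) && length(disp) == 1L) {
    rep(disp, length(gene_ids))
  } else {
    stopifnot(inherits(disp, "dispersions"))
    disp$final[match(gene_ids, disp$gene_id)]
  }
}

#' Absolute differential translation efficiency
#'
#' Estimates, per gene, the spike-scale log2 fold change in TE between two
#' conditions:
#' `log2fc_te = log2(normalized RPF mean, B/A) - log2(normalized RNA mean, B/A)`.
#' With spike-anchored size factors this is an absolute change — a genuine
#' global shutdown appears as a negative shift of the whole distribution,
#' which library-total normalization would erase. Standard errors come from
#' delta-method NB variances, `se^2 = sum over the four assay x condition
#' cells of (1/m + alpha) / (r ln(2)^2)`; Wald tests are run against both
#' H0: log2fc_te = 0 (the spike zero line, `p_abs`) and H0: log2fc_te = g,
#' the bulk median (`p_rel`), each BH-adjusted over tested genes. Genes whose
#' base mean falls below `min_count`, or with a zero condition mean, are
#' marked `low_count` and carry no p-values (a 0.5 pseudocount enters the
#' displayed fold change only). Spike rows are removed from the gene results;
#' the spike aggregate's own log2fc_te (zero by construction under spike
#' anchoring) is reported in attribute `"spike_log2fc_te"`.
#'
#' @param rpf,rna [count_table()]s sharing the same genes and samples.
#' @param design data.frame with columns `sample_id`, `condition`.
#' @param sf_list List with elements `rpf`, `rna` of [spike_size_factors()].
#' @param disp List with elements `rpf`, `rna`, each a `dispersions` table
#'   from [estimate_dispersions()] or a single fixed alpha.
#' @param contrast Character pair `c(reference, treatment)`; defaults to the
#'   first two condition levels in `design`.
#' @param min_count Minimum mean normalized count for testing (default 10).
#' @return data.frame of class `te_result` with columns `gene_id`,
#'   `base_mean`, `log2fc_rpf`, `log2fc_rna`, `log2fc_te`, `se`, `p_abs`,
#'   `padj_abs`, `p_rel`, `padj_rel`, `category` (filled by
#'   [classify_isr()]); the bulk median `g` is attribute `"bulk_median"`.
#' @export
te_foldchange <- function(rpf, rna, design, sf_list, disp,
                          contrast = NULL, min_count = 10) {
  stopifnot(inherits(rpf, "count_table"), inherits(rna, "count_table"))
  if (!setequal(gene_ids(rpf), gene_ids(rna))) {
    stop(sprintf("RPF and RNA gene sets differ (symmetric difference of %d genes)",
                 length(union(setdiff(gene_ids(rpf), gene_ids(rna)),
                              setdiff(gene_ids(rna), gene_ids(rpf))))))
  }
  if (is.null(contrast)) contrast <- unique(design$condition)[1:2]
  stopifnot(length(contrast) == 2, all(contrast %in% design$condition))

  norm_rpf <- normalize_counts(rpf, sf_list$rpf)
  norm_rna <- normalize_counts(rna, sf_list$rna)[gene_ids(rpf), , drop = FALSE]
  reps <- vapply(contrast, function(cc) sum(design$condition == cc), numeric(1))

  m_rpf <- cond_means(norm_rpf, design, contrast)
  m_rna <- cond_means(norm_rna, design, contrast)

  spike <- rpf$is_spike
  sp_lfc <- if (any(spike)) {
    sA <- colSums(norm_rpf[spike, design$sample_id[design$condition == contrast[1]], drop = FALSE])
    sB <- colSums(norm_rpf[spike, design$sample_id[design$condition == contrast[2]], drop = FALSE])
    rA <- colSums(norm_rna[spike, design$sample_id[design$condition == contrast[1]], drop = FALSE])
    rB <- colSums(norm_rna[spike, design$sample_id[design$condition == contrast[2]], drop = FALSE])
    log2_ratio(mean(sB), mean(sA)) - log2_ratio(mean(rB), mean(rA))
  } else NA_real_

  keep <- !spike
  ids <- gene_ids(rpf)[keep]
  mrA <- m_rpf[[1]][keep]; mrB <- m_rpf[[2]][keep]
  mnA <- m_rna[[1]][keep]; mnB <- m_rna[[2]][keep]

  lfc_rpf <- log2_ratio(mrB, mrA)
  lfc_rna <- log2_ratio(mnB, mnA)
  lfc_te <- lfc_rpf - lfc_rna

  a_rpf <- final_alpha(if (is.list(disp) && !is.data.frame(disp)) disp$rpf else disp, ids)
  a_rna <- final_alpha(if (is.list(disp) && !is.data.frame(disp)) disp$rna else disp, ids)
  ln2sq <- log(2)^2
  se2 <- (1 / pmax(mrA, 1e-300) + a_rpf) / (reps[1] * ln2sq) +
         (1 / pmax(mrB, 1e-300) + a_rpf) / (reps[2] * ln2sq) +
         (1 / pmax(mnA, 1e-300) + a_rna) / (reps[1] * ln2sq) +
         (1 / pmax(mnB, 1e-300) + a_rna) / (reps[2] * ln2sq)
  se <- sqrt(se2)

  base_mean <- (rowMeans(norm_rpf)[keep] + rowMeans(norm_rna)[keep]) / 2
  tested <- base_mean >= min_count & mrA > 0 & mrB > 0 & mnA > 0 & mnB > 0

  p_abs <- rep(NA_real_, length(ids))
  p_abs[tested] <- 2 * stats::pnorm(-abs(lfc_te[tested] / se[tested]))
  g <- lower_median(lfc_te[tested])
  p_rel <- rep(NA_real_, length(ids))
  p_rel[tested] <- 2 * stats::pnorm(-abs((lfc_te[tested] - g) / se[tested]))

  res <- data.frame(gene_id = ids, base_mean = base_mean,
                    log2fc_rpf = lfc_rpf, log2fc_rna = lfc_rna,
                    log2fc_te = lfc_te, se = se,
                    p_abs = p_abs, padj_abs = NA_real_,
                    p_rel = p_rel, padj_rel = NA_real_,
                    category = ifelse(tested, NA_character_, "low_count"),
                    stringsAsFactors = FALSE)
  res$padj_abs[tested] <- adjust_bh(p_abs[tested])
  res$padj_rel[tested] <- adjust_bh(p_rel[tested])
  rownames(res) <- NULL
  structure(res, class = c("te_result", "data.frame"),
            contrast = contrast, bulk_median = g,
            spike_log2fc_te = sp_lfc)
}

#' Classify stress-response categories
#'
#' Applies the threshold rule (|log2 FC| > `lfc_threshold`, adjusted p <
#' `alpha`) to both Wald contrasts of a [te_foldchange()] result:
#' *enhanced* genes rise above the spike zero line; *resistant* genes sit
#' near the zero line (at least `lfc_threshold` above the bulk median `g`
#' and not below -`lfc_threshold` absolute); *hypersensitive* genes fall
#' at least `lfc_threshold` below the bulk median; everything else tested is
#' *bulk*, and untested genes stay *low_count*.
#'
#' @param results A `te_result` from [te_foldchange()].
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `results` with the `category` column filled.
#' @export
classify_isr <- function(results, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(results, "te_result"))
  need <- c("log2fc_te", "padj_abs", "padj_rel")
  miss <- setdiff(need, colnames(results))
  if (length(miss)) stop("missing contrast columns: ", paste(miss, collapse = ", "))
  g <- attr(results, "bulk_median")
  lfc <- results$log2fc_te
  tested <- !(results$category %in% "low_count")
  cat <- rep("bulk", nrow(results))
  enh <- lfc > lfc_threshold & results$padj_abs < alpha
  res_ <- !enh & (lfc - g) > lfc_threshold & results$padj_rel < alpha &
    lfc >= -lfc_threshold
  hyp <- !enh & !res_ & (lfc - g) < -lfc_threshold & results$padj_rel < alpha
  cat[which(enh)] <- "enhanced"
  cat[which(res_)] <- "resistant"
  cat[which(hyp)] <- "hypersensitive"
  cat[!tested] <- "low_count"
  results$category <- cat
  results
}

#' Global translation-efficiency shift
#'
#' The fold *reduction* in global TE, `2^(-median log2fc_te)` over expressed
#' non-spike genes: 1 means no change, 20 means a 20-fold global shutdown,
#' values below 1 mean a global increase. Only meaningful with spike (or
#' mito) anchored size factors; library anchoring returns ~1 under a pure
#' global shutdown because composition-relative normalization absorbs it.
#'
#' @inheritParams te_foldchange
#' @return A single positive number (fold reduction).
#' @export
global_te_shift <- function(rpf, rna, design, sf_list, contrast = NULL,
                            min_count = 10) {
  if (is.null(contrast)) contrast <- unique(design$condition)[1:2]
  norm_rpf <- normalize_counts(rpf, sf_list$rpf)
  norm_rna <- normalize_counts(rna, sf_list$rna)[gene_ids(rpf), , drop = FALSE]
  m_rpf <- cond_means(norm_rpf, design, contrast)
  m_rna <- cond_means(norm_rna, design, contrast)
  keep <- !rpf$is_spike
  base_mean <- (rowMeans(norm_rpf)[keep] + rowMeans(norm_rna)[keep]) / 2
  expressed <- base_mean >= min_count &
    m_rpf[[1]][keep] > 0 & m_rpf[[2]][keep] > 0 &
    m_rna[[1]][keep] > 0 & m_rna[[2]][keep] > 0
  if (!any(expressed)) stop("no expressed genes to aggregate")
  lfc <- (log2_ratio(m_rpf[[2]], m_rpf[[1]]) -
            log2_ratio(m_rna[[2]], m_rna[[1]]))[keep]
  2^(-lower_median(lfc[expressed]))
}

#' RPF / RNA decomposition of TE changes
#'
#' Returns the additive decomposition
#' `log2fc_te = log2fc_rpf - log2fc_rna`, exact by construction, for
#' examining whether TE effects are driven by ribosome-footprint changes,
#' mRNA-level changes, or both.
#'
#' @param results A `te_result` from [te_foldchange()].
#' @return data.frame with `gene_id`, `log2fc_rpf`, `log2fc_rna`, `log2fc_te`.
#' @export
rpf_rna_decomposition <- function(results) {
  stopifnot(inherits(results, "te_result"))
  results[, c("gene_id", "log2fc_rpf", "log2fc_rna", "log2fc_te")]
}
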