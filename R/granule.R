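#' Granule-vs-cytoplasm enrichment test
#'
#' Tests each gene for enrichment in a granule fraction relative to the
#' cytoplasmic fraction. Granule preparations carry no spike, so
#' normalization is per-library totals over the shared genes (the comparison
#' is compositional, within sample). The log2 enrichment is the ratio of
#' normalized means, with a delta-method NB Wald p-value (method-of-moments
#' dispersion when both fractions have >= 2 replicates, otherwise a fixed
#' configured alpha), BH adjustment, and the threshold categories *enriched*
#' (log2 > `lfc_threshold`, padj < `alpha`), *depleted* (mirror image),
#' *neither*, or *low_count*.
#'
#' @param granule,cyto [count_table()]s on a shared gene set.
#' @param fixed_alpha NB dispersion used when replicates are insufficient to
#'   estimate one (default 0.05; a documented caveat for unreplicated data).
#' @param lfc_threshold,alpha Category thresholds (defaults 1 and 0.05).
#' @param min_count Minimum mean normalized count for testing.
#' @return data.frame of class `enrichment_table` with columns `gene_id`,
#'   `base_mean`, `log2_enrichment`, `se`, `p`, `padj`, `category`.
#' @export
enrichment_test <- function(granule, cyto, fixed_alpha = 0.05,
                            lfc_threshold = 1, alpha = 0.05, min_count = 10) {
  stopifnot(inherits(granule, "count_table"), inherits(cyto, "count_table"))
  shared <- intersect(gene_ids(granule), gene_ids(cyto))
  if (!length(shared)) stop("granule and cytoplasm tables share no genes")
  gm <- granule$counts[shared, , drop = FALSE]
  cm <- cyto$counts[shared, , drop = FALSE]

  norm1 <- function(m) sweep(m, 2, colSums(m) / exp(mean(log(colSums(m)))), "/")
  gn <- norm1(gm)
  cn <- norm1(cm)

  disp_mom <- function(x) {
    if (ncol(x) < 2) return(rep(fixed_alpha, nrow(x)))
    m <- rowMeans(x); v <- rowVars(x)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    pmax(0.25 * pmax(a, 1e-8) + 0.75 * fixed_alpha, 1e-8)
  }
  a_g <- disp_mom(gn)
  a_c <- disp_mom(cn)

  mg <- rowMeans(gn)
  mc <- rowMeans(cn)
  lfc <- log2(ifelse(mg == 0, 0.5, mg)) - log2(ifelse(mc == 0, 0.5, mc))
  ln2sq <- log(2)^2
  se <- sqrt((1 / pmax(mg, 1e-300) + a_g) / (ncol(gn) * ln2sq) +
             (1 / pmax(mc, 1e-300) + a_c) / (ncol(cn) * ln2sq))
  base_mean <- (mg + mc) / 2
  tested <- base_mean >= min_count & mg > 0 & mc > 0

  p <- rep(NA_real_, length(shared))
  p[tested] <- 2 * stats::pnorm(-abs(lfc[tested] / se[tested]))
  padj <- rep(NA_real_, length(shared))
  padj[tested] <- adjust_bh(p[tested])

  cat <- rep("neither", length(shared))
  cat[which(lfc > lfc_threshold & padj < alpha)] <- "enriched"
  cat[which(lfc < -lfc_threshold & padj < alpha)] <- "depleted"
  cat[!tested] <- "low_count"

  structure(data.frame(gene_id = shared, base_mean = base_mean,
                       log2_enrichment = lfc, se = se, p = p, padj = padj,
                       category = cat, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("enrichment_table", "data.frame"))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), via
#' [stats::cor()]. A constant vector has no defined rank correlation and
#' returns `NA` with a warning.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @return The correlation R_S in `[-1, 1]`, or `NA`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Welch's two-sample, two-tailed t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' via [stats::t.test()].
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @return List with elements `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  fit <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Box-plot style category summary with pairwise Welch tests
#'
#' Per category: n, median, quartiles, whiskers at 1.5x IQR clamped to the
#' data range, and notch half-width `1.58 * IQR / sqrt(n)` (the standard
#' 95%-confidence notch convention); plus Welch's t-test for every category
#' pair.
#'
#' @param values Numeric vector.
#' @param categories Character/factor labels, one per value.
#' @return List of class `category_summary` with a `stats` data.frame and a
#'   `pairwise` data.frame of Welch tests.
#' @export
category_summary <- function(values, categories) {
  if (length(values) != length(categories)) {
    stop("every value must carry a category label")
  }
  categories <- as.character(categories)
  levs <- unique(categories)
  rows <- lapply(levs, function(k) {
    v <- values[categories == k]
    if (!length(v)) {
      return(data.frame(category = k, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_, notch = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.frame(category = k, n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_lo = max(min(v), q[1] - 1.5 * iqr),
               whisker_hi = min(max(v), q[3] + 1.5 * iqr),
               notch = 1.58 * iqr / sqrt(length(v)))
  })
  stats_df <- do.call(rbind, rows)
  pairs <- if (length(levs) >= 2) utils::combn(levs, 2, simplify = FALSE) else list()
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- values[categories == pr[1]]
    b <- values[categories == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(a = pr[1], b = pr[2], t = NA_real_,
                        df = NA_real_, p = NA_real_))
    }
    w <- welch_t(a, b)
    data.frame(a = pr[1], b = pr[2], t = w$t, df = w$df, p = w$p)
  }))
  structure(list(stats = stats_df, pairwise = pw),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  print(x$stats)
  cat("\npairwise Welch tests:\n")
  print(x$pairwise)
  invisible(x)
}

#' Pairwise Spearman correlation matrix of granule enrichments
#'
#' Correlates the `log2_enrichment` columns of several enrichment tables on
#' their shared gene universe (inner join after removing low-count genes in
#' any table).
#'
#' @param tables Named list of >= 2 [enrichment_test()] results.
#' @return Symmetric matrix of R_S values with unit diagonal; the shared
#'   gene count is attribute `"n_shared"` (a warning is recorded below 100).
#' @export
enrichment_correlation_matrix <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 enrichment tables")
  if (is.null(names(tables))) names(tables) <- paste0("table", seq_along(tables))
  kept <- lapply(tables, function(t) t$gene_id[t$category != "low_count"])
  shared <- Reduce(intersect, kept)
  if (length(shared) < 100) {
    warning(sprintf("only %d shared genes in the correlation universe",
                    length(shared)))
  }
  m <- vapply(tables, function(t) {
    t$log2_enrichment[match(shared, t$gene_id)]
  }, numeric(length(shared)))
  k <- length(tables)
  out <- diag(1, k)
  dimnames(out) <- list(names(tables), names(tables))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <- spearman(m[, i], m[, j])
  }
  attr(out, "n_shared") <- length(shared)
  out
}
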