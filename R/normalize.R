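#' Spike-anchored (or mito/library-anchored) size factors
#'
#' Per-sample scaling factors. For the `"spike"` and `"mito"` anchors,
#' `factor_j = anchor_sum_j / geometric mean over samples of anchor sums`,
#' so factors have geometric mean exactly 1 and `normalized = raw / factor`.
#' With the `"spike"` anchor a genuine global shift in translation survives
#' normalization; the `"mito"` anchor instead assumes mitochondrial
#' translation is unaffected — an assumption that fails under arsenite
#' stress. The `"library"` anchor is the standard no-spike comparator:
#' median-of-ratios depth factors over non-spike rows (each sample's median
#' ratio to the per-gene geometric-mean reference, rescaled to geometric
#' mean 1), which centres the typical gene and therefore erases a genuine
#' global shutdown — the methodological contrast the spike exists to expose.
#'
#' @param table A [count_table()].
#' @param anchor `"spike"`, `"mito"`, or `"library"`.
#' @return Named numeric vector of class `size_factors` (one per sample),
#'   with the anchor mode and assay in attributes.
#' @export
spike_size_factors <- function(table, anchor = c("spike", "mito", "library")) {
  stopifnot(inherits(table, "count_table"))
  anchor <- match.arg(anchor)
  rows <- switch(anchor,
    spike = table$is_spike,
    mito = table$is_mito,
    library = !table$is_spike
  )
  if (!any(rows)) stop(sprintf("no rows available for anchor mode '%s'", anchor))
  if (anchor == "library") {
    m <- table$counts[rows, , drop = FALSE]
    pos <- rowSums(m == 0) == 0
    if (!any(pos)) stop("no all-positive rows to compute library factors")
    ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
    f <- apply(m[pos, , drop = FALSE] / ref, 2, stats::median)
    f <- f / exp(mean(log(f)))
  } else {
    s <- colSums(table$counts[rows, , drop = FALSE])
    if (any(s == 0)) {
      stop(sprintf("zero %s counts in sample(s): %s", anchor,
                   paste(names(s)[s == 0], collapse = ", ")))
    }
    f <- s / exp(mean(log(s)))
  }
  structure(f, class = "size_factors", anchor = anchor, assay = table$assay)
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("size_factors (%s anchor, %s):\n", attr(x, "anchor"),
              attr(x, "assay")))
  print(unclass(x))
  invisible(x)
}

#' Normalized counts
#'
#' @param table A [count_table()].
#' @param sf Matching [spike_size_factors()].
#' @return Numeric matrix `counts / factor` (column-wise).
#' @export
normalize_counts <- function(table, sf) {
  stopifnot(inherits(table, "count_table"), inherits(sf, "size_factors"))
  if (!identical(names(sf), colnames(table$counts))) {
    stop("size factors do not match the table's samples")
  }
  sweep(table$counts, 2, as.numeric(sf), "/")
}
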