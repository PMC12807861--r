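#' Construct a count table
#'
#' A `count_table` holds an integer genes x samples matrix for one assay
#' (ribosome-protected fragments or RNA) together with per-gene flags marking
#' spike-in rows and mitochondrially encoded genes.
#'
#' @param counts Non-negative integer matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param assay `"RPF"` or `"RNA"`.
#' @param is_spike,is_mito Logical vectors along the rows of `counts`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, assay = c("RPF", "RNA"),
                        is_spike = rep(FALSE, nrow(counts)),
                        is_mito = rep(FALSE, nrow(counts))) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!is.integer(counts) && max(counts) < .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  }
  stopifnot(length(is_spike) == nrow(counts), length(is_mito) == nrow(counts))
  if (any(is_spike & is_mito)) stop("a spike row can never be mitochondrial")
  structure(
    list(counts = counts, assay = assay,
         is_spike = as.logical(is_spike), is_mito = as.logical(is_mito)),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d genes x %d samples (%d spike, %d mito rows)\n",
              x$assay, nrow(x$counts), ncol(x$counts),
              sum(x$is_spike), sum(x$is_mito)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

gene_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

#' Write / read a count table as TSV
#'
#' Genes are rows, samples are columns; the first column is `gene_id`,
#' followed by `is_spike` and `is_mito` flag columns. A `#`-prefixed header
#' records the assay label.
#'
#' @param x A [count_table()].
#' @param path Output file.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns a [count_table()].
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# assay=%s", x$assay), con)
  df <- data.frame(gene_id = gene_ids(x),
                   is_spike = as.integer(x$is_spike),
                   is_mito = as.integer(x$is_mito),
                   x$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  assay <- sub("^# assay=", "", first)
  if (!assay %in% c("RPF", "RNA")) assay <- "RNA"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), c("gene_id", "is_spike", "is_mito")),
                    drop = FALSE])
  rownames(m) <- df$gene_id
  count_table(m, assay = assay,
              is_spike = as.logical(df$is_spike),
              is_mito = as.logical(df$is_mito))
}
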