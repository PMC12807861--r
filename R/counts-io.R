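#' Read an ORF annotation
#'
#' Accepts either the package's TSV schema (columns `transcript_id`,
#' `gene_id`, `orf_start`, `orf_end`, `is_mito`, `is_spike`,
#' `is_excluded_heme` and optionally `uorf_flag`, `half_life_h`; a header row
#' is optional) or a GTF/GFF file, from which CDS features are merged per
#' transcript (span = min start to max end, converted to 0-based half-open
#' transcript coordinates).
#'
#' @param path Annotation file; `.gtf`/`.gff`/`.gff3` extensions are imported
#'   via rtracklayer, anything else is read as TSV.
#' @return A data.frame of class `orf_annotation`, one row per transcript.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    ann <- read_annotation_gtf(path)
  } else {
    ann <- read_annotation_tsv(path)
  }
  validate_annotation(ann)
}

read_annotation_tsv <- function(path) {
  cols <- c("transcript_id", "gene_id", "orf_start", "orf_end",
            "is_mito", "is_spike", "is_excluded_heme",
            "uorf_flag", "half_life_h")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    df <- data.frame(transcript_id = character(), gene_id = character(),
                     orf_start = integer(), orf_end = integer(),
                     is_mito = logical(), is_spike = logical(),
                     is_excluded_heme = logical())
    return(df)
  }
  has_header <- grepl("^transcript_id", lines[[1]])
  df <- utils::read.table(text = lines, header = has_header, sep = "",
                          stringsAsFactors = FALSE)
  if (!has_header) colnames(df) <- cols[seq_len(ncol(df))]
  missing <- setdiff(cols[1:4], colnames(df))
  if (length(missing)) {
    stop("annotation TSV lacks required columns: ", paste(missing, collapse = ", "))
  }
  for (fl in cols[5:7]) if (is.null(df[[fl]])) df[[fl]] <- FALSE
  for (fl in cols[5:8]) if (!is.null(df[[fl]])) df[[fl]] <- as.logical(df[[fl]])
  df
}

read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF annotations requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      orf_start = integer(), orf_end = integer(),
                      is_mito = logical(), is_spike = logical(),
                      is_excluded_heme = logical()))
  }
  df <- data.frame(transcript_id = as.character(gr$transcript_id),
                   gene_id = as.character(gr$gene_id),
                   start1 = BiocGenerics::start(gr),
                   end1 = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$transcript_id), function(d) {
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               orf_start = min(d$start1) - 1L, orf_end = max(d$end1),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$is_mito <- grepl("^MT-", agg$gene_id)
  agg$is_spike <- FALSE
  agg$is_excluded_heme <- FALSE
  agg
}

validate_annotation <- function(ann) {
  if (nrow(ann)) {
    dup <- ann$transcript_id[duplicated(ann$transcript_id)]
    if (length(dup)) {
      stop("duplicate transcript_id in annotation: ",
           paste(unique(dup), collapse = ", "))
    }
    bad <- which(!(ann$orf_start >= 0 & ann$orf_end > ann$orf_start))
    if (length(bad)) {
      stop(sprintf("invalid ORF span (need 0 <= orf_start < orf_end) at line(s): %s",
                   paste(bad, collapse = ", ")))
    }
    if (any(ann$is_spike & ann$is_mito)) {
      stop("a spike transcript can never be mitochondrial")
    }
  }
  class(ann) <- c("orf_annotation", "data.frame")
  ann
}

#' Read simplified transcript-space alignments
#'
#' BED6-like TSV without header: columns transcript_id (chrom slot), pos5
#' (0-based start slot), end, read_id (name slot), score, strand. Only the
#' 5' end position is used for counting.
#'
#' @param path Alignment file.
#' @return data.frame with columns `read_id`, `transcript_id`, `pos5`, `length`.
#' @export
read_alignments <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("alignment file needs at least 4 BED-like columns")
  out <- data.frame(read_id = as.character(df[[4]]),
                    transcript_id = as.character(df[[1]]),
                    pos5 = as.integer(df[[2]]),
                    length = as.integer(df[[3]]) - as.integer(df[[2]]),
                    stringsAsFactors = FALSE)
  if (any(out$pos5 < 0) || any(out$length <= 0)) {
    stop("alignments must have pos5 >= 0 and end > start")
  }
  out
}

count_reads_one <- function(aln, annotation, exclude_nt, p_offset, lenient) {
  idx <- match(aln$transcript_id, annotation$transcript_id)
  unknown <- is.na(idx)
  if (any(unknown) && !lenient) {
    stop("unknown transcript_id in alignments: ",
         paste(utils::head(unique(aln$transcript_id[unknown]), 5), collapse = ", "),
         " (set lenient = TRUE to skip and tally)")
  }
  pos <- aln$pos5 + p_offset
  lo <- annotation$orf_start[idx] + exclude_nt
  hi <- annotation$orf_end[idx]
  in_orf <- !unknown & pos >= lo & pos < hi
  heme <- in_orf & annotation$is_excluded_heme[idx]
  countable <- in_orf & !heme
  gene <- annotation$gene_id[idx]
  # one count per (read, gene) even if several transcripts of the gene match
  key <- paste(aln$read_id, gene, sep = "\r")
  dup <- countable & duplicated(ifelse(countable, key, NA), incomparables = NA)
  counted <- countable & !dup
  genes_kept <- unique(annotation$gene_id[!annotation$is_excluded_heme])
  tab <- table(factor(gene[counted], levels = genes_kept))
  list(counts = as.integer(tab), genes = genes_kept,
       tally = c(counted = sum(counted), duplicate = sum(dup),
                 heme_excluded = sum(heme),
                 out_of_orf = sum(!unknown & !in_orf),
                 unknown_skipped = sum(unknown)))
}

#' Count reads into a gene-level table with ribosome-profiling filters
#'
#' A read is counted for gene g iff its (optionally P-site-offset) 5' end
#' falls in `[orf_start + exclude_nt, orf_end)` of a transcript of g
#' (0-based half-open), the first `exclude_nt` nucleotides of each ORF being
#' excluded to avoid initiation-peak artifacts. Reads on heme-flagged genes
#' (carry-over from the reticulocyte spike lysate) are excluded and the heme
#' genes dropped from the table; spike-transcript reads are counted into
#' spike rows. Counts are summed over the transcripts of each gene, once per
#' read and gene.
#'
#' @param alignments A data.frame of alignments (one sample) or a named list
#'   of such data.frames (one element per sample); see [read_alignments()].
#' @param annotation An [read_annotation()] table.
#' @param exclude_nt Nucleotides excluded at each ORF start (default 50).
#' @param p_offset P-site offset added to the 5' end (default 0).
#' @param lenient If TRUE, reads on unknown transcripts are skipped and
#'   tallied instead of raising an error.
#' @return A [count_table()]; per-sample read tallies (counted, duplicate,
#'   heme_excluded, out_of_orf, unknown_skipped) in attribute `"tally"`.
#' @export
count_rpf <- function(alignments, annotation, exclude_nt = 50, p_offset = 0,
                      lenient = FALSE) {
  count_assay(alignments, annotation, "RPF", exclude_nt, p_offset, lenient)
}

#' @rdname count_rpf
#' @export
count_rna <- function(alignments, annotation, exclude_nt = 50, p_offset = 0,
                      lenient = FALSE) {
  count_assay(alignments, annotation, "RNA", exclude_nt, p_offset, lenient)
}

count_assay <- function(alignments, annotation, assay, exclude_nt, p_offset,
                        lenient) {
  stopifnot(inherits(annotation, "orf_annotation"))
  if (is.data.frame(alignments)) alignments <- list(sample1 = alignments)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    names(alignments) <- paste0("sample", seq_along(alignments))
  }
  per <- lapply(alignments, count_reads_one, annotation = annotation,
                exclude_nt = exclude_nt, p_offset = p_offset, lenient = lenient)
  genes <- per[[1]]$genes
  m <- vapply(per, `[[`, integer(length(genes)), "counts")
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(alignments)))
  keep <- !annotation$is_excluded_heme
  flags_spike <- tapply(annotation$is_spike[keep], annotation$gene_id[keep], any)
  flags_mito <- tapply(annotation$is_mito[keep], annotation$gene_id[keep], any)
  tab <- count_table(m, assay = assay,
                     is_spike = as.logical(flags_spike[genes]),
                     is_mito = as.logical(flags_mito[genes]))
  attr(tab, "tally") <- lapply(per, `[[`, "tally")
  attr(tab, "filters") <- c(exclude_nt = exclude_nt, p_offset = p_offset)
  tab
}

#' Reads per million
#'
#' `rpm[g, j] = counts[g, j] * 1e6 / column_total_j`, where column totals are
#' computed over non-spike rows so spike loading does not dilute endogenous
#' abundances.
#'
#' @param table A [count_table()].
#' @return Numeric matrix of RPM values (all rows, including spikes).
#' @export
rpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  tot <- colSums(table$counts[!table$is_spike, , drop = FALSE])
  if (any(tot == 0)) {
    stop("zero non-spike column total in sample(s): ",
         paste(colnames(table$counts)[tot == 0], collapse = ", "))
  }
  sweep(table$counts, 2, tot, "/") * 1e6
}
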