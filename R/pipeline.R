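#' Pipeline run configuration
#'
#' Either a simulation preset (`preset`) or paths to count tables must be
#' given for the TE stage. Thresholds must be positive.
#'
#' @param preset Simulation preset name for [isr_preset()] (`"arsenite"`,
#'   `"null"`, `"og"`), or `NULL` when paths are supplied.
#' @param rpf_path,rna_path,design_path TSV inputs (see
#'   [read_count_table()]); ignored when `preset` is given.
#' @param anchor Size-factor anchor mode (`"spike"`, `"mito"`, `"library"`).
#' @param lfc_threshold,alpha,min_count Classification thresholds.
#' @param granule List with `n_enriched`, `n_depleted`, `effect_log2` for the
#'   simulated granule stage, or `NULL` to skip it.
#' @param sim_n_genes Number of genes for simulated presets.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(preset = "arsenite", rpf_path = NULL, rna_path = NULL,
                       design_path = NULL, anchor = "spike",
                       lfc_threshold = 1, alpha = 0.05, min_count = 10,
                       granule = list(n_enriched = 488, n_depleted = 453,
                                      effect_log2 = 3),
                       sim_n_genes = 10000,
                       seed = 1L, out_dir = tempfile("ribospike_run_")) {
  have_paths <- !is.null(rpf_path) || !is.null(rna_path)
  if (is.null(preset) == !have_paths) {
    stop("exactly one of a simulation preset or input paths must be given")
  }
  if (have_paths &&
      !all(file.exists(c(rpf_path, rna_path, design_path)))) {
    stop("referenced input paths must exist")
  }
  for (th in c(lfc_threshold = lfc_threshold, alpha = alpha,
               min_count = min_count)) {
    if (!is.finite(th) || th <= 0) stop("thresholds must be positive")
  }
  structure(list(preset = preset, rpf_path = rpf_path, rna_path = rna_path,
                 design_path = design_path, anchor = anchor,
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 min_count = min_count, granule = granule,
                 sim_n_genes = as.integer(sim_n_genes),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> spike-anchored normalization -> dispersion ->
#' differential TE -> stress-category classification -> granule enrichment
#' and cross-analyses -> TSV artifacts plus a machine-readable summary.
#' Identical configuration and seed reproduce identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`te`,
#'   `global_shift`, `enrichment`, `cross`, `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("ribospike %s",
                         as.character(utils::packageVersion("ribospike"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed=%d anchor=%s lfc=%g alpha=%g min_count=%g",
                         config$seed, config$anchor, config$lfc_threshold,
                         config$alpha, config$min_count))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!is.null(config$preset)) {
    sim <- stage("simulate",
                 simulate_isr_counts(isr_preset(config$preset,
                                                n_genes = config$sim_n_genes,
                                                seed = config$seed)))
    rpf <- sim$rpf_counts; rna <- sim$rna_counts; design <- sim$design
    log_lines <- c(log_lines, sprintf("input=simulated preset '%s'", config$preset))
  } else {
    rpf <- stage("load", read_count_table(config$rpf_path))
    rna <- stage("load", read_count_table(config$rna_path))
    design <- stage("load", utils::read.table(config$design_path, header = TRUE,
                                              sep = "\t", stringsAsFactors = FALSE))
    design <- unique(design[, c("sample_id", "condition")])
    log_lines <- c(log_lines, sprintf("input digests: %s",
      paste(sprintf("%s=%s", basename(c(config$rpf_path, config$rna_path)),
                    tools::md5sum(c(config$rpf_path, config$rna_path))),
            collapse = " ")))
    sim <- NULL
  }

  sf <- stage("normalize", list(rpf = spike_size_factors(rpf, config$anchor),
                                rna = spike_size_factors(rna, config$anchor)))
  disp <- stage("dispersion",
                estimate_dispersions(rpf, rna, design, sf, config$min_count))
  te <- stage("te", classify_isr(
    te_foldchange(rpf, rna, design, sf, disp, min_count = config$min_count),
    lfc_threshold = config$lfc_threshold, alpha = config$alpha))
  shift <- stage("te", global_te_shift(rpf, rna, design, sf,
                                       min_count = config$min_count))

  paths <- list(te = file.path(config$out_dir, "te_results.tsv"))
  utils::write.table(te, paths$te, sep = "\t", quote = FALSE, row.names = FALSE)

  cat_counts <- table(factor(te$category,
                             levels = c("enhanced", "resistant",
                                        "hypersensitive", "bulk", "low_count")))
  summary_rec <- list(seed = config$seed, anchor = config$anchor,
                      global_te_fold_reduction = shift,
                      category_counts = as.list(as.integer(cat_counts)))
  names(summary_rec$category_counts) <- names(cat_counts)

  enr <- cross <- NULL
  if (!is.null(config$granule) && !is.null(sim)) {
    gsim <- stage("granule", simulate_granule_counts(
      sim$config, config$granule$n_enriched, config$granule$n_depleted,
      config$granule$effect_log2, seed = config$seed))
    enr <- stage("granule", enrichment_test(
      gsim$granule_counts, gsim$cyto_counts,
      lfc_threshold = config$lfc_threshold, alpha = config$alpha,
      min_count = config$min_count))
    paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    joint <- merge(te[, c("gene_id", "log2fc_te", "category")],
                   enr[, c("gene_id", "log2_enrichment", "category")],
                   by = "gene_id", suffixes = c("_te", "_enr"))
    joint <- joint[joint$category_te != "low_count" &
                     joint$category_enr != "low_count", ]
    cross <- stage("cross", category_summary(joint$log2_enrichment,
                                             joint$category_te))
    paths$categories <- file.path(config$out_dir, "categories.tsv")
    utils::write.table(cross$stats, paths$categories, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rs <- spearman(joint$log2fc_te, joint$log2_enrichment)
    paths$correlations <- file.path(config$out_dir, "correlations.tsv")
    utils::write.table(
      data.frame(pair = "te_vs_enrichment", spearman = rs),
      paths$correlations, sep = "\t", quote = FALSE, row.names = FALSE)
    summary_rec$enriched_genes <- sum(enr$category == "enriched")
    summary_rec$depleted_genes <- sum(enr$category == "depleted")
    summary_rec$spearman_te_vs_enrichment <- rs
  }

  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_rec, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_lines <- c(log_lines, sprintf("artifact digests: %s",
    paste(sprintf("%s=%s", basename(unlist(paths)),
                  tools::md5sum(unlist(paths))), collapse = " ")))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(te = te, global_shift = shift, enrichment = enr,
                 cross = cross, summary = summary_rec, paths = paths))
}
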