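#' Configuration for the ISR count simulator
#'
#' Describes a two-condition (control vs. stress) ribosome-profiling
#' experiment with matched RNA-seq, an orthogonal spike-in of constant true
#' abundance, a global translation-efficiency (TE) shutdown applied to bulk
#' genes, gene response classes, elevated mitochondrial TE, translation-coupled
#' mRNA (de)stabilization and per-sample technical scaling.
#'
#' @param n_genes Number of endogenous (non-mito, non-spike) genes.
#' @param class_proportions Named fractions over
#'   `c(bulk, resistant, enhanced, hypersensitive)`; must sum to 1.
#' @param global_shutdown_s Fold reduction (> 0) in TE applied to bulk genes
#'   under stress; bulk truth is exactly `-log2(global_shutdown_s)`.
#' @param class_effect_log2 List with elements `resistant`, `enhanced`,
#'   `hypersensitive`, each `c(mean=, sd=)` of gene-level log2 TE offsets
#'   relative to the bulk shutdown. Defaults place resistant genes at the
#'   spike zero line and enhanced genes 2 log2 units above it.
#' @param n_mito Number of mitochondrially encoded genes.
#' @param mito_te_log2fc Absolute log2 TE change of mito genes under stress
#'   (positive: mito translation rises while cytosolic translation collapses).
#' @param n_spike Number of spike-in rows (>= 1).
#' @param spike_frac Fraction of the control RPF library taken by spike reads.
#' @param dispersion_alpha NB dispersion (variance = m + alpha m^2), shared
#'   across genes by the generator (estimators must not assume this).
#' @param spike_alpha Technical dispersion of spike rows. The spike is a
#'   single defined reagent mixed into each lysate before library prep, so
#'   its across-replicate variance is counting noise plus residual pipetting
#'   (default 0.002, about a 4-5% CV), not biological replicate variance.
#' @param depth_mean Expected reads per library before technical scaling.
#' @param tech_scale_sd SD (natural-log scale) of per-sample log-normal
#'   technical scaling; deliberately large by default so naive library
#'   normalization is visibly wrong.
#' @param stability_coupling_rho In `[-1, 0]`; true log2 RNA change =
#'   `rho * true log2 TE change + noise` (translation-coupled destabilization).
#' @param rna_noise_sd SD of the gene-level log2 RNA noise term.
#' @param n_replicates Replicates per condition.
#' @param gene_offsets_log2 Optional numeric vector of length `n_genes`
#'   overriding the class machinery with explicit per-gene log2 TE offsets
#'   (relative to the bulk shutdown); used to plant arbitrary effect patterns.
#' @param seed Integer seed; one named pseudorandom stream per output table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       class_proportions = c(bulk = 0.90, resistant = 0.05,
                                             enhanced = 0.02, hypersensitive = 0.03),
                       global_shutdown_s = 20,
                       class_effect_log2 = NULL,
                       n_mito = 13,
                       mito_te_log2fc = 1,
                       n_spike = 5,
                       spike_frac = 0.01,
                       dispersion_alpha = 0.05,
                       spike_alpha = 0.002,
                       depth_mean = 2e6,
                       tech_scale_sd = 0.5,
                       stability_coupling_rho = -0.2,
                       rna_noise_sd = 0.1,
                       n_replicates = 3,
                       gene_offsets_log2 = NULL,
                       seed = 1L) {
  for (nm in c("n_genes", "global_shutdown_s", "n_mito", "mito_te_log2fc",
               "n_spike", "spike_frac", "dispersion_alpha", "spike_alpha",
               "depth_mean",
               "tech_scale_sd", "stability_coupling_rho", "rna_noise_sd",
               "n_replicates", "seed")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(global_shutdown_s, "global_shutdown_s", lower = 1e-12)
  check_scalar(n_spike, "n_spike", lower = 1)
  check_scalar(dispersion_alpha, "dispersion_alpha", lower = 0)
  check_scalar(spike_alpha, "spike_alpha", lower = 0)
  check_scalar(stability_coupling_rho, "stability_coupling_rho", -1, 0)
  check_scalar(tech_scale_sd, "tech_scale_sd", lower = 0)
  req <- c("bulk", "resistant", "enhanced", "hypersensitive")
  if (!setequal(names(class_proportions), req)) {
    stop("class_proportions must be named over {bulk, resistant, enhanced, hypersensitive}")
  }
  class_proportions <- class_proportions[req]
  if (any(!is.finite(class_proportions)) || any(class_proportions < 0)) {
    stop("'class_proportions' must be finite and non-negative")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("'class_proportions' must sum to 1 within 1e-9")
  }
  if (is.null(class_effect_log2)) {
    l2s <- log2(global_shutdown_s)
    class_effect_log2 <- list(
      resistant = c(mean = l2s, sd = 0.25),
      enhanced = c(mean = l2s + 2, sd = 0.5),
      hypersensitive = c(mean = -2, sd = 0.5)
    )
  }
  if (!is.null(gene_offsets_log2)) {
    if (length(gene_offsets_log2) != n_genes || any(!is.finite(gene_offsets_log2))) {
      stop("'gene_offsets_log2' must be finite and of length n_genes")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), class_proportions = class_proportions,
    global_shutdown_s = global_shutdown_s, class_effect_log2 = class_effect_log2,
    n_mito = as.integer(n_mito), mito_te_log2fc = mito_te_log2fc,
    n_spike = as.integer(n_spike), spike_frac = spike_frac,
    dispersion_alpha = dispersion_alpha, spike_alpha = spike_alpha,
    depth_mean = depth_mean,
    tech_scale_sd = tech_scale_sd, stability_coupling_rho = stability_coupling_rho,
    rna_noise_sd = rna_noise_sd, n_replicates = as.integer(n_replicates),
    gene_offsets_log2 = gene_offsets_log2, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Named simulation presets
#'
#' `"arsenite"` plants the 20-fold global shutdown observed for 500 uM sodium
#' arsenite; `"null"` is the no-effect control (s = 1, no class offsets);
#' `"og"` plants the modest 1.6-fold reduction seen upon optogenetic
#' granule induction without exogenous stress (no ISR classes).
#'
#' @param name One of `"arsenite"`, `"null"`, `"og"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
isr_preset <- function(name = c("arsenite", "null", "og"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    arsenite = list(global_shutdown_s = 20),
    null = list(global_shutdown_s = 1,
                class_proportions = c(bulk = 1, resistant = 0, enhanced = 0,
                                      hypersensitive = 0),
                class_effect_log2 = list(resistant = c(mean = 0, sd = 0),
                                         enhanced = c(mean = 0, sd = 0),
                                         hypersensitive = c(mean = 0, sd = 0)),
                mito_te_log2fc = 0,
                stability_coupling_rho = 0, rna_noise_sd = 0),
    og = list(global_shutdown_s = 1.6,
              class_proportions = c(bulk = 1, resistant = 0, enhanced = 0,
                                    hypersensitive = 0),
              mito_te_log2fc = 0)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate a spike-anchored ISR ribosome-profiling experiment
#'
#' For gene g with baseline RNA abundance `a_g ~ LogNormal(4, 1.5)` and
#' baseline TE `t_g ~ LogNormal(0, 0.75)`, the stressed TE is
#' `t_g * 2^delta_g` with `delta_g = -log2(s) + class offset`, and the
#' stressed RNA is `a_g * 2^(rho * delta_g + noise)`. RPF means are
#' proportional to RNA x TE x depth x per-sample technical scale, RNA means to
#' RNA x depth x technical scale; counts are drawn NB(mean, alpha). Spike rows
#' have constant true abundance, scaled only by each sample's technical
#' factor, so spike-anchored normalization can recover the absolute shutdown
#' that library-total normalization erases.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_experiment` with elements `rpf_counts` and
#'   `rna_counts` ([count_table()]s), `design` (sample_id, condition,
#'   replicate), and `truth` (per-gene class, true `log2fc_te`, true
#'   `log2fc_rna`, flags).
#' @export
simulate_isr_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  nr <- cfg$n_replicates
  l2s <- log2(cfg$global_shutdown_s)

  ids <- c(sprintf("gene%05d", seq_len(n)),
           if (cfg$n_mito > 0) sprintf("MT-g%02d", seq_len(cfg$n_mito)),
           sprintf("spike%02d", seq_len(cfg$n_spike)))
  is_mito <- c(rep(FALSE, n), rep(TRUE, cfg$n_mito), rep(FALSE, cfg$n_spike))
  is_spike <- c(rep(FALSE, n + cfg$n_mito), rep(TRUE, cfg$n_spike))
  n_all <- length(ids)

  # gene classes and TE offsets (relative to the bulk shutdown)
  if (is.null(cfg$gene_offsets_log2)) {
    cls <- with_stream(cfg$seed, "classes",
      sample(names(cfg$class_proportions), n, replace = TRUE,
             prob = cfg$class_proportions))
    offs <- with_stream(cfg$seed, "offsets", {
      o <- numeric(n)
      for (k in c("resistant", "enhanced", "hypersensitive")) {
        idx <- which(cls == k)
        par <- cfg$class_effect_log2[[k]]
        o[idx] <- stats::rnorm(length(idx), par[["mean"]], par[["sd"]])
      }
      o
    })
  } else {
    cls <- rep("planted", n)
    offs <- cfg$gene_offsets_log2
  }

  base <- with_stream(cfg$seed, "baseline", {
    list(a = stats::rlnorm(n + cfg$n_mito, meanlog = 4, sdlog = 1.5),
         t = stats::rlnorm(n + cfg$n_mito, meanlog = 0, sdlog = 0.75))
  })

  # true effects: delta = -log2(s) + offset; mito genes move by mito_te_log2fc
  delta <- c(-l2s + offs, rep(cfg$mito_te_log2fc, cfg$n_mito))
  lfc_rna <- cfg$stability_coupling_rho * delta +
    if (cfg$rna_noise_sd > 0) {
      with_stream(cfg$seed, "rna_noise",
                  stats::rnorm(n + cfg$n_mito, 0, cfg$rna_noise_sd))
    } else 0

  # relative expected abundances per condition (endogenous + mito rows)
  rpf_ctrl <- base$a * base$t
  rpf_strs <- base$a * 2^lfc_rna * base$t * 2^delta
  rna_ctrl <- base$a
  rna_strs <- base$a * 2^lfc_rna

  spike_abund <- cfg$spike_frac / (1 - cfg$spike_frac) *
    sum(rpf_ctrl) / cfg$n_spike
  sp <- rep(spike_abund, cfg$n_spike)

  rel <- list(
    RPF = cbind(control = c(rpf_ctrl, sp), stress = c(rpf_strs, sp)),
    RNA = cbind(control = c(rna_ctrl, sp), stress = c(rna_strs, sp))
  )

  cond <- rep(c("control", "stress"), each = nr)
  samples <- paste0(cond, "_", rep(seq_len(nr), 2L))
  tabs <- list()
  for (assay in c("RPF", "RNA")) {
    tech <- with_stream(cfg$seed, paste0("tech_", assay),
                        stats::rlnorm(2L * nr, 0, cfg$tech_scale_sd))
    K <- sum(rel[[assay]][, "control"])
    mu <- rel[[assay]][, cond] %*% diag(tech) * cfg$depth_mean / K
    alpha_row <- ifelse(is_spike, cfg$spike_alpha, cfg$dispersion_alpha)
    cnt <- with_stream(cfg$seed, paste0("counts_", assay), {
      m <- mu
      m[] <- 0
      for (a in unique(alpha_row)) {
        rr <- alpha_row == a
        m[rr, ] <- rnbinom_mu_alpha(sum(rr) * ncol(mu),
                                    as.vector(mu[rr, , drop = FALSE]), a)
      }
      m
    })
    dimnames(cnt) <- list(ids, samples)
    tabs[[assay]] <- count_table(cnt, assay = assay,
                                 is_spike = is_spike, is_mito = is_mito)
  }

  truth <- data.frame(
    gene_id = ids,
    class = c(cls, rep("mito", cfg$n_mito), rep("spike", cfg$n_spike)),
    log2fc_te = c(delta, rep(0, cfg$n_spike)),
    log2fc_rna = c(lfc_rna, rep(0, cfg$n_spike)),
    is_spike = is_spike, is_mito = is_mito,
    stringsAsFactors = FALSE
  )
  structure(list(
    rpf_counts = tabs$RPF, rna_counts = tabs$RNA,
    design = data.frame(sample_id = samples, condition = cond,
                        replicate = rep(seq_len(nr), 2L),
                        stringsAsFactors = FALSE),
    truth = truth, config = cfg
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d rows x %d samples per assay (s = %g, %d reps)\n",
              nrow(x$rpf_counts$counts), ncol(x$rpf_counts$counts),
              x$config$global_shutdown_s, x$config$n_replicates))
  invisible(x)
}

#' Simulate a granule / cytoplasm fractionation experiment
#'
#' Plants `n_enriched` genes whose granule mean is `2^effect_log2` times their
#' cytoplasmic mean and `n_depleted` genes divided by the same factor; all
#' other genes have equal means in both fractions. Counts are NB-distributed.
#' Planted genes receive cytoplasmic means of at least `planted_min_mean` so
#' that recovery is count-limited only by the chosen depth.
#'
#' @param cfg A [sim_config()] (supplies `n_genes`, `dispersion_alpha`,
#'   `n_replicates`).
#' @param n_enriched,n_depleted Numbers of planted genes.
#' @param effect_log2 Planting effect (> 0, log2 units).
#' @param seed Integer seed.
#' @param planted_min_mean Floor on the cytoplasmic NB mean of planted genes.
#' @param dispersion_alpha NB dispersion of the fraction libraries. Defaults
#'   to 0.02: granule/cytoplasm libraries are parallel RNA-seq preparations
#'   from the same lysate, with replicate variance typical of RNA-seq rather
#'   than of ribosome profiling.
#' @return A list of class `sim_granule_experiment` with `granule_counts`,
#'   `cyto_counts` and a `truth` table of planted classes and true log2
#'   enrichments.
#' @export
simulate_granule_counts <- function(cfg, n_enriched, n_depleted, effect_log2,
                                    seed = cfg$seed, planted_min_mean = 500,
                                    dispersion_alpha = 0.02) {
  stopifnot(inherits(cfg, "sim_config"))
  check_scalar(n_enriched, "n_enriched", lower = 0)
  check_scalar(n_depleted, "n_depleted", lower = 0)
  if (n_enriched + n_depleted > 0) check_scalar(effect_log2, "effect_log2", lower = 1e-12)
  if (n_enriched + n_depleted > cfg$n_genes) {
    stop("n_enriched + n_depleted must be <= n_genes")
  }
  n <- cfg$n_genes
  nr <- max(2L, cfg$n_replicates)
  ids <- sprintf("gene%05d", seq_len(n))

  cyto_mean <- with_stream(seed, "granule_baseline",
                           stats::rlnorm(n, meanlog = log(300), sdlog = 1.1))
  planted <- with_stream(seed, "granule_planting",
                         sample.int(n, n_enriched + n_depleted))
  enr_idx <- planted[seq_len(n_enriched)]
  dep_idx <- planted[seq_len(n_depleted) + n_enriched]
  cyto_mean[planted] <- pmax(cyto_mean[planted], planted_min_mean)

  true_l2 <- numeric(n)
  true_l2[enr_idx] <- effect_log2
  true_l2[dep_idx] <- -effect_log2
  gran_mean <- cyto_mean * 2^true_l2

  draw <- function(mu, stream) {
    with_stream(seed, stream, {
      m <- matrix(rnbinom_mu_alpha(n * nr, rep(mu, nr), dispersion_alpha),
                  nrow = n)
      m
    })
  }
  g <- draw(gran_mean, "granule_counts")
  c_ <- draw(cyto_mean, "cyto_counts")
  dimnames(g) <- list(ids, paste0("granule_", seq_len(nr)))
  dimnames(c_) <- list(ids, paste0("cyto_", seq_len(nr)))

  cls <- rep("neither", n)
  cls[enr_idx] <- "enriched"
  cls[dep_idx] <- "depleted"
  structure(list(
    granule_counts = count_table(g, assay = "RNA"),
    cyto_counts = count_table(c_, assay = "RNA"),
    truth = data.frame(gene_id = ids, planted = cls,
                       log2_enrichment = true_l2, stringsAsFactors = FALSE)
  ), class = "sim_granule_experiment")
}

#' Write a simulated experiment to plain-text files
#'
#' Emits `rpf_counts.tsv`, `rna_counts.tsv`, `truth.tsv`, a `design.tsv`
#' with columns sample_id, condition, assay, replicate, and `config.txt`
#' as key=value lines.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(sim$rpf_counts, file.path(dir, "rpf_counts.tsv"))
  write_count_table(sim$rna_counts, file.path(dir, "rna_counts.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  des <- do.call(rbind, lapply(c("RPF", "RNA"), function(a) {
    transform(sim$design, assay = a)
  }))
  utils::write.table(des[, c("sample_id", "condition", "assay", "replicate")],
                     file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  scalars <- cfg[vapply(cfg, function(x) is.numeric(x) && length(x) == 1L,
                        logical(1))]
  writeLines(c(sprintf("%s=%s", names(scalars), unlist(scalars)),
               sprintf("class_proportions=%s",
                       paste(sprintf("%s:%g", names(cfg$class_proportions),
                                     cfg$class_proportions), collapse = ","))),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Plant two correlated per-gene effect vectors
#'
#' Generates per-gene effect pairs (for example stress-dependent and
#' granule-protein-dependent TE changes) whose population Spearman
#' correlation equals `rho_s`, using the bivariate-normal closed form
#' `rho_s = (6 / pi) * asin(r / 2)`, i.e. planting Pearson
#' `r = 2 * sin(pi * rho_s / 6)` between jointly normal effects.
#'
#' @param n Number of genes.
#' @param rho_s Target population Spearman correlation in (-1, 1).
#' @param effect_sd SD (log2 units) of each effect vector; the default 2
#'   reflects the wide per-gene spread of stress-response TE changes.
#' @param seed Integer seed.
#' @return List with vectors `x`, `y` and the planted Pearson `r`.
#' @export
plant_correlated_effects <- function(n, rho_s, effect_sd = 2, seed = 1L) {
  check_scalar(rho_s, "rho_s", lower = -0.999, upper = 0.999)
  check_scalar(effect_sd, "effect_sd", lower = 1e-12)
  r <- 2 * sin(pi * rho_s / 6)
  with_stream(seed, "correlated_effects", {
    x <- stats::rnorm(n, 0, effect_sd)
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(n, 0, effect_sd)
    list(x = x, y = y, pearson_r = r)
  })
}
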