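test_that("spike-anchored size factors follow geometric-mean anchoring", {
  m <- matrix(c(50L, 100L, 50L, 100L), nrow = 2,
              dimnames = list(c("g1", "spike01"), c("s1", "s2")))
  tab <- count_table(m, "RPF", is_spike = c(FALSE, TRUE))
  expect_equal(unname(as.numeric(spike_size_factors(tab))), c(1, 1))

  m2 <- matrix(c(10L, 100L, 10L, 200L), nrow = 2,
               dimnames = list(c("g1", "spike01"), c("s1", "s2")))
  tab2 <- count_table(m2, "RPF", is_spike = c(FALSE, TRUE))
  expect_equal(unname(as.numeric(spike_size_factors(tab2))),
               c(1 / sqrt(2), sqrt(2)))

  set.seed(14)
  m3 <- matrix(rpois(40, 900) + 1L, nrow = 8,
               dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:5)))
  spk <- c(rep(FALSE, 6), TRUE, TRUE)
  tab3 <- count_table(m3, "RPF", is_spike = spk)
  f <- as.numeric(spike_size_factors(tab3))
  tot <- colSums(m3[spk, ])
  expect_equal(f, unname(tot / exp(mean(log(tot)))), tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)

  m3[7:8, 2] <- 0L
  tab4 <- count_table(m3, "RPF", is_spike = spk)
  expect_error(spike_size_factors(tab4), "s2")
})

make_nb_table <- function(n_genes, mu, alpha, n_reps, seed, conds = 2) {
  set.seed(seed)
  m <- matrix(ribospike:::rnbinom_mu_alpha(n_genes * n_reps * conds,
                                           rep(mu, n_reps * conds), alpha),
              nrow = n_genes)
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      paste0(rep(c("A_", "B_")[seq_len(conds)],
                                 each = n_reps), seq_len(n_reps)))
  count_table(m, "RPF")
}

unit_sf <- function(tab) {
  structure(setNames(rep(1, ncol(tab$counts)), colnames(tab$counts)),
            class = "size_factors", anchor = "spike", assay = tab$assay)
}

test_that("dispersion estimation recovers Poisson and NB truth bands", {
  des <- data.frame(sample_id = c(paste0("A_", 1:8), paste0("B_", 1:8)),
                    condition = rep(c("A", "B"), each = 8))
  pois <- make_nb_table(400, 500, 0, 8, seed = 2)
  d0 <- estimate_dispersions_one(pois, des, unit_sf(pois))
  expect_lt(median(d0$final), 0.01)

  nb <- make_nb_table(400, 800, 0.1, 8, seed = 3)
  d1 <- estimate_dispersions_one(nb, des, unit_sf(nb))
  expect_gt(median(d1$final), 0.05)
  expect_lt(median(d1$final), 0.2)
})

test_that("constant replicate counts floor the raw dispersion at zero", {
  m <- matrix(700L, nrow = 3, ncol = 4,
              dimnames = list(c("g1", "g2", "g3"),
                              c("A_1", "A_2", "B_1", "B_2")))
  tab <- count_table(m, "RPF")
  des <- data.frame(sample_id = colnames(m),
                    condition = rep(c("A", "B"), each = 2))
  d <- estimate_dispersions_one(tab, des, unit_sf(tab))
  expect_true(all(d$raw <= 0))
  expect_true(all(d$final >= 1e-8))
})

test_that("unreplicated designs are refused with fixed-alpha guidance", {
  tab <- make_nb_table(10, 100, 0.05, 1, seed = 4)
  des <- data.frame(sample_id = colnames(tab$counts),
                    condition = c("A", "B"))
  expect_error(estimate_dispersions_one(tab, des, unit_sf(tab)),
               "fixed")
})

test_that("TE fold changes obey the forced arithmetic of the definition", {
  fx <- make_divided_tables(divide_rpf = 1)
  sf <- list(rpf = spike_size_factors(fx$rpf), rna = spike_size_factors(fx$rna))
  te0 <- te_foldchange(fx$rpf, fx$rna, fx$design, sf, disp = 0.05)
  expect_equal(te0$log2fc_te, rep(0, nrow(te0)))

  fx2 <- make_divided_tables(divide_rpf = 2)
  sf2 <- list(rpf = spike_size_factors(fx2$rpf), rna = spike_size_factors(fx2$rna))
  te2 <- te_foldchange(fx2$rpf, fx2$rna, fx2$design, sf2, disp = 0.05)
  expect_equal(te2$log2fc_te, rep(-1, nrow(te2)))

  fx4 <- make_divided_tables(divide_rpf = 4)
  sf4 <- list(rpf = spike_size_factors(fx4$rpf), rna = spike_size_factors(fx4$rna))
  expect_equal(global_te_shift(fx4$rpf, fx4$rna, fx4$design, sf4), 4.0)
  expect_equal(global_te_shift(fx$rpf, fx$rna, fx$design, sf), 1.0)
})

test_that("mismatched gene sets are rejected with the difference size", {
  fx <- make_divided_tables()
  rna <- fx$rna
  rownames(rna$counts)[1] <- "other"
  expect_error(te_foldchange(fx$rpf, rna, fx$design,
                             list(rpf = spike_size_factors(fx$rpf),
                                  rna = spike_size_factors(rna)),
                             disp = 0.05),
               "symmetric difference of 2")
})

test_that("per-gene TE estimates recover simulated truth with little bias", {
  cfg <- sim_config(n_genes = 600, global_shutdown_s = 4,
                    class_proportions = c(bulk = 1, resistant = 0,
                                          enhanced = 0, hypersensitive = 0),
                    dispersion_alpha = 0.05, depth_mean = 8e6,
                    n_mito = 0, seed = 17)
  sim <- simulate_isr_counts(cfg)
  te <- fit_te(sim)
  truth <- sim$truth[match(te$gene_id, sim$truth$gene_id), ]
  hi <- te$base_mean >= 500 & !is.na(te$p_abs)
  bias <- mean(te$log2fc_te[hi] - truth$log2fc_te[hi])
  expect_lt(abs(bias), 0.05)
})

test_that("the classification rule is applied as stated", {
  # craft a minimal te_result with known contrasts: g is about -4.3
  lfc <- c(0, 2, -6, -4.3, -4.3)
  res <- structure(data.frame(
    gene_id = paste0("g", 1:5), base_mean = 1000,
    log2fc_rpf = lfc, log2fc_rna = 0, log2fc_te = lfc, se = 0.1,
    p_abs = c(1e-8, 1e-6, 1e-8, 0.9, 0.9),
    padj_abs = c(1e-8, 1e-6, 1e-8, 0.9, 0.9),
    p_rel = c(1e-9, 1e-9, 1e-8, 0.9, 0.9),
    padj_rel = c(1e-9, 1e-9, 1e-8, 0.9, 0.9),
    category = NA_character_, stringsAsFactors = FALSE),
    class = c("te_result", "data.frame"), bulk_median = -4.3)
  out <- classify_isr(res)
  expect_identical(out$category,
                   c("resistant", "enhanced", "hypersensitive", "bulk", "bulk"))

  bad <- res; bad$padj_rel <- NULL
  expect_error(classify_isr(bad), "padj_rel")
})

test_that("planted response classes are recalled from strong simulations", {
  cfg <- sim_config(n_genes = 1200, global_shutdown_s = 16,
                    class_proportions = c(bulk = 0.85, resistant = 0.05,
                                          enhanced = 0.05, hypersensitive = 0.05),
                    class_effect_log2 = list(resistant = c(mean = 4, sd = 0.1),
                                             enhanced = c(mean = 7, sd = 0.1),
                                             hypersensitive = c(mean = -3, sd = 0.1)),
                    dispersion_alpha = 0.02, depth_mean = 2e7, n_mito = 0,
                    seed = 23)
  sim <- simulate_isr_counts(cfg)
  te <- classify_isr(fit_te(sim))
  truth <- sim$truth[match(te$gene_id, sim$truth$gene_id), ]
  for (k in c("resistant", "enhanced", "hypersensitive")) {
    planted <- truth$class == k & te$category != "low_count"
    expect_gte(mean(te$category[planted] == k), 0.99)
  }
})

test_that("BH adjustment reproduces the step-up formula and its properties", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(200)
  q <- adjust_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the RPF/RNA decomposition is exact and recovers coupling", {
  fx <- make_divided_tables(divide_rpf = 2)
  sf <- list(rpf = spike_size_factors(fx$rpf), rna = spike_size_factors(fx$rna))
  te <- te_foldchange(fx$rpf, fx$rna, fx$design, sf, disp = 0.05)
  dec <- rpf_rna_decomposition(te)
  expect_equal(dec$log2fc_te, dec$log2fc_rpf - dec$log2fc_rna,
               tolerance = 1e-12)

  # RNA -1, RPF 0 => TE +1
  fx_rna <- make_divided_tables(divide_rpf = 1)
  rna2 <- fx_rna$rna
  rna2$counts[rownames(rna2$counts) != "spike01", 4:6] <-
    rna2$counts[rownames(rna2$counts) != "spike01", 4:6] / 2L
  sfr <- list(rpf = spike_size_factors(fx_rna$rpf),
              rna = spike_size_factors(rna2))
  te2 <- te_foldchange(fx_rna$rpf, rna2, fx_rna$design, sfr, disp = 0.05)
  expect_equal(te2$log2fc_rna, rep(-1, nrow(te2)))
  expect_equal(te2$log2fc_te, rep(1, nrow(te2)))

  # slope of RNA change on TE change recovers the planted coupling
  set.seed(31)
  offs <- rnorm(2000, 0, 2)
  sim <- simulate_isr_counts(sim_config(
    n_genes = 2000, global_shutdown_s = 4, gene_offsets_log2 = offs,
    stability_coupling_rho = -0.5, rna_noise_sd = 0.02,
    depth_mean = 2e7, dispersion_alpha = 0.02, n_mito = 0, seed = 33))
  tes <- fit_te(sim)
  ok <- !is.na(tes$p_abs)
  slope <- coef(lm(tes$log2fc_rna[ok] ~ tes$log2fc_te[ok]))[2]
  expect_lt(abs(slope - (-0.5)), 0.05)
})

test_that("spike rows are exactly null after spike anchoring", {
  sim <- simulate_isr_counts(isr_preset("arsenite", n_genes = 400, seed = 44))
  te <- fit_te(sim)
  expect_lt(abs(attr(te, "spike_log2fc_te")), 1e-12)
})

test_that("estimates are invariant to rescaling any single library", {
  sim <- simulate_isr_counts(isr_preset("arsenite", n_genes = 300, seed = 55))
  te1 <- fit_te(sim)
  scaled <- sim
  scaled$rpf_counts$counts[, 2] <- scaled$rpf_counts$counts[, 2] * 7L
  te2 <- fit_te(scaled)
  expect_lt(max(abs(te1$log2fc_te - te2$log2fc_te)), 1e-9)
})

test_that("spike anchoring separates a true shutdown from library anchoring", {
  cfg <- sim_config(n_genes = 1000, global_shutdown_s = 8,
                    class_proportions = c(bulk = 1, resistant = 0,
                                          enhanced = 0, hypersensitive = 0),
                    n_mito = 0, seed = 66)
  sim <- simulate_isr_counts(cfg)
  expect_lt(abs(shift_of(sim, "spike") - 8) / 8, 0.15)
  expect_lt(abs(log2(shift_of(sim, "library"))), log2(1.5))
})

test_that("no planted effect keeps the discovery rate within FDR control", {
  sim <- simulate_isr_counts(isr_preset("null", n_genes = 2000, seed = 77))
  te <- classify_isr(fit_te(sim))
  tested <- !is.na(te$padj_abs)
  expect_lte(mean(te$padj_abs[tested] < 0.05), 0.05)
  expect_lte(mean(te$category[tested] != "bulk"), 0.05)
})

test_that("spike-anchored fold changes agree with an established NB engine", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_isr_counts(sim_config(
    n_genes = 400, global_shutdown_s = 6,
    class_proportions = c(bulk = 1, resistant = 0, enhanced = 0,
                          hypersensitive = 0),
    n_mito = 0, depth_mean = 4e6, seed = 88))
  sf <- spike_size_factors(sim$rpf_counts)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$rpf_counts$counts,
      colData = data.frame(condition = factor(sim$design$condition,
                                              levels = c("control", "stress"))),
      design = ~condition)
    DESeq2::sizeFactors(dds) <- as.numeric(sf)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  sfl <- list(rpf = sf, rna = spike_size_factors(sim$rna_counts))
  disp <- estimate_dispersions(sim$rpf_counts, sim$rna_counts, sim$design, sfl)
  te <- te_foldchange(sim$rpf_counts, sim$rna_counts, sim$design, sfl, disp)
  ok <- !is.na(te$p_abs) & !is.na(res$log2FoldChange[match(te$gene_id,
                                                           rownames(res))])
  ours <- te$log2fc_rpf[ok]
  theirs <- res$log2FoldChange[match(te$gene_id, rownames(res))][ok]
  expect_gt(cor(ours, theirs), 0.98)
  expect_lt(abs(median(ours - theirs)), 0.1)
})
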