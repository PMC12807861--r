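test_that("no-effect configuration plants zero TE change everywhere", {
  cfg <- isr_preset("null", n_genes = 50, seed = 3)
  sim <- simulate_isr_counts(cfg)
  expect_true(all(sim$truth$log2fc_te == 0))
  expect_true(all(sim$truth$log2fc_rna == 0))
})

test_that("a pure 20-fold shutdown forces bulk truth to -log2(20) exactly", {
  cfg <- sim_config(n_genes = 80, global_shutdown_s = 20,
                    class_proportions = c(bulk = 1, resistant = 0,
                                          enhanced = 0, hypersensitive = 0),
                    n_mito = 0, seed = 4)
  sim <- simulate_isr_counts(cfg)
  endo <- !sim$truth$is_spike
  expect_identical(unique(sim$truth$log2fc_te[endo]), -log2(20))
  expect_identical(mean(sim$truth$log2fc_te[sim$truth$class == "bulk"]),
                   -log2(20))
})

test_that("NB draws match the mean/variance relation v = m + alpha m^2", {
  set.seed(11)
  x <- ribospike:::rnbinom_mu_alpha(10000, mu = 100, alpha = 0.1)
  expect_lt(abs(var(x) - 1100) / 1100, 0.10)
  y <- ribospike:::rnbinom_mu_alpha(10000, mu = 100, alpha = 0)
  expect_lt(abs(var(y) - 100) / 100, 0.10)
})

test_that("spike rows have constant true abundance across samples", {
  cfg <- sim_config(n_genes = 300, tech_scale_sd = 0, spike_alpha = 0,
                    dispersion_alpha = 0, depth_mean = 5e6, seed = 5)
  sim <- simulate_isr_counts(cfg)
  expect_true(all(sim$truth$log2fc_te[sim$truth$is_spike] == 0))
  expect_true(all(sim$truth$log2fc_rna[sim$truth$is_spike] == 0))
  # with technical scaling off, realized spike totals are Poisson around a
  # constant mean: CV across samples collapses to counting noise only
  tot <- colSums(sim$rpf_counts$counts[sim$rpf_counts$is_spike, ])
  expect_lt(sd(tot) / mean(tot), 0.02)
})

test_that("identical configuration and seed reproduce bitwise-identical output", {
  cfg <- isr_preset("arsenite", n_genes = 120, seed = 99)
  s1 <- simulate_isr_counts(cfg)
  s2 <- simulate_isr_counts(cfg)
  expect_identical(s1$rpf_counts$counts, s2$rpf_counts$counts)
  expect_identical(s1$rna_counts$counts, s2$rna_counts$counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("stability coupling links RNA truth to TE truth gene by gene", {
  cfg <- sim_config(n_genes = 60, stability_coupling_rho = -0.5,
                    rna_noise_sd = 0, seed = 8)
  sim <- simulate_isr_counts(cfg)
  endo <- !sim$truth$is_spike & !sim$truth$is_mito
  expect_equal(sim$truth$log2fc_rna[endo], -0.5 * sim$truth$log2fc_te[endo],
               tolerance = 1e-12)
})

test_that("invalid simulator parameters are rejected naming the field", {
  expect_error(sim_config(global_shutdown_s = NaN), "global_shutdown_s")
  expect_error(sim_config(dispersion_alpha = -1), "dispersion_alpha")
  expect_error(sim_config(stability_coupling_rho = 0.5), "stability_coupling_rho")
  expect_error(sim_config(class_proportions = c(bulk = 0.5, resistant = 0.2,
                                                enhanced = 0.2,
                                                hypersensitive = 0.2)),
               "sum to 1")
})

test_that("granule planting records exact truth and respects bounds", {
  cfg <- sim_config(n_genes = 200, seed = 7)
  none <- simulate_granule_counts(cfg, 0, 0, 3)
  expect_identical(sum(none$truth$planted != "neither"), 0L)

  gs <- simulate_granule_counts(cfg, 10, 5, 3)
  expect_identical(sum(gs$truth$planted == "enriched"), 10L)
  expect_identical(sum(gs$truth$planted == "depleted"), 5L)
  expect_true(all(gs$truth$log2_enrichment[gs$truth$planted == "enriched"] >= 3))
  expect_true(all(gs$granule_counts$counts >= 0))
  expect_true(all(gs$granule_counts$counts ==
                    round(gs$granule_counts$counts)))
  expect_error(simulate_granule_counts(cfg, 150, 100, 3), "n_genes")
})

test_that("strongly planted enrichment is recovered by the classifier", {
  cfg <- sim_config(n_genes = 1500, seed = 21)
  gs <- simulate_granule_counts(cfg, 60, 40, 3, planted_min_mean = 500)
  enr <- enrichment_test(gs$granule_counts, gs$cyto_counts)
  called <- enr$gene_id[enr$category == "enriched"]
  planted <- gs$truth$gene_id[gs$truth$planted == "enriched"]
  recall <- mean(planted %in% called)
  expect_gte(recall, 0.99)
})

test_that("reporter presets are validated and anchored at their baseline", {
  expect_error(simulate_reporter_timecourse("nope", c(0, 30)),
               "untethered.*tethered_g3bp")
  expect_error(simulate_reporter_timecourse("untethered", c(30, 10)),
               "increasing")
  for (preset in c("untethered", "tethered_g3bp",
                   "tethered_caprin1_plusSG", "tethered_caprin1_minusSG")) {
    ser <- simulate_reporter_timecourse(preset, c(0, 45, 90), seed = 2)
    truth <- attr(ser, "truth")
    pars <- ribospike:::reporter_presets()[[preset]]
    expect_equal(truth$true_te[truth$timepoint_min == 0], pars$te0)
    expect_equal(truth$true_mrna[truth$timepoint_min == 0], 1)
  }
})

test_that("numerical mRNA kinetics agree with the integrating-factor solution", {
  # For the untethered preset TE(t) <= 1 everywhere, so
  # lambda(t) = k_base + k_trans * (fl + (1 - fl) e^(-k t)) integrates in
  # closed form; the exact solution is
  # M(t) = e^(-L(t)) (1 + k_txn Int_0^t e^(L(u)) du)
  # with the integral evaluated by adaptive quadrature — an oracle
  # independent of the ODE solver.
  pars <- ribospike:::reporter_presets()$untethered
  kin <- ribospike:::reporter_kinetics()
  fl <- pars$te_floor; k <- pars$k_te
  L <- function(t) {
    (kin$k_base + kin$k_trans * fl) * t +
      kin$k_trans * (1 - fl) * (1 - exp(-k * t)) / k
  }
  k_txn <- kin$k_base + kin$k_trans  # lambda(TE(0)) with TE(0) = 1
  closed <- function(t) {
    q <- stats::integrate(function(u) exp(L(u)), 0, t, rel.tol = 1e-12)$value
    exp(-L(t)) * (1 + k_txn * q)
  }
  t <- c(15, 45, 90)
  num <- ribospike:::reporter_mrna_curve(pars, t)
  exact <- vapply(t, closed, 1)
  expect_equal(num, exact, tolerance = 1e-6)
})

test_that("translation-free kinetics converge to the basal steady state", {
  # with k_trans = 0, dM/dt = k_txn - k_base M has steady state k_txn/k_base
  kin <- list(k_base = 0.05, k_trans = 0)
  pars <- list(te0 = 1, te_floor = 0.04, k_te = 0.0507)
  m <- ribospike:::reporter_mrna_curve(pars, c(0, 200, 400), kin = kin)
  expect_equal(m[3], 1, tolerance = 1e-6)  # k_txn/k_base = M(0) = 1
})

test_that("polysome fractions are proportions shifted light under stress", {
  p <- simulate_polysome_fractions(12, "unstressed", seed = 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_error(simulate_polysome_fractions(1, "unstressed"), "n_fractions")

  late <- simulate_polysome_fractions(12, "late_stress", seed = 1)
  expect_gt(sum(late[1:3]), sum(p[1:3]))

  idx <- seq_len(12)
  mean_idx <- function(shift, seed) {
    sum(idx * simulate_polysome_fractions(12, shift, seed = seed))
  }
  late_mean <- vapply(1:100, function(s) mean_idx("late_stress", s), 1)
  un_mean <- vapply(1:100, function(s) mean_idx("unstressed", s), 1)
  expect_true(all(late_mean < un_mean))
})

test_that("simulated experiments round-trip through the TSV writers", {
  sim <- simulate_isr_counts(isr_preset("null", n_genes = 30, seed = 12))
  dir <- withr::local_tempdir()
  write_sim_experiment(sim, dir)
  back <- read_count_table(file.path(dir, "rpf_counts.tsv"))
  expect_identical(back$counts, sim$rpf_counts$counts)
  expect_identical(back$is_spike, sim$rpf_counts$is_spike)
  expect_identical(back$assay, "RPF")
  des <- read.table(file.path(dir, "design.tsv"), header = TRUE, sep = "\t")
  expect_setequal(colnames(des), c("sample_id", "condition", "assay", "replicate"))
})
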