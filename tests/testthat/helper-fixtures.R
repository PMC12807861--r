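# Shared fixture builders: everything is generated in code at test time.

# Deterministic two-condition count tables (3 + 3 samples) with one constant
# spike row; stress divides every endogenous RPF count by `divide_rpf`.
make_divided_tables <- function(divide_rpf = 2, n_genes = 6, base = 4000) {
  ids <- c(sprintf("g%02d", seq_len(n_genes)), "spike01")
  samples <- c(paste0("control_", 1:3), paste0("stress_", 1:3))
  gene_counts <- matrix(rep(base * seq_len(n_genes), 6), ncol = 6,
                        dimnames = list(ids[seq_len(n_genes)], samples))
  gene_counts[, 4:6] <- gene_counts[, 4:6] / divide_rpf
  rpf <- rbind(gene_counts, spike01 = rep(1000, 6))
  rna <- rbind(matrix(rep(base * seq_len(n_genes), 6), ncol = 6,
                      dimnames = list(ids[seq_len(n_genes)], samples)),
               spike01 = rep(1000, 6))
  colnames(rpf) <- colnames(rna) <- samples
  list(
    rpf = count_table(rpf, "RPF", is_spike = ids == "spike01"),
    rna = count_table(rna, "RNA", is_spike = ids == "spike01"),
    design = data.frame(sample_id = samples,
                        condition = rep(c("control", "stress"), each = 3),
                        replicate = rep(1:3, 2))
  )
}

fit_te <- function(sim, anchor = "spike") {
  sf <- list(rpf = spike_size_factors(sim$rpf_counts, anchor),
             rna = spike_size_factors(sim$rna_counts, anchor))
  disp <- estimate_dispersions(sim$rpf_counts, sim$rna_counts, sim$design, sf)
  te_foldchange(sim$rpf_counts, sim$rna_counts, sim$design, sf, disp)
}

shift_of <- function(sim, anchor = "spike") {
  sf <- list(rpf = spike_size_factors(sim$rpf_counts, anchor),
             rna = spike_size_factors(sim$rna_counts, anchor))
  global_te_shift(sim$rpf_counts, sim$rna_counts, sim$design, sf)
}
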