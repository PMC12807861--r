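#' Reporter translation efficiency
#'
#' TE of a tethering reporter from one measurement:
#' `TE = (luciferase signal / total protein) / (reporter mRNA / reference
#' mRNA)`, where the mRNA ratio is typically a qPCR relative abundance from
#' [qpcr_rel()]. The quantity is unitless and scale-invariant to jointly
#' rescaling luciferase and protein.
#'
#' @param luc_signal Luminescence units (> 0).
#' @param total_protein Total protein, micrograms (> 0).
#' @param reporter_mrna_rel Reporter mRNA relative to the reference gene (> 0).
#' @return TE (unitless).
#' @export
reporter_te <- function(luc_signal, total_protein, reporter_mrna_rel) {
  vals <- list(luc_signal = luc_signal, total_protein = total_protein,
               reporter_mrna_rel = reporter_mrna_rel)
  for (nm in names(vals)) {
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] <= 0)) {
      stop(sprintf("'%s' must be positive and finite", nm))
    }
  }
  (luc_signal / total_protein) / reporter_mrna_rel
}

#' qPCR relative abundance
#'
#' `efficiency^(Cq_reference - Cq_target)`: equal Cq values give 1; a target
#' amplifying one cycle earlier than the reference at perfect doubling gives 2.
#'
#' @param cq_target,cq_reference Quantification cycles (finite).
#' @param efficiency Amplification efficiency per cycle, in (1, 2] (default
#'   2, perfect doubling).
#' @return Relative abundance (unitless).
#' @export
qpcr_rel <- function(cq_target, cq_reference, efficiency = 2.0) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference))) {
    stop("Cq values must be finite")
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 1 || efficiency > 2) {
    stop("'efficiency' must be in (1, 2]")
  }
  efficiency^(cq_reference - cq_target)
}

#' Relative TE time course
#'
#' Computes per-measurement TE via [reporter_te()] and [qpcr_rel()], then
#' normalizes each replicate's series to that replicate's matched baseline
#' (by default the measurement at the earliest timepoint of the baseline
#' condition), mirroring reporting relative to untethered, unstressed cells
#' of the matched biological replicate. Also reports
#' `percent reduction = 100 * (1 - relative TE)`.
#'
#' @param series A `reporter_series` data.frame (see
#'   [simulate_reporter_timecourse()]) with columns `timepoint_min`,
#'   `condition`, `replicate`, `luc`, `protein_ug`, `cq_reporter`,
#'   `cq_reference`.
#' @param baseline_condition Condition supplying the baseline; defaults to
#'   the condition of the series itself (single-condition series).
#' @param baseline_time Baseline timepoint (default: earliest).
#' @param efficiency qPCR efficiency passed to [qpcr_rel()].
#' @return `series` with added columns `te`, `rel_te`, `pct_reduction`.
#' @export
relative_te <- function(series, baseline_condition = NULL, baseline_time = NULL,
                        efficiency = 2.0) {
  need <- c("timepoint_min", "condition", "replicate", "luc", "protein_ug",
            "cq_reporter", "cq_reference")
  miss <- setdiff(need, colnames(series))
  if (length(miss)) stop("series lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(baseline_condition)) baseline_condition <- series$condition[1]
  if (is.null(baseline_time)) {
    baseline_time <- min(series$timepoint_min[series$condition == baseline_condition])
  }
  mrna <- qpcr_rel(series$cq_reporter, series$cq_reference, efficiency)
  te <- reporter_te(series$luc, series$protein_ug, mrna)
  base <- series$condition == baseline_condition &
    series$timepoint_min == baseline_time
  base_te <- tapply(te[base], series$replicate[base], mean)
  reps <- as.character(series$replicate)
  missing_rep <- setdiff(unique(reps), names(base_te))
  if (length(missing_rep)) {
    stop("no matched baseline measurement for replicate(s): ",
         paste(missing_rep, collapse = ", "))
  }
  series$te <- te
  series$rel_te <- te / as.numeric(base_te[reps])
  series$pct_reduction <- 100 * (1 - series$rel_te)
  series
}

#' Ribosome load of a polysome profile
#'
#' Expected ribosomes per transcript: the proportion of reporter mRNA in each
#' gradient fraction weighted by the mean number of ribosomes on transcripts
#' in that fraction, summed across fractions.
#'
#' @param proportions Fraction proportions (non-negative, summing to 1
#'   within 1e-9).
#' @param ribosomes_per_fraction Ribosome numbers per fraction; the defaults
#'   for a 12-fraction gradient put 0 ribosomes in the free-RNA and subunit
#'   fractions (1-3), 1 in the monosome fraction (4) and 2,3,4,5,6,8,10,12 in
#'   the polysome fractions (5-12). These are a required configuration in
#'   real use: results are exposed as sensitivity analyses in `r_i`.
#' @return `ribosome_load`: the load (ribosomes/transcript);
#'   `relative_load`: the ratio `load_a / load_b`.
#' @export
ribosome_load <- function(proportions,
                          ribosomes_per_fraction = default_ribosomes(length(proportions))) {
  if (length(proportions) != length(ribosomes_per_fraction)) {
    stop("proportions and ribosomes_per_fraction must have equal length")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1")
  }
  if (any(ribosomes_per_fraction < 0)) stop("ribosome numbers must be >= 0")
  sum(proportions * ribosomes_per_fraction)
}

#' @rdname ribosome_load
#' @param a,b Proportion vectors for the two profiles being compared.
#' @param ... Passed to [ribosome_load()].
#' @export
relative_load <- function(a, b, ...) {
  la <- ribosome_load(a, ...)
  lb <- ribosome_load(b, ...)
  if (lb == 0) stop("reference profile has zero ribosome load")
  la / lb
}

default_ribosomes <- function(n) {
  if (n == 12) return(c(0, 0, 0, 1, 2, 3, 4, 5, 6, 8, 10, 12))
  c(rep(0, max(0, ceiling(n / 4) - 1)), 1,
    seq_len(max(0, n - ceiling(n / 4))) + 1)
}

#' Apply per-fraction recovery standards
#'
#' Divides reporter qPCR abundances by the recovery of a fixed in-vitro
#' transcribed standard spiked into every fraction, then renormalizes to
#' proportions, correcting fraction-to-fraction extraction differences.
#'
#' @param reporter_rel Reporter relative abundances per fraction.
#' @param standard_rel Standard relative abundances per fraction (> 0).
#' @return Corrected fraction proportions summing to 1.
#' @export
fraction_proportions <- function(reporter_rel, standard_rel = rep(1, length(reporter_rel))) {
  if (length(reporter_rel) != length(standard_rel)) {
    stop("reporter and standard vectors must have equal length")
  }
  if (any(standard_rel <= 0)) stop("standard recoveries must be positive")
  if (any(reporter_rel < 0)) stop("reporter abundances must be non-negative")
  x <- reporter_rel / standard_rel
  if (sum(x) == 0) stop("all-zero reporter abundances")
  x / sum(x)
}
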