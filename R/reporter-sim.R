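# Tethering-reporter presets. TE(t) = te0 * (floor + (1 - floor) * exp(-k t)),
# in units where the unstressed untethered reporter has TE = 1. The untethered
# decay constants are calibrated so TE(90)/TE(0) = 0.05 (the observed 95%
# reduction over 90 min of arsenite) and so the translation-coupled mRNA
# kinetics accumulate ~5.2-fold over the same course.
reporter_presets <- function() {
  list(
    untethered = list(te0 = 1, te_floor = 0.04, k_te = 0.0507),
    tethered_g3bp = list(te0 = 3, te_floor = 0.30, k_te = 0.035),
    tethered_caprin1_plusSG = list(te0 = 1.2, te_floor = 0.30, k_te = 0.040),
    tethered_caprin1_minusSG = list(te0 = 1, te_floor = 0.22, k_te = 0.045)
  )
}

# mRNA kinetics: dM/dt = k_txn - (k_base + k_trans * min(TE, 1)) * M.
# Destabilization saturates at the unstressed untethered translation rate,
# so tethering above that baseline does not destabilize further.
reporter_kinetics <- function() {
  list(k_base = 0.0025, k_trans = 0.09)
}

reporter_te_curve <- function(preset_pars, t) {
  preset_pars$te0 * (preset_pars$te_floor +
                       (1 - preset_pars$te_floor) * exp(-preset_pars$k_te * t))
}

# Deterministic mRNA trajectory for a preset, M(0) = 1 (pre-stress steady
# state: k_txn = lambda(TE(0))).
reporter_mrna_curve <- function(preset_pars, t, kin = reporter_kinetics()) {
  lam <- function(te) kin$k_base + kin$k_trans * pmin(te, 1)
  k_txn <- lam(reporter_te_curve(preset_pars, 0))
  rhs <- function(tt, y, p) {
    list(k_txn - lam(reporter_te_curve(preset_pars, tt)) * y[1])
  }
  times <- sort(unique(c(0, t)))
  out <- deSolve::ode(y = c(M = 1), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  out[match(t, times), "M"]
}

#' Simulate a tethering-reporter stress time course
#'
#' Emulates a luciferase tethering assay: the reporter's translation
#' efficiency decays according to the chosen preset during arsenite stress
#' while its mRNA follows translation-coupled decay
#' `dM/dt = k_txn - (k_base + k_trans * TE(t)) * M`, so shutting down
#' translation stabilizes and accumulates the untethered reporter mRNA.
#' Luciferase signal is proportional to `TE(t) * M(t)`, total protein is
#' constant up to noise, and reporter mRNA is read out as qPCR Cq values
#' against a constant reference gene.
#'
#' @param preset One of `"untethered"`, `"tethered_g3bp"`,
#'   `"tethered_caprin1_plusSG"`, `"tethered_caprin1_minusSG"`.
#' @param timepoints Minutes of stress; non-empty, non-negative, increasing.
#' @param seed Integer seed.
#' @param n_replicates Biological replicates.
#' @param noise_sd Multiplicative (log-normal) measurement noise SD for
#'   luciferase and protein; Cq noise is `noise_sd` cycles.
#' @return A data.frame of class `reporter_series` with columns
#'   `timepoint_min`, `condition`, `replicate`, `luc`, `protein_ug`,
#'   `cq_reporter`, `cq_reference`; the noise-free truth (`true_te`,
#'   `true_mrna`) is attached as attribute `"truth"`.
#' @export
simulate_reporter_timecourse <- function(preset, timepoints = seq(0, 90, by = 15),
                                         seed = 1L, n_replicates = 3,
                                         noise_sd = 0.04) {
  presets <- reporter_presets()
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available presets: %s",
                 paste(preset, collapse = ","),
                 paste(names(presets), collapse = ", ")))
  }
  if (length(timepoints) == 0 || any(timepoints < 0) ||
      any(diff(timepoints) <= 0)) {
    stop("timepoints must be non-empty, non-negative and increasing")
  }
  pars <- presets[[preset]]
  te <- reporter_te_curve(pars, timepoints)
  M <- reporter_mrna_curve(pars, timepoints)

  nt <- length(timepoints)
  q0 <- 0.05      # reporter / reference abundance at baseline
  k_lum <- 1e4    # luminescence units per unit TE*mRNA*protein
  df <- with_stream(seed, paste0("reporter_", preset), {
    out <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      protein <- 100 * stats::rlnorm(nt, 0, noise_sd)
      luc <- k_lum * te * M * protein * stats::rlnorm(nt, 0, noise_sd)
      cq_ref <- 20 + stats::rnorm(nt, 0, noise_sd)
      cq_rep <- cq_ref - log2(M * q0) + stats::rnorm(nt, 0, noise_sd)
      out[[r]] <- data.frame(timepoint_min = timepoints, condition = preset,
                             replicate = r, luc = luc, protein_ug = protein,
                             cq_reporter = cq_rep, cq_reference = cq_ref,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  attr(df, "truth") <- data.frame(timepoint_min = timepoints,
                                  true_te = te, true_mrna = M)
  class(df) <- c("reporter_series", "data.frame")
  df
}

#' Simulate polysome-gradient fraction proportions
#'
#' Returns the proportion of a reporter mRNA in each of `n_fractions` sucrose
#' gradient fractions (light to heavy). Under stress presets the mass shifts
#' from heavy polysome fractions toward free/monosome fractions, emulating
#' polysome collapse.
#'
#' @param n_fractions Number of fractions (>= 2; default 12).
#' @param shift One of `"unstressed"`, `"early_stress"`, `"late_stress"`.
#' @param seed Integer seed.
#' @param concentration Dirichlet-like concentration; larger = less noise.
#' @return Numeric vector of proportions summing to 1.
#' @export
simulate_polysome_fractions <- function(n_fractions = 12,
                                        shift = c("unstressed", "early_stress",
                                                  "late_stress"),
                                        seed = 1L, concentration = 300) {
  shift <- match.arg(shift)
  if (!is.numeric(n_fractions) || length(n_fractions) != 1L || n_fractions < 2) {
    stop("n_fractions must be >= 2")
  }
  n <- as.integer(n_fractions)
  i <- seq_len(n)
  comp <- function(w_free, w_mono, w_heavy) {
    w <- w_free * stats::dnorm(i, 0.125 * n, 0.1 * n) +
      w_mono * stats::dnorm(i, n / 3, 0.09 * n) +
      w_heavy * stats::dnorm(i, 0.8 * n, 0.18 * n)
    w / sum(w)
  }
  w <- switch(shift,
    unstressed = comp(0.12, 0.18, 0.70),
    early_stress = comp(0.30, 0.30, 0.40),
    late_stress = comp(0.62, 0.26, 0.12)
  )
  p <- with_stream(seed, paste0("polysome_", shift),
                   stats::rgamma(n, shape = concentration * w, rate = 1))
  p / sum(p)
}
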