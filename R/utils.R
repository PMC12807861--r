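#' @keywords internal
"_PACKAGE"

# Deterministic per-table RNG streams: one integer seed drives one named
# stream per output table, so adding a table never perturbs the others.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1009 + h * 7919) %% .Machine$integer.max)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

# NB draws parameterized by mean and dispersion alpha (variance = m + alpha m^2);
# alpha = 0 degenerates to Poisson.
rnbinom_mu_alpha <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, lambda = mu))
  stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}
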