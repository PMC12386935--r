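# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points use this so no
# global state leaks between calls.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  code
}

std_err <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Probability mass function of a gamma(mean, cv) duration rounded to whole
# days with a floor of `min` days. cv = 0 collapses to a point mass. Both the
# simulator and the analytic ground truth draw from / integrate over this same
# pmf, so the two routes share one discretisation.
disc_gamma_pmf <- function(mean, cv, min = 1L, tail = 1e-10) {
  stopifnot(mean >= 0, cv >= 0)
  if (cv == 0 || mean == 0) {
    k <- max(min, as.integer(round(mean)))
    return(list(support = k, pmf = 1))
  }
  shape <- 1 / cv^2
  scale <- mean * cv^2
  hi <- max(min, ceiling(stats::qgamma(1 - tail, shape = shape, scale = scale)))
  support <- min:hi
  upper <- stats::pgamma(support + 0.5, shape = shape, scale = scale)
  lower <- stats::pgamma(support - 0.5, shape = shape, scale = scale)
  pmf <- upper - lower
  pmf[1] <- upper[1]                       # fold mass below min+0.5 into min
  pmf[length(pmf)] <- pmf[length(pmf)] + (1 - upper[length(upper)])
  list(support = support, pmf = pmf / sum(pmf))
}

sample_pmf <- function(dist, n = 1L) {
  if (length(dist$support) == 1L) return(rep(dist$support, n))
  sample(dist$support, n, replace = TRUE, prob = dist$pmf)
}

pmf_mean <- function(dist) sum(dist$support * dist$pmf)
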