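# Bootstrap machinery. The resampling unit is the individual (whole life
# history). All heavy lifting is done with crossproducts of per-individual
# summary matrices against a matrix of resample counts, so B in the tens of
# thousands runs in seconds.

BOOT_PARAMS <- c("R0", "r", "lambda", "T",
                 "Nf_N", "Nfr_Nf", "Nm_N", "fecundity",
                 "female_longevity", "male_longevity", "total_longevity",
                 "preadult", "APOP", "TPOP", "Od")

# Per-individual value (V) and eligibility (M) matrices for the parameters
# that are weighted means over a subset of individuals.
boot_stat_matrices <- function(a) {
  female <- a$sex == "female"
  male <- a$sex == "male"
  ovip <- female & a$total_eggs > 0
  adult <- !is.na(a$emergence)
  fdur <- a$Dur[, a$schema$female]
  mdur <- if (length(a$schema$male)) a$Dur[, a$schema$male[1L]] else
    rep(NA_real_, a$n)
  z <- function(x) ifelse(is.na(x), 0, x)
  V <- cbind(Nf_N = as.numeric(female), Nfr_Nf = as.numeric(ovip),
             Nm_N = as.numeric(male), fecundity = a$total_eggs,
             female_longevity = z(fdur), male_longevity = z(mdur),
             total_longevity = a$death_age, preadult = z(a$emergence),
             APOP = z(a$first_egg - a$emergence), TPOP = z(a$first_egg),
             Od = a$ovi_days)
  M <- cbind(Nf_N = rep(1, a$n), Nfr_Nf = as.numeric(female),
             Nm_N = rep(1, a$n), fecundity = as.numeric(female),
             female_longevity = as.numeric(female & !is.na(fdur)),
             male_longevity = as.numeric(male & !is.na(mdur)),
             total_longevity = rep(1, a$n), preadult = as.numeric(adult),
             APOP = as.numeric(ovip), TPOP = as.numeric(ovip),
             Od = as.numeric(ovip))
  list(V = V, M = M)
}

# Vectorised bisection for the Euler-Lotka root of each column of a
# net-maternity matrix LM (rows = ages 0..A-1, columns = resamples).
solve_r_batch <- function(LM, lower = -1, upper = 2, iter = 60L) {
  nc <- ncol(LM)
  r <- rep(NA_real_, nc)
  ok <- colSums(LM) > 0
  if (!any(ok)) return(r)
  rows <- which(rowSums(LM[, ok, drop = FALSE]) > 0)
  W <- LM[rows, ok, drop = FALSE]
  xp1 <- rows                                  # row index = age + 1
  lo <- rep(lower, sum(ok)); hi <- rep(upper, sum(ok))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fx <- colSums(W * exp(outer(xp1, mid, function(x, m) -x * m))) - 1
    up <- fx > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  r[ok] <- (lo + hi) / 2
  r
}

# Draw B bootstrap resamples and compute the requested parameters for each.
# Not seeded: callers wrap in local_seed(). Returns a B x length(parameters)
# matrix of draws (NA where a parameter is undefined in a resample).
boot_draws <- function(a, B, parameters = BOOT_PARAMS, chunk = 5000L) {
  sm <- boot_stat_matrices(a)
  keep_mean <- intersect(parameters, colnames(sm$V))
  need_R0 <- any(c("R0", "T") %in% parameters)
  need_r <- any(c("r", "lambda", "T") %in% parameters)
  tE <- t(a$E)
  out <- matrix(NA_real_, B, length(parameters),
                dimnames = list(NULL, parameters))
  done <- 0L
  while (done < B) {
    bc <- min(chunk, B - done)
    idx <- sample.int(a$n, a$n * bc, replace = TRUE)
    dim(idx) <- c(a$n, bc)
    W <- vapply(seq_len(bc), function(k) tabulate(idx[, k], nbins = a$n),
                numeric(a$n))
    cols <- done + seq_len(bc)
    if (length(keep_mean)) {
      num <- crossprod(sm$V[, keep_mean, drop = FALSE] *
                         sm$M[, keep_mean, drop = FALSE], W)
      den <- crossprod(sm$M[, keep_mean, drop = FALSE], W)
      vals <- t(num / den)                     # bc x params; NaN when empty
      vals[!is.finite(vals)] <- NA_real_
      out[cols, keep_mean] <- vals
    }
    if (need_R0 || need_r) {
      LM <- (tE %*% W) / a$n                   # net maternity per resample
      if (need_R0 && "R0" %in% parameters) out[cols, "R0"] <- colSums(LM)
      if (need_r) {
        rb <- solve_r_batch(LM)
        if ("r" %in% parameters) out[cols, "r"] <- rb
        if ("lambda" %in% parameters) out[cols, "lambda"] <- exp(rb)
        if ("T" %in% parameters) {
          R0b <- colSums(LM)
          out[cols, "T"] <- ifelse(R0b > 0 & is.finite(rb) & rb != 0,
                                   log(R0b) / rb, NA_real_)
        }
      }
    }
    done <- done + bc
  }
  out
}

new_boot_dist <- function(parameter, draws, conf) {
  good <- draws[is.finite(draws)]
  ci <- if (length(good)) stats::quantile(good, c((1 - conf) / 2,
                                                  1 - (1 - conf) / 2),
                                          names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(parameter = parameter, B = length(draws), draws = draws,
                 mean = if (length(good)) mean(good) else NA_real_,
                 se = if (length(good) > 1) stats::sd(good) else 0,
                 ci = ci, conf = conf,
                 n_missing = sum(!is.finite(draws))),
            class = "boot_dist")
}

#' @export
print.boot_dist <- function(x, ...) {
  cat(sprintf("<boot_dist> %s: mean = %.4g, SE = %.4g, %g%% CI [%.4g, %.4g] (B = %d",
              x$parameter, x$mean, x$se, 100 * x$conf, x$ci[1], x$ci[2], x$B))
  if (x$n_missing > 0) cat(", ", x$n_missing, " undefined resamples", sep = "")
  cat(")\n")
  invisible(x)
}

#' Bootstrap distributions of demographic parameters
#'
#' Resamples n individuals with replacement B times, recomputes every
#' requested parameter for each resample, and returns the bootstrap mean,
#' standard error (SD of the draws) and percentile confidence interval per
#' parameter. Resamples in which a parameter is undefined (e.g. r when a
#' resample contains no reproduction) are recorded as missing and counted.
#'
#' @param cohort A valid [cohort_table()].
#' @param B Number of resamples (default 100,000, the convention for two-sex
#'   life table studies; use 1,000-10,000 for interactive work).
#' @param seed Integer seed; required (all randomness is explicit).
#' @param parameters Character vector of parameter names (subset of
#'   `c("R0","r","lambda","T","Nf_N","Nfr_Nf","Nm_N","fecundity",
#'   "female_longevity","male_longevity","total_longevity","preadult",
#'   "APOP","TPOP","Od")`); default all.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return Named list of `boot_dist` objects.
#' @export
bootstrap_params <- function(cohort, B = 100000L, seed,
                             parameters = BOOT_PARAMS, conf = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"), B >= 1)
  bad <- setdiff(parameters, BOOT_PARAMS)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  a <- cohort_arrays(cohort)
  draws <- local_seed(seed, boot_draws(a, as.integer(B), parameters))
  out <- lapply(parameters, function(p) new_boot_dist(p, draws[, p], conf))
  names(out) <- parameters
  out
}

#' Paired bootstrap test for a between-cohort difference
#'
#' Draws B independent bootstrap resample pairs from two cohorts, forms the
#' difference distribution of the chosen parameter, and reports the two-sided
#' percentile p-value with add-one correction:
#' `p = 2 * min(#(d > 0) + 1, #(d < 0) + 1) / (B + 1)`, capped at 1.
#'
#' @param cohort_a,cohort_b Valid [cohort_table()] objects.
#' @param parameter One parameter name (see [bootstrap_params()]).
#' @param B Number of resample pairs.
#' @param seed Integer seed (one stream drives both cohorts' resampling).
#' @return An object of class `paired_boot_test`: parameter, observed cohort
#'   means and their difference, p-value, B, and a `flagged` marker set when
#'   the parameter was undefined in more than half the resamples of either
#'   cohort (such resample pairs are dropped).
#' @export
paired_bootstrap_test <- function(cohort_a, cohort_b, parameter,
                                  B = 100000L, seed) {
  stopifnot(length(parameter) == 1L, parameter %in% BOOT_PARAMS, B >= 1)
  aa <- cohort_arrays(cohort_a)
  ab <- cohort_arrays(cohort_b)
  B <- as.integer(B)
  dd <- local_seed(seed, {
    da <- boot_draws(aa, B, parameter)[, 1L]
    db <- boot_draws(ab, B, parameter)[, 1L]
    cbind(da, db)
  })
  miss_a <- mean(!is.finite(dd[, 1L]))
  miss_b <- mean(!is.finite(dd[, 2L]))
  flagged <- miss_a > 0.5 || miss_b > 0.5
  d <- dd[, 1L] - dd[, 2L]
  d <- d[is.finite(d)]
  Beff <- length(d)
  p <- if (Beff == 0) NA_real_ else
    min(1, 2 * min(sum(d > 0) + 1, sum(d < 0) + 1) / (Beff + 1))
  mean_a <- mean(dd[is.finite(dd[, 1L]), 1L])
  mean_b <- mean(dd[is.finite(dd[, 2L]), 2L])
  structure(list(parameter = parameter, mean_a = mean_a, mean_b = mean_b,
                 difference = mean_a - mean_b, p.value = p, B = B,
                 B_effective = Beff, flagged = flagged,
                 missing_frac = c(a = miss_a, b = miss_b)),
            class = "paired_boot_test")
}

#' @export
print.paired_boot_test <- function(x, ...) {
  cat(sprintf("<paired_boot_test> %s: %.4g vs %.4g (diff %.4g), p = %.4g (B = %d%s)\n",
              x$parameter, x$mean_a, x$mean_b, x$difference, x$p.value, x$B,
              if (x$flagged) ", FLAGGED: >50% undefined resamples" else ""))
  invisible(x)
}
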