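#' Empirical daily age-stage transition model
#'
#' For every age-stage cell (x, j) observed in the cohort, estimates the
#' empirical probabilities that an individual alive in stage j at age x is, at
#' age x+1, still in stage j (stay), in a later stage j' (advance, possibly
#' skipping supernumerary stages), or dead. Probabilities are the observed
#' fractions, so each occupied row sums to 1 exactly and forward propagation of
#' the full cohort mass through the model reproduces `s_xj`.
#'
#' @param cohort A valid [cohort_table()].
#' @return An object of class `transition_model`: list with `P` (array
#'   `[x+1, j, y]` of move probabilities from age x to x+1, ages 0..omega-1),
#'   `die` (matrix `[x+1, j]`), `counts` (occupancy `n_xj`), `omega`, `n`,
#'   `schema`.
#' @export
fit_transition_model <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  sch <- cohort$schema
  omega <- cohort$omega
  si <- match(d$stage, sch$stages)
  new_id <- c(TRUE, d$id[-1L] != d$id[-nrow(d)])
  last <- c(new_id[-1L], TRUE)

  within <- !new_id[-1L]                      # consecutive-day pairs
  fx <- d$day[-nrow(d)][within]               # age x of the 'from' day
  fj <- si[-nrow(d)][within]
  ty <- si[-1L][within]

  ages <- 0:(omega - 1L)
  move <- table(factor(fx, levels = ages), factor(fj, levels = seq_len(sch$beta)),
                factor(ty, levels = seq_len(sch$beta)))
  move <- array(as.numeric(move), dim = c(omega, sch$beta, sch$beta))
  deaths <- table(factor(d$day[last], levels = ages),
                  factor(si[last], levels = seq_len(sch$beta)))
  deaths <- matrix(as.numeric(deaths), omega, sch$beta)
  counts <- apply(move, c(1, 2), sum) + deaths

  P <- move
  die <- deaths
  pos <- counts > 0
  for (y in seq_len(sch$beta)) P[, , y] <- ifelse(pos, move[, , y] / counts, 0)
  die <- ifelse(pos, deaths / counts, 0)
  dimnames(P) <- list(ages, sch$stages, sch$stages)
  dimnames(die) <- list(ages, sch$stages)
  dimnames(counts) <- list(ages, sch$stages)
  structure(list(P = P, die = die, counts = counts, omega = omega,
                 n = cohort$n, schema = sch),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", x$omega, " daily transitions x ", x$schema$beta,
      " stages (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Age-stage life expectancy
#'
#' `e_xj` is the expected number of remaining days of life (including the
#' current day, so `e_xj >= 1`) for an individual of age x in stage j,
#' obtained by propagating unit mass at (x, j) forward through the empirical
#' transition model. Computed by the equivalent backward recursion
#' `e_xj = 1 + sum_y P(x,j -> y) e_{x+1,y}`. For a newborn egg, `e_0,EGG`
#' equals the cohort mean total longevity.
#'
#' @param tm A [fit_transition_model()] result.
#' @return Matrix of `e_xj` over ages 0..omega-1 (rows) and stages (columns);
#'   `NA` for unoccupied cells.
#' @export
life_expectancy <- function(tm) {
  stopifnot(inherits(tm, "transition_model"))
  omega <- tm$omega; beta <- tm$schema$beta
  e <- matrix(NA_real_, omega, beta,
              dimnames = list(0:(omega - 1L), tm$schema$stages))
  nxt <- numeric(beta)                        # e at age x+1, zeros past omega
  for (x in omega:1) {
    occ <- tm$counts[x, ] > 0
    if (any(occ)) {
      Pm <- matrix(tm$P[x, , ], beta, beta)
      e[x, occ] <- 1 + as.numeric(Pm[occ, , drop = FALSE] %*% nxt)
    }
    nxt <- ifelse(is.na(e[x, ]), 0, e[x, ])
  }
  e
}

#' Age-stage reproductive value
#'
#' `v_xj` is the expected contribution of an individual of age x in stage j to
#' future population growth: unit mass at (x, j) is propagated forward through
#' the transition model, its discounted future reproduction
#' `sum_{i>=x} exp(-r(i+1)) sum_y s'_iy f_iy` is accumulated, and the result is
#' scaled by `exp(r(x+1))`. For a newborn egg `v_0,EGG = lambda`; adult male
#' cells are 0.
#'
#' @param tm A [fit_transition_model()] result.
#' @param fs A [compute_fecundity()] result.
#' @param s An [compute_age_stage_survival()] result (for dimension checks).
#' @param r The intrinsic rate of increase from [solve_intrinsic_rate()].
#' @return Matrix of `v_xj` over ages 0..omega-1 and stages; `NA` for
#'   unoccupied cells.
#' @export
reproductive_value <- function(tm, fs, s, r) {
  stopifnot(inherits(tm, "transition_model"), inherits(fs, "fecundity_schedule"),
            is.finite(r))
  omega <- tm$omega; beta <- tm$schema$beta
  f <- fs$f[seq_len(omega), , drop = FALSE]   # ages 0..omega-1
  u <- matrix(NA_real_, omega, beta,
              dimnames = list(0:(omega - 1L), tm$schema$stages))
  nxt <- numeric(beta)
  for (x in omega:1) {
    occ <- tm$counts[x, ] > 0
    if (any(occ)) {
      Pm <- matrix(tm$P[x, , ], beta, beta)
      u[x, occ] <- exp(-r * x) * f[x, occ] +
        as.numeric(Pm[occ, , drop = FALSE] %*% nxt)
    }
    nxt <- ifelse(is.na(u[x, ]), 0, u[x, ])
  }
  sweep(u, 1, exp(r * seq_len(omega)), `*`)
}
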