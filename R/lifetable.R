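#' Age-stage specific survival rate matrix
#'
#' Computes `s_xj`, the probability that a newborn egg is alive and in stage j
#' at age x days, as the observed count `n_xj` divided by the initial cohort
#' size n. Rows cover ages 0..omega (omega = maximum death age, at which the
#' row is zero); columns are the schema stages.
#'
#' @param cohort A valid [cohort_table()].
#' @return An object of class `age_stage_survival`: list with matrices `s` and
#'   `counts` of dimension (omega+1) x beta, plus `n`, `omega`, `schema`.
#' @export
compute_age_stage_survival <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (cohort$n < 1L) stop("empty cohort")
  d <- cohort$data
  sch <- cohort$schema
  counts <- table(factor(d$day, levels = 0:cohort$omega),
                  factor(d$stage, levels = sch$stages))
  counts <- matrix(as.integer(counts), nrow = cohort$omega + 1L,
                   dimnames = list(0:cohort$omega, sch$stages))
  structure(list(s = counts / cohort$n, counts = counts,
                 n = cohort$n, omega = cohort$omega, schema = sch),
            class = "age_stage_survival")
}

#' Age-specific survival rate
#'
#' `l_x = sum_j s_xj`: the probability a newborn is alive (in any stage) at
#' age x. Non-increasing in x with `l_0 = 1`.
#'
#' @param s An [compute_age_stage_survival()] result.
#' @return Numeric vector of length omega+1, named by age.
#' @export
compute_lx <- function(s) {
  stopifnot(inherits(s, "age_stage_survival"))
  rowSums(s$s)
}

#' Fecundity schedules
#'
#' Computes the age-stage fecundity `f_xj` (mean eggs per living individual of
#' stage j at age x; nonzero only for the adult female stage), the
#' age-specific fecundity `m_x = sum_j s_xj f_xj / l_x` (eggs per living
#' individual of any stage), and the net maternity `l_x m_x` (expected eggs at
#' age x per original newborn).
#'
#' @param cohort A valid [cohort_table()].
#' @param s Optional precomputed [compute_age_stage_survival()] result.
#' @return An object of class `fecundity_schedule`: list with matrix `f`,
#'   vectors `m` and `net_maternity` (length omega+1), and `schema`.
#' @export
compute_fecundity <- function(cohort, s = compute_age_stage_survival(cohort)) {
  sch <- cohort$schema
  d <- cohort$data
  ages <- 0:cohort$omega
  eggs_x <- as.numeric(tapply(d$eggs, factor(d$day, levels = ages), sum))
  eggs_x[is.na(eggs_x)] <- 0
  f <- matrix(0, length(ages), sch$beta, dimnames = list(ages, sch$stages))
  nf <- s$counts[, sch$female]
  f[, sch$female] <- ifelse(nf > 0, eggs_x / nf, 0)
  l <- compute_lx(s)
  m <- ifelse(l > 0, eggs_x / (s$n * l), 0)
  structure(list(f = f, m = m, net_maternity = l * m, schema = sch),
            class = "fecundity_schedule")
}

#' Net reproductive rate
#'
#' `R0 = sum_x l_x m_x`: the expected lifetime offspring per newborn. Satisfies
#' the exact two-sex identity `R0 = (N_f / N) * (mean fecundity per female)`.
#'
#' @param fs A [compute_fecundity()] result.
#' @return Scalar R0.
#' @export
net_reproductive_rate <- function(fs) {
  stopifnot(inherits(fs, "fecundity_schedule"))
  sum(fs$net_maternity)
}

# Root of sum_x exp(-r (x+1)) phi_x = 1 for a net-maternity vector phi
# (index 1 = age 0). The left-hand side is strictly decreasing in r, so
# bisection on [-1, 2] converges to the unique root.
euler_lotka_r <- function(phi, lower = -1, upper = 2, tol = 1e-12,
                          max_iter = 200L) {
  keep <- which(phi > 0)
  if (!length(keep)) stop("no reproduction: Euler-Lotka equation has no root")
  xp1 <- keep                       # ages (x+1) where phi is positive
  w <- phi[keep]
  f <- function(r) sum(exp(-r * xp1) * w) - 1
  flo <- f(lower); fhi <- f(upper)
  if (flo < 0 || fhi > 0)
    stop(sprintf(paste0("intrinsic rate not bracketed in [%g, %g]: ",
                        "f(lower) = %.3g, f(upper) = %.3g, R0 = %.3g"),
                 lower, upper, flo + 1, fhi + 1, sum(w)))
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (fm > 0) lower <- mid else upper <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}

#' Intrinsic rate of increase
#'
#' Solves the discrete Euler-Lotka equation
#' `sum_x exp(-r (x+1)) l_x m_x = 1` for r by bisection on `[-1, 2]`
#' (age counted from 0, reproduction credited at the end of the day, hence the
#' x+1 exponent). The residual at the returned root is below 1e-10.
#'
#' @param sc Age-specific survival `l_x` (from [compute_lx()]).
#' @param fs A [compute_fecundity()] result aligned with `sc`.
#' @return Scalar r (per day).
#' @export
solve_intrinsic_rate <- function(sc, fs) {
  stopifnot(inherits(fs, "fecundity_schedule"), length(sc) == length(fs$m))
  euler_lotka_r(sc * fs$m)
}

#' Finite rate of increase and mean generation time
#'
#' `lambda = exp(r)` and `T = ln(R0) / r`. T is reported as `NA` when R0 <= 0
#' or r = 0 (undefined).
#'
#' @param R0 Net reproductive rate.
#' @param r Intrinsic rate of increase (per day).
#' @return List with elements `lambda` and `T`.
#' @export
derived_rates <- function(R0, r) {
  stopifnot(is.finite(r))
  T <- if (R0 > 0 && r != 0) log(R0) / r else NA_real_
  list(lambda = exp(r), T = T)
}

mean_se <- function(x) {
  x <- x[is.finite(x)]
  c(n = length(x), mean = if (length(x)) mean(x) else NA_real_, se = std_err(x))
}

#' Cohort summary statistics
#'
#' Per-stage development durations (over individuals completing the stage),
#' pre-adult duration, adult longevities by sex, total longevity, APOP (adult
#' pre-oviposition period), TPOP (total pre-oviposition period), number of
#' oviposition days O_d, lifetime fecundity per female, the proportions
#' N_f/N, N_fr/N_f and N_m/N, and the proportion of supernumerary larvae
#' (more than six larval instars among individuals completing the larval
#' stage).
#'
#' @param cohort A valid [cohort_table()].
#' @return An object of class `cohort_summary` (a list; see Details).
#' @export
summarize_cohort <- function(cohort) {
  a <- cohort_arrays(cohort)
  sch <- a$schema

  stage_durations <- do.call(rbind, lapply(sch$stages, function(st) {
    ms <- mean_se(a$Dur[, st])
    data.frame(stage = st, n = unname(ms["n"]), mean = unname(ms["mean"]),
               se = unname(ms["se"]))
  }))

  female <- a$sex == "female"
  male <- a$sex == "male"
  ovip <- female & a$total_eggs > 0
  apop <- a$first_egg[ovip] - a$emergence[ovip]
  adult <- !is.na(a$emergence)

  structure(list(
    n = a$n,
    stage_durations = stage_durations,
    preadult = mean_se(a$emergence[adult]),
    female_adult_longevity = mean_se(a$Dur[female, sch$female]),
    male_adult_longevity = if (length(sch$male))
      mean_se(a$Dur[male, sch$male]) else mean_se(numeric()),
    total_longevity = mean_se(a$death_age),
    apop = mean_se(apop),
    tpop = mean_se(a$first_egg[ovip]),
    ovi_days = mean_se(a$ovi_days[ovip]),
    fecundity = mean_se(a$total_eggs[female]),
    Nf_N = sum(female) / a$n,
    Nfr_Nf = if (any(female)) sum(ovip) / sum(female) else NA_real_,
    Nm_N = sum(male) / a$n,
    supernumerary_prop = if (any(a$reached_pupa))
      mean(a$n_instars[a$reached_pupa] > 6) else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(ms) sprintf("%.1f +/- %.1f (n = %d)", ms["mean"], ms["se"],
                              ms["n"])
  cat("<cohort_summary> n =", x$n, "\n")
  cat("  pre-adult duration (d):", fmt(x$preadult), "\n")
  cat("  total longevity (d):   ", fmt(x$total_longevity), "\n")
  cat("  APOP / TPOP (d):       ", fmt(x$apop), "/", fmt(x$tpop), "\n")
  cat("  fecundity (eggs/female):", fmt(x$fecundity), "\n")
  cat(sprintf("  Nf/N = %.1f%%, Nfr/Nf = %.1f%%, Nm/N = %.1f%%\n",
              100 * x$Nf_N, 100 * x$Nfr_Nf, 100 * x$Nm_N))
  invisible(x)
}

#' Full age-stage two-sex life table analysis
#'
#' Convenience wrapper running the whole pipeline on a cohort: survival and
#' fecundity schedules, demographic parameters (R0, r, lambda, T), the
#' empirical transition model, life expectancy e_xj, reproductive value v_xj,
#' and the cohort summary.
#'
#' @param cohort A valid [cohort_table()].
#' @return An object of class `life_table` with elements `survival`, `lx`,
#'   `fecundity`, `params` (R0, r, lambda, T), `transition`, `e`, `v`,
#'   `summary`.
#' @examples
#' coh <- generate_cohort(synthetic_preset("corn-like"), seed = 1)
#' lt <- life_table(coh)
#' lt$params
#' @export
life_table <- function(cohort) {
  s <- compute_age_stage_survival(cohort)
  lx <- compute_lx(s)
  fs <- compute_fecundity(cohort, s)
  R0 <- net_reproductive_rate(fs)
  r <- if (R0 > 0) solve_intrinsic_rate(lx, fs) else NA_real_
  dr <- if (is.finite(r)) derived_rates(R0, r) else list(lambda = NA_real_,
                                                         T = NA_real_)
  tm <- fit_transition_model(cohort)
  structure(list(survival = s, lx = lx, fecundity = fs,
                 params = c(R0 = R0, r = r, lambda = dr$lambda, T = dr$T),
                 transition = tm,
                 e = life_expectancy(tm),
                 v = if (is.finite(r)) reproductive_value(tm, fs, s, r) else NULL,
                 summary = summarize_cohort(cohort)),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  p <- x$params
  cat("<life_table> n =", x$survival$n, " omega =", x$survival$omega, "\n")
  cat(sprintf("  R0 = %.1f, r = %.4f /d, lambda = %.4f /d, T = %.1f d\n",
              p["R0"], p["r"], p["lambda"], p["T"]))
  invisible(x)
}
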