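#' Configuration for the synthetic cohort generator
#'
#' Describes the stochastic life history the generator draws from: per-stage
#' development-time distributions (gamma, discretised to whole days with a
#' 1-day floor), per-stage daily survival probabilities (geometric within-stage
#' hazard), the probability of supernumerary 7th/8th instars, the sex ratio
#' among emerging adults, adult longevity by sex, the adult pre-oviposition
#' period, the lifetime fecundity distribution, and a unimodal (log-normal
#' shaped) daily egg-allocation curve.
#'
#' @param n Cohort size (initial eggs).
#' @param sex_ratio Probability an emerging adult is female.
#' @param fertile_prob Probability an adult female oviposits at all.
#' @param durations Named list of `c(mean, cv)` pairs for EGG, L1..L6,
#'   optionally L7/L8, and PUPA.
#' @param daily_survival Named vector of per-day survival probabilities for
#'   the pre-adult stages (a single unnamed value is recycled to all).
#' @param supernumerary `c(L7 = p7, L8 = p8)`: probability of a 7th instar,
#'   and of an 8th conditional on the 7th.
#' @param apop `c(mean, cv)` of the adult pre-oviposition period (days >= 1).
#' @param adult_longevity List with `female` and `male` `c(mean, cv)` pairs
#'   (days >= 1). For fertile females the draw is conditioned on exceeding
#'   APOP, so every fertile female has at least one oviposition day.
#' @param fecundity `c(mean, cv)` of lifetime eggs per fertile female
#'   (discretised gamma, support from 0).
#' @param ovi_curve `c(peak, width)`: days-after-first-oviposition peak and
#'   log-scale width of the log-normal daily allocation curve.
#' @param schema A [stage_schema()].
#' @return An object of class `synthetic_config`.
#' @seealso [synthetic_preset()], [generate_cohort()], [ground_truth()]
#' @export
synthetic_config <- function(n = 80L,
                             sex_ratio = 0.4,
                             fertile_prob = 0.95,
                             durations = list(
                               EGG = c(mean = 3, cv = 0),
                               L1 = c(mean = 2, cv = 0.2),
                               L2 = c(mean = 2, cv = 0.2),
                               L3 = c(mean = 2, cv = 0.2),
                               L4 = c(mean = 2, cv = 0.2),
                               L5 = c(mean = 2.5, cv = 0.2),
                               L6 = c(mean = 4, cv = 0.2),
                               L7 = c(mean = 4.5, cv = 0.2),
                               PUPA = c(mean = 8.5, cv = 0.1)),
                             daily_survival = 0.9868,
                             supernumerary = c(L7 = 0.2, L8 = 0),
                             apop = c(mean = 3.5, cv = 0.3),
                             adult_longevity = list(
                               female = c(mean = 12, cv = 0.3),
                               male = c(mean = 12, cv = 0.3)),
                             fecundity = c(mean = 700, cv = 0.35),
                             ovi_curve = c(peak = 3, width = 0.6),
                             schema = default_schema()) {
  stopifnot(n >= 1, sex_ratio >= 0, sex_ratio <= 1,
            fertile_prob >= 0, fertile_prob <= 1,
            all(supernumerary >= 0), all(supernumerary <= 1),
            fecundity[["mean"]] >= 0, ovi_curve[["peak"]] > 0,
            ovi_curve[["width"]] > 0)
  base <- c("EGG", paste0("L", 1:6), "PUPA")
  need <- base
  if (supernumerary[["L7"]] > 0) need <- c(need, "L7")
  if (supernumerary[["L7"]] > 0 && supernumerary[["L8"]] > 0)
    need <- c(need, "L8")
  miss <- setdiff(need, names(durations))
  if (length(miss))
    stop("durations missing for stage(s): ", paste(miss, collapse = ", "))
  for (d in durations) stopifnot(d[["mean"]] >= 1, d[["cv"]] >= 0)
  preadult <- setdiff(schema$stages, schema$adult)
  if (is.null(names(daily_survival)) && length(daily_survival) == 1L)
    daily_survival <- stats::setNames(rep(daily_survival, length(preadult)),
                                      preadult)
  stopifnot(all(daily_survival > 0), all(daily_survival <= 1),
            all(names(durations) %in% preadult))
  structure(list(n = as.integer(n), sex_ratio = sex_ratio,
                 fertile_prob = fertile_prob, durations = durations,
                 daily_survival = daily_survival,
                 supernumerary = supernumerary, apop = apop,
                 adult_longevity = adult_longevity, fecundity = fecundity,
                 ovi_curve = ovi_curve, schema = schema),
            class = "synthetic_config")
}

#' Named synthetic cohort presets
#'
#' `"faw-default"` is the generic fall-armyworm-like validation preset
#' (n = 80, sex ratio 0.4, mean fecundity 700 eggs, pre-adult survival near
#' 0.7). `"corn-like"` emulates a corn-reared cohort (fast development,
#' no supernumerary instars, high fecundity); `"jobs-tears-like"` emulates an
#' early-generation cohort on a poor host (slow larval development, frequent
#' supernumerary instars, reduced fecundity).
#'
#' @param name Preset name.
#' @param n Optional cohort-size override.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("faw-default", "corn-like",
                                      "jobs-tears-like"), n = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "faw-default" = synthetic_config(),
    "corn-like" = synthetic_config(
      n = 80L, sex_ratio = 0.458, fertile_prob = 0.963,
      durations = list(EGG = c(mean = 3, cv = 0), L1 = c(mean = 2, cv = 0.1),
                       L2 = c(mean = 2, cv = 0.1), L3 = c(mean = 2.1, cv = 0.15),
                       L4 = c(mean = 1.5, cv = 0.25), L5 = c(mean = 3, cv = 0.3),
                       L6 = c(mean = 4.6, cv = 0.2), PUPA = c(mean = 8.6, cv = 0.1)),
      daily_survival = 0.9881, supernumerary = c(L7 = 0, L8 = 0),
      apop = c(mean = 3.4, cv = 0.25),
      adult_longevity = list(female = c(mean = 12.6, cv = 0.3),
                             male = c(mean = 14.4, cv = 0.35)),
      fecundity = c(mean = 1095, cv = 0.33),
      ovi_curve = c(peak = 3, width = 0.6)),
    "jobs-tears-like" = synthetic_config(
      n = 100L, sex_ratio = 0.485, fertile_prob = 0.85,
      durations = list(EGG = c(mean = 3, cv = 0), L1 = c(mean = 2.7, cv = 0.25),
                       L2 = c(mean = 2.3, cv = 0.2), L3 = c(mean = 2.2, cv = 0.2),
                       L4 = c(mean = 2.2, cv = 0.2), L5 = c(mean = 2.4, cv = 0.25),
                       L6 = c(mean = 3.6, cv = 0.35), L7 = c(mean = 5.4, cv = 0.3),
                       L8 = c(mean = 5.6, cv = 0.2), PUPA = c(mean = 9.1, cv = 0.1)),
      daily_survival = 0.9882, supernumerary = c(L7 = 0.61, L8 = 0.13),
      apop = c(mean = 5.2, cv = 0.4),
      adult_longevity = list(female = c(mean = 12.2, cv = 0.35),
                             male = c(mean = 12.0, cv = 0.35)),
      fecundity = c(mean = 640, cv = 0.5),
      ovi_curve = c(peak = 4, width = 0.7)))
  if (!is.null(n)) cfg$n <- as.integer(n)
  cfg
}

# ---- internal distribution plumbing ----------------------------------------

config_pmfs <- function(config) {
  dur <- lapply(config$durations,
                function(d) disc_gamma_pmf(d[["mean"]], d[["cv"]], min = 1L))
  list(durations = dur,
       apop = disc_gamma_pmf(config$apop[["mean"]], config$apop[["cv"]],
                             min = 1L),
       longevity = lapply(config$adult_longevity, function(d)
         disc_gamma_pmf(d[["mean"]], d[["cv"]], min = 1L)),
       fecundity = disc_gamma_pmf(config$fecundity[["mean"]],
                                  config$fecundity[["cv"]], min = 0L))
}

# quantile sampling from a pmf truncated to support >= lower
sample_pmf_trunc <- function(dist, lower, n = 1L) {
  keep <- dist$support >= lower
  if (!any(keep)) return(rep(lower, n))
  if (sum(keep) == 1L) return(rep(dist$support[keep], n))
  sample(dist$support[keep], n, replace = TRUE, prob = dist$pmf[keep])
}

ovi_weights <- function(W, curve) {
  w <- stats::dlnorm(seq_len(W), meanlog = log(curve[["peak"]]),
                     sdlog = curve[["width"]])
  if (sum(w) <= 0) w <- rep(1, W)
  w / sum(w)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` independent individuals: stage durations are sampled from
#' the configured distributions, death is applied day by day within pre-adult
#' stages (geometric hazard), supernumerary instars are inserted with the
#' configured probabilities, sex is assigned at adult emergence, and fertile
#' females lay their drawn lifetime total along the unimodal daily allocation
#' curve from the end of the adult pre-oviposition period until death. The
#' output always passes [validate_cohort()].
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; required for reproducibility.
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  pm <- config_pmfs(config)
  sch <- config$schema
  n <- config$n
  p7 <- config$supernumerary[["L7"]]
  p8 <- config$supernumerary[["L8"]]

  local_seed(seed, {
    has7 <- stats::runif(n) < p7
    has8 <- has7 & stats::runif(n) < p8
    stage_cols <- c("EGG", paste0("L", 1:8), "PUPA")
    D <- matrix(0L, n, length(stage_cols), dimnames = list(NULL, stage_cols))
    G <- matrix(Inf, n, length(stage_cols), dimnames = list(NULL, stage_cols))
    for (s in stage_cols) {
      present <- switch(s, L7 = has7, L8 = has8, rep(TRUE, n))
      if (!any(present) || !s %in% names(pm$durations)) next
      D[present, s] <- sample_pmf(pm$durations[[s]], sum(present))
      q <- config$daily_survival[[s]]
      G[present, s] <- if (q >= 1) Inf else
        stats::rgeom(sum(present), prob = 1 - q) + 1
    }
    sex_draw <- stats::runif(n) < config$sex_ratio
    fertile_draw <- stats::runif(n) < config$fertile_prob
    apop_draw <- sample_pmf(pm$apop, n)

    ids <- sprintf("ind%05d", seq_len(n))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      path <- stage_cols[D[i, ] > 0]
      days <- integer(0); stages <- character(0)
      alive <- TRUE
      for (s in path) {
        d <- D[i, s]; g <- G[i, s]
        if (g <= d) {               # dies inside this stage after day g
          days <- c(days, g); stages <- c(stages, s); alive <- FALSE
          break
        }
        days <- c(days, d); stages <- c(stages, s)
      }
      eggs_adult <- NULL
      if (alive) {                  # emerged as adult
        if (sex_draw[i]) {
          sex <- "female"
          a <- apop_draw[i]
          if (fertile_draw[i]) {
            L <- sample_pmf_trunc(pm$longevity$female, a + 1L)
            total <- sample_pmf(pm$fecundity)
            W <- L - a
            w <- ovi_weights(W, config$ovi_curve)
            laid <- as.integer(stats::rmultinom(1L, total, w))
            eggs_adult <- c(rep(0L, a), laid)
          } else {
            L <- sample_pmf(pm$longevity$female)
            eggs_adult <- rep(0L, L)
          }
          stages <- c(stages, sch$female); days <- c(days, L)
        } else {
          sex <- "male"
          L <- sample_pmf(pm$longevity$male)
          stages <- c(stages, sch$male[1L]); days <- c(days, L)
        }
      } else sex <- "unknown"
      total_days <- sum(days)
      eggs <- numeric(total_days)
      if (!is.null(eggs_adult))
        eggs[(total_days - length(eggs_adult) + 1L):total_days] <- eggs_adult
      recs[[i]] <- list(id = rep(ids[i], total_days),
                        day = 0:(total_days - 1L),
                        stage = rep(stages, days),
                        eggs = eggs,
                        sex = rep(sex, total_days))
    }
    cohort_table(data.frame(
      id = unlist(lapply(recs, `[[`, "id")),
      day = unlist(lapply(recs, `[[`, "day")),
      stage = unlist(lapply(recs, `[[`, "stage")),
      eggs = unlist(lapply(recs, `[[`, "eggs")),
      sex = unlist(lapply(recs, `[[`, "sex")),
      stringsAsFactors = FALSE), sch)
  })
}

# subprobability convolution: a[i] is mass at offset i-1+off_a, likewise b
conv_open <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) if (a[i] != 0)
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  out
}

# kernel of a stage: vector over day-offsets 0..max(support) with mass
# pmf(d) * q^d at offset d (probability of completing the stage in d days
# while surviving every daily hazard check)
stage_kernel <- function(dist, q) {
  k <- numeric(max(dist$support) + 1L)
  k[dist$support + 1L] <- dist$pmf * q^dist$support
  k
}

#' Analytic ground truth for a synthetic configuration
#'
#' Computes, from the configured distributions (not from any sampled cohort),
#' the exact expected demographic parameters of the generator: pre-adult
#' survival (the path-weighted product of per-stage `E[q^D]`), the net
#' reproductive rate `R0 = sex_ratio * preadult_survival * fertile_prob *
#' E[lifetime eggs]`, the expected net-maternity schedule (by convolving the
#' emergence-age distribution with the expected daily egg allocation), and the
#' intrinsic rate r solving the Euler-Lotka equation on that schedule.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `ground_truth`: list with `R0`, `r`, `lambda`,
#'   `T`, `preadult_survival`, `mean_fecundity` (per fertile female),
#'   `stage_duration_means`, and the expected `net_maternity` vector (index 1
#'   = age 0).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pm <- config_pmfs(config)
  q <- config$daily_survival
  p7 <- config$supernumerary[["L7"]]
  p8 <- config$supernumerary[["L8"]]

  base <- c("EGG", paste0("L", 1:6))
  g <- 1                                   # mass at age offset 0
  for (s in base) g <- conv_open(g, stage_kernel(pm$durations[[s]], q[[s]]))
  kp <- stage_kernel(pm$durations$PUPA, q[["PUPA"]])
  branches <- list(list(w = 1 - p7, extra = character(0)))
  if (p7 > 0) {
    branches <- c(branches, list(list(w = p7 * (1 - p8), extra = "L7")))
    if (p8 > 0)
      branches <- c(branches, list(list(w = p7 * p8, extra = c("L7", "L8"))))
  }
  gA <- 0
  for (br in branches) {
    if (br$w == 0) next
    gb <- g
    for (s in br$extra) gb <- conv_open(gb, stage_kernel(pm$durations[[s]],
                                                         q[[s]]))
    gb <- conv_open(gb, kp) * br$w
    if (length(gb) > length(gA)) gA <- c(gA, numeric(length(gb) - length(gA)))
    gA[seq_along(gb)] <- gA[seq_along(gb)] + gb
  }                                        # gA[x+1] = P(emerge as adult at age x)
  S_pre <- sum(gA)
  mean_fec <- pmf_mean(pm$fecundity)
  R0 <- config$sex_ratio * S_pre * config$fertile_prob * mean_fec

  # expected eggs laid delta days after adult emergence, per fertile female
  lf <- pm$longevity$female
  h <- numeric(max(lf$support) + max(pm$apop$support))   # h[delta], delta >= 1
  for (ai in seq_along(pm$apop$support)) {
    a <- pm$apop$support[ai]; pa <- pm$apop$pmf[ai]
    keep <- lf$support >= a + 1L
    pkeep <- sum(lf$pmf[keep])
    if (pkeep <= 0) {          # longevity support exhausted: generator uses L = a+1
      h[a] <- h[a] + pa * mean_fec
      next
    }
    for (li in which(keep)) {
      L <- lf$support[li]
      pL <- lf$pmf[li] / pkeep
      W <- L - a
      w <- ovi_weights(W, config$ovi_curve)
      dd <- a + seq_len(W) - 1L            # delta = a .. L-1
      h[dd] <- h[dd] + pa * pL * mean_fec * w
    }
  }

  phi <- config$sex_ratio * config$fertile_prob * conv_open(gA, c(0, h))
  r <- if (R0 > 0) euler_lotka_r(phi) else NA_real_
  dr <- if (is.finite(r)) derived_rates(R0, r) else list(lambda = NA_real_,
                                                         T = NA_real_)
  structure(list(R0 = R0, r = r, lambda = dr$lambda, T = dr$T,
                 preadult_survival = S_pre, mean_fecundity = mean_fec,
                 stage_duration_means = vapply(pm$durations, pmf_mean,
                                               numeric(1)),
                 net_maternity = phi),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> R0 = %.2f, r = %.4f /d, lambda = %.4f,",
                     " T = %.1f d (pre-adult survival %.3f)\n"),
              x$R0, x$r, x$lambda, x$T, x$preadult_survival))
  invisible(x)
}

#' Read / write a synthetic configuration as structured text (JSON)
#'
#' @param path File path.
#' @return `read_synthetic_config()` returns a [synthetic_config()];
#'   `write_synthetic_config()` returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_config(
    n = j$n, sex_ratio = j$sex_ratio, fertile_prob = j$fertile_prob,
    durations = lapply(j$durations, function(d) c(mean = d[["mean"]],
                                                  cv = d[["cv"]])),
    daily_survival = unlist(j$daily_survival),
    supernumerary = c(L7 = j$supernumerary[["L7"]],
                      L8 = j$supernumerary[["L8"]]),
    apop = c(mean = j$apop[["mean"]], cv = j$apop[["cv"]]),
    adult_longevity = lapply(j$adult_longevity,
                             function(d) c(mean = d[["mean"]], cv = d[["cv"]])),
    fecundity = c(mean = j$fecundity[["mean"]], cv = j$fecundity[["cv"]]),
    ovi_curve = c(peak = j$ovi_curve[["peak"]], width = j$ovi_curve[["width"]]))
}

#' @rdname read_synthetic_config
#' @param config A [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- config[setdiff(names(config), "schema")]
  out$durations <- lapply(out$durations, as.list)
  out$adult_longevity <- lapply(out$adult_longevity, as.list)
  out$apop <- as.list(out$apop)
  out$fecundity <- as.list(out$fecundity)
  out$ovi_curve <- as.list(out$ovi_curve)
  out$supernumerary <- as.list(out$supernumerary)
  out$daily_survival <- as.list(out$daily_survival)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
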