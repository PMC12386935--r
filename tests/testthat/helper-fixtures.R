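# Fixtures are built in code; no data files. All cohorts use default_schema().

# One individual's daily records from named stage durations (in days).
# eggs: named numeric vector, names = age-days on which eggs were laid.
make_ind <- function(id, durs, sex = "unknown", eggs = NULL) {
  stages <- rep(names(durs), durs)
  days <- seq_along(stages) - 1L
  e <- numeric(length(days))
  if (!is.null(eggs)) e[match(as.integer(names(eggs)), days)] <- eggs
  data.frame(id = id, day = days, stage = stages, eggs = e, sex = sex,
             stringsAsFactors = FALSE)
}

full_preadult <- c(EGG = 3, L1 = 2, L2 = 2, L3 = 2, L4 = 2, L5 = 3, L6 = 4,
                   PUPA = 9)  # emergence at age 27

# two eggs: A dies as egg after 3 days, B molts to L1 on day 3 then dies
fx_two <- function() {
  cohort_table(rbind(make_ind("A", c(EGG = 3)),
                     make_ind("B", c(EGG = 3, L1 = 1))))
}

# 1 ovipositing female (5 eggs on day 30), 1 male, 1 pre-adult death
fx_three <- function() {
  cohort_table(rbind(
    make_ind("F1", c(full_preadult, ADULT_F = 7), sex = "female",
             eggs = c("30" = 5)),
    make_ind("M1", c(full_preadult, ADULT_M = 5), sex = "male"),
    make_ind("U1", c(EGG = 3, L1 = 2))))
}

# minimal reproduction toy: female lays 10 eggs on her only adult day (age 8),
# male also dies at age 8; so l_8 = 1, m_8 = 5, R0 = 5
fx_toy_R0 <- function() {
  short <- c(EGG = 1, L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1, L6 = 1, PUPA = 1)
  cohort_table(rbind(
    make_ind("F1", c(short, ADULT_F = 1), sex = "female", eggs = c("8" = 10)),
    make_ind("M1", c(short, ADULT_M = 1), sex = "male")))
}

# k identical clones of the fx_toy_R0 female (bootstrap SE must be 0)
fx_clones <- function(k = 8) {
  short <- c(EGG = 1, L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1, L6 = 1, PUPA = 1)
  cohort_table(do.call(rbind, lapply(seq_len(k), function(i)
    make_ind(sprintf("C%02d", i), c(short, ADULT_F = 3), sex = "female",
             eggs = c("9" = 20, "10" = 10)))))
}

# fast-turnaround generator: short generation time (~17 d) and broad
# reproduction, so the projection's generation-cycle transient has damped by
# day 120 (the FAW-like presets have T ~ 30-38 d and have not; see vignette)
fast_config <- function(n = 200) {
  synthetic_config(
    n = n, sex_ratio = 0.5, fertile_prob = 1,
    durations = list(EGG = c(mean = 2, cv = 0), L1 = c(mean = 1, cv = 0.4),
                     L2 = c(mean = 1, cv = 0.4), L3 = c(mean = 1, cv = 0.4),
                     L4 = c(mean = 1, cv = 0.4), L5 = c(mean = 1, cv = 0.4),
                     L6 = c(mean = 2, cv = 0.4), PUPA = c(mean = 3, cv = 0.3)),
    daily_survival = 0.985, supernumerary = c(L7 = 0, L8 = 0),
    apop = c(mean = 2, cv = 0.6),
    adult_longevity = list(female = c(mean = 14, cv = 0.5),
                           male = c(mean = 12, cv = 0.4)),
    fecundity = c(mean = 120, cv = 0.3), ovi_curve = c(peak = 5, width = 1.2))
}

# ---- independent oracles ----------------------------------------------------

# brute-force grid search for the Euler-Lotka root (two-stage refinement)
grid_euler_lotka <- function(phi, lower = -1, upper = 2) {
  f <- function(r) sum(exp(-r * seq_along(phi)) * phi) - 1
  refine <- function(lo, hi, n) {
    g <- seq(lo, hi, length.out = n)
    v <- vapply(g, f, numeric(1))
    i <- which(v < 0)[1L]        # f is strictly decreasing
    c(g[i - 1L], g[i])
  }
  br <- refine(lower, upper, 3001L)
  br <- refine(br[1L], br[2L], 2001L)
  br <- refine(br[1L], br[2L], 2001L)
  mean(br)
}

# forward propagation of unit mass from (x, j) through a transition model;
# returns matrix of s' over ages x..omega-1 (rows) and stages
propagate_mass <- function(tm, x, j) {
  beta <- tm$schema$beta
  sp <- matrix(0, tm$omega, beta)
  sp[x + 1L, j] <- 1
  if (x + 1L <= tm$omega - 1L)
    for (i in (x + 1L):(tm$omega - 1L))
      sp[i + 1L, ] <- sp[i, ] %*% matrix(tm$P[i, , ], beta, beta)
  sp[(x + 1L):tm$omega, , drop = FALSE]
}

# forward-propagation life expectancy and reproductive value (the formulation
# the backward recursion in the package must reproduce)
oracle_exj <- function(tm, x, j) sum(propagate_mass(tm, x, j))
oracle_vxj <- function(tm, fs, x, j, r) {
  sp <- propagate_mass(tm, x, j)
  ages <- x:(tm$omega - 1L)
  fmat <- fs$f[ages + 1L, , drop = FALSE]
  exp(r * (x + 1)) * sum(exp(-r * (ages + 1)) * rowSums(sp * fmat))
}

# exhaustive sign-pattern enumeration for the Quade test with k = 2 choices
oracle_quade_k2 <- function(m) {
  b <- nrow(m)
  d <- m[, 1L] - m[, 2L]
  Q <- rank(abs(d))
  s <- Q * ifelse(d > 0, 0.5, ifelse(d < 0, -0.5, 0))  # S_i1 with mid-ranks
  A <- 2 * sum(s^2)
  Bobs <- 2 * sum(s)^2 / b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), b)))
  Bperm <- 2 * (signs %*% s)^2 / b
  Fstat <- if (A > Bobs) (b - 1) * Bobs / (A - Bobs) else Inf
  list(statistic = Fstat, p_perm = mean(Bperm >= Bobs - 1e-12))
}

# hand-iterated daily projection (independent of project_population internals)
oracle_project <- function(tm, fs, eggs0, days) {
  beta <- tm$schema$beta
  fcol <- match(tm$schema$female, tm$schema$stages)
  M <- matrix(0, tm$omega, beta)
  M[1L, 1L] <- eggs0
  N <- numeric(days + 1L); N[1L] <- sum(M)
  for (t in seq_len(days)) {
    b <- sum(M[, fcol] * fs$f[seq_len(tm$omega), fcol])
    Mn <- matrix(0, tm$omega, beta)
    for (x in seq_len(tm$omega - 1L))
      for (j in seq_len(beta))
        if (M[x, j] > 0)
          for (y in seq_len(beta))
            Mn[x + 1L, y] <- Mn[x + 1L, y] + M[x, j] * tm$P[x, j, y]
    Mn[1L, 1L] <- Mn[1L, 1L] + b
    M <- Mn
    N[t + 1L] <- sum(M)
  }
  N
}
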