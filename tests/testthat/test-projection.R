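test_that("conservation: no death, no eggs keeps N constant", {
  # hand-built transition model: a single EGG stage that always stays
  sch <- default_schema()
  A <- 150L; beta <- sch$beta
  P <- array(0, dim = c(A, beta, beta),
             dimnames = list(0:(A - 1), sch$stages, sch$stages))
  P[, 1, 1] <- 1
  die <- matrix(0, A, beta, dimnames = list(0:(A - 1), sch$stages))
  counts <- matrix(0, A, beta, dimnames = list(0:(A - 1), sch$stages))
  counts[, 1] <- 1
  tm <- structure(list(P = P, die = die, counts = counts, omega = A, n = 1,
                       schema = sch), class = "transition_model")
  f <- matrix(0, A + 1, beta, dimnames = list(0:A, sch$stages))
  fs <- structure(list(f = f, m = numeric(A + 1),
                       net_maternity = numeric(A + 1), schema = sch),
                  class = "fecundity_schedule")
  ps <- project_population(tm, fs, initial_eggs = 10, days = 120)
  expect_true(all(ps$N == 10))
})

test_that("geometric toy matches the hand-iterated oracle", {
  # 1-day egg stage, then a 1-day adult female laying 2 eggs, then death
  sch <- default_schema()
  coh <- cohort_table(make_ind(
    "g", c(EGG = 1, L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1, L6 = 1, PUPA = 1,
           ADULT_F = 1), sex = "female", eggs = c("8" = 2)), sch)
  tm <- fit_transition_model(coh)
  fs <- compute_fecundity(coh)
  ps <- project_population(tm, fs, initial_eggs = 10, days = 40)
  expect_equal(ps$N, oracle_project(tm, fs, 10, 40), tolerance = 1e-12)
  # every 9 days the population doubles (one generation, 2 eggs per female)
  expect_equal(ps$N[1 + 27] / ps$N[1 + 18], 2, tolerance = 1e-12)
})

test_that("mass balance holds exactly at every step", {
  coh <- generate_cohort(synthetic_preset("faw-default"), seed = 13)
  lt <- life_table(coh)
  ps <- project_population(lt$transition, lt$fecundity, 10, 120)
  lhs <- ps$N[-1]
  rhs <- ps$N[-length(ps$N)] - ps$deaths + ps$births
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(ps$retired, 0)
})

test_that("log-slope of N(t) approaches r once the generation cycle has damped", {
  coh <- generate_cohort(fast_config(), seed = 3)
  lt <- life_table(coh)
  ps <- project_population(lt$transition, lt$fecundity, 10, 120)
  r <- unname(lt$params["r"]); T <- unname(lt$params["T"])
  slope <- projection_growth_rate(ps, window = round(2 * T), period = T)
  expect_lt(abs(slope - r), 1e-3)
})

test_that("egg-influx waves mark at least two completed generations in 120 d", {
  coh <- generate_cohort(synthetic_preset("faw-default"), seed = 2)
  lt <- life_table(coh)
  expect_lte(unname(lt$params["T"]), 40)
  ps <- project_population(lt$transition, lt$fecundity, 10, 120)
  lb <- log(ps$births + 1e-12)
  waves <- sum(diff(sign(diff(lb))) == 2)   # local minima delimit generations
  expect_gte(waves, 2)
})

test_that("projection bands behave under resampling", {
  # clone cohort: zero-width band
  clones <- fx_clones(10)
  band0 <- projection_band(clones, initial_eggs = 10, days = 30, B = 20,
                           seed = 1)
  expect_equal(band0$lower, band0$upper, tolerance = 1e-12)

  # point projection inside the band on >= 95% of days
  coh <- generate_cohort(synthetic_preset("faw-default"), seed = 4)
  band <- projection_band(coh, initial_eggs = 10, days = 100, B = 200,
                          seed = 2)
  inside <- mean(band$point >= band$lower & band$point <= band$upper)
  expect_gte(inside, 0.95)
  expect_true(all(band$lower <= band$upper))
})

test_that("cohorts with clearly different r separate before day 120", {
  cfg_lo <- synthetic_preset("faw-default")
  cfg_lo$fecundity <- c(mean = 150, cv = 0.35)   # r lower by ~0.05
  lo <- generate_cohort(cfg_lo, seed = 6)
  hi <- generate_cohort(synthetic_preset("faw-default"), seed = 7)
  r_lo <- life_table(lo)$params[["r"]]
  r_hi <- life_table(hi)$params[["r"]]
  expect_gt(r_hi - r_lo, 0.03)
  band_lo <- projection_band(lo, 10, 120, B = 100, seed = 8)
  band_hi <- projection_band(hi, 10, 120, B = 100, seed = 9)
  expect_gt(band_hi$lower[121], band_lo$upper[121])
})

test_that("stochastic mode tracks the deterministic projection", {
  coh <- generate_cohort(synthetic_preset("faw-default"), seed = 10)
  lt <- life_table(coh)
  det <- project_population(lt$transition, lt$fecundity, 1000, 60)
  sto <- agestage:::local_seed(99,
    project_population(lt$transition, lt$fecundity, 1000, 60,
                       stochastic = TRUE))
  expect_lt(abs(log(sto$N[61]) - log(det$N[61])), 0.5)
})
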