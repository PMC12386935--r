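test_that("age-stage survival matches hand counts", {
  coh <- fx_two()
  s <- compute_age_stage_survival(coh)
  expect_equal(s$s["0", "EGG"], 1)
  expect_equal(s$s["3", "L1"], 0.5)
  expect_equal(s$s["3", "EGG"], 0)
  expect_equal(s$s, s$counts / coh$n)

  lx <- compute_lx(s)
  expect_equal(unname(lx["3"]), 0.5)
  expect_equal(unname(lx["0"]), 1)
  expect_true(all(diff(lx) <= 1e-12))

  # single individual: s is an indicator matrix
  one <- cohort_table(make_ind("solo", c(EGG = 3, L1 = 3)))
  s1 <- compute_age_stage_survival(one)
  expect_true(all(s1$s %in% c(0, 1)))
})

test_that("fecundity schedules and R0 on the reproduction toy", {
  coh <- fx_toy_R0()
  s <- compute_age_stage_survival(coh)
  fs <- compute_fecundity(coh, s)
  expect_equal(fs$f["8", "ADULT_F"], 10)
  expect_equal(unname(fs$m["8"]),
               unname(s$s["8", "ADULT_F"] * 10 / compute_lx(s)["8"]))
  expect_equal(net_reproductive_rate(fs), 5)     # 10 eggs / 2 newborns

  # no eggs anywhere -> zero schedule
  males <- cohort_table(make_ind("m", c(full_preadult, ADULT_M = 2),
                                 sex = "male"))
  fs0 <- compute_fecundity(males)
  expect_true(all(fs0$m == 0))
  expect_equal(net_reproductive_rate(fs0), 0)
})

test_that("Euler-Lotka solver hits closed forms with tiny residual", {
  mk_fs <- function(m) structure(list(m = m, net_maternity = m),
                                 class = "fecundity_schedule")
  sc <- c(1, 1)
  # l_0 m_0 = 1 -> r = 0
  r0 <- solve_intrinsic_rate(sc, mk_fs(c(1, 0)))
  expect_lt(abs(r0), 1e-11)
  # l_1 m_1 = 2 -> r = ln(2)/2
  r1 <- solve_intrinsic_rate(sc, mk_fs(c(0, 2)))
  expect_lt(abs(r1 - log(2) / 2), 1e-11)
  expect_lt(abs(sum(exp(-r1 * (1:2)) * c(0, 2)) - 1), 1e-10)
  # no reproduction raises
  expect_error(solve_intrinsic_rate(sc, mk_fs(c(0, 0))), "no reproduction")
})

test_that("solver agrees with the brute-force grid oracle on random schedules", {
  set.seed(101)
  for (i in 1:25) {
    phi <- numeric(40)
    sup <- sample(5:40, sample(3:12, 1))
    phi[sup] <- stats::runif(length(sup))
    phi <- phi * stats::runif(1, 0.1, 50) / sum(phi)
    r_b <- agestage:::euler_lotka_r(phi)
    r_g <- grid_euler_lotka(phi)
    expect_lt(abs(r_b - r_g), 1e-6)
  }
})

test_that("derived rates reproduce printed and closed-form values", {
  expect_equal(round(derived_rates(100, 0.137)$lambda, 3), 1.147)
  d0 <- derived_rates(5, 0)
  expect_equal(d0$lambda, 1)
  expect_true(is.na(d0$T))
  d <- derived_rates(5, log(2) / 2)
  expect_equal(d$T, log(5) / (log(2) / 2))
})

test_that("cohort summary computes APOP, TPOP and proportions by definition", {
  # female emerges day 27, first egg day 30, eggs on 1 day
  sm <- summarize_cohort(fx_three())
  expect_equal(unname(sm$apop["mean"]), 3)
  expect_equal(unname(sm$tpop["mean"]), 30)
  expect_equal(unname(sm$ovi_days["mean"]), 1)
  expect_equal(sm$Nf_N, 1 / 3)
  expect_equal(sm$Nm_N, 1 / 3)
  expect_equal(sm$Nfr_Nf, 1)
  expect_equal(unname(sm$fecundity["mean"]), 5)

  # stage-duration means include only individuals completing the stage:
  # U1 died as L1, so its L1 days must not enter the L1 mean (2 d for F1/M1)
  durs <- sm$stage_durations
  expect_equal(durs$mean[durs$stage == "L1"], 2)
  expect_equal(durs$n[durs$stage == "L1"], 2)
})

test_that("two-sex identities hold on every generated cohort", {
  for (seed in 1:4) {
    cfg <- if (seed %% 2) synthetic_preset("faw-default")
           else synthetic_preset("jobs-tears-like", n = 60)
    coh <- generate_cohort(cfg, seed = seed)
    lt <- life_table(coh)
    s <- lt$survival
    a <- agestage:::cohort_arrays(coh)
    sm <- lt$summary

    # conservation
    expect_equal(rowSums(s$s), lt$lx, tolerance = 1e-12)
    # R0 = (Nf/N) * mean fecundity per female, exactly
    expect_equal(unname(lt$params["R0"]),
                 sm$Nf_N * unname(sm$fecundity["mean"]), tolerance = 1e-12)
    # lambda = e^r and T = ln(R0)/r
    expect_equal(unname(lt$params["lambda"]), exp(unname(lt$params["r"])),
                 tolerance = 1e-14)
    expect_equal(unname(lt$params["T"]),
                 log(unname(lt$params["R0"])) / unname(lt$params["r"]),
                 tolerance = 1e-12)
    # e_0,EGG = mean total longevity; v_0,EGG = lambda
    expect_equal(lt$e[1, "EGG"], mean(a$death_age), tolerance = 1e-9)
    expect_equal(lt$v[1, "EGG"], unname(lt$params["lambda"]), tolerance = 1e-9)
    # Euler-Lotka residual at the root
    phi <- lt$fecundity$net_maternity
    expect_lt(abs(sum(exp(-lt$params["r"] * seq_along(phi)) * phi) - 1), 1e-10)
  }
})

test_that("raising every female's daily fecundity never decreases R0 or r", {
  coh <- generate_cohort(synthetic_preset("faw-default"), seed = 9)
  lt <- life_table(coh)
  bump <- coh
  fem_days <- bump$data$stage == "ADULT_F"
  bump$data$eggs[fem_days] <- bump$data$eggs[fem_days] + 3
  lt2 <- life_table(bump)
  expect_gte(lt2$params[["R0"]], lt$params[["R0"]])
  expect_gte(lt2$params[["r"]], lt$params[["r"]])
})
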