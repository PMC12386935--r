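test_that("generation is deterministic under a fixed seed and always valid", {
  cfg <- synthetic_preset("faw-default")
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1$data, c2$data)
  c3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(c1$data, c3$data))

  for (p in c("faw-default", "corn-like", "jobs-tears-like")) {
    coh <- generate_cohort(synthetic_preset(p, n = 40), seed = 12)
    expect_identical(nrow(validate_cohort(coh)), 0L)
  }
})

test_that("degenerate config reproduces its own parameters exactly", {
  cfg <- synthetic_config(
    n = 20, sex_ratio = 0, fertile_prob = 1,
    durations = list(EGG = c(mean = 3, cv = 0), L1 = c(mean = 2, cv = 0),
                     L2 = c(mean = 2, cv = 0), L3 = c(mean = 2, cv = 0),
                     L4 = c(mean = 2, cv = 0), L5 = c(mean = 3, cv = 0),
                     L6 = c(mean = 4, cv = 0), PUPA = c(mean = 9, cv = 0)),
    daily_survival = 1, supernumerary = c(L7 = 0, L8 = 0),
    adult_longevity = list(female = c(mean = 10, cv = 0),
                           male = c(mean = 10, cv = 0)))
  coh <- generate_cohort(cfg, seed = 1)
  a <- agestage:::cohort_arrays(coh)
  expect_true(all(a$sex == "male"))
  sm <- summarize_cohort(coh)
  durs <- sm$stage_durations
  for (st in names(cfg$durations))
    expect_equal(durs$mean[durs$stage == st], cfg$durations[[st]][["mean"]])
  expect_equal(unname(sm$male_adult_longevity["mean"]), 10)
  expect_equal(unname(sm$preadult["mean"]), 27)   # 3+2+2+2+2+3+4+9
})

test_that("ground truth closed forms are exact in trivial cases", {
  cfg <- synthetic_config(sex_ratio = 0.5, fertile_prob = 1,
                          daily_survival = 1,
                          supernumerary = c(L7 = 0, L8 = 0),
                          fecundity = c(mean = 100, cv = 0))
  gt <- ground_truth(cfg)
  expect_equal(gt$preadult_survival, 1, tolerance = 1e-12)
  expect_equal(gt$R0, 50, tolerance = 1e-9)
  expect_equal(sum(gt$net_maternity), gt$R0, tolerance = 1e-9)

  cfg0 <- synthetic_config(fecundity = c(mean = 0, cv = 0))
  gt0 <- ground_truth(cfg0)
  expect_equal(gt0$R0, 0)
  expect_true(is.na(gt0$r))
})

test_that("true r matches the life table of a mortality-free mega-cohort", {
  cfg <- synthetic_config(n = 20000, daily_survival = 1)
  gt <- ground_truth(cfg)
  coh <- generate_cohort(cfg, seed = 3)
  s <- compute_age_stage_survival(coh)
  fs <- compute_fecundity(coh, s)
  rhat <- solve_intrinsic_rate(compute_lx(s), fs)
  expect_lt(abs(rhat - gt$r), 1e-3)
})

test_that("presets stay inside the emulation envelope", {
  # mean pre-adult duration within 25.5-32.5 d, mean eggs/female within
  # 278-1055 across the published host-plant range
  for (p in c("corn-like", "jobs-tears-like")) {
    coh <- generate_cohort(synthetic_preset(p), seed = 14)
    sm <- summarize_cohort(coh)
    expect_gte(unname(sm$preadult["mean"]), 25.5)
    expect_lte(unname(sm$preadult["mean"]), 32.5)
    expect_gte(unname(sm$fecundity["mean"]), 278)
    expect_lte(unname(sm$fecundity["mean"]), 1055)
  }
})

test_that("synthetic config survives a JSON round trip", {
  cfg <- synthetic_preset("jobs-tears-like")
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back[setdiff(names(back), "schema")],
               cfg[setdiff(names(cfg), "schema")], tolerance = 1e-12)
  # same seed, same cohort through the round-tripped config
  expect_identical(generate_cohort(cfg, seed = 2)$data,
                   generate_cohort(back, seed = 2)$data)
})
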