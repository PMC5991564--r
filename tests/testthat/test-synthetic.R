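test_that("generators are deterministic in the seed", {
  cfg <- cohort_config(n_subjects = 30)
  expect_identical(generate_subjects(cfg, 71), generate_subjects(cfg, 71))
  s <- generate_subjects(cfg, 71)
  expect_identical(generate_tissue_measurements(s, cfg, "logit", 72),
                   generate_tissue_measurements(s, cfg, "logit", 72))
  cn <- data.frame(sample_id = c("A", "B"), copies = c(100, 200))
  expect_identical(generate_qpcr_plates(cn, cfg, 73)$qpcr,
                   generate_qpcr_plates(cn, cfg, 73)$qpcr)
  expect_false(identical(generate_subjects(cfg, 71),
                         generate_subjects(cfg, 74)))
})

test_that("subject marginals match the configured cohort structure", {
  cfg <- cohort_config(n_subjects = 10000)
  s <- generate_subjects(cfg, 75)
  pf <- 147 / 242
  se <- sqrt(pf * (1 - pf) / 10000)
  expect_lt(abs(mean(s$sex == "female") - pf), 2 * se)
  expect_true(all(s$latent >= 0.05 & s$latent <= 0.95))
  expect_true(all(s$age >= 19.7 & s$age <= 79.9))
  expect_error(generate_subjects(cohort_config(n_subjects = 1)), "n_subjects")
})

test_that("tissue observation models show the expected cohort-level structure", {
  cfg <- cohort_config(n_subjects = 500)
  s <- generate_subjects(cfg, 76)
  m <- generate_tissue_measurements(s, cfg, "logit", 77)
  w <- reshape(m[c("subject_id", "tissue", "level")], idvar = "subject_id",
               timevar = "tissue", direction = "wide")
  # blood-urine correlation in the observed regime (R2 well above 0.5,
  # age interaction included as in the reference analysis)
  r2 <- summary(lm(level.blood ~ level.urine * age_at_sample,
                   data = cbind(w, age_at_sample =
                                  s$age[match(w$subject_id, s$subject_id)])))$r.squared
  expect_gt(r2, 0.5)
  # males average higher urine levels
  mu <- m[m$tissue == "urine", ]
  expect_gt(mean(mu$level[mu$sex == "male"]),
            mean(mu$level[mu$sex == "female"]))
})

test_that("linear urine mode plants the percentage-scale slope and sex gap", {
  cfg <- cohort_config(n_subjects = 2000)
  s <- generate_subjects(cfg, 78)
  m <- generate_tissue_measurements(s, cfg, "linear", 79)
  u <- m[m$tissue == "urine", ]; mus <- m[m$tissue == "muscle", ]
  f <- fit_urine_linear_model(u$level, mus$level, u$sex)
  expect_equal(f$slope, 0.75, tolerance = 0.1)
  expect_equal(f$male_gap, 19.2, tolerance = 0.15)
})

test_that("longitudinal generator: conservation, declining majority, truncation", {
  cfg <- cohort_config(n_subjects = 80)
  s <- generate_subjects(cfg, 80)
  g <- generate_longitudinal(s, cfg, visits = 2:5, span_range = c(4, 12),
                             seed = 81)
  # item decomposition sums back to the intended (integer) scaled total
  sc <- quiet(scale_nmdas_table(g$nmdas))
  items <- as.matrix(g$nmdas[sprintf("item_%02d", 1:29)])
  expect_equal(sc$scaled_score, rowSums(items, na.rm = TRUE),
               tolerance = 1e-9)
  expect_true(all(items >= 0 & items <= 5))
  # blood declines for most subjects followed 4+ years
  tr <- summarise_trajectories(g$blood)
  long <- tr[tr$class != "short-span", ]
  expect_gt(mean(long$class == "declining"), 0.5)
  # zero variance components: all subjects share one trajectory shape
  cfg0 <- cohort_config(n_subjects = 10,
                        progression = list(beta_age = 0.12, beta_int = 0,
                                           sd_age = 0, sd_int = 0,
                                           resid_sd = 0))
  s0 <- generate_subjects(cfg0, 82)
  g0 <- generate_longitudinal(s0, cfg0, visits = 2, seed = 83)
  sc0 <- quiet(scale_nmdas_table(g0$nmdas))
  slope0 <- sqrt(sc0$scaled_score) / sc0$age_at_assessment
  # common slope up to integer rounding of item totals
  expect_lt(diff(range(slope0)), 0.02)
})

test_that("simulate_cohort writes a consistent CSV bundle that reads back", {
  dir <- tempfile("cohort")
  sim <- quiet(simulate_cohort(cohort_config(n_subjects = 40), seed = 84,
                               dir = dir, n_longitudinal = 10))
  expect_true(all(file.exists(file.path(dir, c("heteroplasmy.csv",
                                               "nmdas.csv", "qpcr.csv",
                                               "ground_truth.csv")))))
  het <- quiet(read_measurements(file.path(dir, "heteroplasmy.csv"),
                                 "heteroplasmy"))
  expect_setequal(unique(het$tissue), c("blood", "urine", "muscle"))
  expect_equal(sort(unique(het$subject_id)), sort(sim$subjects$subject_id))
  q <- read_measurements(file.path(dir, "qpcr.csv"), "qpcr")
  expect_setequal(unique(q$role), c("sample", "standard", "control"))
  n <- read_measurements(file.path(dir, "nmdas.csv"), "nmdas")
  expect_equal(nrow(n), nrow(sim$nmdas))
})
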