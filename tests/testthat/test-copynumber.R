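make_curve <- function(slope = -1 / log10(2), intercept = 18, noise = 0,
                       seed = 1) {
  set.seed(seed)
  steps <- 0:5
  ct <- sapply(1:3, function(i) intercept + slope * (-steps) +
                 rnorm(6, 0, noise))
  fit_standard_curve(steps, ct)
}

test_that("standard curve QC reflects efficiency and fit quality", {
  # perfect doubling chemistry: slope exactly -1/log10(2), boundary pass
  sc <- make_curve()
  expect_equal(sc$slope, -3.321928, tolerance = 1e-5)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  expect_true(sc$qc_pass)
  # 85% efficiency is out of the accepted gradient window
  sc85 <- make_curve(slope = -1 / log10(1.85))
  expect_equal(sc85$slope, -3.742911, tolerance = 1e-5)
  expect_false(sc85$qc_pass)
  expect_error(fit_standard_curve(0:2, matrix(20, 3, 3)), ">= 4")
})

test_that("sample quantification removes outlier wells and applies Ct QC", {
  sc <- make_curve()
  q1 <- quantify_sample(c(25.0, 25.1, 25.05), sc)
  expect_true(q1$qc_pass)
  expect_equal(q1$outliers_removed, 0L)
  # |Ct - median| > 0.5 well dropped, mean over the survivors
  q2 <- quantify_sample(c(25.0, 25.1, 28.0), sc)
  expect_equal(q2$outliers_removed, 1L)
  expect_equal(q2$mean_ct, 25.05)
  # high Ct fails
  q3 <- quantify_sample(c(34, 34.05, 33.95), sc)
  expect_false(q3$qc_pass)
  expect_match(q3$qc_reason, "mean Ct")
  # dispersed replicates fail on SD
  q4 <- quantify_sample(c(25.0, 25.49, 24.51), sc)
  expect_false(q4$qc_pass)
  # quantity strictly decreasing in mean Ct
  qs <- vapply(seq(20, 30, by = 1), function(ct)
    quantify_sample(rep(ct, 3), sc)$quantity, 0)
  expect_true(all(diff(qs) < 0))
})

test_that("copies per nucleus combines targets with the diploid and dilution factors", {
  sc_nd1 <- make_curve(intercept = 18)
  sc_b2m <- make_curve(intercept = 24)
  nd1 <- quantify_sample(rep(20, 3), sc_nd1)
  b2m <- quantify_sample(rep(26, 3), sc_b2m)   # same relative quantity
  expect_equal(copies_per_nucleus(nd1, b2m, dilution_ratio = 1), 2,
               tolerance = 1e-9)
  expect_equal(copies_per_nucleus(nd1, b2m, dilution_ratio = 100), 200,
               tolerance = 1e-7)
  bad <- quantify_sample(c(34, 34, 34), sc_b2m)
  expect_message(cn <- copies_per_nucleus(nd1, bad), "QC failure")
  expect_true(is.na(cn))
})

test_that("plate standardisation applies the control ratio formula", {
  expect_equal(standardize_plate(200, 100, 120), 240)
  expect_equal(standardize_plate(c(50, 80), 100, 100), c(50, 80))
  expect_error(standardize_plate(200, NA, 120), "control")
})

test_that("plate simulator round trip recovers copy numbers", {
  # noise-free, no plate effects: exact recovery
  cfg0 <- cohort_config(qpcr = list(ct_sd = 0, efficiency = 1,
                                    nd1_intercept = 18, b2m_intercept = 24,
                                    dilution_ratio = 100,
                                    samples_per_plate = 12L,
                                    plate_effect_sdlog = 0,
                                    control_copies = 150))
  cn <- data.frame(sample_id = sprintf("X%02d", 1:12),
                   copies = seq(100, 3400, length.out = 12))
  g0 <- generate_qpcr_plates(cn, cfg0, seed = 41)
  r0 <- quiet(process_qpcr_plates(g0$qpcr))
  m0 <- merge(r0$samples, g0$truth, by = c("sample_id", "plate_id"))
  expect_equal(m0$standardized_copies_per_nucleus, m0$copies,
               tolerance = 1e-9)
  # default Ct noise 0.1 (plate effects off: standardisation harmonises
  # plates but cannot recover an absolute plate bias): recovery within 5%
  cfg1 <- cohort_config(qpcr = list(ct_sd = 0.1, efficiency = 0.95,
                                    nd1_intercept = 18, b2m_intercept = 24,
                                    dilution_ratio = 100,
                                    samples_per_plate = 12L,
                                    plate_effect_sdlog = 0,
                                    control_copies = 150))
  set.seed(46)
  cn1 <- data.frame(sample_id = sprintf("Y%03d", 1:96),
                    copies = rlnorm(96, log(500), 0.8))
  g1 <- generate_qpcr_plates(cn1, cfg1, seed = 42)
  r1 <- quiet(process_qpcr_plates(g1$qpcr))
  m1 <- merge(r1$samples, g1$truth, by = c("sample_id", "plate_id"))
  # raw copies: the quantification chain itself (standardisation trades a
  # little extra control noise for inter-plate comparability)
  rel <- m1$raw_copies_per_nucleus / m1$copies - 1
  expect_lt(abs(mean(rel)), 0.05)
  expect_lt(median(abs(rel)), 0.05)
})

test_that("standardisation removes a multiplicative plate effect exactly", {
  # simulated on-plate control values distorted by per-plate multipliers
  set.seed(43)
  true_control <- 150
  eff <- rlnorm(8, 0, 0.3)
  on_plate <- true_control * eff
  std <- standardize_plate(on_plate, on_plate, mean(on_plate))
  expect_equal(var(std), 0)
  # and for samples sharing the plate effect, the effect cancels
  sample_raw <- 500 * eff
  sample_std <- standardize_plate(sample_raw, on_plate, mean(on_plate))
  expect_equal(var(sample_std / 500), 0, tolerance = 1e-20)
})

test_that("pipeline excludes plates whose curve fails QC", {
  cfg <- cohort_config()
  cn <- data.frame(sample_id = sprintf("X%02d", 1:24),
                   copies = rep(500, 24))
  g <- generate_qpcr_plates(cn, cfg, seed = 44)
  # sabotage plate P01's ND1 standards
  bad <- g$qpcr$plate_id == "P01" & g$qpcr$role == "standard" &
    g$qpcr$target == "ND1"
  g$qpcr$ct_rep1[bad] <- g$qpcr$ct_rep1[bad] + rnorm(sum(bad), 0, 3)
  r <- quiet(process_qpcr_plates(g$qpcr))
  expect_true("P01" %in% r$excluded_plates)
  expect_false("P01" %in% r$samples$plate_id)
})

test_that("copy-number association models detect planted covariate effects", {
  set.seed(45)
  n <- 150
  het <- runif(n, 0.05, 0.95)
  age <- runif(n, 20, 80)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  # null: no covariate enters
  cn_null <- rlnorm(n, log(1181), 0.5)
  a0 <- copynumber_associations(cn_null, het, age, sex)
  expect_lt(abs(a0$r_squared), 0.08)
  # urine-like male excess
  cn_sex <- rlnorm(n, log(800), 0.4) * ifelse(sex == "male", 2.2, 1)
  a1 <- copynumber_associations(cn_sex, het, age, sex)
  expect_lt(a1$coefficients["male", "p"], 0.01)
  expect_gt(a1$coefficients["male", "estimate"], 0)
  expect_warning(copynumber_associations(cn_null[1:8], het[1:8], age[1:8]),
                 "fewer than 10")
})
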