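test_that("NMDAS scaling drops the respiratory item and rescales partial assessments", {
  # all 29 answered; the 28 scored (non-respiratory) items sum to 58
  items <- rep(0, 29)
  items[setdiff(1:29, 10)] <- rep(c(2, 3), length.out = 28)[1:28]
  items[10] <- 4                      # respiratory score never counts
  s <- sum(items[-10])
  a <- scale_nmdas(items, respiratory_item = 10)
  expect_equal(a$scaled_score, s)     # denominator 29, x29: identity
  expect_true(a$included)

  # 25 answered, scored sum 50 -> 50/25*29 = 58
  items2 <- c(rep(2, 25), rep(NA, 4))
  a2 <- scale_nmdas(items2, respiratory_item = 26)
  expect_equal(a2$n_answered, 25)
  expect_equal(a2$scaled_score, 58)

  # 24 answered -> excluded
  items3 <- c(rep(2, 24), rep(NA, 5))
  expect_message(a3 <- scale_nmdas(items3), "excluded")
  expect_false(a3$included)
  expect_true(is.na(a3$scaled_score))

  # linearity: doubling every answered score doubles the scaled score
  half <- c(rep(c(1, 2), length.out = 26), NA, NA, NA)  # 26 answered
  full <- half * 2
  expect_equal(scale_nmdas(full)$scaled_score,
               2 * scale_nmdas(half)$scaled_score)
})

test_that("burden points take the maximum score at the earliest age", {
  sc <- data.frame(subject_id = c("A", "A", "A", "B", "C"),
                   age_at_assessment = c(30, 35, 40, 50, 60),
                   scaled_score = c(10, 20, 20, 7, 4.9))
  bp <- burden_points(sc)
  expect_equal(bp$max_scaled_score[bp$subject_id == "A"], 20)
  expect_equal(bp$age_at_max[bp$subject_id == "A"], 35)
  expect_equal(bp$sqrt_score[bp$subject_id == "A"], sqrt(20))
  expect_equal(bp$max_scaled_score[bp$subject_id == "B"], 7)
  expect_true(bp$symptomatic[bp$subject_id == "B"])
  expect_false(bp$symptomatic[bp$subject_id == "C"])   # 4.9 < 5
})

test_that("burden regression behaves under the null and flags collinearity", {
  set.seed(51)
  n <- 80
  ids <- sprintf("N%03d", 1:n)
  burden <- data.frame(subject_id = ids,
                       max_scaled_score = runif(n, 1, 80),
                       age_at_max = runif(n, 20, 70))
  burden$sqrt_score <- sqrt(burden$max_scaled_score)
  pred <- data.frame(subject_id = ids, age = runif(n, 20, 70),
                     het_pct = runif(n, 5, 95))
  f0 <- fit_burden_model(burden, pred)
  expect_lt(abs(f0$adj_r_squared), 0.08)
  pred2 <- pred
  pred2$het_copy <- pred2$het_pct      # perfectly collinear
  expect_error(fit_burden_model(burden, pred2), "collinear")
})

test_that("muscle burden model recovers generating coefficients", {
  r <- sapply(1:20, function(seed) {
    g <- generate_burden_cohort(66, cohort_config(), seed)
    coef(fit_burden_model(g$burden, g$predictors))[c("het_pct", "copy_number")]
  })
  expect_equal(mean(r[1, ]), 0.027, tolerance = 0.15)
  expect_equal(mean(r[2, ]) * 100, -0.055, tolerance = 0.15)
})

test_that("bootstrap R2 self-comparison is exactly tied at P = 0.5", {
  g <- generate_burden_cohort(66, cohort_config(), 52)
  cmp <- bootstrap_r2_compare(g$burden, g$predictors, g$predictors,
                              replicates = 40, seed = 3)
  expect_equal(cmp$point_estimate, 0)
  expect_equal(cmp$mean_delta, 0)
  expect_equal(cmp$p_value, 0.5)
})

test_that("a pure-noise extra predictor does not improve adjusted R2", {
  set.seed(53)
  g <- generate_burden_cohort(66, cohort_config(), 54)
  pa <- g$predictors
  pb <- pa
  pb$noise <- rnorm(nrow(pb))
  cmp <- bootstrap_r2_compare(g$burden, pb, pa, replicates = 60, seed = 4)
  # nested model with a junk predictor: adjusted delta centred at or below 0
  expect_lte(cmp$mean_delta, 0.01)
})

test_that("the informative measure wins the bootstrap R2 comparison", {
  set.seed(55)
  g <- generate_burden_cohort(66, cohort_config(), 56)
  pa <- g$predictors[c("subject_id", "age", "het_pct")]
  pb <- pa
  pb$het_pct <- pmin(pmax(pa$het_pct + rnorm(66, 0, 40), 0), 100)
  cmp <- bootstrap_r2_compare(g$burden, pa, pb, replicates = 100, seed = 5,
                              labels = c("true_het", "noisy_het"))
  expect_gt(cmp$point_estimate, 0)
  # P is the bootstrap probability the second (noisy) model is better
  expect_lt(cmp$p_value, 0.2)
})
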