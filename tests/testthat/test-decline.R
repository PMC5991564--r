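test_that("trajectory summaries compute annual change and classes", {
  m <- data.frame(subject_id = rep(c("A", "B", "C", "D"), each = 2),
                  sex = "female", tissue = "blood",
                  age_at_sample = c(30, 40, 30, 35, 30, 32, 50, 60),
                  level = c(0.50, 0.40, 0.30, 0.30, 0.20, 0.10, 0.6, 0.7))
  tr <- summarise_trajectories(m)
  expect_equal(tr$annual_change[tr$subject_id == "A"], -0.01)
  expect_equal(tr$class[tr$subject_id == "A"], "declining")
  expect_equal(tr$annual_change[tr$subject_id == "B"], 0)
  expect_equal(tr$class[tr$subject_id == "B"], "non-declining")
  expect_equal(tr$class[tr$subject_id == "C"], "short-span")
  expect_equal(tr$class[tr$subject_id == "D"], "non-declining")
  # single-measurement subjects are skipped with a message
  m1 <- rbind(m, data.frame(subject_id = "E", sex = "female",
                            tissue = "blood", age_at_sample = 20, level = 0.5))
  expect_message(tr1 <- summarise_trajectories(m1), "skipped")
  expect_false("E" %in% tr1$subject_id)
})

test_that("rate-vs-initial-level regression recovers a proportional decline exactly", {
  set.seed(11)
  first <- runif(20, 0.2, 0.9)
  tr <- data.frame(subject_id = as.character(1:20), first_level = first,
                   age_first = runif(20, 20, 60),
                   annual_change = -0.0185 * first)
  fit <- estimate_linear_decline(tr)
  expect_equal(fit$rate_constant, 0.0185, tolerance = 1e-10)
  expect_error(estimate_linear_decline(tr[1:2, ]), ">= 3")
  tr0 <- tr; tr0$first_level <- 0
  expect_error(estimate_linear_decline(tr0), "degenerate")
})

test_that("age-extended rate model improves fit when decline slows with age", {
  set.seed(12)
  n <- 60
  first <- runif(n, 0.2, 0.9)
  age <- runif(n, 20, 70)
  # older subjects decline more slowly (r1 < 0 in the -(r0 + r1*age) form)
  rate <- pmax(0.03 - 0.0004 * age, 0)
  tr <- data.frame(subject_id = as.character(1:n), first_level = first,
                   age_first = age,
                   annual_change = -rate * first + rnorm(n, 0, 0.001))
  fit <- estimate_linear_decline(tr)
  expect_gt(fit$extended$r_squared, fit$r_squared)
  expect_lt(fit$extended$r1, 0)
})

test_that("compound-decline fit recovers generating constants without noise", {
  set.seed(13)
  n <- 50
  init <- runif(n, 0.1, 0.9)
  age <- runif(n, 20, 75)
  blood <- init * 0.977^(age + 12)
  fit <- fit_compound_decline(blood, init, age)
  expect_equal(fit$params$b, 0.977, tolerance = 1e-3)
  expect_equal(fit$params$k, 12, tolerance = 0.2)
  expect_equal(fit$annual_percent_decline, 2.3, tolerance = 0.1)
  expect_error(fit_compound_decline(blood[1:5], init[1:5], age[1:5]), ">= 10")
})

test_that("no-decline data yields b near 1 and ~0% annual decline", {
  set.seed(14)
  n <- 40
  init <- runif(n, 0.2, 0.8)
  age <- runif(n, 20, 70)
  blood <- pmin(init * 1.0^(age + 12) + rnorm(n, 0, 0.01), 1)
  fit <- fit_compound_decline(pmax(blood, 0), init, age)
  expect_gt(fit$params$b, 0.995)
  expect_lt(fit$annual_percent_decline, 0.5)
})

test_that("grid+refine fit matches an exhaustive brute-force oracle", {
  set.seed(15)
  n <- 20
  init <- runif(n, 0.1, 0.9)
  age <- runif(n, 20, 70)
  blood <- pmin(pmax(init * 0.965^(age + 8) + rnorm(n, 0, 0.01), 0), 1)
  fit <- fit_compound_decline(blood, init, age)
  # independent oracle: exhaustive fine grid over (b, k)
  bs <- seq(0.90, 1.00, by = 0.0005)
  ks <- seq(0, 30, by = 0.25)
  rss <- outer(bs, ks, Vectorize(function(b, k)
    sum((blood - init * b^(age + k))^2)))
  idx <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  expect_equal(fit$params$b, bs[idx[1]], tolerance = 5e-4)
  expect_lte(fit$rss, min(rss) + 1e-10)
})

test_that("muscle validation reports slope and the adjusted-vs-raw improvement", {
  set.seed(16)
  muscle <- runif(40, 0.1, 0.9)
  v <- validate_against_muscle(muscle, muscle)
  expect_equal(v$slope, 1, tolerance = 1e-10)
  expect_equal(v$r_squared, 1, tolerance = 1e-10)
  # shuffled pairing destroys the association
  v2 <- validate_against_muscle(sample(muscle), muscle)
  expect_lt(abs(v2$r_squared), 0.2)
  expect_error(validate_against_muscle(muscle[1:2], muscle[1:2]), ">= 3")
})
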