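#' Logit and inverse-logit transforms with boundary clamping
#'
#' The urine sex adjustment operates on the log-odds scale, so proportions of
#' exactly 0 or 1 must be pulled inside the open interval first. `logit()`
#' clamps its argument into `[eps, 1 - eps]` and records (as an attribute)
#' which elements were clamped; `inv_logit()` is the plain inverse.
#'
#' @param p numeric vector of proportions in \[0, 1\].
#' @param eps clamp width; values are forced into `[eps, 1 - eps]`. The
#'   default 0.005 sits well below the 3% sensitivity of the pyrosequencing
#'   assay, so clamping only ever fires on levels the assay cannot resolve
#'   anyway.
#' @param x numeric vector on the log-odds scale.
#' @return `logit()`: log-odds, with a logical attribute `"clamped"` marking
#'   elements that hit the clamp. `inv_logit()`: proportions in (0, 1).
#' @examples
#' logit(0.5)           # 0
#' inv_logit(0)         # 0.5
#' attr(logit(0), "clamped")
#' @export
logit <- function(p, eps = 0.005) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("logit() expects proportions in [0, 1]")
  clamped <- !is.na(p) & (p < eps | p > 1 - eps)
  p <- pmin(pmax(p, eps), 1 - eps)
  out <- log(p / (1 - p))
  attr(out, "clamped") <- clamped
  out
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Parameters of the compound blood-decline model
#'
#' Blood heteroplasmy decays multiplicatively with age: an individual whose
#' underlying (latent) mutation load is `p` shows a blood level of
#' `p * b^(age + k)`. `b` is the per-year retention factor (the published
#' value 0.977 corresponds to a compound decline of ~2.3% per year) and `k`
#' is an age offset capturing the rapid fall in early life.
#'
#' @param b per-year multiplicative retention factor, in (0, 1].
#' @param k age offset in years, >= 0.
#' @return an object of class `"decline_params"`.
#' @seealso [age_adjust_blood()], [fit_compound_decline()]
#' @export
decline_params <- function(b = 0.977, k = 12) {
  stopifnot(is.numeric(b), length(b) == 1L, b > 0, b <= 1,
            is.numeric(k), length(k) == 1L, k >= 0)
  structure(list(b = b, k = k), class = "decline_params")
}

#' @export
print.decline_params <- function(x, ...) {
  cat(sprintf("Compound blood-decline parameters: b = %.4f, k = %.2f yr (%.2f%%/yr decline)\n",
              x$b, x$k, (1 - x$b) * 100))
  invisible(x)
}

#' Parameters of the urine sex adjustment
#'
#' Urine heteroplasmy is related to the underlying mutation load on the
#' log-odds scale through a proportionality factor `s` and a sex-specific
#' offset: generatively, `logit(urine) = s * (logit(true) + offset_sex)`
#' with `offset_male = +male_offset` and `offset_female = -female_offset`.
#' Inverting gives the adjustment formulas
#' `male adjusted = inv_logit(logit(urine)/s - male_offset)` and
#' `female adjusted = inv_logit(logit(urine)/s + female_offset)`.
#'
#' @param s logit-scale proportionality factor, > 0 (published: 0.791).
#' @param male_offset,female_offset sex offsets in logit units (published:
#'   0.625 and 0.608).
#' @return an object of class `"urine_sex_params"`.
#' @seealso [sex_adjust_urine()], [fit_urine_sex_model()]
#' @export
urine_sex_params <- function(s = 0.791, male_offset = 0.625,
                             female_offset = 0.608) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0,
            is.numeric(male_offset), length(male_offset) == 1L,
            is.numeric(female_offset), length(female_offset) == 1L)
  structure(list(s = s, male_offset = male_offset,
                 female_offset = female_offset),
            class = "urine_sex_params")
}

#' @export
print.urine_sex_params <- function(x, ...) {
  cat(sprintf("Urine sex-adjustment parameters: scale = %.3f, male offset = %.3f, female offset = %.3f (logit units)\n",
              x$s, x$male_offset, x$female_offset))
  invisible(x)
}

#' Age-adjust blood heteroplasmy
#'
#' Undoes the compound age-related decline of blood heteroplasmy:
#' `adjusted = level / b^(age + k)`. With the default parameters this is the
#' published age correction `blood / 0.977^(age + 12)`. Because the decline
#' factor is < 1, the adjusted value can exceed 1 for high levels at high
#' ages; such values are truncated to 1 and flagged.
#'
#' @param level blood heteroplasmy as a proportion in \[0, 1\] (vectorised).
#' @param age age at sampling in years, >= 0 (recycled against `level`).
#' @param params a [decline_params()] object.
#' @return a data.frame with columns `adjusted_level` (proportion, truncated
#'   at 1), `capped` (logical, TRUE where truncation fired) and `method`
#'   (`"age_adjusted_blood"`).
#' @examples
#' age_adjust_blood(0.20, 30)   # ~0.531
#' age_adjust_blood(0.80, 60)   # capped at 1
#' @export
age_adjust_blood <- function(level, age, params = decline_params()) {
  stopifnot(inherits(params, "decline_params"))
  if (any(age < 0, na.rm = TRUE)) stop("age must be >= 0")
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("level must be a proportion in [0, 1]")
  raw <- level / params$b^(age + params$k)
  capped <- !is.na(raw) & raw > 1
  data.frame(adjusted_level = pmin(raw, 1), capped = capped,
             method = "age_adjusted_blood", stringsAsFactors = FALSE)
}

#' Sex-adjust urine heteroplasmy
#'
#' Removes the sex offset from urine heteroplasmy on the log-odds scale:
#' males are adjusted by `inv_logit(logit(level)/s - male_offset)`, females
#' by `inv_logit(logit(level)/s + female_offset)`. With the published
#' defaults, males (who run ~19 percentage points higher in urine) are
#' adjusted downward and females upward toward the underlying mutation load.
#'
#' @param level urine heteroplasmy as a proportion in \[0, 1\] (vectorised).
#' @param sex character vector, `"male"` or `"female"` (recycled).
#' @param params a [urine_sex_params()] object.
#' @param eps clamp width passed to [logit()].
#' @return a data.frame with columns `adjusted_level`, `capped` (TRUE where
#'   the input hit the logit clamp) and `method` (`"sex_adjusted_urine"`).
#' @examples
#' sex_adjust_urine(0.5, "male")     # ~0.349
#' sex_adjust_urine(0.5, "female")   # ~0.647
#' @export
sex_adjust_urine <- function(level, sex, params = urine_sex_params(),
                             eps = 0.005) {
  stopifnot(inherits(params, "urine_sex_params"))
  sex <- as.character(sex)
  if (any(is.na(sex)) || !all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female' for every urine measurement")
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("level must be a proportion in [0, 1]")
  n <- max(length(level), length(sex))
  level <- rep_len(level, n); sex <- rep_len(sex, n)
  lg <- logit(level, eps = eps)
  offset <- ifelse(sex == "male", -params$male_offset, +params$female_offset)
  adj <- inv_logit(as.numeric(lg) / params$s + offset)
  data.frame(adjusted_level = adj, capped = attr(lg, "clamped"),
             method = "sex_adjusted_urine", stringsAsFactors = FALSE)
}

#' Composite adjusted blood-and-urine measure
#'
#' The unweighted arithmetic mean of a subject's age-adjusted blood and
#' sex-adjusted urine levels ("mean adjusted blood and urine"). Subjects
#' missing either component get `NA` and are expected to be dropped from
#' composite analyses.
#'
#' @param blood_adj,urine_adj numeric vectors of adjusted proportions
#'   (aligned by subject; `NA` where a subject lacks the measure).
#' @return a data.frame with `adjusted_level` (NA where either input is
#'   missing) and `method = "composite"`.
#' @export
composite_measure <- function(blood_adj, urine_adj) {
  stopifnot(length(blood_adj) == length(urine_adj))
  out <- (blood_adj + urine_adj) / 2
  n_dropped <- sum(is.na(out))
  if (n_dropped > 0)
    message(n_dropped, " subject(s) missing one component; composite set to NA")
  data.frame(adjusted_level = out, method = "composite",
             stringsAsFactors = FALSE)
}

#' Fit the urine sex-adjustment transformation from paired muscle/urine data
#'
#' Estimates the logit-scale proportionality factor and sex offsets of the
#' urine adjustment by regressing `logit(urine)` on `logit(muscle)` plus a
#' sex indicator (muscle heteroplasmy standing in for the underlying
#' mutation load, with which it agrees closely). Under the generative model
#' `logit(urine) = s*(logit(true) + offset_sex)` the fitted slope is `s`,
#' and the male/female offsets are read off the intercepts:
#' `female_offset = -intercept/s`, `male_offset = (intercept + beta_male)/s`.
#'
#' @param urine,muscle proportions in \[0, 1\], paired by subject.
#' @param sex `"male"`/`"female"` per subject.
#' @param eps clamp width for [logit()].
#' @return a [urine_sex_params()] object with attributes `fit` (the
#'   underlying `lm`) and `r_squared` (adjusted).
#' @export
fit_urine_sex_model <- function(urine, muscle, sex, eps = 0.005) {
  sex <- as.character(sex)
  stopifnot(length(urine) == length(muscle), length(sex) == length(urine),
            all(sex %in% c("male", "female")))
  d <- data.frame(lu = as.numeric(logit(urine, eps)),
                  lm_ = as.numeric(logit(muscle, eps)),
                  male = as.integer(sex == "male"))
  fit <- lm(lu ~ lm_ + male, data = d)
  cf <- coef(fit)
  s <- unname(cf["lm_"])
  if (s <= 0) stop("fitted logit-scale slope is not positive; data degenerate")
  p <- urine_sex_params(s = s,
                        male_offset = unname((cf["(Intercept)"] + cf["male"]) / s),
                        female_offset = unname(-cf["(Intercept)"] / s))
  attr(p, "fit") <- fit
  attr(p, "r_squared") <- summary(fit)$adj.r.squared
  p
}

#' Fit the percentage-scale urine-on-muscle regression with a sex term
#'
#' The alternative, percentage-linear description of the muscle-urine
#' relationship: `urine% = a + slope * muscle% + gap * I(male)`. Reported
#' alongside the logit parameterisation because the sex gap is most readily
#' communicated in percentage points (~19 points higher in males).
#'
#' @param urine,muscle proportions in \[0, 1\], paired by subject.
#' @param sex `"male"`/`"female"` per subject.
#' @return a list of class `"urine_linear_fit"` with `slope` (% per %),
#'   `male_gap` (percentage points), `intercept`, `r_squared` (adjusted) and
#'   the underlying `fit`.
#' @export
fit_urine_linear_model <- function(urine, muscle, sex) {
  sex <- as.character(sex)
  stopifnot(length(urine) == length(muscle), length(sex) == length(urine),
            all(sex %in% c("male", "female")))
  d <- data.frame(u = urine * 100, m = muscle * 100,
                  male = as.integer(sex == "male"))
  fit <- lm(u ~ m + male, data = d)
  cf <- coef(fit)
  structure(list(slope = unname(cf["m"]), male_gap = unname(cf["male"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = summary(fit)$adj.r.squared, fit = fit),
            class = "urine_linear_fit")
}

#' @export
print.urine_linear_fit <- function(x, ...) {
  cat(sprintf("Urine ~ muscle (percentage scale): slope = %.3f %%/%%, male gap = %.1f pp, adj R2 = %.2f\n",
              x$slope, x$male_gap, x$r_squared))
  invisible(x)
}

#' Adjust a cohort's heteroplasmy table
#'
#' Batch application of the tissue adjustments to a long-format measurement
#' table: blood rows are age-adjusted, urine rows sex-adjusted, muscle rows
#' passed through unchanged (muscle is used raw). Adds `adjusted_level`,
#' `method` and `capped` columns.
#'
#' @param measurements a data.frame with columns `subject_id`, `sex`,
#'   `tissue`, `age_at_sample`, `level` (proportions), as returned by
#'   [read_measurements()].
#' @param decline a [decline_params()] object.
#' @param urine_sex a [urine_sex_params()] object.
#' @param eps logit clamp width.
#' @return the input with adjustment columns appended.
#' @export
adjust_cohort <- function(measurements, decline = decline_params(),
                          urine_sex = urine_sex_params(), eps = 0.005) {
  m <- measurements
  m$adjusted_level <- m$level
  m$method <- "raw"
  m$capped <- FALSE
  is_b <- m$tissue == "blood"
  if (any(is_b)) {
    ab <- age_adjust_blood(m$level[is_b], m$age_at_sample[is_b], decline)
    m$adjusted_level[is_b] <- ab$adjusted_level
    m$method[is_b] <- ab$method
    m$capped[is_b] <- ab$capped
  }
  is_u <- m$tissue == "urine"
  if (any(is_u)) {
    au <- sex_adjust_urine(m$level[is_u], m$sex[is_u], urine_sex, eps)
    m$adjusted_level[is_u] <- au$adjusted_level
    m$method[is_u] <- au$method
    m$capped[is_u] <- au$capped
  }
  m
}
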