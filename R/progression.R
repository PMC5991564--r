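#' Linear mixed model of disease progression
#'
#' Models longitudinal square-root scaled NMDAS scores as a function of age
#' and the age-by-heteroplasmy interaction with no intercept anywhere in
#' the model — individuals are assumed asymptomatic at birth, so every
#' fitted trajectory passes through the origin. Fixed effects: age and
#' age x heteroplasmy (the heteroplasmy main effect, dropped in the
#' reference analysis as non-significant, can be re-enabled via
#' `include_het_main`). Random effects: by-subject slopes for age and for
#' the interaction. Estimation is by maximum likelihood (not REML) so AICs
#' are comparable across specifications with different fixed effects.
#'
#' @param scaled a scaled assessment table ([scale_nmdas_table()]).
#' @param heteroplasmy data.frame with `subject_id` and `het`: one
#'   heteroplasmy value per subject, as a proportion.
#' @param include_het_main also include the heteroplasmy main effect
#'   (default FALSE, the reference structure).
#' @param include_random fit the by-subject random slopes (default TRUE).
#'   With `FALSE` the model degenerates to through-origin OLS — useful for
#'   cross-checks and for single-visit data, where random slopes are not
#'   identifiable.
#' @return a list of class `"progression_fit"`: `fixed` (estimates, SE,
#'   two-sided t-distribution P), `random_sd` (by-subject slope SDs),
#'   `residual_sd`, `aic`, `log_lik`, `n_parameters`, `n_subjects`,
#'   `n_observations`, `converged`, `singular`, and the underlying model
#'   object as `fit`.
#' @export
fit_progression <- function(scaled, heteroplasmy, include_het_main = FALSE,
                            include_random = TRUE) {
  d <- merge(scaled, heteroplasmy, by = "subject_id")
  d <- d[complete.cases(d[c("scaled_score", "age_at_assessment", "het")]), ,
         drop = FALSE]
  d$sqrt_score <- sqrt(d$scaled_score)
  d$age <- d$age_at_assessment
  d$age_het <- d$age * d$het
  fixed_terms <- c("age", "age_het", if (include_het_main) "het")
  fixed_form <- stats::reformulate(c("0", fixed_terms),
                                   response = "sqrt_score")
  if (!include_random) {
    fit <- lm(fixed_form, data = d)
    sm <- summary(fit)
    ll <- logLik(fit)
    return(structure(list(
      fixed = cbind(estimate = coef(fit), se = sm$coefficients[, 2],
                    p = sm$coefficients[, 4]),
      random_sd = c(age = 0, age_het = 0),
      residual_sd = sm$sigma, aic = AIC(fit),
      log_lik = as.numeric(ll), n_parameters = attr(ll, "df"),
      n_subjects = length(unique(d$subject_id)), n_observations = nrow(d),
      converged = TRUE, singular = FALSE, fit = fit),
      class = "progression_fit"))
  }
  fit <- tryCatch(
    nlme::lme(fixed = fixed_form,
              random = ~ 0 + age + age_het | subject_id,
              data = d, method = "ML",
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         niterEM = 50, opt = "optim",
                                         returnObject = TRUE)),
    error = function(e)
      stop("progression model failed to converge: ", conditionMessage(e)))
  tt <- summary(fit)$tTable
  vc <- nlme::VarCorr(fit)
  rand_sd <- suppressWarnings(as.numeric(vc[fixed_terms[1:2], "StdDev"]))
  names(rand_sd) <- c("age", "age_het")
  singular <- any(rand_sd < 1e-6)
  if (singular)
    warning("random-effects covariance is (near-)singular; fit returned")
  ll <- logLik(fit)
  structure(list(
    fixed = cbind(estimate = tt[, "Value"], se = tt[, "Std.Error"],
                  p = tt[, "p-value"]),
    random_sd = rand_sd,
    residual_sd = fit$sigma, aic = AIC(fit),
    log_lik = as.numeric(ll), n_parameters = attr(ll, "df"),
    n_subjects = length(unique(d$subject_id)), n_observations = nrow(d),
    converged = TRUE, singular = singular, fit = fit),
    class = "progression_fit")
}

#' @export
print.progression_fit <- function(x, ...) {
  cat(sprintf("Progression mixed model (ML, no intercept): %d obs / %d subjects, AIC = %.1f\n",
              x$n_observations, x$n_subjects, x$aic))
  cat("Fixed effects (two-sided t-distribution P):\n")
  print(round(x$fixed, 5))
  cat(sprintf("Random slope SDs: age = %.4f, age x het = %.4f; residual SD = %.3f\n",
              x$random_sd["age"], x$random_sd["age_het"], x$residual_sd))
  if (x$singular) cat("  note: random-effects covariance near-singular\n")
  invisible(x)
}

#' @export
coef.progression_fit <- function(object, ...) object$fixed[, "estimate"]

#' Predicted population-level trajectory
#'
#' Evaluates the fixed-effect trajectory `(b_age + b_int * het) * age` for
#' given ages and a heteroplasmy level; by construction it is 0 at age 0.
#'
#' @param object a [fit_progression()] result.
#' @param age ages in years.
#' @param het heteroplasmy proportion.
#' @param ... unused.
#' @return predicted sqrt-NMDAS values.
#' @export
predict.progression_fit <- function(object, age, het, ...) {
  b <- object$fixed[, "estimate"]
  unname(b["age"] * age + b["age_het"] * age * het +
           (if ("het" %in% names(b)) b["het"] * het else 0))
}

#' Bootstrap AIC comparison of two progression models
#'
#' Fits the progression model with two different heteroplasmy measures on
#' the same subjects, then resamples subjects with replacement, refits both
#' on each replicate, and summarises `AIC(a) - AIC(b)`. Lower AIC is
#' better, so the reported P is the proportion of replicates with a
#' difference below zero — the bootstrap probability that the first model
#' fits better (exact ties counted half); a P near 0 or 1 indicates a
#' consistent preference, for model A or model B respectively.
#'
#' @param scaled a scaled assessment table.
#' @param het_a,het_b per-subject heteroplasmy tables (`subject_id`, `het`)
#'   for the two measures; restricted to shared subjects.
#' @param replicates bootstrap replicate count (default 1000).
#' @param seed RNG seed.
#' @param labels character(2) descriptors.
#' @param include_random passed to [fit_progression()].
#' @return a `"comparison_result"` with statistic `"delta_aic"`.
#' @export
bootstrap_aic_compare <- function(scaled, het_a, het_b, replicates = 1000L,
                                  seed = 1L, labels = c("measure_a", "measure_b"),
                                  include_random = TRUE) {
  common <- Reduce(intersect, list(scaled$subject_id, het_a$subject_id,
                                   het_b$subject_id))
  if (length(common) < 10) stop("fewer than 10 subjects shared by both measures")
  scaled <- scaled[scaled$subject_id %in% common, , drop = FALSE]
  fit_pair <- function(s, a, b)
    fit_progression(s, a, include_random = include_random)$aic -
      fit_progression(s, b, include_random = include_random)$aic
  point <- fit_pair(scaled, het_a, het_b)
  by_subj <- split(scaled, scaled$subject_id)
  ids <- names(by_subj)
  set.seed(seed)
  deltas <- rep(NA_real_, replicates)
  for (i in seq_len(replicates)) {
    pick <- sample(ids, replace = TRUE)
    s <- do.call(rbind, lapply(seq_along(pick), function(j) {
      d <- by_subj[[pick[j]]]
      d$orig_id <- d$subject_id
      d$subject_id <- sprintf("s%d", j)
      d
    }))
    ha <- data.frame(subject_id = sprintf("s%d", seq_along(pick)),
                     het = het_a$het[match(pick, het_a$subject_id)])
    hb <- data.frame(subject_id = sprintf("s%d", seq_along(pick)),
                     het = het_b$het[match(pick, het_b$subject_id)])
    s$orig_id <- NULL
    deltas[i] <- tryCatch(fit_pair(s, ha, hb), error = function(e) NA_real_)
  }
  failed <- sum(is.na(deltas))
  if (failed > 0.05 * replicates)
    warning(failed, " of ", replicates, " replicates failed to converge")
  deltas <- deltas[!is.na(deltas)]
  .comparison_result("delta_aic", labels[1], labels[2], point, deltas,
                     replicates, failed)
}
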