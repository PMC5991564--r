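#' Scale an NMDAS assessment
#'
#' The NMDAS instrument has 29 clinician-rated items scored 0-5. The
#' respiratory-function item is hard to record reliably and is excluded
#' from the score sum. To keep assessments with a few unanswered items
#' comparable, the sum of answered (non-respiratory) items is divided by
#' the number of answered items and multiplied by 29; assessments with
#' fewer than 25 of 29 responses are excluded.
#'
#' @param items numeric vector of length 29; `NA` = unanswered.
#' @param respiratory_item index (1-29) of the respiratory-function item;
#'   the instrument does not fix which published index this is, so it is
#'   configurable (default 10).
#' @param min_answered inclusion threshold on the number of answered items
#'   (default 25).
#' @return a list of class `"nmdas_assessment"`: `scaled_score` (0-145
#'   scale), `n_answered`, `included` (FALSE when under the threshold, with
#'   `scaled_score = NA`).
#' @examples
#' scale_nmdas(rep(2, 29))          # scaled 56: 28 scored items x 2 / 29 x 29
#' @export
scale_nmdas <- function(items, respiratory_item = 10L, min_answered = 25L) {
  stopifnot(length(items) == 29L, respiratory_item >= 1, respiratory_item <= 29)
  answered <- !is.na(items)
  n_answered <- sum(answered)
  scored <- items[-respiratory_item]
  if (n_answered < min_answered) {
    message("assessment excluded: only ", n_answered, " of 29 items answered")
    return(structure(list(scaled_score = NA_real_, n_answered = n_answered,
                          included = FALSE), class = "nmdas_assessment"))
  }
  total <- sum(scored, na.rm = TRUE)
  structure(list(scaled_score = total / n_answered * 29,
                 n_answered = n_answered, included = TRUE),
            class = "nmdas_assessment")
}

#' @export
print.nmdas_assessment <- function(x, ...) {
  if (x$included)
    cat(sprintf("NMDAS assessment: scaled score = %.1f (%d/29 items answered)\n",
                x$scaled_score, x$n_answered))
  else
    cat(sprintf("NMDAS assessment: excluded (%d/29 items answered)\n",
                x$n_answered))
  invisible(x)
}

#' Scale a long-format NMDAS table
#'
#' Applies [scale_nmdas()] to every row of an assessment table with columns
#' `subject_id`, `age_at_assessment` and `item_01` .. `item_29`, dropping
#' excluded assessments.
#'
#' @param nmdas the assessment table ([read_measurements()] schema
#'   `"nmdas"`).
#' @inheritParams scale_nmdas
#' @return a data.frame with `subject_id`, `age_at_assessment`,
#'   `scaled_score`, `n_answered` for included assessments.
#' @export
scale_nmdas_table <- function(nmdas, respiratory_item = 10L,
                              min_answered = 25L) {
  items <- as.matrix(nmdas[sprintf("item_%02d", 1:29)])
  res <- apply(items, 1L, function(r)
    suppressMessages(scale_nmdas(as.numeric(r), respiratory_item, min_answered)))
  keep <- vapply(res, `[[`, TRUE, "included")
  n_excl <- sum(!keep)
  if (n_excl) message(n_excl, " assessment(s) excluded (< ", min_answered,
                      " of 29 items answered)")
  data.frame(subject_id = nmdas$subject_id[keep],
             age_at_assessment = nmdas$age_at_assessment[keep],
             scaled_score = vapply(res[keep], `[[`, 0, "scaled_score"),
             n_answered = vapply(res[keep], `[[`, 0L, "n_answered"),
             stringsAsFactors = FALSE)
}

#' Per-subject maximum disease burden
#'
#' Collapses a subject's longitudinal assessments to a single independent
#' burden point: the maximum scaled NMDAS score and the earliest age at
#' which it was reached. Subjects with a scaled score of at least 5 at
#' that point are flagged symptomatic.
#'
#' @param scaled a scaled assessment table ([scale_nmdas_table()]).
#' @param symptomatic_threshold scaled NMDAS defining symptomatic status
#'   (default 5).
#' @return a data.frame with one row per subject: `subject_id`,
#'   `max_scaled_score`, `age_at_max`, `sqrt_score`, `symptomatic`.
#' @export
burden_points <- function(scaled, symptomatic_threshold = 5) {
  by_subj <- split(scaled, scaled$subject_id)
  rows <- lapply(by_subj, function(d) {
    mx <- max(d$scaled_score)
    age <- min(d$age_at_assessment[d$scaled_score == mx])
    data.frame(subject_id = d$subject_id[1L], max_scaled_score = mx,
               age_at_max = age, sqrt_score = sqrt(mx),
               symptomatic = mx >= symptomatic_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-sectional disease-burden regression
#'
#' OLS of the square-root scaled NMDAS score (the square root keeps the
#' residuals near normal) on age plus one heteroplasmy measure — or, for
#' the muscle model, on age, muscle heteroplasmy and mtDNA copy number.
#' Heteroplasmy enters in percentage points and copy number in
#' copies/nucleus, so coefficients read as change in sqrt-NMDAS per 1%
#' heteroplasmy and per copy respectively.
#'
#' @param burden a [burden_points()] table.
#' @param predictors a data.frame with `subject_id` plus numeric predictor
#'   columns (e.g. `age`, `het` as a percentage, `copy_number`). Joined to
#'   `burden` by subject.
#' @param formula model formula on the joined table; default regresses
#'   `sqrt_score` on every predictor column except `subject_id`.
#' @return a list of class `"burden_fit"`: `coefficients` (estimates,
#'   95% CIs, P), `adj_r_squared`, `n`, `shapiro_p` (normality of
#'   residuals), `fit`.
#' @export
fit_burden_model <- function(burden, predictors, formula = NULL) {
  d <- merge(burden, predictors, by = "subject_id")
  pred_cols <- setdiff(names(predictors), "subject_id")
  if (is.null(formula))
    formula <- stats::reformulate(pred_cols, response = "sqrt_score")
  d <- d[complete.cases(d[all.vars(formula)]), , drop = FALSE]
  fit <- lm(formula, data = d)
  if (fit$rank < length(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- stats::confint(fit)
  shp <- if (nrow(d) >= 3 && nrow(d) <= 5000)
    stats::shapiro.test(stats::residuals(fit))$p.value else NA_real_
  structure(list(coefficients = cbind(estimate = coef(fit),
                                      lower = ci[, 1], upper = ci[, 2],
                                      p = sm$coefficients[, 4]),
                 adj_r_squared = sm$adj.r.squared, n = nrow(d),
                 shapiro_p = shp, formula = formula, fit = fit),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat(sprintf("Burden model %s (n = %d, adj R2 = %.4f):\n",
              deparse(x$formula), x$n, x$adj_r_squared))
  print(round(x$coefficients, 4))
  if (!is.na(x$shapiro_p))
    cat(sprintf("  residual normality (Shapiro-Wilk) P = %.3f\n", x$shapiro_p))
  invisible(x)
}

#' @export
coef.burden_fit <- function(object, ...) object$coefficients[, "estimate"]

# Shared result container for bootstrap model comparisons.
.comparison_result <- function(statistic, label_a, label_b, point, deltas,
                               n_replicates, n_failed) {
  ci <- unname(quantile(deltas, c(0.025, 0.975), na.rm = TRUE))
  structure(list(statistic = statistic, model_a = label_a, model_b = label_b,
                 point_estimate = point, conf_int = ci,
                 mean_delta = mean(deltas),
                 p_value = mean(deltas < 0) + 0.5 * mean(deltas == 0),
                 n_replicates = n_replicates, n_failed = n_failed,
                 deltas = deltas),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Bootstrap %s comparison: %s vs %s\n  point estimate = %.4f, mean = %.4f (95%% CI %.4f to %.4f), P = %.3f (%d replicates, %d failed)\n",
              x$statistic, x$model_a, x$model_b, x$point_estimate,
              x$mean_delta, x$conf_int[1], x$conf_int[2], x$p_value,
              x$n_replicates, x$n_failed))
  invisible(x)
}

#' Bootstrap comparison of two burden models by adjusted R-squared
#'
#' Resamples subjects (the independent unit — each contributes one burden
#' point) with replacement, refits both models on each replicate, and
#' summarises the distribution of `adj R2(a) - adj R2(b)`. The reported P
#' value is the proportion of replicates in which model A fails to beat
#' model B (differences of exactly zero counted half), i.e. the bootstrap
#' probability that the second model is at least as good as the first; a
#' small P means model A is consistently better.
#'
#' @param burden a [burden_points()] table.
#' @param predictors_a,predictors_b predictor tables for the two models
#'   (see [fit_burden_model()]); restricted to subjects present in both.
#' @param formula_a,formula_b optional model formulas.
#' @param replicates bootstrap replicate count (default 1000).
#' @param seed RNG seed.
#' @param labels character(2) descriptors for reporting.
#' @return a `"comparison_result"`: point estimate (full-sample difference),
#'   bootstrap mean, percentile 95% CI, one-sided `p_value`,
#'   `n_replicates`, `n_failed`.
#' @export
bootstrap_r2_compare <- function(burden, predictors_a, predictors_b,
                                 formula_a = NULL, formula_b = NULL,
                                 replicates = 1000L, seed = 1L,
                                 labels = c("model_a", "model_b")) {
  common <- Reduce(intersect, list(burden$subject_id,
                                   predictors_a$subject_id,
                                   predictors_b$subject_id))
  if (length(common) < 10) stop("fewer than 10 subjects shared by both models")
  burden <- burden[burden$subject_id %in% common, , drop = FALSE]
  r2_pair <- function(b) {
    fa <- fit_burden_model(b, predictors_a, formula_a)
    fb <- fit_burden_model(b, predictors_b, formula_b)
    fa$adj_r_squared - fb$adj_r_squared
  }
  point <- r2_pair(burden)
  set.seed(seed)
  deltas <- rep(NA_real_, replicates)
  for (i in seq_len(replicates)) {
    idx <- sample(nrow(burden), replace = TRUE)
    b <- burden[idx, , drop = FALSE]
    # resampled subjects must look distinct so merge() keeps duplicates
    b$subject_id_orig <- b$subject_id
    b$subject_id <- sprintf("%s.%d", b$subject_id, seq_len(nrow(b)))
    pa <- predictors_a[match(b$subject_id_orig, predictors_a$subject_id), ,
                       drop = FALSE]
    pb <- predictors_b[match(b$subject_id_orig, predictors_b$subject_id), ,
                       drop = FALSE]
    pa$subject_id <- b$subject_id; pb$subject_id <- b$subject_id
    b$subject_id_orig <- NULL
    deltas[i] <- tryCatch(
      fit_burden_model(b, pa, formula_a)$adj_r_squared -
        fit_burden_model(b, pb, formula_b)$adj_r_squared,
      error = function(e) NA_real_)
  }
  failed <- sum(is.na(deltas))
  if (failed > 0.05 * replicates)
    warning(failed, " of ", replicates, " replicates failed to fit")
  deltas <- deltas[!is.na(deltas)]
  .comparison_result("delta_r_squared", labels[1], labels[2], point, deltas,
                     replicates, failed)
}
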