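#' Configuration of the synthetic-cohort generator
#'
#' Bundles every parameter of the generative model. Defaults reproduce the
#' statistical structure of the reference m.3243A>G cohort: 242 subjects
#' (147 female), ages uniform over 19.7-79.9 years, latent mutation load
#' uniform over 0.05-0.95, blood decaying from the latent level by the
#' compound model (b = 0.977, k = 12), urine related to the latent level on
#' the logit scale with sex offsets (s = 0.791, male +0.625, female
#' -0.608), tissue copy numbers log-normal with medians/IQRs of 3523/1708
#' (muscle), 144/81 (blood) and 1181/2870 (urine), and qPCR plates with
#' 0.1-Ct well noise. Noise SDs not fixed by the reference cohort are free
#' choices kept small enough that simulated between-tissue correlations
#' stay in the observed regime.
#'
#' @param n_subjects cohort size.
#' @param female_fraction expected fraction of females.
#' @param age_range,latent_range uniform supports for age (years) and latent
#'   heteroplasmy (proportion).
#' @param decline a [decline_params()] object (blood forward model).
#' @param urine_sex a [urine_sex_params()] object (urine forward model).
#' @param blood_sd blood observation noise SD, proportion scale.
#' @param urine_logit_sd,muscle_logit_sd observation noise SDs, logit scale.
#' @param urine_linear percentage-scale urine model: list with `slope`
#'   (urine % per muscle %), `male_gap` (pp), `intercept` (pp, female
#'   baseline), `sd` (residual pp).
#' @param linear_rate continuous per-year blood decline rate used by the
#'   longitudinal trajectory generator.
#' @param cv_target within-subject dispersion for repeated-measurement
#'   cohorts, as a fraction of the population mean.
#' @param burden burden-model generating coefficients on the sqrt-NMDAS
#'   scale: `intercept`, `age` (per year), `het_pct` (per % heteroplasmy),
#'   `copy_number` (per copy/nucleus), `resid_sd`.
#' @param progression progression-model generating parameters: fixed slopes
#'   `beta_age`, `beta_int` (interaction, per unit age x proportion), random
#'   slope SDs `sd_age`, `sd_int`, residual `resid_sd`.
#' @param copy_number per-tissue log-normal medians and IQRs.
#' @param detection_threshold assay sensitivity as a proportion; simulated
#'   tissue levels below it are reported as 0, as the pyrosequencing assay
#'   (sensitivity > 3% mutant) would.
#' @param qpcr plate simulator settings: `ct_sd` (well noise),
#'   `efficiency` (amplification efficiency; the default 0.95 gives a
#'   standard-curve slope near the middle of the accepted -3.3..-3.6
#'   window, where real assays run),
#'   `nd1_intercept`, `b2m_intercept` (undiluted-standard Cts),
#'   `dilution_ratio`, `samples_per_plate`, `plate_effect_sdlog`
#'   (log-normal SD of the multiplicative inter-plate effect; 0.15 gives a
#'   control CV near the observed 17%), `control_copies`.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 242L, female_fraction = 147 / 242,
                          age_range = c(19.7, 79.9),
                          latent_range = c(0.05, 0.95),
                          decline = decline_params(),
                          urine_sex = urine_sex_params(),
                          blood_sd = 0.02, urine_logit_sd = 0.35,
                          muscle_logit_sd = 0.2,
                          urine_linear = list(slope = 0.75, male_gap = 19.2,
                                              intercept = 0, sd = 8),
                          linear_rate = 0.0185,
                          cv_target = 0.189,
                          burden = list(intercept = 3, age = 0.04,
                                        het_pct = 0.027,
                                        copy_number = -0.00055,
                                        resid_sd = 1.5),
                          progression = list(beta_age = 0.04, beta_int = 0.06,
                                             sd_age = 0.02, sd_int = 0.02,
                                             resid_sd = 0.5),
                          copy_number = list(
                            muscle = c(median = 3523, iqr = 1708),
                            blood = c(median = 144, iqr = 81),
                            urine = c(median = 1181, iqr = 2870)),
                          qpcr = list(ct_sd = 0.1, efficiency = 0.95,
                                      nd1_intercept = 18, b2m_intercept = 24,
                                      dilution_ratio = 100,
                                      samples_per_plate = 12L,
                                      plate_effect_sdlog = 0.15,
                                      control_copies = 150),
                          detection_threshold = 0.03) {
  stopifnot(n_subjects >= 2, female_fraction > 0, female_fraction < 1,
            blood_sd >= 0, urine_logit_sd >= 0, muscle_logit_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 female_fraction = female_fraction, age_range = age_range,
                 latent_range = latent_range, decline = decline,
                 urine_sex = urine_sex, blood_sd = blood_sd,
                 urine_logit_sd = urine_logit_sd,
                 muscle_logit_sd = muscle_logit_sd,
                 urine_linear = urine_linear, linear_rate = linear_rate,
                 cv_target = cv_target, burden = burden,
                 progression = progression, copy_number = copy_number,
                 qpcr = qpcr, detection_threshold = detection_threshold),
            class = "cohort_config")
}

# below-sensitivity readings are reported as undetectable (0)
.apply_detection <- function(level, threshold) ifelse(level < threshold, 0, level)

# meanlog/sdlog of a log-normal with the given median and IQR
.lognormal_from_median_iqr <- function(median, iqr) {
  median <- unname(median); iqr <- unname(iqr)
  sdlog <- asinh(iqr / (2 * median)) / qnorm(0.75)
  c(meanlog = log(median), sdlog = sdlog)
}

#' Generate the subject table
#'
#' Draws subjects with sex, age and a latent (true) heteroplasmy level.
#' The latent level is the quantity the tissue observation models distort;
#' it is what the adjustment formulas aim to recover.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return a data.frame: `subject_id`, `sex`, `age` (years), `latent`
#'   (proportion).
#' @export
generate_subjects <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             sex = ifelse(rbinom(n, 1L, config$female_fraction) == 1L,
                          "female", "male"),
             age = runif(n, config$age_range[1], config$age_range[2]),
             latent = runif(n, config$latent_range[1], config$latent_range[2]),
             stringsAsFactors = FALSE)
}

#' Generate single-visit tissue heteroplasmy measurements
#'
#' Applies the tissue observation models to a subject table, one
#' measurement per subject per tissue:
#' * muscle: `inv_logit(logit(latent) + e_m)` — an essentially unbiased,
#'   age-free readout;
#' * blood: `latent * b^(age + k) + e_b`, clamped to \[0, 1\] — the
#'   compound age decline;
#' * urine, `mode = "logit"`: `inv_logit(s * (logit(latent) + offset_sex)
#'   + e_u)` with offsets +male_offset / -female_offset, the model the
#'   published sex-adjustment formulas invert;
#' * urine, `mode = "linear"`: `urine% = intercept + slope * muscle% +
#'   male_gap * I(male) + e`, the percentage-scale description, clamped to
#'   \[0, 100\]%.
#'
#' @param subjects a [generate_subjects()] table.
#' @param config a [cohort_config()].
#' @param mode urine observation model, `"logit"` or `"linear"`.
#' @param seed RNG seed.
#' @return a long-format heteroplasmy table (`subject_id`, `sex`, `tissue`,
#'   `age_at_sample`, `level`) with one blood, urine and muscle row per
#'   subject.
#' @export
generate_tissue_measurements <- function(subjects, config = cohort_config(),
                                         mode = c("logit", "linear"),
                                         seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- nrow(subjects)
  lg_lat <- as.numeric(logit(subjects$latent))
  muscle <- inv_logit(lg_lat + rnorm(n, 0, config$muscle_logit_sd))
  blood <- pmin(pmax(
    subjects$latent * config$decline$b^(subjects$age + config$decline$k) +
      rnorm(n, 0, config$blood_sd), 0), 1)
  if (mode == "logit") {
    off <- ifelse(subjects$sex == "male",
                  +config$urine_sex$male_offset,
                  -config$urine_sex$female_offset)
    urine <- inv_logit(config$urine_sex$s * (lg_lat + off) +
                         rnorm(n, 0, config$urine_logit_sd))
  } else {
    ul <- config$urine_linear
    urine_pct <- ul$intercept + ul$slope * muscle * 100 +
      ul$male_gap * (subjects$sex == "male") + rnorm(n, 0, ul$sd)
    urine <- pmin(pmax(urine_pct, 0), 100) / 100
  }
  muscle <- .apply_detection(muscle, config$detection_threshold)
  urine <- .apply_detection(urine, config$detection_threshold)
  blood <- .apply_detection(blood, config$detection_threshold)
  out <- rbind(
    data.frame(subject_id = subjects$subject_id, sex = subjects$sex,
               tissue = "blood", age_at_sample = subjects$age,
               level = blood, stringsAsFactors = FALSE),
    data.frame(subject_id = subjects$subject_id, sex = subjects$sex,
               tissue = "urine", age_at_sample = subjects$age,
               level = urine, stringsAsFactors = FALSE),
    data.frame(subject_id = subjects$subject_id, sex = subjects$sex,
               tissue = "muscle", age_at_sample = subjects$age,
               level = muscle, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# Deterministic largest-remainder split of an integer total over 28 scored
# items (cap 5 each); respiratory item set to 0 (answered).
.decompose_items <- function(total, respiratory_item = 10L) {
  total <- as.integer(min(max(round(total), 0), 140))
  base <- total %/% 28L
  rem <- total - base * 28L
  scored <- rep(base, 28L) + c(rep(1L, rem), rep(0L, 28L - rem))
  items <- integer(29L)
  items[-respiratory_item] <- scored
  items[respiratory_item] <- 0L
  items
}

#' Generate longitudinal blood series and NMDAS trajectories
#'
#' For each subject draws a visit schedule, lets blood heteroplasmy follow
#' the compound decline between visits (plus observation noise), and
#' generates square-root NMDAS trajectories from the no-intercept
#' random-slope model
#' `sqrt(NMDAS)_ij = (beta_age + u_i) * age_ij + (beta_int + v_i) * age_ij
#' * het_i + e_ij`, truncated to the representable score range, squared,
#' and decomposed into 29 integer item scores consistent with the total
#' (respiratory item scored 0; 28 scored items cap the total at 140).
#'
#' @param subjects a [generate_subjects()] table.
#' @param config a [cohort_config()].
#' @param visits integer vector of possible visit counts per subject
#'   (sampled uniformly; default 2:5).
#' @param span_range follow-up span range in years (default 4-12).
#' @param seed RNG seed.
#' @return a list: `blood` (heteroplasmy-schema table of repeated blood
#'   measurements), `nmdas` (nmdas-schema table), `truth` (per-subject
#'   random slopes and heteroplasmy used).
#' @export
generate_longitudinal <- function(subjects, config = cohort_config(),
                                  visits = 2:5, span_range = c(4, 12),
                                  seed = 1L) {
  stopifnot(all(visits >= 1), span_range[1] >= 0)
  set.seed(seed)
  pr <- config$progression
  n <- nrow(subjects)
  u <- rnorm(n, 0, pr$sd_age)
  v <- rnorm(n, 0, pr$sd_int)
  blood_rows <- list(); nmdas_rows <- list()
  for (i in seq_len(n)) {
    nv <- if (length(visits) == 1L) visits else sample(visits, 1L)
    span <- runif(1, span_range[1], span_range[2])
    ages <- subjects$age[i] +
      if (nv == 1L) 0 else c(0, sort(runif(nv - 2L, 0, span)), span)
    blood <- .apply_detection(pmin(pmax(
      subjects$latent[i] * config$decline$b^(ages + config$decline$k) +
        rnorm(nv, 0, config$blood_sd), 0), 1), config$detection_threshold)
    blood_rows[[i]] <- data.frame(
      subject_id = subjects$subject_id[i], sex = subjects$sex[i],
      tissue = "blood", age_at_sample = ages, level = blood,
      stringsAsFactors = FALSE)
    sqrt_sc <- (pr$beta_age + u[i]) * ages +
      (pr$beta_int + v[i]) * ages * subjects$latent[i] +
      rnorm(nv, 0, pr$resid_sd)
    sqrt_sc <- pmin(pmax(sqrt_sc, 0), sqrt(140))
    items <- t(vapply(sqrt_sc^2, .decompose_items, integer(29L)))
    colnames(items) <- sprintf("item_%02d", 1:29)
    nmdas_rows[[i]] <- cbind(
      data.frame(subject_id = subjects$subject_id[i],
                 age_at_assessment = ages, stringsAsFactors = FALSE),
      as.data.frame(items))
  }
  list(blood = do.call(rbind, blood_rows),
       nmdas = do.call(rbind, nmdas_rows),
       truth = data.frame(subject_id = subjects$subject_id,
                          het = subjects$latent, u = u, v = v,
                          stringsAsFactors = FALSE))
}

#' Generate exponentially declining blood trajectories
#'
#' Longitudinal blood series for the rate-constant estimator: each
#' subject's level decays as `level0 * exp(-rate * t)` from baseline, with
#' Gaussian observation noise per measurement.
#'
#' @param n_subjects number of subjects (default 35, the multi-measurement
#'   subset followed 4+ years in the reference cohort).
#' @param config a [cohort_config()] (`linear_rate` and `blood_sd` used).
#' @param visits possible measurement counts (default 2:5).
#' @param span_range follow-up span range in years (default 4-12).
#' @param level0_range baseline level support.
#' @param seed RNG seed.
#' @return a heteroplasmy-schema table of blood measurements.
#' @export
generate_decline_trajectories <- function(n_subjects = 35L,
                                          config = cohort_config(),
                                          visits = 2:5,
                                          span_range = c(4, 12),
                                          level0_range = c(0.2, 0.9),
                                          seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    nv <- if (length(visits) == 1L) visits else sample(visits, 1L)
    span <- runif(1, span_range[1], span_range[2])
    t_rel <- if (nv == 1L) 0 else c(0, sort(runif(nv - 2L, 0, span)), span)
    age0 <- runif(1, 20, 60)
    lvl0 <- runif(1, level0_range[1], level0_range[2])
    lvl <- .apply_detection(pmin(pmax(lvl0 * exp(-config$linear_rate * t_rel) +
                                        rnorm(nv, 0, config$blood_sd), 0), 1),
                            config$detection_threshold)
    data.frame(subject_id = sprintf("D%04d", i), sex = "female",
               tissue = "blood", age_at_sample = age0 + t_rel, level = lvl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a repeated-measurement cohort for CV estimation
#'
#' Subjects with 3-6 repeated measurements of one measure; within-subject
#' values are Gaussian around the subject's mean with SD equal to
#' `cv_target` times the population mean level, so the generating mean CV
#' is `cv_target` by construction.
#'
#' @param n_subjects number of subjects (default 39, the repeated-urine
#'   subset of the reference cohort).
#' @param config a [cohort_config()] (`cv_target` used).
#' @param repeats possible repeat counts (default 3:6).
#' @param mean_range support of the per-subject mean level.
#' @param seed RNG seed.
#' @return a data.frame with `subject_id` and `level`.
#' @export
generate_cv_cohort <- function(n_subjects = 39L, config = cohort_config(),
                               repeats = 3:6, mean_range = c(0.2, 0.6),
                               seed = 1L) {
  stopifnot(all(repeats >= 3))
  set.seed(seed)
  subj_mean <- runif(n_subjects, mean_range[1], mean_range[2])
  sigma <- config$cv_target * mean(mean_range)
  rows <- lapply(seq_len(n_subjects), function(i) {
    k <- if (length(repeats) == 1L) repeats else sample(repeats, 1L)
    data.frame(subject_id = sprintf("C%04d", i),
               level = rnorm(k, subj_mean[i], sigma),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a muscle burden-model cohort
#'
#' Cross-sectional cohort for the muscle disease-burden regression:
#' subjects with age, muscle heteroplasmy, log-normal muscle copy number,
#' and a square-root NMDAS outcome generated as
#' `intercept + age_coef * age + het_coef * het% + cn_coef * copies + e`,
#' truncated to the representable score range.
#'
#' @param n_subjects cohort size (default 66, the muscle copy-number subset
#'   of the reference cohort).
#' @param config a [cohort_config()] (`burden` and `copy_number$muscle`).
#' @param seed RNG seed.
#' @return a list: `burden` (a [burden_points()]-shaped table) and
#'   `predictors` (`subject_id`, `age`, `het_pct`, `copy_number`).
#' @export
generate_burden_cohort <- function(n_subjects = 66L,
                                   config = cohort_config(), seed = 1L) {
  set.seed(seed)
  bd <- config$burden
  ln <- .lognormal_from_median_iqr(config$copy_number$muscle["median"],
                                   config$copy_number$muscle["iqr"])
  age <- runif(n_subjects, 19.7, 79.9)
  het_pct <- runif(n_subjects, 5, 95)
  cn <- rlnorm(n_subjects, ln["meanlog"], ln["sdlog"])
  sqrt_sc <- bd$intercept + bd$age * age + bd$het_pct * het_pct +
    bd$copy_number * cn + rnorm(n_subjects, 0, bd$resid_sd)
  sqrt_sc <- pmin(pmax(sqrt_sc, 0), sqrt(145))
  ids <- sprintf("B%04d", seq_len(n_subjects))
  list(burden = data.frame(subject_id = ids,
                           max_scaled_score = sqrt_sc^2, age_at_max = age,
                           sqrt_score = sqrt_sc,
                           symptomatic = sqrt_sc^2 >= 5,
                           stringsAsFactors = FALSE),
       predictors = data.frame(subject_id = ids, age = age,
                               het_pct = het_pct, copy_number = cn,
                               stringsAsFactors = FALSE))
}

#' Generate plate-structured qPCR data
#'
#' Simulates 96-well-style plates for given true copies/nucleus: per plate
#' a six-point ten-fold plasmid dilution series per target (triplicate), a
#' shared control sample, and the study samples, all with Gaussian Ct noise.
#' Inter-plate variation is injected as a log-normal multiplicative effect
#' on the ND1-derived quantity of sample and control wells (standards carry
#' nominal quantities, so the effect propagates into copy numbers and is
#' what the control-based standardisation must remove). Ct values follow
#' `intercept + slope * log10(quantity)` with
#' `slope = -1/log10(1 + efficiency)`.
#'
#' @param copy_numbers data.frame with `sample_id` and `copies` (> 0).
#' @param config a [cohort_config()] (`qpcr` settings used).
#' @param seed RNG seed.
#' @return a list: `qpcr` (qpcr-schema table), `truth` (per-sample true
#'   copies and plate), `plate_effects` (per-plate multiplier).
#' @export
generate_qpcr_plates <- function(copy_numbers, config = cohort_config(),
                                 seed = 1L) {
  stopifnot(nrow(copy_numbers) >= 1, all(copy_numbers$copies > 0))
  set.seed(seed)
  qp <- config$qpcr
  slope <- -1 / log10(1 + qp$efficiency)
  n_plates <- ceiling(nrow(copy_numbers) / qp$samples_per_plate)
  plate_of <- rep(seq_len(n_plates),
                  each = qp$samples_per_plate)[seq_len(nrow(copy_numbers))]
  eff_p <- rlnorm(n_plates, 0, qp$plate_effect_sdlog)
  ct_noise <- function(k) rnorm(k, 0, qp$ct_sd)
  well <- function(plate, sid, role, target, step, q) {
    ic <- if (target == "ND1") qp$nd1_intercept else qp$b2m_intercept
    ct <- ic + slope * log10(q) + ct_noise(3L)
    data.frame(plate_id = sprintf("P%02d", plate), sample_id = sid,
               role = role, target = target, dilution_step = step,
               ct_rep1 = ct[1], ct_rep2 = ct[2], ct_rep3 = ct[3],
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (p in seq_len(n_plates)) {
    for (tg in c("ND1", "B2M")) for (step in 0:5)
      rows[[length(rows) + 1L]] <- well(p, sprintf("STD%d", step),
                                        "standard", tg, step, 10^(-step))
    ids <- c(copy_numbers$sample_id[plate_of == p], "CTRL")
    copies <- c(copy_numbers$copies[plate_of == p], qp$control_copies)
    roles <- c(rep("sample", length(ids) - 1L), "control")
    for (j in seq_along(ids)) {
      # per-sample DNA input (cancels in the target ratio); scaled so both
      # targets fall inside the standard curve's range rather than above it
      amount <- 0.05 * rlnorm(1, 0, 0.1)
      q_b2m <- amount
      q_nd1 <- copies[j] * q_b2m / (2 * qp$dilution_ratio) * eff_p[p]
      rows[[length(rows) + 1L]] <- well(p, ids[j], roles[j], "ND1", NA, q_nd1)
      rows[[length(rows) + 1L]] <- well(p, ids[j], roles[j], "B2M", NA, q_b2m)
    }
  }
  qpcr <- do.call(rbind, rows)
  rownames(qpcr) <- NULL
  list(qpcr = qpcr,
       truth = data.frame(sample_id = copy_numbers$sample_id,
                          copies = copy_numbers$copies,
                          plate_id = sprintf("P%02d", plate_of),
                          stringsAsFactors = FALSE),
       plate_effects = data.frame(plate_id = sprintf("P%02d", seq_len(n_plates)),
                                  effect = eff_p, stringsAsFactors = FALSE))
}

#' Simulate a full synthetic cohort
#'
#' One call producing every input the pipeline consumes — subjects,
#' single-visit tissue measurements, longitudinal blood/NMDAS series for a
#' subset, tissue copy numbers and plate-structured qPCR data — with the
#' generating ground truth alongside. Optionally writes the three
#' pipeline CSVs plus a ground-truth CSV to a directory.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; sub-generators use fixed offsets from it.
#' @param dir optional output directory for `heteroplasmy.csv`,
#'   `nmdas.csv`, `qpcr.csv`, `ground_truth.csv`.
#' @param n_longitudinal number of subjects given longitudinal follow-up.
#' @return a list: `subjects`, `heteroplasmy` (single-visit + longitudinal
#'   blood rows), `nmdas`, `qpcr`, `copy_truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L, dir = NULL,
                            n_longitudinal = 96L) {
  subjects <- generate_subjects(config, seed)
  tissue <- generate_tissue_measurements(subjects, config, "logit", seed + 1L)
  idx <- seq_len(min(n_longitudinal, nrow(subjects)))
  longi <- generate_longitudinal(subjects[idx, ], config, seed = seed + 2L)
  ln_b <- .lognormal_from_median_iqr(config$copy_number$blood["median"],
                                     config$copy_number$blood["iqr"])
  set.seed(seed + 3L)
  cn <- data.frame(sample_id = subjects$subject_id,
                   copies = rlnorm(nrow(subjects), ln_b["meanlog"],
                                   ln_b["sdlog"]),
                   stringsAsFactors = FALSE)
  plates <- generate_qpcr_plates(cn, config, seed + 4L)
  het <- rbind(tissue, longi$blood)
  het <- het[!duplicated(paste(het$subject_id, het$tissue,
                               het$age_at_sample)), ]
  rownames(het) <- NULL
  out <- list(subjects = subjects, heteroplasmy = het, nmdas = longi$nmdas,
              qpcr = plates$qpcr, copy_truth = plates$truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_measurements(het, file.path(dir, "heteroplasmy.csv"), "heteroplasmy")
    write.csv(longi$nmdas, file.path(dir, "nmdas.csv"), row.names = FALSE)
    write.csv(plates$qpcr, file.path(dir, "qpcr.csv"), row.names = FALSE)
    write.csv(merge(subjects, plates$truth,
                    by.x = "subject_id", by.y = "sample_id", all.x = TRUE),
              file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  out
}
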