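#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Ct on log10 relative template quantity
#' over a ten-fold dilution series (six points in the reference protocol).
#' A curve passes QC if R2 > 0.999 and the gradient lies in [-3.6, -3.3]
#' (100% amplification efficiency gives exactly -1/log10(2) = -3.3219 Ct
#' per ten-fold dilution).
#'
#' @param dilution_step integer dilution index per point (0 = undiluted,
#'   each step a further ten-fold dilution), or a vector of log10 relative
#'   quantities via `log10_quantity`.
#' @param ct matrix or data.frame of replicate Cts (rows = dilution points),
#'   or a vector of mean Cts.
#' @param target label (`"ND1"` or `"B2M"`).
#' @param log10_quantity optional explicit log10 relative quantities;
#'   default `-dilution_step`.
#' @return a list of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`, `qc_pass`, `target`, `n_points`.
#' @export
fit_standard_curve <- function(dilution_step, ct, target = "ND1",
                               log10_quantity = NULL) {
  mean_ct <- if (is.matrix(ct) || is.data.frame(ct))
    rowMeans(as.matrix(ct), na.rm = TRUE) else as.numeric(ct)
  lq <- if (is.null(log10_quantity)) -as.numeric(dilution_step) else log10_quantity
  ok <- complete.cases(lq, mean_ct)
  lq <- lq[ok]; mean_ct <- mean_ct[ok]
  if (length(lq) < 4) stop("standard curve needs >= 4 usable dilution points")
  fit <- lm(mean_ct ~ lq)
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2L])
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 qc_pass = r2 > 0.999 && slope >= -3.6 && slope <= -3.3,
                 target = target, n_points = length(lq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve [%s]: slope = %.4f Ct/log10, intercept = %.2f, R2 = %.5f, QC %s (%d points)\n",
              x$target, x$slope, x$intercept, x$r_squared,
              if (x$qc_pass) "pass" else "FAIL", x$n_points))
  invisible(x)
}

#' Quantify one sample from Ct triplicates and a standard curve
#'
#' Removes within-sample outlier wells (|Ct - median| > 0.5 by default),
#' averages the surviving Cts and reads the relative quantity off the
#' standard curve: `quantity = 10^((mean_ct - intercept)/slope)`. A sample
#' passes QC if, after outlier removal, at least two wells survive, the Ct
#' SD is <= 0.3 and the mean Ct is <= 33.
#'
#' @param cts numeric vector of replicate Cts (typically 3).
#' @param curve a [fit_standard_curve()] result; must itself pass QC.
#' @param sample_id label carried into the result.
#' @param outlier_ct maximum |Ct - median| for a well to be kept.
#' @param max_sd,max_ct QC limits on the surviving replicates.
#' @return a list of class `"sample_quant"`: `sample_id`, `target`,
#'   `mean_ct`, `ct_sd`, `quantity` (arbitrary units, NA on QC failure),
#'   `qc_pass`, `qc_reason`, `outliers_removed`.
#' @export
quantify_sample <- function(cts, curve, sample_id = "sample",
                            outlier_ct = 0.5, max_sd = 0.3, max_ct = 33) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$qc_pass) stop("standard curve failed QC; sample cannot be quantified")
  cts <- cts[!is.na(cts)]
  keep <- abs(cts - median(cts)) <= outlier_ct
  removed <- sum(!keep)
  cts_kept <- cts[keep]
  fail <- function(reason) structure(
    list(sample_id = sample_id, target = curve$target, mean_ct = NA_real_,
         ct_sd = NA_real_, quantity = NA_real_, qc_pass = FALSE,
         qc_reason = reason, outliers_removed = removed),
    class = "sample_quant")
  if (length(cts_kept) < 2) return(fail("fewer than 2 wells after outlier removal"))
  m <- mean(cts_kept); s <- sd(cts_kept)
  if (s > max_sd) return(fail(sprintf("Ct SD %.3f > %.1f", s, max_sd)))
  if (m > max_ct) return(fail(sprintf("mean Ct %.2f > %g", m, max_ct)))
  structure(list(sample_id = sample_id, target = curve$target, mean_ct = m,
                 ct_sd = s,
                 quantity = 10^((m - curve$intercept) / curve$slope),
                 qc_pass = TRUE, qc_reason = "ok",
                 outliers_removed = removed),
            class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("Sample %s [%s]: mean Ct = %s, SD = %s, quantity = %s, QC %s (%d outlier(s) removed; %s)\n",
              x$sample_id, x$target, format(round(x$mean_ct, 3)),
              format(round(x$ct_sd, 3)), format(signif(x$quantity, 4)),
              if (x$qc_pass) "pass" else "FAIL", x$outliers_removed, x$qc_reason))
  invisible(x)
}

#' mtDNA copies per nucleus from paired target quantifications
#'
#' Combines the mitochondrial (ND1) and nuclear (B2M) quantifications:
#' `copies/nucleus = 2 * (nd1_quantity * dilution_ratio) / b2m_quantity`.
#' The factor 2 reflects the two B2M copies per diploid nucleus; the
#' dilution ratio compensates for the different working concentrations of
#' the two assays (~10 ng/ul for B2M vs ~0.1 ng/ul for ND1, i.e. 100 by
#' default).
#'
#' @param nd1,b2m [quantify_sample()] results for the two targets.
#' @param dilution_ratio B2M-to-ND1 DNA concentration ratio (default 100).
#' @return copies per nucleus (numeric), or `NA` with a message if either
#'   target failed QC.
#' @export
copies_per_nucleus <- function(nd1, b2m, dilution_ratio = 100) {
  stopifnot(inherits(nd1, "sample_quant"), inherits(b2m, "sample_quant"))
  if (!nd1$qc_pass || !b2m$qc_pass) {
    message("sample ", nd1$sample_id, ": target QC failure (",
            if (!nd1$qc_pass) nd1$qc_reason else b2m$qc_reason,
            "); no copy number")
    return(NA_real_)
  }
  2 * (nd1$quantity * dilution_ratio) / b2m$quantity
}

#' Standardise copy numbers for inter-plate variation
#'
#' Scales every copy number on a plate by the ratio of the control sample's
#' grand-mean copy number to its on-plate value:
#' `standardised = raw / control_on_plate * control_grand_mean`. A shared
#' control DNA run on every plate thereby cancels multiplicative plate
#' effects exactly.
#'
#' @param copy_numbers raw copies/nucleus for the plate's samples.
#' @param control_on_plate the control sample's raw value on this plate
#'   (vectorised: may be given per element of `copy_numbers` to
#'   standardise values from several plates at once).
#' @param control_grand_mean the control's mean over all plates.
#' @return standardised copies/nucleus.
#' @export
standardize_plate <- function(copy_numbers, control_on_plate,
                              control_grand_mean) {
  if (any(is.na(control_on_plate) | control_on_plate <= 0))
    stop("plate control missing or failed QC; plate must be excluded")
  copy_numbers / control_on_plate * control_grand_mean
}

#' Process a plate-structured qPCR table into standardised copy numbers
#'
#' Full pipeline over a long-format qPCR table ([read_measurements()]
#' schema `"qpcr"`): per plate and target, fits the standard curve from the
#' `standard` rows, quantifies `sample` and `control` rows, combines ND1
#' and B2M into raw copies/nucleus, then standardises across plates using
#' the shared control. Plates whose curve or control fails QC are excluded
#' and reported.
#'
#' @param qpcr a validated qPCR table.
#' @param dilution_ratio see [copies_per_nucleus()].
#' @return a list of class `"copynumber_table"`: `samples` (data.frame with
#'   `plate_id`, `sample_id`, `raw_copies_per_nucleus`,
#'   `standardized_copies_per_nucleus`, `qc_pass`), `curves` (per
#'   plate/target QC), `control_grand_mean`, `excluded_plates`.
#' @export
process_qpcr_plates <- function(qpcr, dilution_ratio = 100) {
  plates <- split(qpcr, qpcr$plate_id)
  curve_rows <- list(); plate_quants <- list(); excluded <- character()
  for (pid in names(plates)) {
    p <- plates[[pid]]
    curves <- list()
    for (tg in c("ND1", "B2M")) {
      std <- p[p$role == "standard" & p$target == tg, , drop = FALSE]
      curves[[tg]] <- tryCatch(
        fit_standard_curve(std$dilution_step,
                           std[c("ct_rep1", "ct_rep2", "ct_rep3")],
                           target = tg),
        error = function(e) NULL)
      if (!is.null(curves[[tg]]))
        curve_rows[[paste(pid, tg)]] <- data.frame(
          plate_id = pid, target = tg, slope = curves[[tg]]$slope,
          intercept = curves[[tg]]$intercept,
          r_squared = curves[[tg]]$r_squared,
          qc_pass = curves[[tg]]$qc_pass, stringsAsFactors = FALSE)
    }
    if (is.null(curves$ND1) || is.null(curves$B2M) ||
        !curves$ND1$qc_pass || !curves$B2M$qc_pass) {
      excluded <- c(excluded, pid)
      message("plate ", pid, " excluded: standard curve missing or failed QC")
      next
    }
    quant_one <- function(sid, role) {
      per_target <- lapply(c("ND1", "B2M"), function(tg) {
        w <- p[p$role == role & p$sample_id == sid & p$target == tg, ,
               drop = FALSE]
        if (!nrow(w)) return(NULL)
        quantify_sample(as.numeric(w[1L, c("ct_rep1", "ct_rep2", "ct_rep3")]),
                        curves[[tg]], sample_id = sid)
      })
      if (any(vapply(per_target, is.null, TRUE))) return(NA_real_)
      suppressMessages(copies_per_nucleus(per_target[[1L]], per_target[[2L]],
                                          dilution_ratio))
    }
    ctrl_ids <- unique(p$sample_id[p$role == "control"])
    ctrl_cn <- if (length(ctrl_ids)) quant_one(ctrl_ids[1L], "control") else NA_real_
    samp_ids <- unique(p$sample_id[p$role == "sample"])
    cn <- vapply(samp_ids, quant_one, 0, role = "sample")
    plate_quants[[pid]] <- list(plate_id = pid, control = ctrl_cn,
                                samples = data.frame(
                                  plate_id = pid, sample_id = samp_ids,
                                  raw_copies_per_nucleus = unname(cn),
                                  stringsAsFactors = FALSE))
  }
  if (!length(plate_quants)) stop("no plate passed QC")
  ctrls <- vapply(plate_quants, function(q) q$control, 0)
  usable <- !is.na(ctrls) & ctrls > 0
  if (!any(usable)) stop("no plate has a QC-passing control sample")
  grand_mean <- mean(ctrls[usable])
  rows <- lapply(plate_quants, function(q) {
    s <- q$samples
    if (is.na(q$control) || q$control <= 0) {
      message("plate ", q$plate_id, " excluded from standardisation: control failed QC")
      excluded <<- c(excluded, q$plate_id)
      return(NULL)
    }
    s$standardized_copies_per_nucleus <-
      standardize_plate(s$raw_copies_per_nucleus, q$control, grand_mean)
    s$qc_pass <- !is.na(s$raw_copies_per_nucleus)
    s
  })
  samples <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(samples) <- NULL
  structure(list(samples = samples,
                 curves = do.call(rbind, c(curve_rows,
                                           list(make.row.names = FALSE))),
                 control_grand_mean = grand_mean,
                 excluded_plates = unique(excluded)),
            class = "copynumber_table")
}

#' @export
print.copynumber_table <- function(x, ...) {
  cat(sprintf("qPCR copy-number table: %d sample(s) on %d plate(s), control grand mean = %.1f copies/nucleus\n",
              nrow(x$samples), length(unique(x$samples$plate_id)),
              x$control_grand_mean))
  if (length(x$excluded_plates))
    cat("  excluded plates:", paste(x$excluded_plates, collapse = ", "), "\n")
  invisible(x)
}

#' Per-tissue association of copy number with heteroplasmy, age and sex
#'
#' Ordinary linear regression of copy number on heteroplasmy level, age and
#' (for urine, where males run higher) sex, fit separately per tissue —
#' e.g. the weak positive correlation of blood copy number with
#' heteroplasmy, or the male excess in urine copy number.
#'
#' @param copy_number copies/nucleus per subject.
#' @param heteroplasmy matched heteroplasmy proportions.
#' @param age matched ages (years).
#' @param sex matched `"male"`/`"female"`, or `NULL` to omit the sex term.
#' @return a list of class `"copynumber_assoc"`: `coefficients` (matrix with
#'   estimates, 95% CIs, P), `r_squared` (adjusted), `n`, `fit`.
#' @export
copynumber_associations <- function(copy_number, heteroplasmy, age,
                                    sex = NULL) {
  d <- data.frame(cn = copy_number, het = heteroplasmy * 100, age = age)
  form <- cn ~ het + age
  if (!is.null(sex)) {
    d$male <- as.integer(as.character(sex) == "male")
    form <- cn ~ het + age + male
  }
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    warning("fewer than 10 complete observations; estimates will be unstable")
  fit <- lm(form, data = d)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  structure(list(coefficients = cbind(estimate = coef(fit),
                                      lower = ci[, 1], upper = ci[, 2],
                                      p = sm$coefficients[, 4]),
                 r_squared = sm$adj.r.squared, n = nrow(d), fit = fit),
            class = "copynumber_assoc")
}

#' @export
print.copynumber_assoc <- function(x, ...) {
  cat(sprintf("Copy-number association model (n = %d, adj R2 = %.3f):\n",
              x$n, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}
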