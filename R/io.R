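#' Run configuration
#'
#' A flat list of the knobs shared across pipeline stages. Every stochastic
#' routine in the package takes a seed derived from here (or passed
#' explicitly) so whole runs are reproducible.
#'
#' @param seed integer seed for all stochastic operations.
#' @param bootstrap_replicates bootstrap replicate count (default 1000).
#' @param detection_threshold assay sensitivity as a proportion; levels
#'   below it are flagged `below_detection` (default 0.03).
#' @param logit_clamp_epsilon clamp width used before logit transforms.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, bootstrap_replicates = 1000L,
                       detection_threshold = 0.03,
                       logit_clamp_epsilon = 0.005) {
  stopifnot(bootstrap_replicates >= 1,
            logit_clamp_epsilon > 0, logit_clamp_epsilon < 0.5,
            detection_threshold >= 0, detection_threshold < 1)
  structure(list(seed = as.integer(seed),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 detection_threshold = detection_threshold,
                 logit_clamp_epsilon = logit_clamp_epsilon),
            class = "run_config")
}

# Required columns per schema. nmdas additionally requires item_01..item_29.
.schema_columns <- list(
  heteroplasmy = c("subject_id", "sex", "tissue", "age_at_sample", "level"),
  nmdas = c("subject_id", "age_at_assessment"),
  qpcr = c("plate_id", "sample_id", "role", "target", "dilution_step",
           "ct_rep1", "ct_rep2", "ct_rep3")
)

#' Read and validate a pipeline CSV
#'
#' Reads one of the three long-format input tables (heteroplasmy
#' measurements, NMDAS assessments, qPCR wells), validates it against the
#' schema, and normalises units. Heteroplasmy levels may be given either as
#' proportions (all values <= 1) or percentages (values > 1 present);
#' percentage input is detected, divided by 100, and the choice reported. A
#' column mixing the two scales (some values > 1 alongside fractional
#' values in (0, 1)) is rejected: the caller must supply a single scale.
#'
#' @param path path to a CSV file with a header row.
#' @param schema one of `"heteroplasmy"`, `"nmdas"`, `"qpcr"`.
#' @param detection_threshold proportion below which a heteroplasmy level is
#'   flagged `below_detection`.
#' @return a validated data.frame. Heteroplasmy tables gain a
#'   `below_detection` flag and carry levels as proportions.
#' @export
read_measurements <- function(path, schema = c("heteroplasmy", "nmdas", "qpcr"),
                              detection_threshold = 0.03) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- .schema_columns[[schema]]
  if (schema == "nmdas")
    required <- c(required, sprintf("item_%02d", 1:29))
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("schema error [", schema, "]: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  switch(schema,
         heteroplasmy = .validate_heteroplasmy(d, detection_threshold),
         nmdas = .validate_nmdas(d),
         qpcr = .validate_qpcr(d))
}

.validate_heteroplasmy <- function(d, detection_threshold) {
  bad_tissue <- which(!d$tissue %in% c("blood", "urine", "muscle"))
  if (length(bad_tissue))
    stop("validation error: unknown tissue at row(s) ",
         paste(head(bad_tissue, 5), collapse = ", "))
  bad_sex <- which(!d$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop("validation error: sex must be male/female at row(s) ",
         paste(head(bad_sex, 5), collapse = ", "))
  if (any(d$age_at_sample < 0, na.rm = TRUE))
    stop("validation error: negative age_at_sample at row(s) ",
         paste(head(which(d$age_at_sample < 0), 5), collapse = ", "))
  lv <- d$level
  bad <- which(is.na(lv) | lv < 0 | lv > 100)
  if (length(bad))
    stop("validation error: level outside [0, 100] (or missing) at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (any(lv > 1)) {
    if (any(lv > 0 & lv < 1))
      stop("level column mixes percentages (> 1) with proportions in (0, 1); ",
           "supply a single scale")
    message("levels > 1 detected: interpreting the level column as percent ",
            "and dividing by 100")
    d$level <- lv / 100
  }
  d$below_detection <- d$level < detection_threshold
  d
}

.validate_nmdas <- function(d) {
  items <- as.matrix(d[sprintf("item_%02d", 1:29)])
  bad <- which(apply(items, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) && (any(r < 0) || any(r > 5) || any(r != round(r)))
  }))
  if (length(bad))
    stop("validation error: item scores must be integers 0-5 at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (any(d$age_at_assessment < 0, na.rm = TRUE))
    stop("validation error: negative age_at_assessment")
  d
}

.validate_qpcr <- function(d) {
  if (!all(d$role %in% c("sample", "standard", "control")))
    stop("validation error: role must be sample/standard/control")
  if (!all(d$target %in% c("ND1", "B2M")))
    stop("validation error: target must be ND1 or B2M")
  cts <- as.matrix(d[c("ct_rep1", "ct_rep2", "ct_rep3")])
  if (any(cts <= 0 | cts > 45, na.rm = TRUE))
    stop("validation error: Ct values must lie in (0, 45]")
  d
}

#' Write a pipeline table back to CSV
#'
#' Inverse of [read_measurements()]: heteroplasmy levels are written as
#' percentages (the reporting convention), everything else verbatim, so a
#' read/write/read round trip is lossless.
#'
#' @param d a table as returned by [read_measurements()].
#' @param path output path.
#' @param schema the schema `d` conforms to.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(d, path,
                               schema = c("heteroplasmy", "nmdas", "qpcr")) {
  schema <- match.arg(schema)
  out <- d
  if (schema == "heteroplasmy") {
    out$level <- out$level * 100
    out$below_detection <- NULL
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude post-renal-transplant urine measurements
#'
#' Renal transplantation replaces the urinary epithelium sampled in urinary
#' sediment, so urine heteroplasmy measured after a transplant no longer
#' reflects the recipient's mutation load (post-transplant urine levels
#' collapse). Urine measurements taken at or after the subject's transplant
#' age are removed; all other rows are retained. The operation is
#' idempotent.
#'
#' @param measurements a heteroplasmy table ([read_measurements()]).
#' @param subjects a data.frame with `subject_id` and (optionally)
#'   `renal_transplant_age` in years (`NA` = no transplant). Subjects absent
#'   from this table cause an error.
#' @return the filtered table, with an `exclusions` attribute: a data.frame
#'   of removed rows and the reason.
#' @export
apply_exclusions <- function(measurements, subjects) {
  stopifnot("subject_id" %in% names(subjects))
  orphan <- setdiff(unique(measurements$subject_id), subjects$subject_id)
  if (length(orphan))
    stop("measurements reference unknown subject_id(s): ",
         paste(head(orphan, 10), collapse = ", "))
  if (!"renal_transplant_age" %in% names(subjects)) {
    attr(measurements, "exclusions") <-
      data.frame(row = integer(), subject_id = character(),
                 reason = character(), stringsAsFactors = FALSE)
    return(measurements)
  }
  tx <- setNames(subjects$renal_transplant_age, subjects$subject_id)
  tx_age <- unname(tx[measurements$subject_id])
  drop <- measurements$tissue == "urine" & !is.na(tx_age) &
    measurements$age_at_sample >= tx_age
  excl <- data.frame(row = which(drop),
                     subject_id = measurements$subject_id[drop],
                     reason = rep("urine measurement at or after renal transplant",
                                  sum(drop)),
                     stringsAsFactors = FALSE)
  if (nrow(excl))
    message("excluded ", nrow(excl), " post-transplant urine measurement(s)")
  out <- measurements[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}
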