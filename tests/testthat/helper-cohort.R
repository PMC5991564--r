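# Shared fixtures built in code.

quiet <- function(expr) suppressMessages(expr)

# A tiny valid heteroplasmy CSV on disk; returns the path.
write_het_fixture <- function(levels = c(45, 60, 12),
                              tissues = c("blood", "urine", "muscle"),
                              path = tempfile(fileext = ".csv")) {
  d <- data.frame(subject_id = c("S1", "S1", "S2"),
                  sex = c("female", "female", "male"),
                  tissue = tissues,
                  age_at_sample = c(30, 30, 45),
                  level = levels)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

# Noise-free cohort config used by round-trip checks.
noiseless_config <- function(...) {
  cohort_config(blood_sd = 0, urine_logit_sd = 0, muscle_logit_sd = 0,
                detection_threshold = 0, ...)
}

# Scaled NMDAS table + per-subject heteroplasmy from the longitudinal
# generator, small enough for mixed-model tests.
make_progression_data <- function(n = 60, visits = 2:4, seed = 1,
                                  config = cohort_config(n_subjects = n)) {
  s <- generate_subjects(config, seed)
  g <- generate_longitudinal(s, config, visits = visits, seed = seed + 1000)
  list(scaled = quiet(scale_nmdas_table(g$nmdas)),
       het = data.frame(subject_id = s$subject_id, het = s$latent),
       subjects = s, truth = g$truth)
}
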