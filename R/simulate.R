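#' Simulate a synthetic multi-rater screening cohort
#'
#' Generates `n_patients` patients with two eyes each. Per eye, a latent
#' true vertical CDR is drawn from a truncated bivariate normal (eyes
#' correlated within patient); three expert annotators, the AI tool and a
#' first-year resident observe it through calibrated noise models; the
#' ground-truth CDR is the mean of the three experts where all are present.
#' Gradability is drawn per patient (nested by default: AI-gradable implies
#' expert-gradable implies resident-assessed), and estimates are missing
#' exactly where the corresponding gradability flag is `FALSE`. Patients
#' additionally carry age, cataract-related symptoms, a true retinal-disease
#' risk tier and binary disease calls by AI and resident drawn at the
#' configured per-tier operating points.
#'
#' Each field group consumes its own RNG substream spawned from the master
#' seed, so identical `(config, seed)` yield bit-identical cohorts and
#' adding a field group never perturbs existing draws.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synopht_cohort`: a list with tibbles `eyes`
#'   (one row per eye) and `patients` (one row per patient), plus the
#'   generating `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' dplyr::count(cohort$patients, disease_tier_true)
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  simulate_cohort_impl(config, tier_mode = "sample")
}

#' Simulate a cohort with a tier-structured retinal-disease panel
#'
#' Like [simulate_cohort()], but the retinal-disease risk tiers can be
#' assigned deterministically: each tier receives its expected count
#' (largest-remainder apportionment of `n_patients * prevalence`), so at the
#' default prevalences and `n_patients = 395` the cohort carries exactly
#' 239 / 75 / 40 / 41 patients in tiers none / mild / medium / high —
#' the integer structure of the published retinal-disease panel. Rater
#' disease calls are still drawn at the configured per-tier operating
#' points.
#'
#' @inheritParams simulate_cohort
#' @param deterministic If `TRUE` (default), tier counts are exact expected
#'   counts; if `FALSE`, tiers are sampled as in [simulate_cohort()].
#' @return A `synopht_cohort`.
#' @export
simulate_tiered_cohort <- function(config, deterministic = TRUE) {
  config <- validate_sim_config(config)
  simulate_cohort_impl(config,
                       tier_mode = if (deterministic) "expected" else "sample")
}

# sub-seeds are spawned by position so that appending a field group leaves
# the streams of existing groups untouched
rng_substreams <- function(seed, n = 12L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed)
  expr
}

# correlated truncated-normal pairs by joint rejection; the truncation mass
# at the defaults is ~0.2%, so the loop converges in one or two passes
rtrunc_pair <- function(n, mean, sd, rho, lo, hi) {
  t1 <- numeric(n)
  t2 <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    zp <- stats::rnorm(m)
    e1 <- stats::rnorm(m)
    e2 <- stats::rnorm(m)
    a <- mean + sd * (sqrt(rho) * zp + sqrt(1 - rho) * e1)
    b <- mean + sd * (sqrt(rho) * zp + sqrt(1 - rho) * e2)
    ok <- a >= lo & a <= hi & b >= lo & b <= hi
    t1[todo[ok]] <- a[ok]
    t2[todo[ok]] <- b[ok]
    todo <- todo[!ok]
  }
  list(t1 = t1, t2 = t2)
}

rtrunc_scalar <- function(n, mean, sd, lo, hi) {
  x <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    y <- stats::rnorm(length(todo), mean, sd)
    ok <- y >= lo & y <= hi
    x[todo[ok]] <- y[ok]
    todo <- todo[!ok]
  }
  x
}

largest_remainder_counts <- function(n, probs) {
  exact <- n * probs
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

tier_levels <- c("none", "mild", "medium", "high")

simulate_cohort_impl <- function(config, tier_mode) {
  n <- as.integer(config$n_patients)
  streams <- rng_substreams(config$seed, 12L)
  pid <- sprintf("P%05d", seq_len(n))
  n_eyes <- 2L * n

  # --- eyes -----------------------------------------------------------
  tr <- with_stream(streams[1], rtrunc_pair(
    n, config$cdr_mean, config$cdr_sd, config$eye_correlation,
    config$cdr_bounds[1], config$cdr_bounds[2]
  ))
  cdr_true <- as.vector(rbind(tr$t1, tr$t2))  # right, left per patient

  expert_noise <- with_stream(streams[2], matrix(
    stats::rnorm(n_eyes * 3, 0, rep(config$expert_noise_sd, each = n_eyes)),
    nrow = n_eyes, ncol = 3
  ))
  experts <- clip01(cdr_true + expert_noise)

  ai_eta <- with_stream(streams[3], stats::rnorm(n_eyes, 0, config$ai_noise_sd))
  cdr_ai_all <- clip01(cdr_true + config$ai_bias + ai_eta)
  ai_extra <- with_stream(streams[4],
                          stats::rnorm(n_eyes, 0, config$ungradable_extra_sd))

  res_xi <- with_stream(streams[5], stats::rnorm(n_eyes, 0, config$resident_noise_sd))
  cdr_resident_all <- clip01(
    config$resident_center +
      config$resident_slope * (cdr_true - config$resident_center) +
      config$resident_bias + res_xi
  )

  gr <- config$gradability_rates
  if (isTRUE(config$nested_gradability)) {
    u <- with_stream(streams[6], stats::runif(n))
    g_ai <- u < gr[["ai"]]
    g_expert <- u < gr[["expert"]]
    g_resident <- u < gr[["resident"]]
  } else {
    um <- with_stream(streams[6], matrix(stats::runif(3L * n), ncol = 3))
    g_ai <- um[, 1] < gr[["ai"]]
    g_expert <- um[, 2] < gr[["expert"]]
    g_resident <- um[, 3] < gr[["resident"]]
  }
  eg_ai <- rep(g_ai, each = 2L)
  eg_expert <- rep(g_expert, each = 2L)
  eg_resident <- rep(g_resident, each = 2L)

  # ungated AI estimate: identical draw where gradable, degraded otherwise
  cdr_ai_nogate <- ifelse(eg_ai, cdr_ai_all,
                          clip01(cdr_ai_all + ai_extra))

  experts[!eg_expert, ] <- NA_real_
  cdr_gt <- ifelse(eg_expert, rowMeans(experts), NA_real_)
  cdr_ai <- ifelse(eg_ai, cdr_ai_all, NA_real_)
  cdr_resident <- ifelse(eg_resident, cdr_resident_all, NA_real_)

  eyes <- tibble::tibble(
    patient_id = rep(pid, each = 2L),
    side = rep(c("right", "left"), times = n),
    cdr_true = cdr_true,
    cdr_expert_1 = experts[, 1],
    cdr_expert_2 = experts[, 2],
    cdr_expert_3 = experts[, 3],
    cdr_gt = cdr_gt,
    cdr_ai = cdr_ai,
    cdr_resident = cdr_resident,
    gradable_ai = eg_ai,
    gradable_expert = eg_expert,
    gradable_resident = eg_resident,
    cdr_ai_nogate = cdr_ai_nogate
  )

  # --- patients -------------------------------------------------------
  pv <- config$disease_prevalence[tier_levels]
  tier <- if (tier_mode == "expected") {
    counts <- largest_remainder_counts(n, pv)
    factor(rep(tier_levels, counts), levels = tier_levels, ordered = TRUE)
  } else {
    with_stream(streams[7], factor(
      sample(tier_levels, n, replace = TRUE, prob = pv),
      levels = tier_levels, ordered = TRUE
    ))
  }

  draw_calls <- function(stream_seed, op) {
    p_pos <- ifelse(tier == "none", 1 - op$specificity,
                    op$sensitivity[as.character(tier)])
    with_stream(stream_seed, stats::runif(n) < p_pos)
  }
  calls_ai <- draw_calls(streams[8], config$rater_operating_points$ai)
  calls_resident <- draw_calls(streams[9], config$rater_operating_points$resident)
  # a disease call exists only for patients with >= 1 gradable image
  disease_pos_ai <- ifelse(g_ai, calls_ai, NA)
  disease_pos_resident <- ifelse(g_resident, calls_resident, NA)

  opac <- config$opacity_params
  age <- with_stream(streams[10], rtrunc_scalar(
    n, opac$age_mean, opac$age_sd, opac$age_bounds[1], opac$age_bounds[2]
  ))
  symp <- with_stream(streams[11], matrix(
    stats::runif(4L * n), ncol = 4
  ) < rep(opac$symptom_probs[c("blurry_vision", "color_change",
                               "light_sensitivity", "night_difficulty")],
          each = n))
  p_cat <- clip01(opac$cataract_base +
                    opac$cataract_age60 * (age >= 60) +
                    opac$cataract_ungradable * (!g_ai))
  cataract <- with_stream(streams[12], stats::runif(n) < p_cat)

  patients <- tibble::tibble(
    patient_id = pid,
    age = age,
    disease_tier_true = tier,
    disease_pos_ai = disease_pos_ai,
    disease_pos_resident = disease_pos_resident,
    blurry_vision = symp[, 1],
    color_change = symp[, 2],
    light_sensitivity = symp[, 3],
    night_difficulty = symp[, 4],
    cataract_dx_resident = cataract
  )

  new_cohort(eyes, patients, config)
}

new_cohort <- function(eyes, patients, config = NULL) {
  structure(list(eyes = eyes, patients = patients, config = config),
            class = "synopht_cohort")
}

#' @export
print.synopht_cohort <- function(x, ...) {
  cat("<synopht_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$eyes), " eyes\n", sep = "")
  if (nrow(x$eyes)) {
    cat(sprintf("  gradable: ai %.1f%%, expert %.1f%%, resident %.1f%%\n",
                100 * mean(x$eyes$gradable_ai),
                100 * mean(x$eyes$gradable_expert),
                100 * mean(x$eyes$gradable_resident)))
  }
  invisible(x)
}

#' Write or read a cohort as delimited text
#'
#' Cohorts are persisted as two UTF-8 comma-separated tables with header
#' rows and literal `NA` for missing values: `eyes.csv` (one row per eye)
#' and `patients.csv` (one row per patient).
#'
#' @param cohort A `synopht_cohort`.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `synopht_cohort` (with `config = NULL`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synopht_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$eyes, file.path(dir, "eyes.csv"), na = "NA")
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "NA")
  invisible(dir)
}

eyes_schema <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    side = readr::col_character(),
    cdr_true = readr::col_double(),
    cdr_expert_1 = readr::col_double(),
    cdr_expert_2 = readr::col_double(),
    cdr_expert_3 = readr::col_double(),
    cdr_gt = readr::col_double(),
    cdr_ai = readr::col_double(),
    cdr_resident = readr::col_double(),
    gradable_ai = readr::col_logical(),
    gradable_expert = readr::col_logical(),
    gradable_resident = readr::col_logical(),
    cdr_ai_nogate = readr::col_double()
  )
}

patients_schema <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    age = readr::col_double(),
    disease_tier_true = readr::col_character(),
    disease_pos_ai = readr::col_logical(),
    disease_pos_resident = readr::col_logical(),
    blurry_vision = readr::col_logical(),
    color_change = readr::col_logical(),
    light_sensitivity = readr::col_logical(),
    night_difficulty = readr::col_logical(),
    cataract_dx_resident = readr::col_logical()
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  eyes_path <- file.path(dir, "eyes.csv")
  patients_path <- file.path(dir, "patients.csv")
  if (!file.exists(eyes_path) || !file.exists(patients_path)) {
    stop("expected `eyes.csv` and `patients.csv` under ", dir, call. = FALSE)
  }
  eyes <- readr::read_csv(eyes_path, col_types = eyes_schema(), na = "NA",
                          progress = FALSE)
  patients <- readr::read_csv(patients_path, col_types = patients_schema(),
                              na = "NA", progress = FALSE)
  patients$disease_tier_true <- factor(patients$disease_tier_true,
                                       levels = tier_levels, ordered = TRUE)
  validate_cohort(new_cohort(eyes, patients))
}

validate_cohort <- function(cohort) {
  eyes <- cohort$eyes
  patients <- cohort$patients
  problems <- character()
  note <- function(rows, what) {
    if (length(rows)) {
      sprintf("%s (rows %s)", what,
              paste(utils::head(rows, 5), collapse = ", "))
    } else character()
  }
  cdr_cols <- c("cdr_true", "cdr_expert_1", "cdr_expert_2", "cdr_expert_3",
                "cdr_gt", "cdr_ai", "cdr_resident")
  for (col in cdr_cols) {
    bad <- which(!is.na(eyes[[col]]) & (eyes[[col]] < 0 | eyes[[col]] > 1))
    problems <- c(problems, note(bad, paste0("eyes$", col, " outside [0,1]")))
  }
  problems <- c(problems,
    note(which(is.na(eyes$cdr_ai) != !eyes$gradable_ai),
         "cdr_ai missingness disagrees with gradable_ai"),
    note(which(is.na(eyes$cdr_resident) != !eyes$gradable_resident),
         "cdr_resident missingness disagrees with gradable_resident"),
    note(which(is.na(eyes$cdr_gt) != !eyes$gradable_expert),
         "cdr_gt missingness disagrees with gradable_expert"),
    note(which(patients$age <= 0), "non-positive age"),
    note(which(is.na(patients$disease_tier_true)), "unknown disease tier")
  )
  dup <- eyes |>
    dplyr::count(.data$patient_id, .data$side) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    problems <- c(problems,
                  paste0("duplicate eye sides for patients: ",
                         paste(utils::head(dup$patient_id, 5), collapse = ", ")))
  }
  if (length(problems)) {
    stop("cohort schema violations:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cohort
}
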