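#' Parameters of the CDR-based glaucoma-suspect rule
#'
#' The ground-truth rule flags a patient when the maximum CDR reaches 0.6
#' or the inter-eye CDR difference exceeds 0.2. AI and resident predictions
#' apply a plain threshold to the patient-level maximum CDR without the
#' asymmetry clause; the AI operating threshold of 0.55 was tuned for
#' maximum F1 at a high-specificity point.
#'
#' @param cdr_threshold Inclusive CDR threshold in (0, 1).
#' @param asymmetry_threshold Exclusive inter-eye difference threshold.
#' @param use_asymmetry Whether the asymmetry clause participates.
#' @return A list of class `suspect_params`.
#' @export
suspect_params <- function(cdr_threshold = 0.6,
                           asymmetry_threshold = 0.2,
                           use_asymmetry = TRUE) {
  stopifnot(cdr_threshold > 0, cdr_threshold < 1,
            asymmetry_threshold > 0, asymmetry_threshold < 1)
  structure(list(cdr_threshold = cdr_threshold,
                 asymmetry_threshold = asymmetry_threshold,
                 use_asymmetry = isTRUE(use_asymmetry)),
            class = "suspect_params")
}

#' Glaucoma-suspect rule on a pair of eye CDRs
#'
#' A patient is a suspect when the maximum available CDR is at or above
#' `cdr_threshold` (inclusive), or — when both eyes are present and the
#' asymmetry clause is enabled — when the absolute inter-eye difference
#' strictly exceeds `asymmetry_threshold`. With neither CDR available the
#' result is undetermined (`NA`).
#'
#' Vectorized over patients.
#'
#' @param cdr_right,cdr_left CDR values in \[0, 1\], `NA` for missing.
#' @param params A [suspect_params()] object.
#' @return Logical vector (`NA` = undetermined).
#' @export
#' @examples
#' glaucoma_suspect(0.65, 0.5)                   # TRUE  (threshold clause)
#' glaucoma_suspect(0.3, 0.55)                   # TRUE  (asymmetry clause)
#' glaucoma_suspect(0.59, 0.59)                  # FALSE
glaucoma_suspect <- function(cdr_right, cdr_left, params = suspect_params()) {
  stopifnot(inherits(params, "suspect_params"))
  n <- max(length(cdr_right), length(cdr_left))
  r <- rep_len(cdr_right, n)
  l <- rep_len(cdr_left, n)
  bad <- (!is.na(r) & (r < 0 | r > 1)) | (!is.na(l) & (l < 0 | l > 1))
  if (any(bad)) stop("CDR values must lie in [0, 1]", call. = FALSE)
  max_cdr <- pmax(r, l, na.rm = TRUE)
  max_cdr[is.na(r) & is.na(l)] <- NA_real_
  hit_threshold <- max_cdr >= params$cdr_threshold
  hit_asym <- params$use_asymmetry & !is.na(r) & !is.na(l) &
    abs(r - l) > params$asymmetry_threshold
  out <- hit_threshold | hit_asym
  out[is.na(max_cdr)] <- NA
  out
}

#' Patient-level maximum CDR per rater
#'
#' The maximum CDR over a patient's gradable eyes for one rater — the
#' continuous score underlying the glaucoma ROC analyses. Patients with no
#' gradable eye for that rater get `NA`.
#'
#' @param eyes Eye-level tibble (as in `simulate_cohort()$eyes`).
#' @param rater One of `"gt"`, `"ai"`, `"resident"`, or any `cdr_*` column
#'   suffix present in `eyes`.
#' @return A tibble with columns `patient_id` and `cdr_max`.
#' @export
patient_max_cdr <- function(eyes, rater) {
  col <- paste0("cdr_", rater)
  if (!col %in% names(eyes)) {
    stop("no column `", col, "` in eye table", call. = FALSE)
  }
  eyes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      cdr_max = if (all(is.na(.data[[col]]))) NA_real_
                else max(.data[[col]], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Default vocabulary of retinal findings and their risk tiers
#'
#' A configurable mapping from finding labels to risk-of-vision-loss tiers.
#' High-risk findings include vitreous haemorrhage, retinal detachment and
#' neovascularization; medium covers referable disease such as moderate or
#' severe non-proliferative diabetic retinopathy, macular edema, wet AMD
#' and pathological myopia; mild covers early disease. Tessellated fundus
#' is a normal variant and maps to `none` (excluded from positivity). The
#' default map is a package choice and should be reviewed against local
#' grading guidelines before use on real data.
#'
#' @return A named character vector: names are finding labels, values are
#'   tiers among `none`, `mild`, `medium`, `high`.
#' @export
default_risk_map <- function() {
  c(
    tessellated_fundus = "none",
    mild_npdr = "mild",
    drusen = "mild",
    dry_amd_early = "mild",
    epiretinal_membrane = "mild",
    moderate_npdr = "medium",
    severe_npdr = "medium",
    macular_edema = "medium",
    wet_amd = "medium",
    pathological_myopia = "medium",
    retinal_vein_occlusion = "medium",
    proliferative_dr = "high",
    vitreous_hemorrhage = "high",
    retinal_detachment = "high",
    neovascularization = "high"
  )
}

#' Retinal-disease positivity from per-eye finding sets
#'
#' A case is positive when any configured disease finding is present in any
#' eye; findings mapping to tier `none` (e.g. tessellated fundus) do not
#' count.
#'
#' @param findings A list of character vectors, one per eye (an empty
#'   vector means no findings in that eye).
#' @param risk_map Named tier mapping as from [default_risk_map()].
#' @return Single logical.
#' @export
#' @examples
#' retinal_disease_positive(list(right = "moderate_npdr"))        # TRUE
#' retinal_disease_positive(list(right = "tessellated_fundus"))   # FALSE
retinal_disease_positive <- function(findings, risk_map = default_risk_map()) {
  if (!is.list(findings)) findings <- list(findings)
  labels <- unique(unlist(findings, use.names = FALSE))
  if (length(labels) == 0) return(FALSE)
  unknown <- setdiff(labels, names(risk_map))
  if (length(unknown)) {
    stop("unknown finding label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  any(risk_map[labels] != "none")
}

#' Risk-of-vision-loss tier for a set of findings
#'
#' The highest tier among all findings across eyes; `none` when there are
#' no (tier-relevant) findings. Adding a finding can never lower the tier.
#'
#' @inheritParams retinal_disease_positive
#' @return Ordered factor with levels `none < mild < medium < high`.
#' @export
risk_tier <- function(findings, risk_map = default_risk_map()) {
  if (!is.list(findings)) findings <- list(findings)
  labels <- unique(unlist(findings, use.names = FALSE))
  unknown <- setdiff(labels, names(risk_map))
  if (length(unknown)) {
    stop("unmapped finding label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tiers <- factor(unname(risk_map[labels]), levels = tier_levels,
                  ordered = TRUE)
  if (length(tiers) == 0) {
    return(factor("none", levels = tier_levels, ordered = TRUE))
  }
  max(tiers)
}

#' Media-opacity screening rule
#'
#' Fires when any configured conjunction rule is satisfied. The default
#' rule set contains a single rule: age at least 60 years, blurry vision
#' reported, and no image of gradable quality. Each rule is a list with
#' fields `min_age` (years), `symptoms` (character vector, all required)
#' and `requires_ungradable` (logical).
#'
#' Vectorized over patients when `age`, `any_gradable_image` are vectors
#' and `symptoms` is a logical data frame with one column per symptom.
#'
#' @param age Age in years.
#' @param symptoms Character vector of present symptoms for one patient, or
#'   a logical data frame (columns = symptom names) for many.
#' @param any_gradable_image Whether at least one image met the quality
#'   threshold.
#' @param rules List of conjunction rules.
#' @return Logical vector.
#' @export
#' @examples
#' media_opacity(62, "blurry_vision", any_gradable_image = FALSE)  # TRUE
#' media_opacity(62, "blurry_vision", any_gradable_image = TRUE)   # FALSE
media_opacity <- function(age, symptoms, any_gradable_image,
                          rules = default_opacity_rules()) {
  if (is.character(symptoms) || is.null(symptoms)) {
    all_symptoms <- c("blurry_vision", "color_change", "light_sensitivity",
                      "night_difficulty")
    present <- union(symptoms, character())
    symptoms <- as.data.frame(as.list(stats::setNames(
      all_symptoms %in% present, all_symptoms
    )))
  }
  n <- length(age)
  out <- rep(FALSE, n)
  for (rule in rules) {
    sym_ok <- rep(TRUE, n)
    for (s in rule$symptoms) {
      if (!s %in% names(symptoms)) {
        stop("symptom `", s, "` not present in symptom table", call. = FALSE)
      }
      sym_ok <- sym_ok & symptoms[[s]]
    }
    fire <- age >= rule$min_age & sym_ok
    if (isTRUE(rule$requires_ungradable)) fire <- fire & !any_gradable_image
    out <- out | fire
  }
  out
}

#' @rdname media_opacity
#' @export
default_opacity_rules <- function() {
  list(list(min_age = 60, symptoms = "blurry_vision",
            requires_ungradable = TRUE))
}

#' OR-combination of two classifier outputs
#'
#' The synergistic call is positive if either assessor is positive. With
#' one undetermined (`NA`) input, the determinate assessor decides (the
#' combined analysis includes patients evaluated by at least one method);
#' with both undetermined the result stays undetermined.
#'
#' @param pred_a,pred_b Logical vectors, `NA` = undetermined.
#' @return Logical vector.
#' @export
#' @examples
#' synergy_or(c(TRUE, FALSE, NA, NA), c(FALSE, FALSE, FALSE, NA))
synergy_or <- function(pred_a, pred_b) {
  n <- max(length(pred_a), length(pred_b))
  a <- rep_len(as.logical(pred_a), n)
  b <- rep_len(as.logical(pred_b), n)
  out <- dplyr::case_when(
    !is.na(a) & a ~ TRUE,
    !is.na(b) & b ~ TRUE,
    !is.na(a) & !is.na(b) ~ FALSE,  # both determinate, both FALSE
    !is.na(a) ~ a,                  # only a determinate (and FALSE)
    !is.na(b) ~ b,
    TRUE ~ NA
  )
  out
}

#' F1-optimal threshold for a score-based rule
#'
#' Scans the unique observed score values as candidate thresholds for the
#' rule `score >= tau` and returns the threshold maximizing F1. Ties are
#' broken toward the largest threshold (the highest-specificity operating
#' point among the F1 maximizers).
#'
#' @param scores Numeric scores.
#' @param labels Logical truth labels.
#' @return A list with `threshold`, `f1`, and the tibble `candidates`
#'   (threshold, tp, fp, fn, f1) for inspection.
#' @export
#' @examples
#' optimize_threshold_f1(c(0.2, 0.7), c(FALSE, TRUE))$threshold  # 0.7
optimize_threshold_f1 <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to optimize a threshold",
         call. = FALSE)
  }
  cand <- sort(unique(scores))
  stats_at <- purrr::map_dfr(cand, function(tau) {
    pred <- scores >= tau
    tibble::tibble(
      threshold = tau,
      tp = sum(pred & labels),
      fp = sum(pred & !labels),
      fn = sum(!pred & labels)
    )
  })
  stats_at$f1 <- with(stats_at, 2 * tp / (2 * tp + fp + fn))
  best <- max(stats_at$f1)
  # largest threshold among maximizers
  tau <- max(stats_at$threshold[stats_at$f1 == best])
  list(threshold = tau, f1 = best, candidates = stats_at)
}
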