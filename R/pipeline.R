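#' Run the full screening-evaluation study on a cohort
#'
#' Orchestrates every analysis stage on a simulated or user-supplied
#' cohort, mirroring the structure of a published human-vs-AI screening
#' evaluation:
#'
#' * **Glaucoma-suspect panel** — restricted to patients with CDR available
#'   from the residents, the AI tool and the experts. Ground truth applies
#'   the full rule (max CDR >= 0.6 or inter-eye difference > 0.2) to the
#'   expert-mean CDRs; AI and resident calls threshold the patient-level
#'   maximum CDR (AI at `ai_threshold`, resident at
#'   `resident_threshold`); the synergistic call is their OR. Metrics with
#'   percentile-bootstrap CIs, paired bootstrap p-values (AI vs resident;
#'   synergy vs each for sensitivity), single-score ROC curves for AI and
#'   resident and the dual-threshold OR-synergy envelope.
#' * **CDR agreement panel** — eyes graded by all raters: MAE, relative
#'   error, bias, Bland-Altman limits, Pearson r per rater, and the full
#'   rater correlation matrix.
#' * **Retinal-disease panel** — patients with an AI disease call:
#'   overall metrics plus tier-restricted sensitivities (medium+ risk,
#'   high risk) for AI, resident and their OR.
#' * **Media-opacity panel** — AI opacity rule (age/symptoms/quality
#'   conjunctions) against the residents' cataract diagnoses: confusion
#'   matrix, percent agreement and Cohen's kappa.
#'
#' Every exclusion is logged so that analysis subset sizes plus exclusions
#' sum to the cohort size.
#'
#' @param cohort A `synopht_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param ai_threshold AI operating threshold on patient max CDR.
#' @param resident_threshold Resident threshold on patient max CDR.
#' @param ai_use_asymmetry,resident_use_asymmetry Whether the AI / resident
#'   call also uses the inter-eye asymmetry clause (default `FALSE`: the
#'   plain cutoff mode applied to the patient-level maximum CDR).
#' @param gt_params [suspect_params()] for the ground-truth rule.
#' @param n_boot Bootstrap resamples for CIs and p-values; `0` skips
#'   bootstrap inference entirely.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `study_report` (a nested list of tibbles;
#'   see Details).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(300, seed = 11))
#' rep <- run_study(cohort, n_boot = 0)
#' rep$glaucoma$table
run_study <- function(cohort,
                      ai_threshold = 0.55,
                      resident_threshold = 0.6,
                      ai_use_asymmetry = FALSE,
                      resident_use_asymmetry = FALSE,
                      gt_params = suspect_params(0.6, 0.2, use_asymmetry = TRUE),
                      n_boot = 2000,
                      seed = 1) {
  stopifnot(inherits(cohort, "synopht_cohort"))
  validate_cohort(cohort)
  eyes <- cohort$eyes
  patients <- cohort$patients
  n_total <- nrow(patients)
  exclusions <- list()

  # --- glaucoma panel -------------------------------------------------
  wide <- eyes_to_wide(eyes)
  gl <- wide |>
    dplyr::mutate(
      truth = glaucoma_suspect(.data$gt_right, .data$gt_left, gt_params),
      score_ai = pmax_na(.data$ai_right, .data$ai_left),
      score_resident = pmax_na(.data$resident_right, .data$resident_left),
      pred_ai = threshold_call(.data$ai_right, .data$ai_left,
                               ai_threshold, ai_use_asymmetry),
      pred_resident = threshold_call(.data$resident_right,
                                     .data$resident_left,
                                     resident_threshold,
                                     resident_use_asymmetry)
    )
  gl_subset <- gl |>
    dplyr::filter(!is.na(.data$truth), !is.na(.data$pred_ai),
                  !is.na(.data$pred_resident)) |>
    dplyr::mutate(pred_synergy = synergy_or(.data$pred_ai, .data$pred_resident))
  exclusions$glaucoma <- tibble::tibble(
    analysis = "glaucoma",
    reason = c("missing expert ground truth", "missing AI CDR",
               "missing resident CDR"),
    n = c(sum(is.na(gl$truth)),
          sum(!is.na(gl$truth) & is.na(gl$pred_ai)),
          sum(!is.na(gl$truth) & !is.na(gl$pred_ai) &
                is.na(gl$pred_resident)))
  )
  glaucoma <- analyze_panel(
    gl_subset, truth = "truth",
    preds = c(resident = "pred_resident", ai = "pred_ai",
              synergy = "pred_synergy"),
    n_boot = n_boot, seed = seed
  )
  glaucoma$roc <- list(
    ai = roc_curve(gl_subset$score_ai, gl_subset$truth),
    resident = roc_curve(gl_subset$score_resident, gl_subset$truth),
    synergy = synergy_roc(gl_subset$score_ai, gl_subset$score_resident,
                          gl_subset$truth)
  )
  glaucoma$data <- gl_subset

  # --- CDR agreement panel -------------------------------------------
  agree_eyes <- eyes |>
    dplyr::filter(.data$gradable_expert, .data$gradable_ai,
                  .data$gradable_resident)
  exclusions$agreement <- tibble::tibble(
    analysis = "agreement", reason = "eye not graded by all raters",
    n = nrow(eyes) - nrow(agree_eyes)
  )
  agreement <- list(
    n_eyes = nrow(agree_eyes),
    summaries = dplyr::bind_rows(
      ai = cdr_agreement(agree_eyes$cdr_ai, agree_eyes$cdr_gt),
      resident = cdr_agreement(agree_eyes$cdr_resident, agree_eyes$cdr_gt),
      .id = "rater"
    ),
    correlations = correlation_matrix(
      agree_eyes[, c("cdr_expert_1", "cdr_expert_2", "cdr_expert_3",
                     "cdr_gt", "cdr_ai", "cdr_resident")]
    ),
    data = agree_eyes
  )

  # --- retinal panel --------------------------------------------------
  ret <- patients |>
    dplyr::filter(!is.na(.data$disease_pos_ai),
                  !is.na(.data$disease_pos_resident)) |>
    dplyr::mutate(
      truth = .data$disease_tier_true != "none",
      pred_synergy = synergy_or(.data$disease_pos_ai,
                                .data$disease_pos_resident)
    )
  exclusions$retinal <- tibble::tibble(
    analysis = "retinal",
    reason = c("no AI disease call", "no resident disease call"),
    n = c(sum(is.na(patients$disease_pos_ai)),
          sum(!is.na(patients$disease_pos_ai) &
                is.na(patients$disease_pos_resident)))
  )
  retinal <- analyze_panel(
    ret, truth = "truth",
    preds = c(resident = "disease_pos_resident", ai = "disease_pos_ai",
              synergy = "pred_synergy"),
    n_boot = n_boot, seed = seed + 1
  )
  retinal$table <- dplyr::left_join(
    retinal$table, tiered_sensitivities(ret), by = "approach"
  )
  retinal$data <- ret

  # --- media-opacity panel -------------------------------------------
  patient_any_gradable <- eyes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(any_gradable = any(.data$gradable_ai), .groups = "drop")
  op <- patients |>
    dplyr::left_join(patient_any_gradable, by = "patient_id") |>
    dplyr::mutate(ai_opacity = media_opacity(
      .data$age,
      dplyr::pick("blurry_vision", "color_change", "light_sensitivity",
                  "night_difficulty"),
      .data$any_gradable
    ))
  op_cm <- confusion(pred = op$ai_opacity, truth = op$cataract_dx_resident)
  opacity <- list(
    cm = op_cm,
    # a degenerate table (expected agreement 1) has no defined kappa
    kappa = tryCatch(cohen_kappa(op_cm), error = function(e) NA_real_),
    percent_agreement = percent_agreement(op_cm),
    data = op
  )

  structure(
    list(
      glaucoma = glaucoma,
      agreement = agreement,
      retinal = retinal,
      opacity = opacity,
      exclusions = dplyr::bind_rows(exclusions),
      provenance = list(
        n_patients = n_total,
        seed = seed,
        n_boot = n_boot,
        ai_threshold = ai_threshold,
        resident_threshold = resident_threshold,
        config = cohort$config,
        package_version = as.character(utils::packageVersion("synopht"))
      )
    ),
    class = "study_report"
  )
}

eyes_to_wide <- function(eyes) {
  eyes |>
    dplyr::select("patient_id", "side", gt = "cdr_gt", ai = "cdr_ai",
                  resident = "cdr_resident") |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("gt", "ai", "resident"),
                       names_sep = "_")
}

pmax_na <- function(a, b) {
  out <- pmax(a, b, na.rm = TRUE)
  out[is.na(a) & is.na(b)] <- NA_real_
  out
}

threshold_call <- function(right, left, threshold, use_asymmetry) {
  glaucoma_suspect(right, left,
                   suspect_params(cdr_threshold = threshold,
                                  asymmetry_threshold = 0.2,
                                  use_asymmetry = use_asymmetry))
}

# shared per-panel machinery: metric table with bootstrap CIs and paired
# p-values between approaches
analyze_panel <- function(data, truth, preds, n_boot, seed) {
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "f1")
  table <- purrr::imap_dfr(preds, function(col, approach) {
    cm <- confusion(data[[col]], data[[truth]])
    out <- metric_set(cm)
    out$approach <- approach
    out
  }) |>
    dplyr::select("approach", dplyr::everything())
  if (n_boot > 0) {
    cis <- purrr::imap_dfr(preds, function(col, approach) {
      purrr::map_dfr(metrics, function(m) {
        b <- bootstrap_metric(data, m, pred = col, truth = truth,
                              n_boot = n_boot, seed = seed)
        tibble::tibble(approach = approach, metric = m,
                       ci_low = b$ci_low, ci_high = b$ci_high)
      })
    })
    lows <- tidyr::pivot_wider(
      dplyr::select(cis, -"ci_high"), names_from = "metric",
      values_from = "ci_low", names_glue = "{metric}_ci_low"
    )
    highs <- tidyr::pivot_wider(
      dplyr::select(cis, -"ci_low"), names_from = "metric",
      values_from = "ci_high", names_glue = "{metric}_ci_high"
    )
    table <- table |>
      dplyr::left_join(lows, by = "approach") |>
      dplyr::left_join(highs, by = "approach")
    comparisons <- dplyr::bind_rows(
      purrr::map_dfr(metrics, function(m) tibble::tibble(
        comparison = "ai_vs_resident", metric = m,
        p_value = paired_bootstrap_pvalue(
          data, m, rater_a = preds[["ai"]], rater_b = preds[["resident"]],
          truth = truth, n_boot = n_boot, seed = seed
        )
      )),
      tibble::tibble(
        comparison = c("synergy_vs_ai", "synergy_vs_resident"),
        metric = "sensitivity",
        p_value = c(
          paired_bootstrap_pvalue(data, "sensitivity",
                                  rater_a = preds[["synergy"]],
                                  rater_b = preds[["ai"]], truth = truth,
                                  n_boot = n_boot, seed = seed),
          paired_bootstrap_pvalue(data, "sensitivity",
                                  rater_a = preds[["synergy"]],
                                  rater_b = preds[["resident"]],
                                  truth = truth, n_boot = n_boot, seed = seed)
        )
      )
    )
  } else {
    comparisons <- NULL
  }
  list(n = nrow(data), table = table, p_values = comparisons)
}

tiered_sensitivities <- function(ret) {
  preds <- c(resident = "disease_pos_resident", ai = "disease_pos_ai",
             synergy = "pred_synergy")
  purrr::imap_dfr(preds, function(col, approach) {
    med <- ret$disease_tier_true >= "medium"
    high <- ret$disease_tier_true == "high"
    tibble::tibble(
      approach = approach,
      sensitivity_medium_plus = if (any(med)) mean(ret[[col]][med]) else NA_real_,
      sensitivity_high = if (any(high)) mean(ret[[col]][high]) else NA_real_
    )
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  glaucoma panel: n =", x$glaucoma$n, "\n")
  print(x$glaucoma$table[, c("approach", "accuracy", "sensitivity",
                             "specificity", "ppv", "f1")])
  cat("  agreement panel: n_eyes =", x$agreement$n_eyes, "\n")
  print(x$agreement$summaries[, c("rater", "mae", "bias", "loa_low",
                                  "loa_high", "pearson_r")])
  cat("  retinal panel: n =", x$retinal$n, "\n")
  print(x$retinal$table[, c("approach", "accuracy", "sensitivity",
                            "sensitivity_medium_plus", "sensitivity_high",
                            "specificity")])
  cat(sprintf("  opacity panel: agreement %.1f%%, kappa %.3f\n",
              100 * x$opacity$percent_agreement, x$opacity$kappa))
  invisible(x)
}

#' Impact of the image-quality gate on AI glaucoma metrics
#'
#' Compares the glaucoma-suspect metrics of the AI with its quality gate in
#' place (quality-failed eyes contribute no estimate) against the ungated
#' pipeline (every eye keeps its — possibly degraded — estimate, carried in
#' the `cdr_ai_nogate` column). The ungated analysis is additionally split
#' by whether the patient's images passed the quality gate.
#'
#' @inheritParams run_study
#' @return A list of class `quality_ablation` with tibbles `gated` (one
#'   row) and `ungated` (rows `all`, `sufficient_quality`,
#'   `insufficient_quality`), each carrying the five panel metrics and the
#'   subset size.
#' @export
quality_ablation <- function(cohort, ai_threshold = 0.55,
                             gt_params = suspect_params(0.6, 0.2, TRUE)) {
  stopifnot(inherits(cohort, "synopht_cohort"))
  eyes <- cohort$eyes
  if (!"cdr_ai_nogate" %in% names(eyes) || all(is.na(eyes$cdr_ai_nogate))) {
    stop("cohort carries no ungated AI estimates", call. = FALSE)
  }
  if (all(is.na(eyes$cdr_ai)) && all(is.na(eyes$cdr_ai_nogate))) {
    stop("no AI estimates at all", call. = FALSE)
  }
  wide_gt <- eyes_to_wide(eyes)
  base <- wide_gt |>
    dplyr::mutate(truth = glaucoma_suspect(.data$gt_right, .data$gt_left,
                                           gt_params)) |>
    dplyr::filter(!is.na(.data$truth))
  nogate <- eyes |>
    dplyr::select("patient_id", "side", "cdr_ai_nogate") |>
    tidyr::pivot_wider(names_from = "side", values_from = "cdr_ai_nogate",
                       names_prefix = "nogate_")
  ai_quality <- eyes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(sufficient = any(.data$gradable_ai), .groups = "drop")
  base <- base |>
    dplyr::left_join(nogate, by = "patient_id") |>
    dplyr::left_join(ai_quality, by = "patient_id") |>
    dplyr::mutate(
      score_gated = pmax_na(.data$ai_right, .data$ai_left),
      score_ungated = pmax_na(.data$nogate_right, .data$nogate_left),
      pred_gated = .data$score_gated >= ai_threshold,
      pred_ungated = .data$score_ungated >= ai_threshold
    )

  row_metrics <- function(df, pred_col, label) {
    df <- df[!is.na(df[[pred_col]]), , drop = FALSE]
    if (nrow(df) == 0 || !any(df$truth) || all(df$truth)) {
      return(tibble::tibble(subset = label, n = nrow(df),
                            accuracy = NA_real_, sensitivity = NA_real_,
                            specificity = NA_real_, ppv = NA_real_,
                            f1 = NA_real_))
    }
    out <- metric_set(confusion(df[[pred_col]], df$truth))
    dplyr::bind_cols(tibble::tibble(subset = label, n = nrow(df)), out)
  }

  structure(
    list(
      gated = row_metrics(base, "pred_gated", "gated"),
      ungated = dplyr::bind_rows(
        row_metrics(base, "pred_ungated", "all"),
        row_metrics(dplyr::filter(base, .data$sufficient),
                    "pred_ungated", "sufficient_quality"),
        row_metrics(dplyr::filter(base, !.data$sufficient),
                    "pred_ungated", "insufficient_quality")
      )
    ),
    class = "quality_ablation"
  )
}

#' @export
print.quality_ablation <- function(x, ...) {
  cat("<quality_ablation>\n  gated:\n")
  print(x$gated)
  cat("  ungated:\n")
  print(x$ungated)
  invisible(x)
}

#' Write a study report as JSON plus delimited tables
#'
#' Emits `report.json` (full precision, machine readable) and the
#' human-readable CSV tables `table_glaucoma.csv`, `table_retinal.csv`,
#' `table_opacity.csv`, `roc_points.csv` and `agreement.csv`; percentages
#' in the CSV tables are printed at one decimal with half-up rounding.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pct <- function(x) round_half_up(100 * x, 1)
  fmt_panel <- function(tab) {
    dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric), pct))
  }
  readr::write_csv(fmt_panel(report$glaucoma$table),
                   file.path(dir, "table_glaucoma.csv"), na = "NA")
  readr::write_csv(fmt_panel(report$retinal$table),
                   file.path(dir, "table_retinal.csv"), na = "NA")
  op <- report$opacity
  readr::write_csv(
    tibble::tibble(
      cell = c("tp", "fp", "fn", "tn"),
      count = c(op$cm$tp, op$cm$fp, op$cm$fn, op$cm$tn),
      kappa = op$kappa, percent_agreement = pct(op$percent_agreement)
    ),
    file.path(dir, "table_opacity.csv")
  )
  roc_pts <- purrr::imap_dfr(report$glaucoma$roc,
                             function(r, nm) dplyr::mutate(tidy(r), curve = nm))
  readr::write_csv(roc_pts, file.path(dir, "roc_points.csv"), na = "NA")
  readr::write_csv(report$agreement$summaries,
                   file.path(dir, "agreement.csv"), na = "NA")
  json <- list(
    glaucoma = list(n = report$glaucoma$n, table = report$glaucoma$table,
                    p_values = report$glaucoma$p_values,
                    auc = purrr::map_dbl(report$glaucoma$roc, "auc")),
    agreement = list(n_eyes = report$agreement$n_eyes,
                     summaries = report$agreement$summaries),
    retinal = list(n = report$retinal$n, table = report$retinal$table,
                   p_values = report$retinal$p_values),
    opacity = list(cm = unclass(op$cm), kappa = op$kappa,
                   percent_agreement = op$percent_agreement),
    exclusions = report$exclusions,
    provenance = report$provenance[c("n_patients", "seed", "n_boot",
                                     "ai_threshold", "resident_threshold",
                                     "package_version")]
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
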