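#' Continuous agreement between CDR estimates and a reference
#'
#' Error and agreement statistics for paired measurements: mean absolute
#' error (and its SD), relative error in percent of the reference value,
#' mean bias (estimate minus reference, so negative bias means
#' underestimation), Bland-Altman 95% limits of agreement
#' (`bias +/- 1.96 * SD(differences)`, fixed multiplier), and the Pearson
#' correlation.
#'
#' @param estimates,reference Paired numeric vectors; pairs with a missing
#'   value in either are dropped.
#' @param relative_to Denominator of the relative error: `"reference"`
#'   (default) or `"mean"` of each pair.
#' @return A one-row tibble of class `agreement_summary` with columns
#'   `n_pairs`, `mae`, `mae_sd`, `relative_error_mean`, `relative_error_sd`
#'   (percent), `bias`, `sd_diff`, `loa_low`, `loa_high`, `pearson_r`
#'   (`NA` when either vector has zero variance).
#' @export
#' @examples
#' cdr_agreement(c(0.35, 0.38, 0.56, 0.55, 0.77),
#'               c(0.30, 0.40, 0.50, 0.60, 0.70))
cdr_agreement <- function(estimates, reference,
                          relative_to = c("reference", "mean")) {
  relative_to <- match.arg(relative_to)
  keep <- !is.na(estimates) & !is.na(reference)
  e <- estimates[keep]
  g <- reference[keep]
  if (length(e) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- e - g
  abs_err <- abs(d)
  denom <- if (relative_to == "reference") g else (e + g) / 2
  if (any(denom <= 0)) {
    stop("relative error undefined: non-positive denominator", call. = FALSE)
  }
  rel <- 100 * abs_err / denom
  sd_diff <- stats::sd(d)
  bias <- mean(d)
  r <- if (stats::sd(e) == 0 || stats::sd(g) == 0) {
    NA_real_
  } else {
    stats::cor(e, g)
  }
  out <- tibble::tibble(
    n_pairs = length(e),
    mae = mean(abs_err),
    mae_sd = stats::sd(abs_err),
    relative_error_mean = mean(rel),
    relative_error_sd = stats::sd(rel),
    bias = bias,
    sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff,
    loa_high = bias + 1.96 * sd_diff,
    pearson_r = r
  )
  class(out) <- c("agreement_summary", class(out))
  out
}

#' Pairwise-complete Pearson correlation matrix across raters
#'
#' @param raters A data frame (or named list) of numeric vectors with
#'   missing values allowed; correlations use pairwise-complete pairs.
#' @param min_pairs Minimum number of complete pairs per cell; cells below
#'   it are `NA`.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
#' @examples
#' eyes <- simulate_cohort(sim_config(500, seed = 3))$eyes
#' correlation_matrix(eyes[, c("cdr_expert_1", "cdr_expert_2",
#'                             "cdr_expert_3", "cdr_gt", "cdr_ai")])
correlation_matrix <- function(raters, min_pairs = 2) {
  df <- tibble::as_tibble(raters)
  k <- ncol(df)
  out <- matrix(NA_real_, k, k, dimnames = list(names(df), names(df)))
  diag(out) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      ok <- !is.na(df[[i]]) & !is.na(df[[j]])
      if (sum(ok) >= min_pairs &&
          stats::sd(df[[i]][ok]) > 0 && stats::sd(df[[j]][ok]) > 0) {
        out[i, j] <- out[j, i] <- stats::cor(df[[i]][ok], df[[j]][ok])
      }
    }
  }
  out
}

#' Bland-Altman plot data and plot
#'
#' `bland_altman_data()` returns the per-pair means and differences plus
#' the bias and limits of agreement; `plot_bland_altman()` draws the
#' conventional plot.
#'
#' @inheritParams cdr_agreement
#' @return A list with `points` (tibble `mean`, `difference`) and `summary`
#'   (an `agreement_summary`).
#' @export
bland_altman_data <- function(estimates, reference) {
  keep <- !is.na(estimates) & !is.na(reference)
  e <- estimates[keep]
  g <- reference[keep]
  summary <- cdr_agreement(e, g)
  list(
    points = tibble::tibble(mean = (e + g) / 2, difference = e - g),
    summary = summary
  )
}

#' @rdname bland_altman_data
#' @export
plot_bland_altman <- function(estimates, reference) {
  ba <- bland_altman_data(estimates, reference)
  s <- ba$summary
  ggplot2::ggplot(ba$points,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = s$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(s$loa_low, s$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of estimate and reference",
                  y = "Estimate - reference",
                  title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                                  s$bias, s$loa_low, s$loa_high)) +
    ggplot2::theme_minimal()
}
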