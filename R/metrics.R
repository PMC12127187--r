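#' Build a 2x2 confusion matrix from paired predictions and truth
#'
#' @param pred,truth Logical vectors of equal length without `NA`
#'   (undetermined cases must be excluded upstream).
#' @return A list of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  if (anyNA(pred) || anyNA(truth)) {
    stop("undetermined entries are not allowed; filter them first",
         call. = FALSE)
  }
  confusion_matrix(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    fn = sum(!pred & truth), tn = sum(!pred & !truth)
  )
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != trunc(cells))) {
    stop("confusion-matrix cells must be non-negative integers",
         call. = FALSE)
  }
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              pred = c("pos", "neg")))
  print(m)
  invisible(x)
}

cm_total <- function(cm) cm$tp + cm$fp + cm$fn + cm$tn

#' Classification metrics of a confusion matrix
#'
#' Accuracy, sensitivity, specificity, positive predictive value and F1.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' as 0.
#'
#' @param cm A `confusion_matrix`.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `f1`.
#' @export
#' @examples
#' metric_set(confusion_matrix(29, 11, 17, 188))
metric_set <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / n,
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    ppv = safe_div(cm$tp, cm$tp + cm$fp),
    f1 = safe_div(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  )
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with expected
#' agreement `pe` from the marginal products.
#'
#' @param cm A `confusion_matrix` (one rater along rows, the other along
#'   columns; `tp`/`tn` are the agreeing cells).
#' @return Numeric kappa in \[-1, 1\]; error if `pe = 1`.
#' @export
#' @examples
#' cohen_kappa(confusion_matrix(tp = 14, fp = 35, fn = 26, tn = 360))
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- (cm$tp + cm$tn) / n
  p_yes_a <- (cm$tp + cm$fn) / n   # rater A marginal (truth side)
  p_yes_b <- (cm$tp + cm$fp) / n   # rater B marginal (prediction side)
  pe <- p_yes_a * p_yes_b + (1 - p_yes_a) * (1 - p_yes_b)
  if (pe >= 1) stop("kappa undefined: expected agreement is 1", call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Percent agreement of a 2x2 table
#'
#' @inheritParams cohen_kappa
#' @return Proportion of agreeing pairs `(tp + tn) / total`.
#' @export
percent_agreement <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  (cm$tp + cm$tn) / n
}

# round half-up to `digits` decimals (printed tables use this convention,
# not banker's rounding); a tiny epsilon guards against binary float error
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Reconstruct integer confusion matrices from rounded published metrics
#'
#' Published diagnostic panels print metrics rounded to one decimal in
#' percent. When several classifiers share the same truth (the same number
#' of true positives `P` and negatives `N = n - P`), the rounded values
#' over-determine the integer cell counts, which can then be recovered
#' exactly by exhaustive search: for each `P` in `1..n-1`, find for every
#' classifier all cell combinations whose metrics round (half-up, 1
#' decimal) to every printed value. A `P` is feasible when every classifier
#' has at least one solution; the reconstruction is unique when exactly one
#' feasible `P` remains and each classifier has a single solution.
#'
#' @param printed A data frame with one row per classifier and columns
#'   `approach` plus any of `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `f1` in percent (1 decimal); `NA` entries are ignored.
#' @param n Total number of cases.
#' @return A list of class `panel_reconstruction`: `n`, `p` (feasible
#'   positive counts), `unique` (logical), and `solutions` — for the unique
#'   `P`, a tibble with columns `approach`, `tp`, `fp`, `fn`, `tn` (one row
#'   per classifier solution).
#' @export
#' @examples
#' panel <- tibble::tibble(
#'   approach = c("ai", "resident"),
#'   sensitivity = c(63.0, 50.0), specificity = c(94.5, 90.5)
#' )
#' reconstruct_counts(panel, n = 245)
reconstruct_counts <- function(printed, n) {
  stopifnot(is.data.frame(printed), "approach" %in% names(printed), n >= 2)
  metric_cols <- intersect(c("accuracy", "sensitivity", "specificity",
                             "ppv", "f1"), names(printed))
  if (length(metric_cols) == 0) {
    stop("`printed` must contain at least one metric column", call. = FALSE)
  }

  match_printed <- function(value, target) {
    # target NA = unconstrained; undefined metrics never match a number
    is.na(target) | (!is.na(value) & round_half_up(100 * value, 1) == target)
  }

  printed_value <- function(row, nm) {
    if (nm %in% names(row)) row[[nm]] else NA_real_
  }

  solutions_for <- function(row, P, N) {
    # candidate tp constrained by printed sensitivity, tn by specificity;
    # remaining metrics filter the (tp, tn) grid
    sens <- printed_value(row, "sensitivity")
    spec <- printed_value(row, "specificity")
    acc <- printed_value(row, "accuracy")
    ppv_t <- printed_value(row, "ppv")
    f1_t <- printed_value(row, "f1")
    tp <- 0:P
    if (!is.na(sens)) tp <- tp[match_printed(tp / P, sens)]
    tn <- 0:N
    if (!is.na(spec)) tn <- tn[match_printed(tn / N, spec)]
    if (length(tp) == 0 || length(tn) == 0) return(NULL)
    grid <- expand.grid(tp = tp, tn = tn)
    grid$fp <- N - grid$tn
    grid$fn <- P - grid$tp
    keep <- rep(TRUE, nrow(grid))
    if (!is.na(acc)) {
      keep <- keep & match_printed((grid$tp + grid$tn) / (P + N), acc)
    }
    if (!is.na(ppv_t)) {
      ppv <- ifelse(grid$tp + grid$fp == 0, NA_real_,
                    grid$tp / (grid$tp + grid$fp))
      keep <- keep & match_printed(ppv, ppv_t)
    }
    if (!is.na(f1_t)) {
      f1 <- ifelse(2 * grid$tp + grid$fp + grid$fn == 0, NA_real_,
                   2 * grid$tp / (2 * grid$tp + grid$fp + grid$fn))
      keep <- keep & match_printed(f1, f1_t)
    }
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0) NULL else grid
  }

  rows <- split(printed, seq_len(nrow(printed)))
  feasible <- list()
  for (P in 1:(n - 1)) {
    N <- n - P
    per_rater <- lapply(rows, solutions_for, P = P, N = N)
    if (all(!vapply(per_rater, is.null, logical(1)))) {
      feasible[[as.character(P)]] <- per_rater
    }
  }
  if (length(feasible) == 0) {
    stop("no integer confusion matrices are consistent with the printed ",
         "values at n = ", n, call. = FALSE)
  }
  p_values <- as.integer(names(feasible))
  unique_p <- length(p_values) == 1
  sols <- NULL
  if (unique_p) {
    per_rater <- feasible[[1]]
    sols <- purrr::imap_dfr(per_rater, function(grid, i) {
      tibble::tibble(
        approach = rows[[as.integer(i)]]$approach,
        tp = grid$tp, fp = grid$fp, fn = grid$fn, tn = grid$tn
      )
    })
  }
  structure(
    list(n = n, p = p_values, unique = unique_p, solutions = sols),
    class = "panel_reconstruction"
  )
}

#' @export
print.panel_reconstruction <- function(x, ...) {
  cat("<panel_reconstruction> n =", x$n, "\n")
  if (x$unique) {
    cat("  unique positives P =", x$p, "\n")
    print(x$solutions)
  } else {
    cat("  ambiguous: feasible P in {", paste(x$p, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Confusion matrices from a unique panel reconstruction
#'
#' Convenience accessor: asserts that the reconstruction is unique (one
#' feasible `P`, one solution per classifier) and returns named
#' `confusion_matrix` objects.
#'
#' @param recon A `panel_reconstruction`.
#' @return Named list of `confusion_matrix` objects.
#' @export
reconstructed_matrices <- function(recon) {
  stopifnot(inherits(recon, "panel_reconstruction"))
  if (!recon$unique) {
    stop("reconstruction is ambiguous: feasible P in {",
         paste(recon$p, collapse = ", "), "}", call. = FALSE)
  }
  counts <- dplyr::count(recon$solutions, .data$approach)
  if (any(counts$n > 1)) {
    stop("reconstruction is ambiguous within classifiers: ",
         paste(counts$approach[counts$n > 1], collapse = ", "), call. = FALSE)
  }
  out <- purrr::pmap(recon$solutions,
                     function(approach, tp, fp, fn, tn) {
                       confusion_matrix(tp, fp, fn, tn)
                     })
  stats::setNames(out, recon$solutions$approach)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
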