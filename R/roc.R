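#' Single-score ROC curve
#'
#' Standard ROC over the threshold grid formed by the unique observed score
#' values plus `+Inf`, with a positive call when `score >= tau`. Pairs with
#' missing scores are excluded (pairwise deletion). The AUC is computed by
#' the trapezoidal rule and equals the Mann-Whitney concordance fraction
#' (ties counted half).
#'
#' @param scores Numeric scores (higher = more disease-like).
#' @param labels Logical truth labels.
#' @return An object of class `roc_frontier`: list with `points` (tibble
#'   `fpr`, `tpr`, `threshold_a`, `threshold_b` — the latter `NA` for a
#'   single-score curve), `auc`, `n_pos`, `n_neg`, `type = "single"`.
#' @export
#' @examples
#' roc <- roc_curve(c(0.2, 0.4, 0.6, 0.8), c(FALSE, TRUE, FALSE, TRUE))
#' glance(roc)
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  check_two_classes(labels)
  taus <- c(sort(unique(scores), decreasing = TRUE), Inf)
  pts <- purrr::map_dfr(taus, function(tau) {
    pred <- scores >= tau
    tibble::tibble(
      fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels),
      threshold_a = tau,
      threshold_b = NA_real_
    )
  })
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  new_roc_frontier(pts, n_pos = sum(labels), n_neg = sum(!labels),
                   type = "single")
}

#' Dual-threshold OR-synergy ROC envelope
#'
#' For every pair of cutoffs `(tau_a, tau_b)` over the unique observed
#' values of each score (plus `+Inf`), the combined rule calls a case
#' positive when `score_a >= tau_a` OR `score_b >= tau_b`; a missing score
#' never contributes a positive. The returned frontier is the
#' Pareto-dominant upper-left set of the achievable (FPR, TPR) cloud, each
#' point annotated with one achieving threshold pair (the largest
#' `tau_a`, then largest `tau_b`, among achievers). The AUC is the
#' trapezoid over the frontier closed at (0,0) and (1,1).
#'
#' Cases missing both scores are excluded.
#'
#' @param scores_a,scores_b Numeric score vectors (e.g. AI and resident
#'   maximum CDR per patient); `NA` = not assessed.
#' @param labels Logical truth labels.
#' @return An object of class `roc_frontier` with `type = "synergy"`.
#' @export
synergy_roc <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & !(is.na(scores_a) & is.na(scores_b))
  a <- scores_a[keep]
  b <- scores_b[keep]
  labels <- labels[keep]
  check_two_classes(labels)
  # a missing score compares FALSE against every finite or infinite cutoff
  af <- ifelse(is.na(a), -Inf, a)
  bf <- ifelse(is.na(b), -Inf, b)
  taus_a <- c(sort(unique(a[!is.na(a)]), decreasing = TRUE), Inf)
  taus_b <- c(sort(unique(b[!is.na(b)]), decreasing = TRUE), Inf)
  # negA[i, k] = TRUE when case i is NOT called by cutoff k on score a
  negA <- outer(af, taus_a, `<`)
  negB <- outer(bf, taus_b, `<`)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  # OR-positive count = total - both-negative count, via cross products
  tp <- n_pos - crossprod(negA[labels, , drop = FALSE],
                          negB[labels, , drop = FALSE])
  fp <- n_neg - crossprod(negA[!labels, , drop = FALSE],
                          negB[!labels, , drop = FALSE])
  cloud <- tibble::tibble(
    fpr = as.vector(fp) / n_neg,
    tpr = as.vector(tp) / n_pos,
    threshold_a = rep(taus_a, times = length(taus_b)),
    threshold_b = rep(taus_b, each = length(taus_a))
  )
  pts <- pareto_frontier(cloud)
  new_roc_frontier(pts, n_pos = n_pos, n_neg = n_neg, type = "synergy")
}

# Pareto-dominant upper-left set of a (fpr, tpr) cloud; among points that
# tie on (fpr, tpr) the largest (threshold_a, threshold_b) is kept
pareto_frontier <- function(cloud) {
  cloud <- dplyr::arrange(cloud, .data$fpr, dplyr::desc(.data$tpr),
                          dplyr::desc(.data$threshold_a),
                          dplyr::desc(.data$threshold_b))
  cloud <- dplyr::distinct(cloud, .data$fpr, .data$tpr, .keep_all = TRUE)
  best <- -Inf
  keep <- logical(nrow(cloud))
  for (i in seq_len(nrow(cloud))) {
    if (cloud$tpr[i] > best) {
      keep[i] <- TRUE
      best <- cloud$tpr[i]
    }
  }
  cloud[keep, , drop = FALSE]
}

new_roc_frontier <- function(points, n_pos, n_neg, type) {
  pts <- dplyr::arrange(points, .data$fpr, .data$tpr)
  # close the curve for integration without duplicating existing corners
  xs <- c(0, pts$fpr, 1)
  ys <- c(0, pts$tpr, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg, type = type),
    class = "roc_frontier"
  )
}

check_two_classes <- function(labels) {
  if (length(labels) == 0 || !any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' @export
print.roc_frontier <- function(x, ...) {
  cat(sprintf("<roc_frontier> %s, %d points, AUC %.4f (%d pos / %d neg)\n",
              x$type, nrow(x$points), x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `roc_frontier`.
#' @param ... Unused.
#' @export
tidy.roc_frontier <- function(x, ...) x$points

#' @rdname roc_curve
#' @export
glance.roc_frontier <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 n_points = nrow(x$points), type = x$type)
}

#' @rdname roc_curve
#' @param object A `roc_frontier`.
#' @export
autoplot.roc_frontier <- function(object, ...) {
  pts <- object$points
  closed <- dplyr::bind_rows(
    tibble::tibble(fpr = 0, tpr = 0),
    pts[, c("fpr", "tpr")],
    tibble::tibble(fpr = 1, tpr = 1)
  )
  ggplot2::ggplot(closed, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = pts, size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s ROC (AUC = %.3f)",
                      if (object$type == "synergy") "OR-synergy" else
                        "Single-score", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Extract an operating point from a ROC frontier
#'
#' @param frontier A `roc_frontier`.
#' @param mode `"match_specificity"` (highest sensitivity among points with
#'   specificity at least `target`), `"match_sensitivity"` (highest
#'   specificity among points with sensitivity at least `target`), or
#'   `"max_f1"` (F1-optimal point given `prevalence`).
#' @param target Target specificity or sensitivity (ignored for
#'   `"max_f1"`).
#' @param prevalence Positive-class prevalence used to form PPV for
#'   `"max_f1"`; defaults to the frontier's own class balance.
#' @return One-row tibble `fpr`, `tpr`, `threshold_a`, `threshold_b`, plus
#'   `sensitivity`, `specificity` (and `f1` for `"max_f1"`).
#' @export
operating_point <- function(frontier,
                            mode = c("match_specificity", "match_sensitivity",
                                     "max_f1"),
                            target = NULL, prevalence = NULL) {
  stopifnot(inherits(frontier, "roc_frontier"))
  mode <- match.arg(mode)
  pts <- dplyr::bind_rows(
    frontier$points,
    # the trivial corners are always achievable
    tibble::tibble(fpr = c(0, 1), tpr = c(0, 1),
                   threshold_a = c(Inf, -Inf), threshold_b = c(Inf, -Inf))
  ) |>
    dplyr::distinct(.data$fpr, .data$tpr, .keep_all = TRUE)
  pts$sensitivity <- pts$tpr
  pts$specificity <- 1 - pts$fpr
  if (mode == "match_specificity") {
    stopifnot(!is.null(target))
    ok <- pts[pts$specificity >= target - 1e-12, , drop = FALSE]
    out <- ok[which.max(ok$tpr), , drop = FALSE]
    if (out$tpr == 0) {
      warning("no frontier point with positive sensitivity reaches ",
              "specificity ", target, "; returning (0, 0)", call. = FALSE)
    }
    return(tibble::as_tibble(out))
  }
  if (mode == "match_sensitivity") {
    stopifnot(!is.null(target))
    ok <- pts[pts$sensitivity >= target - 1e-12, , drop = FALSE]
    if (nrow(ok) == 0) stop("unreachable sensitivity target", call. = FALSE)
    return(tibble::as_tibble(ok[which.max(ok$specificity), , drop = FALSE]))
  }
  # max_f1
  pi <- prevalence %||% (frontier$n_pos / (frontier$n_pos + frontier$n_neg))
  stopifnot(pi > 0, pi < 1)
  den <- 2 * pi * pts$tpr + pi * (1 - pts$tpr) + (1 - pi) * pts$fpr
  pts$f1 <- ifelse(den == 0, NA_real_, 2 * pi * pts$tpr / den)
  tibble::as_tibble(pts[which.max(pts$f1), , drop = FALSE])
}
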