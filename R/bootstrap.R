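#' Bootstrap confidence interval for a classification metric
#'
#' Percentile bootstrap over resampled observation units (patients for
#' classification panels, eyes for CDR error panels). Undetermined
#' (`NA`) predictions must be filtered before calling. Resamples in which
#' the metric is undefined (zero denominator) are dropped; if more than
#' half of the resamples are undefined the call errors.
#'
#' @param data A data frame with logical columns named in `pred` and
#'   `truth`.
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"ppv"`, `"f1"`.
#' @param pred,truth Column names of prediction and truth.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf Confidence level for the percentile interval.
#' @return A list of class `boot_result` with `point`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `metric`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(pred = c(TRUE, TRUE, FALSE, FALSE),
#'                     truth = c(TRUE, FALSE, FALSE, TRUE))
#' bootstrap_metric(d, "accuracy", n_boot = 200, seed = 1)
bootstrap_metric <- function(data, metric, pred = "pred", truth = "truth",
                             n_boot = 2000, seed = 1, conf = 0.95) {
  check_boot_args(data, n_boot)
  p <- as.logical(data[[pred]])
  t <- as.logical(data[[truth]])
  stopifnot(!anyNA(p), !anyNA(t))
  point <- metric_value(p, t, metric)
  stats <- with_stream(as.integer(seed), {
    replicate(n_boot, {
      i <- sample.int(length(p), replace = TRUE)
      metric_value(p[i], t[i], metric)
    })
  })
  ok <- !is.na(stats)
  if (mean(ok) < 0.5) {
    stop("metric `", metric, "` undefined in more than half of the resamples",
         call. = FALSE)
  }
  q <- stats::quantile(stats[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 7)
  structure(
    list(point = point, ci_low = q[1], ci_high = q[2], p_value = NULL,
         n_boot = n_boot, seed = seed, metric = metric, n = length(p)),
    class = "boot_result"
  )
}

#' Paired bootstrap p-value for a metric difference between two raters
#'
#' Resamples patients jointly (preserving the pairing of the two raters'
#' predictions with the shared truth) and computes the two-sided p-value
#' for the difference `metric(rater_a) - metric(rater_b)`:
#' `p = 2 * min(frac(delta* <= 0), frac(delta* >= 0))`, ties counted on
#' both sides, clipped to `(1/n_boot, 1]`.
#'
#' @param data Data frame with logical prediction columns for both raters
#'   and a shared truth column.
#' @param metric Metric selector as in [bootstrap_metric()].
#' @param rater_a,rater_b Prediction column names.
#' @param truth Truth column name.
#' @inheritParams bootstrap_metric
#' @return A single p-value in `(0, 1]`.
#' @export
paired_bootstrap_pvalue <- function(data, metric, rater_a, rater_b,
                                    truth = "truth", n_boot = 2000, seed = 1) {
  check_boot_args(data, n_boot)
  pa <- as.logical(data[[rater_a]])
  pb <- as.logical(data[[rater_b]])
  t <- as.logical(data[[truth]])
  stopifnot(!anyNA(pa), !anyNA(pb), !anyNA(t))
  deltas <- with_stream(as.integer(seed), {
    replicate(n_boot, {
      i <- sample.int(length(t), replace = TRUE)
      metric_value(pa[i], t[i], metric) - metric_value(pb[i], t[i], metric)
    })
  })
  ok <- !is.na(deltas)
  if (mean(ok) < 0.5) {
    stop("metric `", metric, "` undefined in more than half of the resamples",
         call. = FALSE)
  }
  deltas <- deltas[ok]
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  min(max(p, 1 / n_boot), 1)
}

check_boot_args <- function(data, n_boot) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("`data` must be a non-empty data frame", call. = FALSE)
  }
  if (n_boot < 100) {
    stop("`n_boot` must be at least 100", call. = FALSE)
  }
}

metric_value <- function(pred, truth, metric) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  den <- switch(metric,
    accuracy = tp + fp + fn + tn,
    sensitivity = tp + fn,
    specificity = tn + fp,
    ppv = tp + fp,
    f1 = 2 * tp + fp + fn,
    stop("unknown metric `", metric, "`", call. = FALSE)
  )
  num <- switch(metric,
    accuracy = tp + tn,
    sensitivity = tp,
    specificity = tn,
    ppv = tp,
    f1 = 2 * tp
  )
  if (den == 0) NA_real_ else num / den
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("<boot_result> %s = %.4f [%.4f, %.4f] (n = %d, %d resamples)\n",
              x$metric, x$point, x$ci_low, x$ci_high, x$n, x$n_boot))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bootstrap_metric
#' @param x A `boot_result`.
#' @param ... Unused.
#' @export
tidy.boot_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, estimate = x$point,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname bootstrap_metric
#' @export
glance.boot_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, seed = x$seed)
}
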