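# Independent oracles used against the package implementations. These are
# deliberately written with a different mechanism than the production code
# (plain loops and domination filters instead of vectorized grids and
# sort-scan frontiers).

# AUC as the Mann-Whitney concordance fraction (ties counted half)
oracle_concordance_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# brute-force OR-synergy frontier: enumerate every threshold pair, collect
# the (fpr, tpr) cloud, and keep the non-dominated points
oracle_synergy_frontier <- function(a, b, labels) {
  keep <- !is.na(labels) & !(is.na(a) & is.na(b))
  a <- a[keep]
  b <- b[keep]
  labels <- labels[keep]
  ta <- c(sort(unique(a[!is.na(a)])), Inf)
  tb <- c(sort(unique(b[!is.na(b)])), Inf)
  pts <- matrix(NA_real_, length(ta) * length(tb), 2)
  k <- 0
  for (x in ta) {
    for (y in tb) {
      pred <- (!is.na(a) & a >= x) | (!is.na(b) & b >= y)
      k <- k + 1
      pts[k, ] <- c(sum(pred & !labels) / sum(!labels),
                    sum(pred & labels) / sum(labels))
    }
  }
  pts <- unique(pts)
  dominated <- apply(pts, 1, function(p) {
    any(pts[, 1] <= p[1] & pts[, 2] >= p[2] &
          (pts[, 1] < p[1] | pts[, 2] > p[2]))
  })
  out <- pts[!dominated, , drop = FALSE]
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# brute-force F1 over every candidate threshold
oracle_best_f1_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  f1 <- vapply(cand, function(tau) {
    pred <- scores >= tau
    tp <- sum(pred & labels)
    2 * tp / (2 * tp + sum(pred & !labels) + sum(!pred & labels))
  }, numeric(1))
  max(cand[f1 == max(f1)])
}

sens_spec <- function(pred, truth) {
  c(sens = sum(pred & truth) / sum(truth),
    spec = sum(!pred & !truth) / sum(!truth))
}

# noise-free degenerate configuration: every rater observes the truth
noise_free_config <- function(n, seed = 1) {
  sim_config(
    n_patients = n, seed = seed,
    expert_noise_sd = c(0, 0, 0),
    ai_bias = 0, ai_noise_sd = 0,
    resident_slope = 1, resident_bias = 0, resident_noise_sd = 0,
    gradability_rates = c(ai = 1, expert = 1, resident = 1),
    rater_operating_points = list(
      ai = list(sensitivity = c(mild = 1, medium = 1, high = 1),
                specificity = 1),
      resident = list(sensitivity = c(mild = 1, medium = 1, high = 1),
                      specificity = 1)
    ),
    ungradable_extra_sd = 0
  )
}
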