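test_that("confusion counts standard 2x2 cells", {
  cm <- confusion(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                  c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 2L, tn = 1L))

  agree <- confusion(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(agree$fp + agree$fn, 0L)
  flipped <- confusion(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(flipped$tp + flipped$tn, 0L)

  expect_error(confusion(c(TRUE, FALSE), TRUE), "equal length")
  expect_error(confusion(c(TRUE, NA), c(TRUE, TRUE)), "undetermined")
})

test_that("metric_set computes the five panel metrics with NA for empty denominators", {
  m <- metric_set(confusion_matrix(29, 11, 17, 188))
  expect_equal(m$sensitivity, 29 / 46)
  expect_equal(m$specificity, 188 / 199)
  expect_equal(m$accuracy, 217 / 245)
  expect_equal(m$ppv, 29 / 40)
  expect_equal(m$f1, 58 / 86)

  perfect <- metric_set(confusion_matrix(1, 0, 0, 1))
  expect_true(all(perfect == 1))
  degenerate <- metric_set(confusion_matrix(0, 0, 1, 1))
  expect_equal(degenerate$sensitivity, 0)
  expect_true(is.na(degenerate$ppv))
})

test_that("accuracy decomposes as prevalence-weighted sensitivity and specificity", {
  set.seed(41)
  for (i in 1:25) {
    cells <- rmultinom(1, size = sample(20:400, 1), prob = runif(4, 0.05, 1))
    cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    m <- metric_set(cm)
    prev <- (cm$tp + cm$fn) / (cm$tp + cm$fp + cm$fn + cm$tn)
    if (prev == 0 || prev == 1) next
    expect_equal(m$accuracy,
                 m$sensitivity * prev + m$specificity * (1 - prev))
  }
})

test_that("cohen_kappa and percent_agreement reproduce the published opacity table", {
  cm <- study_opacity_counts()
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 435L)
  expect_equal(round(cohen_kappa(cm), 3), 0.237)
  expect_equal(round(100 * percent_agreement(cm), 1), 86.0)
})

test_that("cohen_kappa endpoints behave", {
  expect_equal(cohen_kappa(confusion_matrix(50, 0, 0, 50)), 1)
  expect_equal(cohen_kappa(confusion_matrix(25, 25, 25, 25)), 0)
  expect_error(cohen_kappa(confusion_matrix(3, 0, 0, 0)), "undefined")
  set.seed(7)
  for (i in 1:25) {
    cells <- rmultinom(1, 200, runif(4, 0.05, 1))
    cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    k <- cohen_kappa(cm)
    expect_gte(k, -1)
    expect_lte(k, 1)
    both_classes <- (cm$tp + cm$fn) > 0 && (cm$fp + cm$tn) > 0
    if (both_classes) {
      expect_equal(k == 1, cm$fp == 0 && cm$fn == 0)
    }
  }
})

test_that("the glaucoma panel reconstructs uniquely from printed sensitivity/specificity", {
  gp <- study_glaucoma_panel()
  rec <- reconstruct_counts(
    gp$table[, c("approach", "sensitivity", "specificity")], n = gp$n
  )
  expect_true(rec$unique)
  expect_equal(rec$p, 46L)
  cms <- reconstructed_matrices(rec)
  expect_equal(unlist(unclass(cms$ai)), c(tp = 29L, fp = 11L, fn = 17L, tn = 188L))
  expect_equal(unlist(unclass(cms$resident)),
               c(tp = 23L, fp = 19L, fn = 23L, tn = 180L))
  expect_equal(unlist(unclass(cms$synergy)),
               c(tp = 37L, fp = 27L, fn = 9L, tn = 172L))
})

test_that("reconstructed cells round-trip every printed metric of the panel", {
  for (panel in list(study_glaucoma_panel(), study_retinal_panel())) {
    printed <- panel$table[, c("approach", "sensitivity", "specificity")]
    rec <- reconstruct_counts(printed, n = panel$n)
    cms <- reconstructed_matrices(rec)
    for (i in seq_len(nrow(panel$table))) {
      row <- panel$table[i, ]
      m <- metric_set(cms[[row$approach]])
      for (col in c("accuracy", "sensitivity", "specificity", "ppv", "f1")) {
        expect_equal(synopht:::round_half_up(100 * m[[col]], 1), row[[col]],
                     info = paste(row$approach, col))
      }
    }
  }
})

test_that("the retinal panel reconstructs uniquely with resident PPV/F1 tie-breakers", {
  rp <- study_retinal_panel()
  printed <- rp$table[, c("approach", "sensitivity", "specificity", "ppv", "f1")]
  printed$ppv[printed$approach != "resident"] <- NA
  printed$f1[printed$approach != "resident"] <- NA
  rec <- reconstruct_counts(printed, n = rp$n)
  expect_true(rec$unique)
  expect_equal(rec$p, 156L)
  cms <- reconstructed_matrices(rec)
  expect_equal(unlist(unclass(cms$ai)),
               c(tp = 119L, fp = 10L, fn = 37L, tn = 229L))
})

test_that("reconstruction reports infeasible printed values as an error", {
  expect_error(
    reconstruct_counts(tibble::tibble(approach = "x", sensitivity = 33.3),
                       n = 2),
    "no integer confusion matrices"
  )
})

test_that("bootstrap_metric is deterministic under seed and exact on degenerate data", {
  d <- tibble::tibble(pred = rep(c(TRUE, FALSE), 20),
                      truth = rep(c(TRUE, FALSE), 20))
  b1 <- bootstrap_metric(d, "sensitivity", n_boot = 300, seed = 5)
  b2 <- bootstrap_metric(d, "sensitivity", n_boot = 300, seed = 5)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_equal(c(b1$ci_low, b1$point, b1$ci_high), c(1, 1, 1))

  expect_error(bootstrap_metric(d, "accuracy", n_boot = 1), "at least 100")
  td <- tidy(b1)
  expect_named(td, c("metric", "estimate", "conf.low", "conf.high"))
})

test_that("bootstrap CI for sensitivity covers the generating value at nominal rate", {
  set.seed(2024)
  n <- 1000
  covered <- vapply(1:150, function(i) {
    truth <- runif(n) < 0.5
    pred <- ifelse(truth, runif(n) < 0.8, runif(n) < 0.1)
    b <- bootstrap_metric(tibble::tibble(pred = pred, truth = truth),
                          "sensitivity", n_boot = 200, seed = i)
    b$ci_low <= 0.8 && 0.8 <= b$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("paired bootstrap p-value is 1 for identical raters and detects strong differences", {
  d <- tibble::tibble(a = rep(c(TRUE, FALSE), 25),
                      b = rep(c(TRUE, FALSE), 25),
                      truth = rep(c(TRUE, TRUE, FALSE, FALSE), length.out = 50))
  expect_equal(
    paired_bootstrap_pvalue(d, "sensitivity", "a", "b", n_boot = 200, seed = 1),
    1
  )
  # strong alternative: sensitivity 0.9 vs 0.5 at n = 500
  set.seed(11)
  hits <- vapply(1:30, function(i) {
    truth <- runif(500) < 0.4
    a <- ifelse(truth, runif(500) < 0.9, runif(500) < 0.1)
    b <- ifelse(truth, runif(500) < 0.5, runif(500) < 0.1)
    paired_bootstrap_pvalue(tibble::tibble(a = a, b = b, truth = truth),
                            "sensitivity", "a", "b",
                            n_boot = 200, seed = i) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
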