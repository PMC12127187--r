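test_that("glaucoma_suspect applies the threshold and asymmetry clauses with quoted boundary semantics", {
  expect_true(glaucoma_suspect(0.65, 0.5))
  expect_true(glaucoma_suspect(0.3, 0.55))   # |diff| = 0.25 > 0.2
  expect_false(glaucoma_suspect(0.59, 0.59))
  expect_true(glaucoma_suspect(0.6, 0.6))    # threshold inclusive
  expect_false(glaucoma_suspect(0.4, 0.6 - 1e-9))
  expect_false(glaucoma_suspect(0.3, 0.5))   # diff exactly 0.2 is exclusive
  # one-eye patients use the available eye; no asymmetry possible
  expect_true(glaucoma_suspect(NA, 0.7))
  expect_false(glaucoma_suspect(0.5, NA))
  expect_true(is.na(glaucoma_suspect(NA, NA)))
  # asymmetry clause can be disabled (prediction mode)
  p <- suspect_params(0.6, use_asymmetry = FALSE)
  expect_false(glaucoma_suspect(0.3, 0.55, p))
  expect_error(glaucoma_suspect(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the threshold rule is monotone per eye; the full rule under joint shifts", {
  # the asymmetry clause is intentionally non-monotone in a single eye
  # (raising the lower eye can dissolve the inter-eye difference), so
  # per-eye monotonicity is a property of the threshold-only rule
  p <- suspect_params(0.6, use_asymmetry = FALSE)
  set.seed(13)
  for (i in 1:200) {
    r <- runif(1); l <- runif(1)
    bump <- runif(1, 0, 1 - max(r, l))
    base <- glaucoma_suspect(r, l, p)
    expect_false(isTRUE(base) && !glaucoma_suspect(min(r + bump, 1), l, p))
    expect_false(isTRUE(base) && !glaucoma_suspect(r, min(l + bump, 1), p))
    # the full rule never flips positive -> negative when both eyes rise
    # together (threshold clause monotone, asymmetry preserved)
    full <- glaucoma_suspect(r, l)
    expect_false(isTRUE(full) &&
                   !glaucoma_suspect(min(r + bump, 1), min(l + bump, 1)))
  }
})

test_that("patient_max_cdr takes the maximum over gradable eyes", {
  eyes <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c", "c"),
    cdr_ai = c(0.4, 0.7, NA, 0.5, NA, NA)
  )
  out <- patient_max_cdr(eyes, "ai")
  expect_equal(out$cdr_max, c(0.7, 0.5, NA))
  expect_error(patient_max_cdr(eyes, "gt"), "no column")
})

test_that("retinal_disease_positive counts any mapped disease and excludes tessellated fundus", {
  expect_true(retinal_disease_positive(list(right = "moderate_npdr")))
  expect_false(retinal_disease_positive(list(right = "tessellated_fundus")))
  expect_false(retinal_disease_positive(list(right = character(),
                                             left = character())))
  expect_true(retinal_disease_positive(list(right = "tessellated_fundus",
                                            left = "retinal_detachment")))
  expect_error(retinal_disease_positive(list(right = "dragon_pox")), "unknown")
})

test_that("risk_tier returns the highest tier and never lowers when findings are added", {
  expect_equal(as.character(risk_tier("retinal_detachment")), "high")
  expect_equal(as.character(risk_tier("mild_npdr")), "mild")
  expect_equal(as.character(risk_tier(character())), "none")
  labels <- names(default_risk_map())
  set.seed(3)
  for (i in 1:50) {
    base <- sample(labels, sample(0:4, 1))
    extra <- sample(labels, 1)
    expect_gte(as.integer(risk_tier(c(base, extra))),
               as.integer(risk_tier(base)))
  }
  expect_error(risk_tier("not_a_finding"), "unmapped")
})

test_that("media_opacity fires on the full conjunction only", {
  expect_true(media_opacity(62, "blurry_vision", any_gradable_image = FALSE))
  expect_false(media_opacity(62, "blurry_vision", any_gradable_image = TRUE))
  expect_false(media_opacity(45, "blurry_vision", any_gradable_image = FALSE))
  expect_false(media_opacity(62, "night_difficulty", any_gradable_image = FALSE))
  expect_true(media_opacity(60, "blurry_vision", any_gradable_image = FALSE))
  # vectorized over a symptom table
  df <- tibble::tibble(blurry_vision = c(TRUE, TRUE, FALSE),
                       color_change = FALSE, light_sensitivity = FALSE,
                       night_difficulty = FALSE)
  expect_equal(media_opacity(c(70, 70, 70), df, c(FALSE, TRUE, FALSE)),
               c(TRUE, FALSE, FALSE))
})

test_that("synergy_or follows OR semantics with undetermined propagation", {
  expect_true(synergy_or(TRUE, FALSE))
  expect_false(synergy_or(FALSE, FALSE))
  expect_false(synergy_or(NA, FALSE))     # the available rater decides
  expect_true(synergy_or(NA, TRUE))
  expect_true(is.na(synergy_or(NA, NA)))
  expect_equal(synergy_or(c(TRUE, FALSE, NA), c(FALSE, NA, NA)),
               c(TRUE, FALSE, NA))
})

test_that("OR-combination dominates its components in sensitivity and trails in specificity", {
  set.seed(29)
  for (i in 1:30) {
    n <- 100
    truth <- runif(n) < 0.3
    a <- ifelse(truth, runif(n) < 0.7, runif(n) < 0.1)
    b <- ifelse(truth, runif(n) < 0.5, runif(n) < 0.2)
    both <- synergy_or(a, b)
    ss_a <- sens_spec(a, truth)
    ss_b <- sens_spec(b, truth)
    ss_or <- sens_spec(both, truth)
    expect_gte(ss_or["sens"], max(ss_a["sens"], ss_b["sens"]))
    expect_lte(ss_or["spec"], min(ss_a["spec"], ss_b["spec"]))
  }
})

test_that("optimize_threshold_f1 matches brute force and breaks ties high", {
  expect_equal(optimize_threshold_f1(c(0.2, 0.7), c(FALSE, TRUE))$threshold,
               0.7)
  expect_error(optimize_threshold_f1(c(0.2, 0.7), c(TRUE, TRUE)),
               "both classes")
  toy <- list(scores = c(0.1, 0.3, 0.5, 0.55, 0.6, 0.9),
              labels = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(optimize_threshold_f1(toy$scores, toy$labels)$threshold,
               oracle_best_f1_threshold(toy$scores, toy$labels))
  expect_equal(optimize_threshold_f1(toy$scores, toy$labels)$threshold, 0.55)
  set.seed(19)
  for (i in 1:25) {
    s <- round(runif(30), 1)
    l <- runif(30) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(optimize_threshold_f1(s, l)$threshold,
                 oracle_best_f1_threshold(s, l))
  }
})
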