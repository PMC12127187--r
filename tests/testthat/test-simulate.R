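test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(-1), "non-negative integer")
  expect_error(sim_config(10, cdr_bounds = c(0.5, 0.4)), "interval")
  expect_error(sim_config(10, disease_prevalence =
                            c(none = 0.5, mild = 0.2, medium = 0.2, high = 0.2)),
               "sum to 1")
  expect_error(sim_config(10, gradability_rates =
                            c(ai = 0.9, expert = 0.5, resident = 0.95)),
               "nested")
  expect_error(sim_config(10, eye_correlation = 1.2), "eye_correlation")
})

test_that("an empty cohort is allowed and empty", {
  co <- simulate_cohort(sim_config(0))
  expect_equal(nrow(co$eyes), 0)
  expect_equal(nrow(co$patients), 0)
})

test_that("with all noise off every rater observes the true CDR", {
  co <- simulate_cohort(noise_free_config(200))
  eyes <- co$eyes
  for (col in c("cdr_expert_1", "cdr_expert_2", "cdr_expert_3", "cdr_gt",
                "cdr_ai", "cdr_resident", "cdr_ai_nogate")) {
    expect_equal(eyes[[col]], eyes$cdr_true, info = col)
  }
})

test_that("cohorts are bit-identical under the same seed and differ across seeds", {
  a <- simulate_cohort(sim_config(150, seed = 42))
  b <- simulate_cohort(sim_config(150, seed = 42))
  expect_identical(a$eyes, b$eyes)
  expect_identical(a$patients, b$patients)
  c <- simulate_cohort(sim_config(150, seed = 43))
  expect_false(identical(a$eyes, c$eyes))
})

test_that("emitted records respect range, missingness and nesting invariants", {
  for (seed in 1:3) {
    co <- simulate_cohort(sim_config(400, seed = seed))
    eyes <- co$eyes
    cdr_cols <- c("cdr_true", "cdr_expert_1", "cdr_expert_2", "cdr_expert_3",
                  "cdr_gt", "cdr_ai", "cdr_resident", "cdr_ai_nogate")
    for (col in cdr_cols) {
      vals <- eyes[[col]]
      expect_false(any(is.nan(vals)))
      expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
    }
    # missing estimate <=> gradability flag false
    expect_identical(is.na(eyes$cdr_ai), !eyes$gradable_ai)
    expect_identical(is.na(eyes$cdr_resident), !eyes$gradable_resident)
    expect_identical(is.na(eyes$cdr_gt), !eyes$gradable_expert)
    # cdr_gt is the expert mean exactly where present
    present <- eyes$gradable_expert
    expect_equal(eyes$cdr_gt[present],
                 rowMeans(eyes[present, c("cdr_expert_1", "cdr_expert_2",
                                          "cdr_expert_3")]))
    # nested gradability ordering
    expect_true(all(!eyes$gradable_ai | eyes$gradable_expert))
    expect_true(all(!eyes$gradable_expert | eyes$gradable_resident))
    expect_false(anyNA(co$patients$age))
    expect_true(all(co$patients$age > 0))
  }
})

test_that("gradability marginals match configured rates at n = 10,000 eyes", {
  co <- simulate_cohort(sim_config(5000, seed = 9))
  rates <- co$config$gradability_rates
  expect_lt(abs(mean(co$eyes$gradable_ai) - rates[["ai"]]), 0.015)
  expect_lt(abs(mean(co$eyes$gradable_expert) - rates[["expert"]]), 0.015)
  expect_lt(abs(mean(co$eyes$gradable_resident) - rates[["resident"]]), 0.015)
})

test_that("deterministic tier assignment reproduces the published panel counts", {
  co <- simulate_tiered_cohort(sim_config(395, seed = 1), deterministic = TRUE)
  counts <- table(co$patients$disease_tier_true)
  expect_equal(as.integer(counts[c("none", "mild", "medium", "high")]),
               c(239L, 75L, 40L, 41L))
  # positives total and tier make-up mirror the 156:81:41 structure
  expect_equal(sum(counts[c("mild", "medium", "high")]), 156)
  expect_equal(sum(counts[c("medium", "high")]), 81)
})

test_that("sampled tiers stay within 3 binomial standard errors of the prevalences", {
  co <- simulate_tiered_cohort(sim_config(3950, seed = 7), deterministic = FALSE)
  prev <- co$config$disease_prevalence
  emp <- prop.table(table(co$patients$disease_tier_true))
  for (tier in names(prev)) {
    se <- sqrt(prev[[tier]] * (1 - prev[[tier]]) / 3950)
    expect_lt(abs(emp[[tier]] - prev[[tier]]), 3 * se)
  }
})

test_that("per-tier sensitivity 1 yields no false-negative disease calls", {
  cfg <- sim_config(
    600, seed = 2,
    rater_operating_points = list(
      ai = list(sensitivity = c(mild = 1, medium = 1, high = 1),
                specificity = 229 / 239),
      resident = list(sensitivity = c(mild = 1, medium = 1, high = 1),
                      specificity = 216 / 239)
    )
  )
  co <- simulate_cohort(cfg)
  diseased <- co$patients$disease_tier_true != "none"
  called <- !is.na(co$patients$disease_pos_ai)
  expect_true(all(co$patients$disease_pos_ai[diseased & called]))
  called_r <- !is.na(co$patients$disease_pos_resident)
  expect_true(all(co$patients$disease_pos_resident[diseased & called_r]))
})

test_that("cohorts round-trip through CSV and configs through YAML", {
  co <- simulate_cohort(sim_config(80, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$eyes), as.data.frame(co$eyes))
  expect_equal(as.data.frame(back$patients), as.data.frame(co$patients))

  cfg_path <- file.path(dir, "config.yaml")
  write_sim_config(co$config, cfg_path)
  cfg2 <- read_sim_config(cfg_path)
  co2 <- simulate_cohort(cfg2)
  expect_identical(co2$eyes, co$eyes)

  # schema violations are reported with row context
  eyes_bad <- co$eyes
  eyes_bad$cdr_ai[1] <- 1.7
  eyes_bad$gradable_ai[1] <- TRUE
  readr::write_csv(eyes_bad, file.path(dir, "eyes.csv"), na = "NA")
  expect_error(read_cohort(dir), "outside \\[0,1\\]")
})

test_that("adding draws for one field group does not perturb the others", {
  # the truth stream is the first group: cohorts with different gradability
  # settings must still share identical true CDRs
  a <- simulate_cohort(sim_config(100, seed = 6))
  b <- simulate_cohort(sim_config(100, seed = 6, nested_gradability = FALSE))
  expect_identical(a$eyes$cdr_true, b$eyes$cdr_true)
  expect_identical(a$eyes$cdr_expert_1[a$eyes$gradable_expert &
                                         b$eyes$gradable_expert],
                   b$eyes$cdr_expert_1[a$eyes$gradable_expert &
                                         b$eyes$gradable_expert])
})
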