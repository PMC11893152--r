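# shared moderate cohort: nonzero arm-A effect, null arm-B, no interaction
shared_co <- small_test_cohort(n = 6000, seed = 101, hr50_a = 0.8)

test_that("per-50 hazard ratio is internally consistent with its Cox fit", {
  h <- per50_hr(shared_co, shared_co$scores$lpa, "cvd")
  b <- h$fit$coefficients[["score"]]
  expect_equal(h$hr, exp(-50 * b), tolerance = 1e-12)
  expect_lte(h$ci_low, h$hr); expect_lte(h$hr, h$ci_high)
  expect_gt(h$ci_low, 0)
  expect_equal(h$n_events, sum(shared_co$data$event_cvd))
})

test_that("per-50 reporting is invariant to flipping the score orientation", {
  h1 <- per50_hr(shared_co, shared_co$scores$lpa, "cvd")
  h2 <- per50_hr(shared_co, flip_score(shared_co$scores$lpa), "cvd")
  expect_equal(h1$hr, h2$hr, tolerance = 1e-9)
  expect_equal(h1$ci_low, h2$ci_low, tolerance = 1e-9)
})

test_that("non-lipid arms are refused the mg/dL scale and get per-SD reporting", {
  s_bmi <- structure(rnorm(6000), trait = "bmi", units = "kg/m2",
                     orientation = "trait-increasing",
                     class = "score_vector")
  expect_error(per50_hr(shared_co, s_bmi, "cvd"), "per_sd_hr")
  h <- per_sd_hr(shared_co, s_bmi, "cvd")
  expect_equal(h$scale, "per SD decrease")
  expect_gt(h$ci_high, h$ci_low)
})

test_that("null-generator contrasts stay within 3 SE of no effect", {
  co <- small_test_cohort(n = 6000, seed = 102)  # both arms null
  alloc <- allocate_factorial(co$scores$lpa, co$scores$ldlr)
  fc <- factorial_contrasts(co, alloc, "cvd")
  tf <- tidy_fit(fc$fit)
  grp <- tf[tf$term %in% c("lowerA_only", "lowerB_only", "both_lower"), ]
  expect_true(all(abs(grp$estimate) < 3 * grp$se))

  it <- interaction_test(co, co$scores$lpa, co$scores$ldlr, "cvd")
  expect_lt(abs(it$product_coefficient), 3 * it$se)
})

test_that("factorial output schema has four rows with the reference first", {
  alloc <- allocate_factorial(shared_co$scores$lpa, shared_co$scores$ldlr)
  fc <- factorial_contrasts(shared_co, alloc, "cvd")
  expect_equal(nrow(fc$table), 4L)
  expect_equal(fc$table$group[1], "both_higher")
  expect_equal(fc$table$hr[1], 1)
  expect_equal(sum(fc$table$n), 6000)
  expect_equal(sum(fc$table$n_events), sum(shared_co$data$event_cvd))
  # identical scores leave two cells empty -> error
  expect_error(
    factorial_contrasts(shared_co,
                        allocate_factorial(shared_co$scores$lpa,
                                           shared_co$scores$lpa), "cvd"),
    "empty")
})

test_that("interaction test rejects degenerate scores", {
  expect_error(interaction_test(shared_co, rep(1, 6000),
                                shared_co$scores$ldlr, "cvd"), "constant")
})

test_that("biomarker median-split contrast matches its brute-force expectation", {
  w <- bundled_weights("lpa")
  cfg <- cohort_config(n = 20000, seed = 103, scores = w,
                       outcomes = default_outcomes("lpa"))
  co <- generate_cohort(cfg)
  a <- biomarker_association(co, co$scores$lpa, "lpa")
  # brute-force expectation of the lower-vs-higher score contrast from the
  # generating parameters alone (independent large-sample enumeration)
  set.seed(9001)
  sims <- as.numeric(
    generate_genotypes(setNames(w$lpa$eaf, w$lpa$variant_id), 200000,
                       seed = 77) %*% w$lpa$beta)
  med <- median(sims)
  expected <- mean(sims[sims <= med]) - mean(sims[sims > med])
  expect_lt(abs(a$contrast$estimate - expected), 3 * a$contrast$se)
  expect_lt(a$contrast$estimate, 0)
})

test_that("an Lp(a)-like arm reproduces the qualitative cross-trait pattern", {
  cfg <- cohort_config(n = 20000, seed = 104,
                       scores = bundled_weights(c("lpa", "hmgcr")),
                       outcomes = default_outcomes(c("lpa", "hmgcr")))
  co <- generate_cohort(cfg)
  lpa_lpa <- biomarker_association(co, co$scores$lpa, "lpa")$contrast
  lpa_ldl <- biomarker_association(co, co$scores$lpa, "ldl_c")$contrast
  lpa_tg <- biomarker_association(co, co$scores$lpa, "tg")$contrast
  hm_ldl <- biomarker_association(co, co$scores$hmgcr, "ldl_c")$contrast
  hm_lpa <- biomarker_association(co, co$scores$hmgcr, "lpa")$contrast
  # the Lp(a) arm lowers measured Lp(a) strongly, LDL-C weakly, raises TG
  expect_lt(lpa_lpa$ci_high, 0)
  expect_lt(lpa_ldl$estimate, 0)
  expect_gt(abs(lpa_lpa$estimate), 5 * abs(lpa_ldl$estimate))
  expect_gt(lpa_tg$estimate, 0)
  # the LDL-C arm lowers LDL-C but not Lp(a)
  expect_lt(hm_ldl$ci_high, 0)
  expect_lt(abs(hm_lpa$estimate), 3 * hm_lpa$se)
})

test_that("composite outcomes follow the first-event rule", {
  co <- small_test_cohort(n = 300, seed = 105)
  # hand case on a two-row cohort patch
  co$data$time_a <- c(2, 5, rep(6, 298)); co$data$event_a <- c(1L, 0L, rep(0L, 298))
  co$data$time_b <- c(5, 5, rep(1, 298)); co$data$event_b <- c(0L, 0L, rep(1L, 298))
  co2 <- composite_outcome(co, c("a", "b"), "comp")
  expect_equal(co2$data$time_comp[1], 2)
  expect_equal(co2$data$event_comp[1], 1L)
  # all components censored -> censored at the shortest component horizon
  expect_equal(co2$data$event_comp[2], 0L)
  expect_equal(co2$data$time_comp[2], 5)
  # composite events >= max of component events
  expect_gte(sum(co2$data$event_comp),
             max(sum(co2$data$event_a), sum(co2$data$event_b)))
  expect_error(composite_outcome(co, "a", "x"), "at least 2")
  expect_error(composite_outcome(co, c("a", "zzz"), "x"), "not present")
})

test_that("analysis results are invariant to cohort row order", {
  co <- shared_co
  set.seed(106)
  perm <- sample(nrow(co$data))
  co_p <- co
  co_p$data <- co$data[perm, ]
  co_p$scores <- lapply(co$scores, function(s) {
    structure(as.numeric(s)[perm], trait = attr(s, "trait"),
              units = attr(s, "units"),
              orientation = attr(s, "orientation"),
              class = "score_vector")
  })
  h1 <- per50_hr(co, co$scores$lpa, "cvd")
  h2 <- per50_hr(co_p, co_p$scores$lpa, "cvd")
  expect_equal(h1$hr, h2$hr, tolerance = 1e-9)
  it1 <- interaction_test(co, co$scores$lpa, co$scores$ldlr, "cvd")
  it2 <- interaction_test(co_p, co_p$scores$lpa, co_p$scores$ldlr, "cvd")
  expect_equal(it1$p_interaction, it2$p_interaction, tolerance = 1e-9)
})
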