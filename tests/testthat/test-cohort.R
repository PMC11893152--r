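one_variant_weights <- function(beta = 3, trait = "lpa")
  validate_weights(data.frame(variant_id = "rs1", effect_allele = "A",
                              eaf = 0.5, beta = beta, trait = trait))

test_that("noise-free biomarkers are exact affine functions of the score", {
  w <- list(s = one_variant_weights(beta = 3))
  dos <- list(s = matrix(c(0L, 1L, 2L), 3, 1,
                         dimnames = list(NULL, "rs1")))
  bio_spec <- data.frame(biomarker = "lpa", mean = 20, noise_sd = 0)
  load <- data.frame(score = "s", biomarker = "lpa", coef = 1)
  b <- generate_biomarkers(dos, w, load, bio_spec, seed = 1)
  intercept <- 20 - expected_score_mean(w$s)
  expect_equal(b$lpa, intercept + c(0, 3, 6))
  expect_equal(b$lpa[3] - intercept, 6)
  expect_error(
    generate_biomarkers(dos, w, load,
                        data.frame(biomarker = "lpa", mean = 0,
                                   noise_sd = -1), 1),
    "noise_sd")
})

test_that("a negative pleiotropy loading produces the opposed biomarker pattern", {
  cfg <- cohort_config(
    n = 5000, seed = 2, scores = bundled_weights("lpa"),
    loadings = rbind(default_loadings()[1:3, ]),
    outcomes = default_outcomes("lpa"))
  co <- generate_cohort(cfg)
  s <- as.numeric(co$scores$lpa)
  expect_gt(cor(s, co$data$lpa), 0.5)   # score raises its own trait
  expect_lt(cor(s, co$data$tg), 0)      # and lowers TG (negative loading)
})

test_that("regressing a generated biomarker on the true score recovers slope 1", {
  cfg <- cohort_config(n = 20000, seed = 3, scores = bundled_weights("lpa"),
                       outcomes = default_outcomes("lpa"))
  co <- generate_cohort(cfg)
  f <- fit_linear(co$data$lpa,
                  cbind(intercept = 1, score = as.numeric(co$scores$lpa)))
  expect_lt(abs(f$coefficients[["score"]] - 1), 3 * f$se[["score"]])
})

test_that("with no effects the event proportion matches the exponential closed form", {
  w <- list(s = one_variant_weights())
  cfg <- cohort_config(
    n = 20000, seed = 4, scores = w,
    biomarkers = data.frame(biomarker = character(), mean = numeric(),
                            noise_sd = numeric()),
    loadings = data.frame(score = character(), biomarker = character(),
                          coef = numeric()),
    outcomes = list(ev = list(baseline_hazard = 0.02,
                              log_hr = list(s = 0))),
    covariate_log_hr = list(age = 0, sex = 0, pc = 0,
                            center_amplitude = 0),
    admin_censor_time = 10)
  co <- generate_cohort(cfg)
  p_expect <- 1 - exp(-0.02 * 10)
  se <- sqrt(p_expect * (1 - p_expect) / 20000)
  expect_lt(abs(mean(co$data$event_ev) - p_expect), 3 * se)
  expect_true(all(co$data$time_ev > 0))
  expect_true(all(co$data$time_ev[co$data$event_ev == 1] <= 10))
})

test_that("a protective score effect lowers event rates above the median", {
  co <- generate_cohort(sim_config(n = 20000, seed = 5, hr50_a = 0.6))
  grp <- dichotomize(as.numeric(co$scores$lpa))
  # trait-increasing score with HR < 1 per decrease: higher score = higher risk
  expect_gt(mean(co$data$event_cvd[grp == "higher"]),
            mean(co$data$event_cvd[grp == "lower"]))
})

test_that("default covariate and biomarker distributions match their targets", {
  cfg <- cohort_config(n = 50000, seed = 6, scores = bundled_weights("lpa"),
                       outcomes = default_outcomes("lpa"))
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$data$age) - 56.7), 0.2)
  expect_lt(abs(mean(co$data$lpa) - 17.6), 0.3)
  expect_lt(abs(mean(co$data$sex) - 0.46), 0.01)
  expect_true(all(co$data$center %in% 1:22))
})

test_that("the ground-truth sidecar round-trips the configuration exactly", {
  cfg <- sim_config(n = 500, seed = 9, hr50_a = 0.73,
                    interaction_log_hr = 0.05)
  co <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_truth(file.path(d, "cohort_truth.json"))
  expect_identical(back, cfg)
})

test_that("cohort files are byte-identical under a fixed seed", {
  cfg <- sim_config(n = 300, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  expect_identical(readLines(file.path(d1, "cohort.tsv")),
                   readLines(file.path(d2, "cohort.tsv")))
  expect_identical(readLines(file.path(d1, "cohort_truth.json")),
                   readLines(file.path(d2, "cohort_truth.json")))
  back <- read_cohort(d1)
  expect_equal(back$data$age, generate_cohort(cfg)$data$age,
               tolerance = 1e-12)
  expect_identical(back$dosages$lpa, generate_cohort(cfg)$dosages$lpa)
})

test_that("a non-finite linear predictor names the offending individuals", {
  w <- list(s = one_variant_weights())
  covs <- data.frame(age = c(50, 60), sex = c(0, 1), center = c(1, 1),
                     pc1 = 0)
  cfg <- sim_config(n = 2, seed = 1)
  expect_error(
    generate_survival(list(lpa = c(1, NaN), ldlr = c(0, 0)), covs, cfg, 1),
    "non-finite linear predictor.*2")
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(cohort_config(n = 1), "at least 2")
  expect_error(sim_config(n = 100, baseline_hazard = -1), "baseline_hazard")
  expect_error(cohort_config(n = 10, scores = bundled_weights("lpa"),
                             outcomes = list(x = list(baseline_hazard = 1,
                                                      log_hr = list(zzz = 1)))),
               "unknown")
  expect_error(cohort_config(n = 10, scores = bundled_weights("lpa"),
                             admin_censor_time = 0), "admin_censor_time")
})
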