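#' Default biomarker specification for the synthetic cohort
#'
#' Seven blood lipids and lipoproteins with population means matching a
#' large mid-life European cohort and residual noise chosen so that total
#' variances are realistic once the genetic-score contribution is added
#' (e.g. Lp(a): mean 17.6 mg/dL, genetic SD about 17 plus noise SD 10 gives
#' a total SD near 19.7).
#'
#' @return data.frame with columns `biomarker`, `mean`, `noise_sd`.
#' @export
default_biomarkers <- function() {
  data.frame(
    biomarker = c("lpa", "ldl_c", "hdl_c", "tc", "tg", "apob", "apoa"),
    mean = c(17.6, 138.0, 56.2, 220.8, 154.9, 103.4, 154.2),
    noise_sd = c(10.0, 32.0, 14.8, 43.0, 90.0, 23.0, 27.1)
  )
}

#' Default score-to-biomarker loading matrix
#'
#' Long-format pleiotropy map: each row says that one trait unit of a
#' genetic score moves a measured biomarker by `coef` of its units. The
#' identity loadings (each lipid score onto its own lipid) carry the main
#' signal; the Lp(a)-score cross-loadings onto LDL-C (positive, small) and
#' triglycerides (negative) emulate the measured cross-trait pattern of
#' LPA-region variants.
#'
#' @return data.frame with columns `score`, `biomarker`, `coef`.
#' @export
default_loadings <- function() {
  rbind(
    data.frame(score = "lpa", biomarker = c("lpa", "ldl_c", "tg"),
               coef = c(1.0, 0.0523, -0.1198)),
    data.frame(score = c("hmgcr", "npc1l1", "pcsk9", "ldlr", "ldl_overall"),
               biomarker = "ldl_c", coef = 1.0),
    data.frame(score = c("hmgcr", "npc1l1", "pcsk9", "ldlr", "ldl_overall"),
               biomarker = "tc", coef = 1.0),
    data.frame(score = c("hmgcr", "npc1l1", "pcsk9", "ldlr", "ldl_overall"),
               biomarker = "apob", coef = 0.6)
  )
}

#' Default survival-outcome specification
#'
#' Cardiovascular endpoints generated from an exponential
#' proportional-hazards model. Baseline hazards are set so that 12-year
#' cumulative incidences land in the 4-12% range -- deliberately inflated
#' relative to a real mid-life cohort so that moderate sample sizes carry
#' adequate events. Score effects are per trait unit (per mg/dL for
#' lipids), oriented so a trait-increasing score raises hazard; e.g. the
#' Lp(a)-score effect on peripheral artery disease corresponds to a hazard
#' ratio of 0.73 per 50-mg/dL decrease.
#'
#' @param scores character vector of score labels present in the cohort;
#'   effects for absent scores are dropped.
#' @return named list, one element per outcome, each a list with
#'   `baseline_hazard` (events per person-year), `log_hr` (named list, per
#'   trait unit) and `interaction` (`NULL` or
#'   `list(scores = c(a, b), log_hr = x)` on the product of the two
#'   standardized scores).
#' @export
default_outcomes <- function(scores = NULL) {
  hr50 <- function(x) -log(x) / 50   # per-mg/dL log-HR from a per-50 HR
  out <- list(
    cad = list(baseline_hazard = 0.0107,
               log_hr = list(lpa = hr50(0.85), hmgcr = hr50(0.75),
                             npc1l1 = hr50(0.75), pcsk9 = hr50(0.75),
                             ldlr = hr50(0.75), ldl_overall = hr50(0.75),
                             bmi = 0.05, sbp = 0.02, smoking = 0.30,
                             alcohol = 0.01, activity = -0.30)),
    pad = list(baseline_hazard = 0.0043,
               log_hr = list(lpa = hr50(0.73), hmgcr = hr50(0.85),
                             npc1l1 = hr50(0.85), pcsk9 = hr50(0.85),
                             ldlr = hr50(0.85), ldl_overall = hr50(0.85),
                             bmi = 0.04, sbp = 0.02, smoking = 0.45,
                             alcohol = 0.01, activity = -0.25)),
    stroke = list(baseline_hazard = 0.0052,
                  log_hr = list(lpa = hr50(0.90), hmgcr = hr50(0.90),
                                npc1l1 = hr50(0.90), pcsk9 = hr50(0.90),
                                ldlr = hr50(0.90), ldl_overall = hr50(0.90),
                                bmi = 0.03, sbp = 0.03, smoking = 0.25,
                                alcohol = 0.01, activity = -0.20)),
    vte = list(baseline_hazard = 0.0034,
               log_hr = list(lpa = hr50(0.95))),
    hf = list(baseline_hazard = 0.0043,
              log_hr = list(lpa = hr50(0.93), bmi = 0.08, sbp = 0.02)),
    cvd_death = list(baseline_hazard = 0.0052,
                     log_hr = list(lpa = hr50(0.85), hmgcr = hr50(0.85),
                                   npc1l1 = hr50(0.85), pcsk9 = hr50(0.85),
                                   ldlr = hr50(0.85), ldl_overall = hr50(0.85),
                                   bmi = 0.05, sbp = 0.03, smoking = 0.50,
                                   alcohol = 0.02, activity = -0.30))
  )
  if (!is.null(scores))
    out <- lapply(out, function(o) {
      o$log_hr <- o$log_hr[intersect(names(o$log_hr), scores)]
      o
    })
  out
}

#' Generator configuration for a synthetic factorial-MR cohort
#'
#' Encodes the full data-generating process: Hardy-Weinberg genotypes for
#' independent (clumped) variants, weighted-score-driven biomarkers with
#' optional cross-trait pleiotropy, standard epidemiological covariates,
#' and exponentially distributed event times under proportional hazards
#' with administrative censoring. Every parameter is recorded in the
#' ground-truth sidecar written next to a generated cohort.
#'
#' @param n number of individuals.
#' @param seed master seed; every component derives a substream from it.
#' @param scores named list of `weight_table`s (default: the bundled
#'   fixture tables, see [bundled_weights()]).
#' @param age_mean,age_sd age distribution in years.
#' @param p_male probability of male sex (sex coded 1 = male, 0 = female).
#' @param n_centers number of assessment centers (uniform categorical).
#' @param n_pcs number of genetic principal components (standard normal).
#' @param biomarkers data.frame as [default_biomarkers()].
#' @param loadings data.frame as [default_loadings()]; rows whose score is
#'   not in `scores` are dropped.
#' @param outcomes named list as [default_outcomes()].
#' @param covariate_log_hr list with `age` (per year, age centered),
#'   `sex`, `pc` (per PC unit) and `center_amplitude` (spread of fixed
#'   center effects); small nonzero defaults so covariate adjustment is
#'   exercised, not vacuous.
#' @param admin_censor_time administrative censoring horizon in years.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n = 20000, seed = 1, scores = bundled_weights(),
                          age_mean = 56.7, age_sd = 8.0, p_male = 0.46,
                          n_centers = 22, n_pcs = 10,
                          biomarkers = default_biomarkers(),
                          loadings = default_loadings(),
                          outcomes = default_outcomes(names(scores)),
                          covariate_log_hr = list(age = 0.02, sex = 0.15,
                                                  pc = 0.02,
                                                  center_amplitude = 0.05),
                          admin_censor_time = 12) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed), scores = scores,
              age_mean = as.numeric(age_mean), age_sd = as.numeric(age_sd),
              p_male = as.numeric(p_male), n_centers = as.integer(n_centers),
              n_pcs = as.integer(n_pcs), biomarkers = biomarkers,
              loadings = loadings, outcomes = outcomes,
              covariate_log_hr = covariate_log_hr,
              admin_censor_time = as.numeric(admin_censor_time))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n < 2) stop2("n must be at least 2")
  if (!length(cfg$scores) || is.null(names(cfg$scores)))
    stop2("scores must be a non-empty named list of weight tables")
  for (nm in names(cfg$scores)) {
    cfg$scores[[nm]] <- validate_weights(as.data.frame(cfg$scores[[nm]]),
                                         paste0("score '", nm, "'"))
    if (nrow(cfg$scores[[nm]]) == 0) stop2("score '", nm, "' has no variants")
  }
  if (cfg$age_sd <= 0) stop2("age_sd must be > 0")
  check_prob(cfg$p_male, "p_male")
  if (cfg$n_centers < 1) stop2("n_centers must be >= 1")
  if (any(cfg$biomarkers$noise_sd < 0)) stop2("biomarker noise_sd must be >= 0")
  cfg$loadings <- cfg$loadings[cfg$loadings$score %in% names(cfg$scores), ,
                               drop = FALSE]
  bad_bio <- setdiff(cfg$loadings$biomarker, cfg$biomarkers$biomarker)
  if (length(bad_bio)) stop2("loadings refer to unknown biomarker(s): ",
                             paste(bad_bio, collapse = ", "))
  if (!length(cfg$outcomes) || is.null(names(cfg$outcomes)))
    stop2("outcomes must be a non-empty named list")
  for (nm in names(cfg$outcomes)) {
    o <- cfg$outcomes[[nm]]
    if (is.null(o$baseline_hazard) || o$baseline_hazard <= 0)
      stop2("outcome '", nm, "': baseline_hazard must be > 0")
    bad <- setdiff(names(o$log_hr), names(cfg$scores))
    if (length(bad)) stop2("outcome '", nm, "': log_hr names unknown: ",
                           paste(bad, collapse = ", "))
    if (!is.null(o$interaction)) {
      if (length(o$interaction$scores) != 2 ||
          !all(o$interaction$scores %in% names(cfg$scores)))
        stop2("outcome '", nm, "': interaction must name two known scores")
    }
  }
  if (cfg$admin_censor_time <= 0) stop2("admin_censor_time must be > 0")
  structure(cfg, class = "cohort_config")
}

#' Hardy-Weinberg genotype dosages for independent variants
#'
#' Each dosage is drawn Binomial(2, freq) independently across variants and
#' individuals, matching clumped instruments in weak linkage
#' disequilibrium.
#'
#' @param freqs named vector of effect-allele frequencies in (0, 1).
#' @param n number of individuals.
#' @param seed integer seed.
#' @return integer matrix `n x length(freqs)` with variant ids as colnames.
#' @export
generate_genotypes <- function(freqs, n, seed) {
  check_prob(freqs, "allele frequencies")
  with_seed(seed, {
    g <- vapply(freqs, function(f) rbinom(n, 2L, f), integer(n))
    if (n == 1L) g <- matrix(g, nrow = 1L, dimnames = list(NULL, names(freqs)))
    g
  })
}

#' Biomarkers as genetic score plus noise
#'
#' Each biomarker is `intercept + sum_s loading[s, b] * S_s + N(0, noise_sd)`
#' where `S_s` is the weighted genetic score for arm `s` computed from the
#' dosages. Intercepts are chosen so population means match the target
#' means, using the Hardy-Weinberg score expectation.
#'
#' @param dosages named list of dosage matrices, one per score.
#' @param weights named list of `weight_table`s (same names as `dosages`).
#' @param pleiotropy loading data.frame (`score`, `biomarker`, `coef`);
#'   cross-trait rows are the pleiotropy entries.
#' @param biomarkers data.frame as [default_biomarkers()].
#' @param seed integer seed.
#' @return data.frame of biomarker columns, `n` rows.
#' @export
generate_biomarkers <- function(dosages, weights, pleiotropy, biomarkers,
                                seed) {
  if (any(biomarkers$noise_sd < 0)) stop2("noise_sd must be >= 0")
  stopifnot(identical(sort(names(dosages)), sort(names(weights))))
  scores <- lapply(names(weights), function(nm)
    as.numeric(compute_score(dosages[[nm]], weights[[nm]])))
  names(scores) <- names(weights)
  n <- length(scores[[1]])
  escore <- vapply(weights, expected_score_mean, numeric(1))
  with_seed(seed, {
    out <- lapply(seq_len(nrow(biomarkers)), function(i) {
      b <- biomarkers$biomarker[i]
      rows <- pleiotropy[pleiotropy$biomarker == b, , drop = FALSE]
      gen <- rep(0, n); egen <- 0
      for (k in seq_len(nrow(rows))) {
        s <- rows$score[k]
        if (!s %in% names(scores)) next
        gen <- gen + rows$coef[k] * scores[[s]]
        egen <- egen + rows$coef[k] * escore[[s]]
      }
      (biomarkers$mean[i] - egen) + gen +
        rnorm(n, 0, biomarkers$noise_sd[i])
    })
    names(out) <- biomarkers$biomarker
    as.data.frame(out)
  })
}

#' Censored survival outcomes from an exponential proportional-hazards model
#'
#' For each outcome the linear predictor is the sum of score effects (per
#' trait unit), covariate effects, and optionally an interaction
#' coefficient on the product of two standardized scores. Event times are
#' exponential with rate `baseline_hazard * exp(lp)`, administratively
#' censored at `admin_censor_time`.
#'
#' @param scores named list of numeric score vectors.
#' @param covariates data.frame with `age`, `sex`, `center`, `pc1..`.
#' @param config a `cohort_config` (outcome specs, covariate effects,
#'   censoring horizon are read from it).
#' @param seed master seed; each outcome uses its own substream.
#' @return data.frame with `time_<outcome>` and `event_<outcome>` columns.
#' @export
generate_survival <- function(scores, covariates, config, seed) {
  n <- nrow(covariates)
  cl <- config$covariate_log_hr
  k <- config$n_centers
  center_eff <- cl$center_amplitude * (seq_len(k) - (k + 1) / 2) / max(1, k)
  pc_cols <- grep("^pc", names(covariates), value = TRUE)
  lp_cov <- cl$age * (covariates$age - config$age_mean) +
    cl$sex * covariates$sex +
    center_eff[covariates$center] +
    if (length(pc_cols)) rowSums(as.matrix(covariates[pc_cols]) * cl$pc) else 0
  out <- list()
  for (nm in names(config$outcomes)) {
    o <- config$outcomes[[nm]]
    lp <- lp_cov
    for (s in names(o$log_hr)) lp <- lp + o$log_hr[[s]] * scores[[s]]
    if (!is.null(o$interaction) && o$interaction$log_hr != 0) {
      za <- as.numeric(scale(scores[[o$interaction$scores[1]]]))
      zb <- as.numeric(scale(scores[[o$interaction$scores[2]]]))
      lp <- lp + o$interaction$log_hr * za * zb
    }
    if (any(!is.finite(lp)))
      stop2("outcome '", nm, "': non-finite linear predictor for ",
            "individual(s) ", paste(utils::head(which(!is.finite(lp)), 5),
                                    collapse = ", "))
    tt <- with_seed(substream_seed(seed, paste0("survival:", nm)),
                    rexp(n, rate = o$baseline_hazard * exp(lp)))
    cens <- config$admin_censor_time
    out[[paste0("time_", nm)]] <- pmin(tt, cens)
    out[[paste0("event_", nm)]] <- as.integer(tt <= cens)
  }
  as.data.frame(out)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full data-generating process of a [cohort_config()]:
#' genotypes, covariates (age, sex, assessment center, principal
#' components), measured biomarkers, and censored survival outcomes. Every
#' stochastic component draws from its own substream of the master seed.
#'
#' @param config a `cohort_config`.
#' @return object of class `mr_cohort`: list with `data` (one row per
#'   individual), `dosages` (named list of matrices), `scores` (named list
#'   of score vectors in trait units) and `config` (the ground truth).
#' @export
generate_cohort <- function(config) {
  config <- validate_config(unclass(config))
  n <- config$n
  dosages <- lapply(names(config$scores), function(nm) {
    w <- config$scores[[nm]]
    generate_genotypes(setNames(w$eaf, w$variant_id), n,
                       substream_seed(config$seed, paste0("genotypes:", nm)))
  })
  names(dosages) <- names(config$scores)
  scores <- lapply(names(config$scores), function(nm)
    compute_score(dosages[[nm]], config$scores[[nm]]))
  names(scores) <- names(config$scores)

  covariates <- with_seed(substream_seed(config$seed, "covariates"), {
    cov <- data.frame(
      age = rnorm(n, config$age_mean, config$age_sd),
      sex = rbinom(n, 1L, config$p_male),
      center = sample.int(config$n_centers, n, replace = TRUE)
    )
    for (j in seq_len(config$n_pcs)) cov[[paste0("pc", j)]] <- rnorm(n)
    cov
  })

  surv <- generate_survival(lapply(scores, as.numeric), covariates, config,
                            config$seed)
  dat <- cbind(data.frame(id = seq_len(n)), covariates)
  if (nrow(config$biomarkers) > 0) {
    bio <- generate_biomarkers(dosages, config$scores, config$loadings,
                               config$biomarkers,
                               substream_seed(config$seed, "biomarkers"))
    dat <- cbind(dat, bio)
  }
  dat <- cbind(dat, surv)
  structure(list(data = dat, dosages = dosages, scores = scores,
                 config = config),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat("Synthetic MR cohort: n =", x$config$n,
      ";", length(x$scores), "genetic scores (",
      paste(names(x$scores), collapse = ", "), ")\n")
  ev <- grep("^event_", names(x$data), value = TRUE)
  for (e in ev)
    cat(sprintf("  %-12s %d events (%.1f%%)\n", sub("^event_", "", e),
                sum(x$data[[e]]), 100 * mean(x$data[[e]])))
  invisible(x)
}
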