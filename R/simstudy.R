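#' Compact deterministic weight table for simulation scenarios
#'
#' Builds a synthetic instrument with fixed (non-random) frequencies and
#' effect sizes, scaled so the resulting score has a chosen
#' Hardy-Weinberg standard deviation. Used by [sim_config()] so that
#' simulation scenarios are fully determined by their parameters.
#'
#' @param trait score label (controls units; e.g. `"lpa"` is mg/dL).
#' @param n_variants number of variants.
#' @param target_sd desired score SD in trait units.
#' @return a `weight_table`.
#' @export
make_sim_weights <- function(trait, n_variants = 20, target_sd = 17) {
  eaf <- seq(0.10, 0.90, length.out = n_variants)
  beta <- rep_len(c(1, -0.6, 0.8, -1.2, 0.5), n_variants)
  beta <- beta * target_sd / sqrt(sum(beta^2 * 2 * eaf * (1 - eaf)))
  validate_weights(data.frame(
    variant_id = sprintf("%s_sim%03d", trait, seq_len(n_variants)),
    effect_allele = rep_len(c("A", "C", "G", "T"), n_variants),
    eaf = eaf, beta = beta, trait = trait))
}

#' Generator configuration for Monte-Carlo scenarios
#'
#' A compact two-arm cohort: an Lp(a)-like score (arm A, mg/dL) and an
#' LDLR-like score (arm B, mg/dL), one outcome `"cvd"`, no biomarkers.
#' The baseline hazard gives roughly a 19% 12-year event proportion --
#' inflated relative to a real cohort so that moderate samples carry
#' adequate events. Main effects are stated as hazard ratios per
#' 50-mg/dL decrease; the interaction coefficient applies to the product
#' of the two standardized scores.
#'
#' @param n individuals per replicate.
#' @param seed master seed.
#' @param hr50_a,hr50_b true hazard ratios per 50-mg/dL decrease for the
#'   two arms.
#' @param interaction_log_hr true coefficient on the standardized-score
#'   product.
#' @param baseline_hazard events per person-year.
#' @param n_variants variants per score.
#' @param score_sd_a,score_sd_b score SDs in mg/dL.
#' @param n_centers assessment centers (fewer than the cohort default to
#'   keep scenario designs compact).
#' @return a `cohort_config`.
#' @export
sim_config <- function(n = 5000, seed = 1, hr50_a = 1.0, hr50_b = 1.0,
                       interaction_log_hr = 0, baseline_hazard = 0.018,
                       n_variants = 20, score_sd_a = 17, score_sd_b = 5,
                       n_centers = 4) {
  scores <- list(lpa = make_sim_weights("lpa", n_variants, score_sd_a),
                 ldlr = make_sim_weights("ldlr", n_variants, score_sd_b))
  inter <- if (interaction_log_hr != 0)
    list(scores = c("lpa", "ldlr"), log_hr = interaction_log_hr) else NULL
  cohort_config(
    n = n, seed = seed, scores = scores,
    n_centers = n_centers,
    biomarkers = data.frame(biomarker = character(), mean = numeric(),
                            noise_sd = numeric()),
    loadings = data.frame(score = character(), biomarker = character(),
                          coef = numeric()),
    outcomes = list(cvd = list(
      baseline_hazard = baseline_hazard,
      log_hr = list(lpa = -log(hr50_a) / 50, ldlr = -log(hr50_b) / 50),
      interaction = inter))
  )
}

#' Monte-Carlo experiment specification
#'
#' @param name scenario name (unique within a suite).
#' @param analysis one of `"recovery"`, `"type1"`, `"power"`,
#'   `"additivity"`.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param seed master seed; replicate r of scenario s uses substream
#'   `(seed, "<s>:<r>")`.
#' @param params named list of scenario parameters: [sim_config()]
#'   overrides (e.g. `n`, `hr50_a`) and analysis-specific parameters
#'   (`hr50_grid` for recovery, `effect_grid` for power, `alpha`).
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, analysis, n_replicates, seed,
                            params = list()) {
  stopifnot(n_replicates >= 1)
  analysis <- match.arg(analysis, c("recovery", "type1", "power",
                                    "additivity"))
  structure(list(name = name, analysis = analysis,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), params = params),
            class = "experiment_spec")
}

spec_param <- function(spec, key, default) {
  if (!is.null(spec$params[[key]])) spec$params[[key]] else default
}

rate_mc_se <- function(p_hat, R) sqrt(p_hat * (1 - p_hat) / R) * 100

new_report <- function(spec, metrics, details = list()) {
  structure(list(scenario = spec$name, analysis = spec$analysis,
                 n_replicates = spec$n_replicates, seed = spec$seed,
                 metrics = metrics, details = details),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s), %d replicates, seed %d\n", x$scenario,
              x$analysis, x$n_replicates, x$seed))
  print(x$metrics, digits = 4, row.names = FALSE)
  invisible(x)
}

replicate_config <- function(spec, label, r, overrides = list()) {
  args <- spec$params[intersect(names(spec$params),
                                names(formals(sim_config)))]
  args[names(overrides)] <- overrides
  args$seed <- substream_seed(spec$seed, sprintf("%s:%s:%d", spec$name,
                                                 label, r))
  do.call(sim_config, args)
}

#' Estimator-recovery experiment for the per-50-mg/dL hazard ratio
#'
#' For each generating truth in `hr50_grid`, simulates replicates, fits
#' the continuous-score Cox model and reports bias of the per-50-decrease
#' log-HR, its empirical SE, and empirical 95% CI coverage, each with a
#' Monte-Carlo SE. The truth is read from each replicate's generating
#' configuration, never restated.
#'
#' @param spec an [experiment_spec()] with `analysis = "recovery"`;
#'   params: `hr50_grid` (default `c(0.7, 0.9, 1.0)`), plus
#'   [sim_config()] overrides.
#' @return an `experiment_report`; `metrics` has one row per (truth,
#'   metric), with non-convergent replicates counted, not dropped.
#' @export
run_recovery <- function(spec) {
  grid <- spec_param(spec, "hr50_grid", c(0.7, 0.9, 1.0))
  R <- spec$n_replicates
  rows <- list(); details <- list()
  for (truth in grid) {
    est <- se <- truths <- numeric(R); bad <- 0L
    for (r in seq_len(R)) {
      cfg <- replicate_config(spec, sprintf("hr%g", truth), r,
                              list(hr50_a = truth))
      co <- generate_cohort(cfg)
      truths[r] <- -50 * co$config$outcomes$cvd$log_hr$lpa
      h <- per50_hr(co, co$scores$lpa, "cvd")
      if (!h$fit$converged) bad <- bad + 1L
      est[r] <- h$log_hr_per50; se[r] <- h$se_per50
    }
    bias <- mean(est - truths)
    emp_se <- sd(est)
    cover <- mean(abs(est - truths) <= qnorm(0.975) * se)
    rows[[length(rows) + 1L]] <- data.frame(
      truth_hr50 = truth,
      metric = c("bias_log_hr50", "empirical_se", "coverage_pct",
                 "nonconverged"),
      value = c(bias, emp_se, 100 * cover, bad),
      mc_se = c(emp_se / sqrt(R), emp_se / sqrt(2 * (R - 1)),
                rate_mc_se(cover, R), NA))
    details[[sprintf("hr%g", truth)]] <- list(est = est, se = se,
                                              truth = truths[1])
  }
  new_report(spec, do.call(rbind, rows), details)
}

#' Type-I error of the continuous product-term interaction test
#'
#' Simulates under interaction truth zero and reports the rejection rate
#' at each `alpha` with its binomial Monte-Carlo SE. The replicate
#' p-values are kept in `details$p_values` for distributional checks.
#'
#' @param spec an [experiment_spec()]; params: `alpha` (default
#'   `c(0.05, 0.01)`), plus [sim_config()] overrides (the interaction
#'   truth is forced to 0).
#' @return an `experiment_report`.
#' @export
run_type1 <- function(spec) {
  R <- spec$n_replicates
  alphas <- spec_param(spec, "alpha", c(0.05, 0.01))
  pvals <- numeric(R); bad <- 0L
  for (r in seq_len(R)) {
    cfg <- replicate_config(spec, "null", r, list(interaction_log_hr = 0))
    co <- generate_cohort(cfg)
    it <- interaction_test(co, co$scores$lpa, co$scores$ldlr, "cvd")
    if (!it$converged) bad <- bad + 1L
    pvals[r] <- it$p_interaction
  }
  rej <- vapply(alphas, function(a) mean(pvals < a), numeric(1))
  metrics <- data.frame(
    alpha = c(alphas, NA),
    metric = c(sprintf("rejection_pct_alpha_%g", alphas), "nonconverged"),
    value = c(100 * rej, bad),
    mc_se = c(rate_mc_se(rej, R), NA))
  new_report(spec, metrics, list(p_values = pvals))
}

#' Power comparison: continuous vs dichotomized interaction tests
#'
#' Across a grid of interaction effect sizes, both tests run on the same
#' replicates, so their power difference carries a paired Monte-Carlo SE.
#'
#' @param spec an [experiment_spec()]; params: `effect_grid` (default
#'   `c(0, 0.05, 0.1, 0.15)`), `alpha` (default 0.05), plus
#'   [sim_config()] overrides.
#' @return an `experiment_report`; `metrics` has one row per (effect,
#'   test).
#' @export
run_power_comparison <- function(spec) {
  grid <- spec_param(spec, "effect_grid", c(0, 0.05, 0.1, 0.15))
  alpha <- spec_param(spec, "alpha", 0.05)
  R <- spec$n_replicates
  rows <- list(); details <- list()
  for (eff in grid) {
    rej_c <- rej_d <- logical(R); bad <- 0L
    for (r in seq_len(R)) {
      cfg <- replicate_config(spec, sprintf("eff%g", eff), r,
                              list(interaction_log_hr = eff))
      co <- generate_cohort(cfg)
      itc <- interaction_test(co, co$scores$lpa, co$scores$ldlr, "cvd")
      itd <- interaction_test_dichotomized(co, co$scores$lpa,
                                           co$scores$ldlr, "cvd")
      if (!itc$converged || !itd$converged) bad <- bad + 1L
      rej_c[r] <- itc$p_interaction < alpha
      rej_d[r] <- itd$p_interaction < alpha
    }
    pc <- mean(rej_c); pd <- mean(rej_d)
    diff_se <- sd(as.numeric(rej_c) - as.numeric(rej_d)) / sqrt(R) * 100
    rows[[length(rows) + 1L]] <- data.frame(
      effect = eff,
      metric = c("power_continuous_pct", "power_dichotomized_pct",
                 "power_diff_pct", "nonconverged"),
      value = c(100 * pc, 100 * pd, 100 * (pc - pd), bad),
      mc_se = c(rate_mc_se(pc, R), rate_mc_se(pd, R), diff_se, NA))
    details[[sprintf("eff%g", eff)]] <- list(rej_c = rej_c, rej_d = rej_d)
  }
  new_report(spec, do.call(rbind, rows), details)
}

#' Additivity of factorial subgroup effects under zero interaction
#'
#' With both arm effects nonzero and interaction truth zero, the
#' both-lower factorial log-HR should equal the sum of the two single-arm
#' log-HRs (the additive baseline against which interaction is tested).
#' Reports the mean discrepancy with its Monte-Carlo SE.
#'
#' @param spec an [experiment_spec()]; params: [sim_config()] overrides
#'   (defaults `hr50_a = 0.8`, `hr50_b = 0.75`, interaction 0).
#' @return an `experiment_report`.
#' @export
run_additivity <- function(spec) {
  R <- spec$n_replicates
  disc <- numeric(R); bad <- 0L
  for (r in seq_len(R)) {
    cfg <- replicate_config(spec, "additivity", r,
                            list(hr50_a = spec_param(spec, "hr50_a", 0.8),
                                 hr50_b = spec_param(spec, "hr50_b", 0.75),
                                 interaction_log_hr = 0))
    co <- generate_cohort(cfg)
    alloc <- allocate_factorial(co$scores$lpa, co$scores$ldlr)
    fc <- factorial_contrasts(co, alloc, "cvd")
    if (!fc$fit$converged) bad <- bad + 1L
    lh <- log(fc$table$hr)
    disc[r] <- lh[4] - (lh[2] + lh[3])
  }
  metrics <- data.frame(
    metric = c("mean_discrepancy_log_hr", "empirical_se", "nonconverged"),
    value = c(mean(disc), sd(disc), bad),
    mc_se = c(sd(disc) / sqrt(R), NA, NA))
  new_report(spec, metrics, list(discrepancy = disc))
}

#' Run one experiment spec
#'
#' @param spec an [experiment_spec()].
#' @return an `experiment_report`.
#' @export
run_experiment <- function(spec) {
  switch(spec$analysis,
         recovery = run_recovery(spec),
         type1 = run_type1(spec),
         power = run_power_comparison(spec),
         additivity = run_additivity(spec))
}

#' Run a simulation suite defined in a YAML file
#'
#' A suite file has a `name` and a list of `scenarios`, each with `name`,
#' `analysis`, `n_replicates` and scenario parameters. Suites bundled
#' with the package live in `inst/suites/`.
#'
#' @param suite suite name (bundled) or path to a YAML file.
#' @param seed master seed applied to every scenario.
#' @param out_dir if non-NULL, writes one TSV per scenario plus a
#'   `summary.txt`.
#' @return named list of `experiment_report`s, invisibly if writing.
#' @export
run_suite <- function(suite, seed = 1, out_dir = NULL) {
  path <- if (file.exists(suite)) suite else
    system.file("suites", paste0(suite, ".yaml"), package = "factorialMR")
  if (!nzchar(path) || !file.exists(path)) {
    avail <- sub("\\.yaml$", "",
                 list.files(system.file("suites", package = "factorialMR")))
    stop2("unknown suite '", suite, "'; available: ",
          paste(avail, collapse = ", "))
  }
  suite_def <- yaml::read_yaml(path)
  nm <- vapply(suite_def$scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop2("duplicate scenario names in suite")
  reports <- list()
  for (sc in suite_def$scenarios) {
    args <- sc[setdiff(names(sc), c("name", "analysis", "n_replicates"))]
    # YAML 1.1 booleanizes a bare `n` key; suites say n_individuals
    if ("n_individuals" %in% names(args)) {
      args$n <- args$n_individuals
      args$n_individuals <- NULL
    }
    spec <- experiment_spec(name = sc$name, analysis = sc$analysis,
                            n_replicates = sc$n_replicates, seed = seed,
                            params = args)
    message("suite '", suite_def$name, "': scenario '", sc$name, "' (",
            sc$analysis, ", ", sc$n_replicates, " replicates)")
    reports[[sc$name]] <- run_experiment(spec)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(reports))
      write.table(reports[[nm]]$metrics,
                  file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    con <- file(file.path(out_dir, "summary.txt"), "w")
    for (nm in names(reports)) {
      sink(con); print(reports[[nm]]); cat("\n"); sink()
    }
    close(con)
    return(invisible(reports))
  }
  reports
}
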