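#' Read and validate a pipeline run configuration
#'
#' YAML with fields: `out_dir`; optional `seed` (default 1); optional
#' `cohort` overrides (`n`, `scores`: score labels to include,
#' `n_centers`, `admin_censor_time`); optional `analysis` block
#' (`outcomes`, `ldl_pairs`: LDL-C arms crossed with the Lp(a) arm,
#' `lifestyle_pairs`, `composites`: named lists of component outcomes);
#' optional `suite` name for evaluation.
#'
#' @param path YAML file.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a list with the same fields as the YAML file.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stop2("config must name an out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  ch <- config$cohort %||% list()
  # YAML 1.1 reads a bare `n` key as boolean FALSE, so the config key is
  # n_individuals throughout
  ch$n <- as.integer(ch$n_individuals %||% ch$n %||% 20000L)
  ch$scores <- ch$scores %||% c("lpa", "hmgcr", "npc1l1", "pcsk9", "ldlr",
                                "bmi", "sbp", "smoking", "alcohol",
                                "activity")
  config$cohort <- ch
  an <- config$analysis %||% list()
  an$outcomes <- an$outcomes %||% c("cad", "pad", "stroke", "vte", "hf",
                                    "cvd_death", "mace3", "mace4")
  an$ldl_pairs <- an$ldl_pairs %||% intersect(
    c("hmgcr", "npc1l1", "pcsk9", "ldlr"), ch$scores)
  an$lifestyle_pairs <- an$lifestyle_pairs %||% intersect(
    c("bmi", "sbp", "smoking", "alcohol", "activity"), ch$scores)
  an$composites <- an$composites %||% list(
    mace3 = c("cad", "stroke", "cvd_death"),
    mace4 = c("cad", "stroke", "hf", "cvd_death"))
  config$analysis <- an
  config$suite <- config$suite %||% "acceptance"
  structure(config, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(config, out_dir, extra = list()) {
  cfg_json <- as.character(jsonlite::toJSON(unclass(config),
                                            digits = I(17),
                                            auto_unbox = TRUE))
  manifest <- c(list(
    config = unclass(config),
    config_hash = fnv1a_hex(cfg_json),
    seed = config$seed,
    package_version = as.character(packageVersion("factorialMR")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ), extra)
  write_json_exact(manifest, file.path(out_dir, "manifest.json"))
}

#' Generate and write the configured synthetic cohort
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @return paths written, invisibly.
#' @export
pipeline_simulate <- function(config) {
  config <- validate_run_config(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out_dir, 2L) != 0L)
    stop2("output directory not writable: ", config$out_dir)
  w <- bundled_weights(config$cohort$scores)
  gen <- cohort_config(n = config$cohort$n, seed = config$seed, scores = w,
                       outcomes = default_outcomes(names(w)))
  if (!is.null(config$cohort$n_centers))
    gen <- validate_config(utils::modifyList(unclass(gen), list(
      n_centers = as.integer(config$cohort$n_centers))))
  if (!is.null(config$cohort$admin_censor_time))
    gen <- validate_config(utils::modifyList(unclass(gen), list(
      admin_censor_time = as.numeric(config$cohort$admin_censor_time))))
  message("simulate: generating cohort (n = ", gen$n, ", ",
          length(gen$scores), " scores, seed ", gen$seed, ")")
  co <- generate_cohort(gen)
  paths <- write_cohort(co, config$out_dir)
  write_manifest(config, config$out_dir)
  message("simulate: wrote ", paths[["cohort"]])
  invisible(paths)
}

#' Run every configured analysis stage on a written cohort
#'
#' Produces one TSV per stage in `out_dir`:
#' `fig2_associations.tsv` (median-split biomarker contrasts),
#' `fig3_scaled_hrs.tsv` (per-50-mg/dL hazard ratios for the Lp(a) arm),
#' `fig4_factorial.tsv` (Lp(a) x LDL-C-target factorial contrasts with
#' interaction p-values) and `fig5_factorial.tsv` (Lp(a) x lifestyle
#' arms). One log line per model goes to stderr; per-model failures are
#' collected and summarized, not fatal.
#'
#' @param config a `run_config`; the cohort must have been written by
#'   [pipeline_simulate()] to `config$out_dir`.
#' @return named list of the output data.frames, invisibly.
#' @export
pipeline_analyze <- function(config) {
  config <- validate_run_config(unclass(config))
  co <- read_cohort(config$out_dir)
  an <- config$analysis
  failures <- character()
  note <- function(what, n, ev, ok = TRUE)
    message(sprintf("analyze: %-40s n=%d events=%s %s", what, n,
                    as.character(ev), if (ok) "" else "FAILED"))
  run_stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, paste0(what, ": ", conditionMessage(e)))
      message("analyze: ", what, " failed: ", conditionMessage(e))
      NULL
    })
  }
  for (nm in names(an$composites)) {
    comp <- intersect(an$composites[[nm]],
                      sub("^event_", "",
                          grep("^event_", names(co$data), value = TRUE)))
    if (length(comp) >= 2) co <- composite_outcome(co, comp, nm)
  }
  have_outcome <- function(o) paste0("event_", o) %in% names(co$data)
  outcomes <- Filter(have_outcome, an$outcomes)

  # Stage 1: instrument validity -- biomarker associations
  lipid_arms <- intersect(c("lpa", "hmgcr", "npc1l1", "pcsk9", "ldlr",
                            "ldl_overall"), names(co$scores))
  biomarkers <- intersect(co$config$biomarkers$biomarker, names(co$data))
  fig2 <- list()
  for (arm in lipid_arms) for (b in biomarkers) {
    res <- run_stage(paste0("association ", arm, " ~ ", b), {
      a <- biomarker_association(co, co$scores[[arm]], b)
      note(paste0("association ", arm, " -> ", b), a$fit$n, "-")
      cbind(data.frame(score = arm, biomarker = b),
            a$contrast[setdiff(names(a$contrast), "term")])
    })
    if (!is.null(res)) fig2[[length(fig2) + 1L]] <- res
  }

  # Stage 2: per-50-mg/dL hazard ratios for the Lp(a) arm
  fig3 <- list()
  if ("lpa" %in% names(co$scores)) for (o in outcomes) {
    res <- run_stage(paste0("per50 lpa ~ ", o), {
      h <- per50_hr(co, co$scores$lpa, o)
      note(paste0("per50 lpa -> ", o), h$n, h$n_events, h$fit$converged)
      data.frame(outcome = o, hr_per50_decrease = h$hr, ci_low = h$ci_low,
                 ci_high = h$ci_high, p = h$p, n = h$n,
                 n_events = h$n_events)
    })
    if (!is.null(res)) fig3[[length(fig3) + 1L]] <- res
  }

  factorial_stage <- function(arms) {
    rows <- list()
    for (arm in arms) for (o in outcomes) {
      res <- run_stage(paste0("factorial lpa x ", arm, " ~ ", o), {
        alloc <- allocate_factorial(co$scores$lpa, co$scores[[arm]])
        fc <- factorial_contrasts(co, alloc, o)
        it <- interaction_test(co, co$scores$lpa, co$scores[[arm]], o)
        note(paste0("factorial lpa x ", arm, " -> ", o), fc$fit$n,
             fc$fit$n_events, fc$fit$converged && it$converged)
        cbind(data.frame(arm_a = "lpa", arm_b = arm, outcome = o),
              fc$table, p_interaction = it$p_interaction)
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    rows
  }
  fig4 <- factorial_stage(intersect(an$ldl_pairs, names(co$scores)))
  fig5 <- factorial_stage(intersect(an$lifestyle_pairs, names(co$scores)))

  out <- list(fig2_associations = do.call(rbind, fig2),
              fig3_scaled_hrs = do.call(rbind, fig3),
              fig4_factorial = do.call(rbind, fig4),
              fig5_factorial = do.call(rbind, fig5))
  for (nm in names(out))
    if (!is.null(out[[nm]]))
      write.table(out[[nm]], file.path(config$out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(failures))
    message("analyze: ", length(failures), " model(s) failed:\n  ",
            paste(failures, collapse = "\n  "))
  else message("analyze: all models completed")
  invisible(out)
}

#' Run a simulation suite from a pipeline configuration
#'
#' @param config a `run_config` (uses `config$suite` and writes under
#'   `<out_dir>/evaluate/`).
#' @return list of `experiment_report`s, invisibly.
#' @export
pipeline_evaluate <- function(config) {
  config <- validate_run_config(unclass(config))
  out <- file.path(config$out_dir, "evaluate")
  run_suite(config$suite, seed = config$seed, out_dir = out)
}
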