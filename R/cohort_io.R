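# Column-name contract (version 1) for the cohort TSV:
#   id, age, sex, center, pc1..pcK, <biomarkers>, time_<outcome>,
#   event_<outcome>, then one dosage column per variant id.
COHORT_FORMAT_VERSION <- 1L

config_to_list <- function(cfg) {
  list(
    format_version = COHORT_FORMAT_VERSION,
    n = cfg$n, seed = cfg$seed,
    scores = lapply(cfg$scores, function(w) as.list(as.data.frame(w))),
    age_mean = cfg$age_mean, age_sd = cfg$age_sd, p_male = cfg$p_male,
    n_centers = cfg$n_centers, n_pcs = cfg$n_pcs,
    biomarkers = as.list(cfg$biomarkers),
    loadings = as.list(cfg$loadings),
    outcomes = cfg$outcomes,
    covariate_log_hr = cfg$covariate_log_hr,
    admin_censor_time = cfg$admin_censor_time
  )
}

list_to_config <- function(x) {
  num <- function(v) as.numeric(unlist(v, use.names = FALSE))
  scores <- lapply(x$scores, function(w)
    validate_weights(data.frame(
      variant_id = as.character(unlist(w$variant_id)),
      effect_allele = as.character(unlist(w$effect_allele)),
      eaf = num(w$eaf), beta = num(w$beta),
      trait = as.character(unlist(w$trait)))))
  outcomes <- lapply(x$outcomes, function(o) {
    res <- list(baseline_hazard = num(o$baseline_hazard),
                log_hr = lapply(o$log_hr, num))
    res$interaction <- if (is.null(o$interaction)) NULL else
      list(scores = as.character(unlist(o$interaction$scores)),
           log_hr = num(o$interaction$log_hr))
    res
  })
  validate_config(list(
    n = as.integer(x$n), seed = as.integer(x$seed), scores = scores,
    age_mean = num(x$age_mean), age_sd = num(x$age_sd),
    p_male = num(x$p_male), n_centers = as.integer(x$n_centers),
    n_pcs = as.integer(x$n_pcs),
    biomarkers = data.frame(biomarker = as.character(unlist(x$biomarkers$biomarker)),
                            mean = num(x$biomarkers$mean),
                            noise_sd = num(x$biomarkers$noise_sd)),
    loadings = data.frame(score = as.character(unlist(x$loadings$score)),
                          biomarker = as.character(unlist(x$loadings$biomarker)),
                          coef = num(x$loadings$coef)),
    outcomes = outcomes,
    covariate_log_hr = lapply(x$covariate_log_hr, num),
    admin_censor_time = num(x$admin_censor_time)
  ))
}

#' Write a cohort as one TSV plus a ground-truth JSON sidecar
#'
#' The TSV holds one row per individual (covariates, biomarkers, outcomes,
#' then dosage columns named by variant id). The sidecar records every
#' generating parameter with full double precision, so reading it back
#' reproduces the configuration exactly.
#'
#' @param cohort an `mr_cohort`.
#' @param dir output directory (created if missing).
#' @param name file stem; writes `<name>.tsv` and `<name>_truth.json`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, name = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dat <- cohort$data
  for (nm in names(cohort$dosages))
    dat <- cbind(dat, as.data.frame(cohort$dosages[[nm]]))
  tsv <- file.path(dir, paste0(name, ".tsv"))
  write.table(dat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- file.path(dir, paste0(name, "_truth.json"))
  write_json_exact(config_to_list(cohort$config), sidecar)
  invisible(c(cohort = tsv, truth = sidecar))
}

#' Read a ground-truth sidecar back into a `cohort_config`
#'
#' @param path the `_truth.json` file.
#' @return a `cohort_config` identical to the one that generated the data.
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(as.integer(x$format_version), COHORT_FORMAT_VERSION))
    stop2("unsupported cohort format version: ", x$format_version)
  list_to_config(x)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding the files.
#' @param name file stem used when writing.
#' @return an `mr_cohort` (dosages and scores reconstructed from the
#'   sidecar's weight tables).
#' @export
read_cohort <- function(dir, name = "cohort") {
  tsv <- file.path(dir, paste0(name, ".tsv"))
  config <- read_truth(file.path(dir, paste0(name, "_truth.json")))
  dat <- read.delim(tsv, sep = "\t", check.names = FALSE)
  dosages <- lapply(config$scores, function(w) {
    g <- as.matrix(dat[w$variant_id])
    storage.mode(g) <- "integer"
    g
  })
  scores <- lapply(names(config$scores), function(nm)
    compute_score(dosages[[nm]], config$scores[[nm]]))
  names(scores) <- names(config$scores)
  keep <- setdiff(names(dat), unlist(lapply(config$scores,
                                            function(w) w$variant_id)))
  structure(list(data = dat[keep], dosages = dosages, scores = scores,
                 config = config),
            class = "mr_cohort")
}
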