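WEIGHT_COLUMNS <- c("variant_id", "effect_allele", "eaf", "beta", "trait")

# Native units for each score label; lipid scores are in mg/dL, which is
# what licenses the per-50-mg/dL hazard-ratio rescaling downstream.
TRAIT_UNITS <- c(
  lpa = "mg/dL", hmgcr = "mg/dL", npc1l1 = "mg/dL", pcsk9 = "mg/dL",
  ldlr = "mg/dL", ldl_overall = "mg/dL",
  bmi = "kg/m2", sbp = "mmHg", smoking = "SD", alcohol = "drinks/week",
  activity = "SD"
)

#' Units of a score's trait
#'
#' @param trait score label (e.g. `"lpa"`, `"bmi"`).
#' @return character unit string; `"unknown"` for unrecognized labels.
#' @export
trait_units <- function(trait) {
  u <- unname(TRAIT_UNITS[trait])
  ifelse(is.na(u), "unknown", u)
}

#' Read a variant weight table
#'
#' A weight table defines one weighted genetic score: one row per variant
#' with its effect allele, effect-allele frequency and per-allele effect on
#' the trait in trait units (mg/dL for lipids). Weights are stored
#' trait-increasing; "lowering" is represented at analysis time by the sign
#' of fitted coefficients, never by flipping weights.
#'
#' @param path TSV file with header
#'   `variant_id effect_allele eaf beta trait`.
#' @return a `weight_table`: data.frame with the five columns validated.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop2("weight table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "character"))
  if (!identical(names(tab), WEIGHT_COLUMNS))
    stop2("weight table header must be: ", paste(WEIGHT_COLUMNS, collapse = " "),
          " (got: ", paste(names(tab), collapse = " "), ")")
  validate_weights(tab, path)
}

validate_weights <- function(tab, origin = "weight table") {
  if (nrow(tab) > 0) {
    dup <- duplicated(tab$variant_id)
    if (any(dup))
      stop2(origin, ": duplicate variant_id: ",
            paste(unique(tab$variant_id[dup]), collapse = ", "))
    bad_allele <- !tab$effect_allele %in% c("A", "C", "G", "T")
    if (any(bad_allele))
      stop2(origin, ": invalid effect allele on line(s) ",
            paste(which(bad_allele) + 1L, collapse = ", "))
    bad_eaf <- !is.finite(tab$eaf) | tab$eaf <= 0 | tab$eaf >= 1
    if (any(bad_eaf))
      stop2(origin, ": eaf outside (0,1) on line(s) ",
            paste(which(bad_eaf) + 1L, collapse = ", "))
    if (any(!is.finite(tab$beta)))
      stop2(origin, ": non-finite beta on line(s) ",
            paste(which(!is.finite(tab$beta)) + 1L, collapse = ", "))
  }
  class(tab) <- c("weight_table", "data.frame")
  tab
}

#' Write a weight table
#'
#' @param weights a `weight_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the weight tables bundled with the package
#'
#' Synthetic fixture tables for the ten score arms (Lp(a); LDL-C via HMGCR,
#' NPC1L1, PCSK9, LDLR; overall LDL-C; BMI; SBP; smoking; alcohol; physical
#' activity). Variant counts per arm match the instrument cardinalities of
#' the published scores (43/26/6/42/52/237/62/455/248/98/16); frequencies
#' and per-allele effects are synthetic, calibrated so the default cohort
#' reproduces realistic biomarker distributions.
#'
#' @param traits which score labels to load (default: all bundled).
#' @return named list of `weight_table`s.
#' @export
bundled_weights <- function(traits = NULL) {
  dir <- system.file("extdata", "weights", package = "factorialMR")
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  names(files) <- sub("\\.tsv$", "", basename(files))
  if (!is.null(traits)) {
    missing <- setdiff(traits, names(files))
    if (length(missing))
      stop2("no bundled weight table for: ", paste(missing, collapse = ", "))
    files <- files[traits]
  }
  lapply(files, read_weights)
}

#' Per-individual weighted genetic score
#'
#' \eqn{S_i = \sum_j g_{ij} \beta_j}, the predicted trait change in trait
#' units, oriented trait-increasing. Dosage columns are aligned to the
#' weight table by `variant_id`, so the result is invariant to column order.
#'
#' @param dosages integer matrix of effect-allele dosages in `{0,1,2}`,
#'   columns named by variant id.
#' @param weights a `weight_table`.
#' @return numeric vector of class `score_vector` with attributes `trait`
#'   and `units`.
#' @export
compute_score <- function(dosages, weights) {
  if (nrow(weights) == 0) stop2("empty weight table: nothing to score")
  if (is.null(colnames(dosages))) stop2("dosage matrix must have variant ids as colnames")
  missing <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing))
    stop2("variants in weights missing from dosages: ",
          paste(missing, collapse = ", "))
  g <- dosages[, weights$variant_id, drop = FALSE]
  s <- as.numeric(g %*% weights$beta)
  trait <- if (nrow(weights)) weights$trait[1] else NA_character_
  structure(s, trait = trait, units = trait_units(trait),
            orientation = "trait-increasing", class = "score_vector")
}

#' Reverse the stored orientation of a score vector
#'
#' Negates the values and toggles the orientation flag, so scaled
#' hazard-ratio reporting (which is stated per trait *decrease*) is
#' unchanged by the flip.
#'
#' @param scores a `score_vector`.
#' @return the re-oriented `score_vector`.
#' @export
flip_score <- function(scores) {
  orient <- attr(scores, "orientation")
  if (is.null(orient)) orient <- "trait-increasing"
  structure(-as.numeric(scores), trait = attr(scores, "trait"),
            units = attr(scores, "units"),
            orientation = if (orient == "trait-increasing")
              "trait-decreasing" else "trait-increasing",
            class = "score_vector")
}

orientation_sign <- function(scores) {
  orient <- attr(scores, "orientation")
  if (is.null(orient) || orient == "trait-increasing") 1 else -1
}

#' Expected population mean of a score under Hardy-Weinberg genotypes
#'
#' \eqn{E[S] = \sum_j 2\,\mathrm{eaf}_j\,\beta_j}.
#'
#' @param weights a `weight_table`.
#' @return scalar expectation in trait units.
#' @export
expected_score_mean <- function(weights) sum(2 * weights$eaf * weights$beta)

#' Median split of a score into lower and higher groups
#'
#' Ties at the sample median go to the lower group, keeping the allocation
#' deterministic; for continuous scores the two groups differ in size by at
#' most one.
#'
#' @param scores numeric vector, `n >= 2`, non-constant.
#' @return factor with levels `lower`, `higher`.
#' @export
dichotomize <- function(scores) {
  if (length(scores) < 2) stop2("need at least 2 individuals to split")
  if (anyNA(scores)) stop2("missing scores")
  m <- median(scores)
  if (max(scores) == min(scores))
    stop2("constant score vector: no median split possible")
  factor(ifelse(scores <= m, "lower", "higher"), levels = c("lower", "higher"))
}

FACTORIAL_LEVELS <- c("both_higher", "lowerA_only", "lowerB_only", "both_lower")

#' 2x2 factorial allocation from two genetic scores
#'
#' Cross-classifies the cohort by the median splits of two scores into four
#' subgroups, mimicking a 2x2 factorial randomized trial. The reference
#' group is higher on both scores (both exposures at their "untreated"
#' level).
#'
#' @param scoresA,scoresB numeric vectors of equal length.
#' @return factor with levels `both_higher` (reference), `lowerA_only`,
#'   `lowerB_only`, `both_lower`.
#' @export
allocate_factorial <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop2("scoresA and scoresB must have equal length")
  ga <- dichotomize(scoresA)
  gb <- dichotomize(scoresB)
  lab <- ifelse(ga == "lower",
                ifelse(gb == "lower", "both_lower", "lowerA_only"),
                ifelse(gb == "lower", "lowerB_only", "both_higher"))
  factor(lab, levels = FACTORIAL_LEVELS)
}
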