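# Build the synthetic fixture weight tables shipped in inst/extdata/weights/.
# Run once from the repository root: Rscript tools/make_fixtures.R
#
# Variant counts per arm match the published instrument cardinalities;
# frequencies and per-allele effects are synthetic, with each score's
# variance calibrated so that downstream median-split biomarker contrasts
# land at realistic magnitudes (see the methods vignette).

set.seed(20260929)

# trait -> c(n_variants, target score SD in trait units)
arms <- list(
  lpa         = c(43, 17.0),
  hmgcr       = c(26, 1.566),
  npc1l1      = c(6, 0.664),
  pcsk9       = c(42, 1.692),
  ldlr        = c(52, 2.419),
  ldl_overall = c(237, 8.0),
  bmi         = c(62, 0.60),
  sbp         = c(455, 3.00),
  smoking     = c(248, 0.15),
  alcohol     = c(98, 2.00),
  activity    = c(16, 0.08)
)

dir.create(file.path("inst", "extdata", "weights"), recursive = TRUE,
           showWarnings = FALSE)

for (trait in names(arms)) {
  m <- arms[[trait]][1]
  target_sd <- arms[[trait]][2]
  eaf <- round(runif(m, 0.05, 0.95), 4)
  beta_raw <- rnorm(m)
  # scale betas so Var(S) = sum(beta^2 * 2 f (1-f)) hits the target
  scale <- target_sd / sqrt(sum(beta_raw^2 * 2 * eaf * (1 - eaf)))
  beta <- round(beta_raw * scale, 6)
  tab <- data.frame(
    variant_id = sprintf("%s_v%03d", trait, seq_len(m)),
    effect_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    eaf = eaf,
    beta = beta,
    trait = trait
  )
  write.table(tab, file.path("inst", "extdata", "weights",
                             paste0(trait, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote", length(arms), "weight tables\n")
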