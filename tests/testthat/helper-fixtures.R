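# In-code fixture builders and independent oracles shared across the suite.

# Brute-force KS tag statistic: explicit evaluation of the two running maxima
# over every j. Kept loop-wise and independent of the package's vectorized
# implementation.
ks_oracle <- function(positions, n) {
  t <- length(positions)
  v <- sort(positions)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# same evaluation, returning the two running maxima as well
ks_oracle_ab <- function(positions, n) {
  t <- length(positions)
  v <- sort(positions)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  list(a = a, b = b, es = if (a > b) a else -b)
}

write_tmp <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

gwas_file <- function(rows) {
  write_tmp(c("trait\tmapped_gene\tsnp\tp_value\tancestry\tpubmed_id", rows))
}

phewas_file <- function(rows) {
  write_tmp(c("snp\tphenotype\tp_value\tgene", rows))
}

metab_file <- function(rows) {
  write_tmp(c("metabolite\tprotein\trole", rows))
}

drug_file <- function(rows) {
  write_tmp(c("drug\tdrug_id\tgroup\ttarget\ttarget_category\tactions\tindication",
              rows))
}

patho_file <- function(rows) {
  write_tmp(c("target\tdirection\tdescription\tprovenance", rows))
}

trial_file <- function(rows) {
  write_tmp(c("drug\tstage\tcondition", rows))
}

# evidence records straight from code (already harmonized)
ev_rec <- function(gene, source, p_value = NA_real_) {
  tibble::tibble(gene = gene, source = source, trait = NA_character_,
                 p_value = p_value, snp_id = NA_character_,
                 metabolite = NA_character_, role = NA_character_,
                 citation = NA_character_)
}

# a tiny ranked-signature panel built directly in memory
signature_panel <- function(rankings, drugs, cell_line = "MCF7") {
  tibble::tibble(
    instance_id = sprintf("i%02d", seq_along(rankings)),
    drug = drugs,
    cell_line = cell_line,
    ranking = rankings
  )
}

# small fixture directory for fast pipeline tests: scaled-down study shape
small_config <- function(seed = 7L) {
  synth_config(
    seed = seed, n_universe = 260L,
    source_sizes = c(GWAS = 12L, PHEWAS = 40L, METABOLOMICS = 90L,
                     TRANSCRIPTOMICS = 8L, BIOMEDICAL = 5L),
    multi_source_overlap = 10L, n_metabolites = 6L, n_assocs = 120L,
    n_mapped_targets = 40L, n_mapped_drugs = 120L,
    n_trial_drugs = 40L, trial_overlap = 15L,
    n_targets_after_exclusion = 38L,
    n_patho_targets = 16L, n_patho_drugs = 50L, n_discordant = 20L,
    n_decoy_group = 15L, n_decoy_offtarget = 10L,
    sig_universe = 300L, n_tags_up = 12L, n_tags_down = 12L,
    n_final_drugs = 10L, n_final_targets = 6L,
    n_cmap_reversed = 12L, instances_per_drug = 2L
  )
}
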