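## Synthetic fixture generator. Emits a complete, statistically structured
## input set for every pipeline stage -- five evidence tables, the drug/trial/
## pathogenesis tables, and a ranked-signature panel -- with the planted ground
## truth exposed in a manifest so recovery is testable offline. Defaults are
## the study conditions: per-source gene counts 55/260/616/27/11, 50
## multi-source genes, 23 metabolites with ~800 protein associations, a
## 731-drug/193-target mapping stage, 75 known-indication drugs, a
## 277-drug/74-target concordance stage and a 35-drug/20-target final panel.

#' Synthetic study configuration
#'
#' Collects every knob of the fixture generator, validated for mutual
#' feasibility. The defaults reproduce the cascade shape of the melanoma
#' study end-to-end; all are overridable.
#'
#' @param seed Integer master seed. Each generator derives an independent
#'   stream from it by label, so regeneration is byte-identical and adding a
#'   generator never perturbs existing fixtures.
#' @param n_universe Size of the gene universe the evidence sources draw from.
#' @param source_sizes Named integer vector: unique genes per evidence source.
#' @param multi_source_overlap Number of genes planted in two or more sources.
#' @param n_metabolites,n_assocs Metabolite node count and total
#'   metabolite-protein association rows (every metabolomics protein gets at
#'   least one).
#' @param gwas_p_range,phewas_p_range Log-uniform sampling ranges for the
#'   association p-values.
#' @param n_mapped_targets,n_mapped_drugs Planted size of the drug-mapping
#'   stage (distinct druggable targets / approved drugs hitting them).
#' @param n_trial_drugs,trial_overlap Size of the known-indication trial list
#'   and how many of its drugs overlap the mapped candidates.
#' @param n_targets_after_exclusion Distinct targets left once the overlapping
#'   drugs are removed (the excluded drugs exclusively cover the difference).
#' @param n_patho_targets,n_patho_drugs Annotated targets and drugs planted to
#'   survive the strict concordance filter.
#' @param n_discordant Drugs planted with a discordant action on an annotated
#'   target (rejected by the concordance filter).
#' @param n_decoy_group,n_decoy_offtarget Decoy drugs in a non-approved group
#'   / approved decoys whose targets lie outside the unified gene set.
#' @param sig_universe,n_tags_up,n_tags_down Signature gene-universe size and
#'   query tag-set sizes.
#' @param n_final_drugs,n_final_targets Drugs planted as connectivity-active
#'   (and the distinct targets they span) -- the final candidate panel.
#' @param n_cmap_reversed,n_cmap_inactive Drugs planted with a reversed /
#'   unstructured expression response.
#' @param instances_per_drug Signature instances (cell-line treatments) per
#'   panel drug.
#' @param concentration Truncated-geometric rate in (0, 1) biasing active
#'   drugs' up-tags toward the top ranks (and down-tags toward the bottom);
#'   larger is stronger.
#' @param anchors_pos,anchors_neg Anchor drug names planted active / reversed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_universe = 1500L,
                         source_sizes = c(GWAS = 55L, PHEWAS = 260L,
                                          METABOLOMICS = 616L,
                                          TRANSCRIPTOMICS = 27L,
                                          BIOMEDICAL = 11L),
                         multi_source_overlap = 50L,
                         n_metabolites = 23L,
                         n_assocs = 800L,
                         gwas_p_range = c(4e-37, 8e-06),
                         phewas_p_range = c(1.106e-16, 0.05),
                         n_mapped_targets = 193L,
                         n_mapped_drugs = 731L,
                         n_trial_drugs = 215L,
                         trial_overlap = 75L,
                         n_targets_after_exclusion = 184L,
                         n_patho_targets = 74L,
                         n_patho_drugs = 277L,
                         n_discordant = 100L,
                         n_decoy_group = 120L,
                         n_decoy_offtarget = 80L,
                         sig_universe = 1000L,
                         n_tags_up = 30L,
                         n_tags_down = 30L,
                         n_final_drugs = 35L,
                         n_final_targets = 20L,
                         n_cmap_reversed = 60L,
                         n_cmap_inactive = 0L,
                         instances_per_drug = 2L,
                         concentration = 0.05,
                         anchors_pos = c("paclitaxel", "vinblastine"),
                         anchors_neg = "selegiline") {
  cfg <- list(seed = as.integer(seed), n_universe = as.integer(n_universe),
              source_sizes = source_sizes,
              multi_source_overlap = as.integer(multi_source_overlap),
              n_metabolites = as.integer(n_metabolites),
              n_assocs = as.integer(n_assocs),
              gwas_p_range = gwas_p_range, phewas_p_range = phewas_p_range,
              n_mapped_targets = as.integer(n_mapped_targets),
              n_mapped_drugs = as.integer(n_mapped_drugs),
              n_trial_drugs = as.integer(n_trial_drugs),
              trial_overlap = as.integer(trial_overlap),
              n_targets_after_exclusion = as.integer(n_targets_after_exclusion),
              n_patho_targets = as.integer(n_patho_targets),
              n_patho_drugs = as.integer(n_patho_drugs),
              n_discordant = as.integer(n_discordant),
              n_decoy_group = as.integer(n_decoy_group),
              n_decoy_offtarget = as.integer(n_decoy_offtarget),
              sig_universe = as.integer(sig_universe),
              n_tags_up = as.integer(n_tags_up),
              n_tags_down = as.integer(n_tags_down),
              n_final_drugs = as.integer(n_final_drugs),
              n_final_targets = as.integer(n_final_targets),
              n_cmap_reversed = as.integer(n_cmap_reversed),
              n_cmap_inactive = as.integer(n_cmap_inactive),
              instances_per_drug = as.integer(instances_per_drug),
              concentration = concentration,
              anchors_pos = anchors_pos, anchors_neg = anchors_neg)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$source_sizes, cfg$multi_source_overlap, cfg$n_metabolites,
              cfg$n_assocs, cfg$n_mapped_targets, cfg$n_mapped_drugs,
              cfg$n_trial_drugs, cfg$trial_overlap, cfg$n_patho_targets,
              cfg$n_patho_drugs, cfg$n_discordant, cfg$n_decoy_group,
              cfg$n_decoy_offtarget, cfg$n_final_drugs, cfg$n_cmap_reversed,
              cfg$n_cmap_inactive, cfg$instances_per_drug)
  if (any(counts < 0)) abort("All synthetic counts must be non-negative.")
  if (!setequal(names(cfg$source_sizes), EVIDENCE_SOURCES)) {
    abort("`source_sizes` must be named by the five evidence sources.")
  }
  if (2L * cfg$multi_source_overlap > sum(cfg$source_sizes)) {
    abort("Infeasible `multi_source_overlap`: not enough source capacity.")
  }
  if (cfg$multi_source_overlap > sum(cfg$source_sizes) - max(cfg$source_sizes)) {
    abort("Infeasible `multi_source_overlap`: a single source cannot host overlaps alone.")
  }
  if (cfg$n_universe < sum(cfg$source_sizes) + cfg$n_decoy_offtarget) {
    abort("`n_universe` too small for the source sizes plus off-set decoy targets.")
  }
  if (cfg$n_assocs < cfg$source_sizes[["METABOLOMICS"]]) {
    abort("`n_assocs` must cover every metabolomics protein at least once.")
  }
  if (cfg$n_assocs > cfg$n_metabolites * cfg$source_sizes[["METABOLOMICS"]]) {
    abort("`n_assocs` exceeds the number of distinct metabolite-protein pairs.")
  }
  if (cfg$n_mapped_targets > sum(cfg$source_sizes) - cfg$multi_source_overlap) {
    abort("`n_mapped_targets` exceeds the unified gene set size.")
  }
  if (cfg$n_patho_targets > cfg$n_mapped_targets) {
    abort("`n_patho_targets` cannot exceed `n_mapped_targets`.")
  }
  if (cfg$n_targets_after_exclusion > cfg$n_mapped_targets ||
      cfg$n_targets_after_exclusion < cfg$n_patho_targets) {
    abort("`n_targets_after_exclusion` must lie between `n_patho_targets` and `n_mapped_targets`.")
  }
  if (cfg$n_mapped_targets - cfg$n_targets_after_exclusion > cfg$trial_overlap) {
    abort("Excluded drugs are too few to exclusively cover the targets lost at exclusion.")
  }
  if (cfg$trial_overlap > min(cfg$n_trial_drugs, cfg$n_mapped_drugs)) {
    abort("`trial_overlap` exceeds the trial list or the mapped drug panel.")
  }
  if (cfg$n_patho_drugs < cfg$n_patho_targets) {
    abort("`n_patho_drugs` must cover every annotated target at least once.")
  }
  n_rest <- cfg$n_mapped_drugs - cfg$n_patho_drugs - cfg$trial_overlap - cfg$n_discordant
  if (n_rest < cfg$n_targets_after_exclusion - cfg$n_patho_targets) {
    abort("Not enough unannotated drugs to cover the unannotated targets.")
  }
  if (cfg$n_final_targets > cfg$n_patho_targets ||
      cfg$n_final_drugs < cfg$n_final_targets) {
    abort("`n_final_drugs`/`n_final_targets` are infeasible for the annotated target set.")
  }
  if (cfg$n_final_drugs + cfg$n_cmap_reversed + cfg$n_cmap_inactive > cfg$n_patho_drugs) {
    abort("The signature panel exceeds the surviving drug panel.")
  }
  if (cfg$sig_universe < cfg$n_tags_up + cfg$n_tags_down + 2L) {
    abort("`sig_universe` too small for the tag sets.")
  }
  if (!is.numeric(cfg$concentration) || cfg$concentration <= 0 ||
      cfg$concentration >= 1) {
    abort("`concentration` must lie in (0, 1).")
  }
  invisible(cfg)
}

## One named pseudo-random stream per file type: the label is hashed into the
## seed so streams are independent and adding a generator never shifts the
## draws of another.
label_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h * 131) %% 2147483641)
}

rs_id <- function(n) sprintf("rs%07d", sample.int(9999999L, n, replace = TRUE))

#' Generate the five evidence-source fixture files
#'
#' Writes GWAS, PheWAS, metabolite, transcriptome and biomedical tables into
#' `dir` with the per-source unique-gene counts, the planted multi-source
#' overlap, and log-uniform p-values in the configured ranges. Deterministic
#' under a fixed config.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths) and `truth` (universe,
#'   per-source gene lists, union, planted multi-source genes).
#' @export
generate_evidence <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(label_seed(config$seed, "evidence"))
  sizes <- config$source_sizes[EVIDENCE_SOURCES]
  universe <- sprintf("GN%05d", seq_len(config$n_universe))
  shuffled <- sample(universe)

  ## plant multi-source genes: each picks 2-3 sources, weighted by remaining
  ## capacity so small sources are not exhausted
  overlap_genes <- shuffled[seq_len(config$multi_source_overlap)]
  capacity <- sizes
  membership <- setNames(vector("list", length(overlap_genes)), overlap_genes)
  for (g in overlap_genes) {
    open <- names(capacity)[capacity > 0]
    if (length(open) < 2L) abort("Infeasible multi-source overlap for these source sizes.")
    k <- min(sample(c(2L, 3L), 1L, prob = c(0.8, 0.2)), length(open))
    chosen <- sample(open, k, prob = capacity[open])
    capacity[chosen] <- capacity[chosen] - 1L
    membership[[g]] <- chosen
  }
  source_genes <- lapply(EVIDENCE_SOURCES, function(s) {
    overlap_genes[map_lgl(membership, ~ s %in% .x)]
  })
  names(source_genes) <- EVIDENCE_SOURCES
  cursor <- config$multi_source_overlap
  for (s in EVIDENCE_SOURCES) {
    n_excl <- capacity[[s]]
    if (n_excl > 0) {
      source_genes[[s]] <- c(source_genes[[s]],
                             shuffled[cursor + seq_len(n_excl)])
      cursor <- cursor + n_excl
    }
  }
  stopifnot(all(lengths(source_genes) == sizes))

  log_unif <- function(n, range) exp(runif(n, log(min(range)), log(max(range))))

  ## GWAS: 1-3 risk alleles per gene, plus a few multi-gene cells and decoy
  ## traits that the parser must filter out
  gw_genes <- source_genes$GWAS
  gw_rows <- rep(gw_genes, times = sample(1:3, length(gw_genes), replace = TRUE))
  gwas <- tibble(
    trait = sample(c("Melanoma", "Cutaneous malignant melanoma"),
                   length(gw_rows), replace = TRUE),
    mapped_gene = gw_rows,
    snp = rs_id(length(gw_rows)),
    p_value = log_unif(length(gw_rows), config$gwas_p_range),
    ancestry = sample(c("European", "East Asian", "African"),
                      length(gw_rows), replace = TRUE),
    pubmed_id = sample.int(22000000L, length(gw_rows), replace = TRUE) + 10000000L
  )
  if (length(gw_genes) >= 4L) {
    pairs <- matrix(sample(gw_genes, 4L), ncol = 2L)
    gwas <- bind_rows(gwas, tibble(
      trait = "Melanoma",
      mapped_gene = paste(pairs[, 1], pairs[, 2], sep = ", "),
      snp = rs_id(2L),
      p_value = log_unif(2L, config$gwas_p_range),
      ancestry = "European",
      pubmed_id = sample.int(22000000L, 2L) + 10000000L
    ))
  }
  gwas <- bind_rows(gwas, tibble(
    trait = sample(c("Lung cancer", "Breast carcinoma"), 10L, replace = TRUE),
    mapped_gene = sprintf("ZZOFF%03d", 1:10),
    snp = rs_id(10L),
    p_value = log_unif(10L, c(1e-12, 1e-6)),
    ancestry = "European",
    pubmed_id = sample.int(22000000L, 10L, replace = TRUE) + 10000000L
  ))
  gwas <- gwas[sample(nrow(gwas)), ]

  ## PheWAS: ~3 alleles per gene
  ph_genes <- source_genes$PHEWAS
  ph_rows <- rep(ph_genes, times = 1L + rpois(length(ph_genes), 1.9))
  phewas <- tibble(
    snp = rs_id(length(ph_rows)),
    phenotype = sample(c("Melanoma", "Skin cancer"), length(ph_rows), replace = TRUE),
    p_value = log_unif(length(ph_rows), config$phewas_p_range),
    gene = ph_rows
  )
  phewas <- bind_rows(phewas, tibble(
    snp = rs_id(15L),
    phenotype = sample(c("Hypertension", "Type 2 diabetes"), 15L, replace = TRUE),
    p_value = log_unif(15L, c(1e-10, 0.05)),
    gene = sprintf("ZZOFF%03d", 11:25)
  ))
  phewas <- phewas[sample(nrow(phewas)), ]

  ## metabolite-protein associations: every metabolomics protein covered once,
  ## extra distinct pairs up to n_assocs
  prots <- source_genes$METABOLOMICS
  mets <- sprintf("metab_%02d", seq_len(config$n_metabolites))
  base <- tibble(metabolite = sample(mets, length(prots), replace = TRUE),
                 protein = prots)
  n_extra <- config$n_assocs - length(prots)
  pair_id <- function(m, p) (match(m, mets) - 1L) * length(prots) + match(p, prots)
  taken <- pair_id(base$metabolite, base$protein)
  pool <- setdiff(seq_len(length(mets) * length(prots)), taken)
  extra_idx <- sample(pool, n_extra)
  extra <- tibble(metabolite = mets[(extra_idx - 1L) %/% length(prots) + 1L],
                  protein = prots[(extra_idx - 1L) %% length(prots) + 1L])
  metab <- bind_rows(base, extra) |>
    mutate(role = sample(METABOLITE_ROLES, dplyr::n(), replace = TRUE,
                         prob = c(0.45, 0.35, 0.20)))
  metab <- metab[sample(nrow(metab)), ]

  biomedical <- tibble(gene = source_genes$BIOMEDICAL, omim_id = "155600",
                       disease = "Cutaneous malignant melanoma")

  files <- c(gwas = file.path(dir, "gwas.tsv"),
             phewas = file.path(dir, "phewas.tsv"),
             metabolites = file.path(dir, "metabolites.tsv"),
             transcriptome = file.path(dir, "transcriptome.txt"),
             biomedical = file.path(dir, "biomedical.tsv"))
  readr::write_tsv(gwas, files[["gwas"]])
  readr::write_tsv(phewas, files[["phewas"]])
  readr::write_tsv(metab, files[["metabolites"]])
  writeLines(source_genes$TRANSCRIPTOMICS, files[["transcriptome"]])
  readr::write_tsv(biomedical, files[["biomedical"]])

  union <- sort_cx(unique(unlist(source_genes)))
  truth <- list(universe = universe,
                source_genes = lapply(source_genes, sort_cx),
                union = union,
                n_union = length(union),
                multi_source_genes = sort_cx(overlap_genes),
                n_multi_source = length(overlap_genes),
                n_metabolites = length(mets),
                n_assocs = nrow(metab))
  invisible(list(files = files, truth = truth))
}

#' Generate the drug, trial and pathogenesis fixture files
#'
#' Builds a drug-target panel whose cascade behaviour is planted exactly:
#' `n_mapped_drugs` approved drugs over `n_mapped_targets` in-set targets
#' (plus group and off-target decoys that the mapping stage must reject), a
#' trial list overlapping the panel in exactly `trial_overlap` drugs, and
#' GOF/LOF annotations under which precisely `n_patho_drugs` drugs spanning
#' `n_patho_targets` targets survive the strict concordance filter, of which
#' `n_final_drugs` spanning `n_final_targets` targets form the
#' connectivity-active panel.
#'
#' @param config A [synth_config()].
#' @param evidence_truth The `truth` component of [generate_evidence()].
#' @param dir Output directory.
#' @return Invisibly, a list with `files` and `truth` (planted counts and the
#'   survivor / active drug lists).
#' @export
generate_pharm <- function(config, evidence_truth, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(label_seed(config$seed, "pharm"))
  union <- evidence_truth$union
  suppressing <- c("INHIBITOR", "ANTAGONIST", "BLOCKER")
  enhancing <- c("AGONIST", "INDUCER", "ACTIVATOR")

  targets <- sample(union, config$n_mapped_targets)
  annotated <- targets[seq_len(config$n_patho_targets)]
  unannotated <- setdiff(targets, annotated)
  n_lost <- config$n_mapped_targets - config$n_targets_after_exclusion
  u_excl <- unannotated[seq_len(n_lost)]          # covered only by excluded drugs
  u_rest <- setdiff(unannotated, u_excl)
  direction <- setNames(sample(PATHOGENESIS_DIRECTIONS, length(annotated),
                               replace = TRUE, prob = c(0.7, 0.3)), annotated)
  target_category <- setNames(sample(TARGET_CATEGORIES, length(targets),
                                     replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1)),
                              targets)
  indications <- c("Hypertension", "Congestive heart failure",
                   "Type 2 diabetes mellitus", "Rheumatoid arthritis",
                   "Chronic asthma", "Depression", "Tuberculosis",
                   "Peptic ulcer disease", "Urinary tract infection")

  drugs <- sprintf("drug_%04d", seq_len(config$n_mapped_drugs))
  drugs <- sample(drugs)
  survivors <- drugs[seq_len(config$n_patho_drugs)]
  excluded <- drugs[config$n_patho_drugs + seq_len(config$trial_overlap)]
  disc_n <- config$n_discordant
  discordant <- drugs[config$n_patho_drugs + config$trial_overlap + seq_len(disc_n)]
  rest <- setdiff(drugs, c(survivors, excluded, discordant))

  concordant_action <- function(tg) sample(
    if (direction[[tg]] == "GOF") suppressing else enhancing, 1L)
  discordant_action <- function(tg) sample(
    if (direction[[tg]] == "GOF") enhancing else suppressing, 1L)

  ## survivors: round-robin over annotated targets with a concordant action;
  ## the first n_final_drugs span exactly the first n_final_targets targets
  surv_target <- annotated[(seq_along(survivors) - 1L) %% length(annotated) + 1L]
  final_pool_idx <- which(match(surv_target, annotated) <= config$n_final_targets)
  if (length(final_pool_idx) < config$n_final_drugs) {
    abort("Infeasible final panel: too few survivors on the final target block.")
  }
  cover_idx <- final_pool_idx[match(seq_len(config$n_final_targets),
                                    match(surv_target[final_pool_idx], annotated))]
  extra_idx <- setdiff(final_pool_idx, cover_idx)
  active_idx <- sort(c(cover_idx,
                       sample(extra_idx,
                              config$n_final_drugs - config$n_final_targets)))
  active_drugs <- survivors[active_idx]

  surv_rows <- tibble(drug = survivors, target = surv_target) |>
    mutate(actions = map_chr(.data$target, concordant_action))
  ## some survivors also hit an unannotated target (judged on annotated only)
  extra_surv <- surv_rows |>
    dplyr::slice_sample(prop = 0.3) |>
    mutate(target = sample(u_rest, dplyr::n(), replace = TRUE),
           actions = sample(DRUG_ACTIONS, dplyr::n(), replace = TRUE))

  excl_target <- c(u_excl,
                   sample(targets, length(excluded) - length(u_excl), replace = TRUE))
  excl_rows <- tibble(drug = excluded, target = excl_target,
                      actions = sample(DRUG_ACTIONS, length(excluded), replace = TRUE))

  disc_rows <- tibble(drug = discordant,
                      target = sample(annotated, disc_n, replace = TRUE)) |>
    mutate(actions = map_chr(.data$target, discordant_action))

  rest_target <- c(u_rest,
                   sample(u_rest, length(rest) - length(u_rest), replace = TRUE))
  rest_rows <- tibble(drug = rest, target = rest_target[seq_along(rest)],
                      actions = sample(DRUG_ACTIONS, length(rest), replace = TRUE))

  mapped <- bind_rows(surv_rows, extra_surv, excl_rows, disc_rows, rest_rows) |>
    mutate(group = "APPROVED")

  decoy_group <- tibble(
    drug = sprintf("xdrug_group_%03d", seq_len(config$n_decoy_group)),
    target = sample(targets, config$n_decoy_group, replace = TRUE),
    actions = sample(DRUG_ACTIONS, config$n_decoy_group, replace = TRUE),
    group = sample(setdiff(DRUG_GROUPS, "APPROVED"), config$n_decoy_group,
                   replace = TRUE)
  )
  off_pool <- setdiff(evidence_truth$universe, union)
  decoy_off <- tibble(
    drug = sprintf("xdrug_off_%03d", seq_len(config$n_decoy_offtarget)),
    target = sample(off_pool, config$n_decoy_offtarget, replace = TRUE),
    actions = sample(DRUG_ACTIONS, config$n_decoy_offtarget, replace = TRUE),
    group = "APPROVED"
  )
  all_rows <- bind_rows(mapped, decoy_group, decoy_off)
  drug_names <- unique(all_rows$drug)
  drug_id <- setNames(sprintf("SB%05d", seq_along(drug_names)), drug_names)
  cat_for <- function(tg) {
    ifelse(tg %in% targets, target_category[tg],
           sample(TARGET_CATEGORIES, 1L))
  }
  drug_tbl <- all_rows |>
    mutate(drug_id = unname(drug_id[.data$drug]),
           target_category = map_chr(.data$target, cat_for),
           indication = sample(indications, dplyr::n(), replace = TRUE)) |>
    select("drug", "drug_id", "group", "target", "target_category",
           "actions", "indication")
  drug_tbl <- drug_tbl[sample(nrow(drug_tbl)), ]

  ## trial list: the planted overlap (some names case-mangled to exercise the
  ## name-level join) plus unrelated trial-only drugs
  overlap_names <- excluded
  mangle <- seq_along(overlap_names) %% 5L == 0L
  overlap_names[mangle] <- toupper(overlap_names[mangle])
  trials <- tibble(
    drug = c(overlap_names,
             sprintf("trialdrug_%03d",
                     seq_len(config$n_trial_drugs - length(excluded)))),
    stage = sample(paste("Phase", 0:4), config$n_trial_drugs, replace = TRUE),
    condition = "Melanoma"
  )
  trials <- trials[sample(nrow(trials)), ]

  patho <- tibble(
    target = annotated,
    direction = unname(direction[annotated]),
    description = sample(c("Oxygen binding", "Symporter activity",
                           "Steroid hydroxylase activity",
                           "Protein homodimerization activity",
                           "Oxidoreductase activity"),
                         length(annotated), replace = TRUE),
    provenance = "OMIM"
  ) |>
    arrange(.data$target)

  files <- c(drug_targets = file.path(dir, "drug_targets.tsv"),
             trials = file.path(dir, "trials.tsv"),
             pathogenesis = file.path(dir, "pathogenesis.tsv"))
  readr::write_tsv(mutate(drug_tbl, actions = .data$actions),
                   files[["drug_targets"]])
  readr::write_tsv(trials, files[["trials"]])
  readr::write_tsv(patho, files[["pathogenesis"]])

  truth <- list(
    n_mapped_targets = config$n_mapped_targets,
    n_mapped_drugs = config$n_mapped_drugs,
    trial_overlap = config$trial_overlap,
    n_post_exclusion_drugs = config$n_mapped_drugs - config$trial_overlap,
    n_targets_after_exclusion = config$n_targets_after_exclusion,
    n_patho_drugs = config$n_patho_drugs,
    n_patho_targets = config$n_patho_targets,
    survivor_drugs = sort_cx(survivors),
    annotated_targets = sort_cx(annotated),
    active_drugs = sort_cx(active_drugs),
    n_final_drugs = config$n_final_drugs,
    n_final_targets = config$n_final_targets
  )
  invisible(list(files = files, truth = truth))
}

## Strict permutation with up-tags biased toward the top and down-tags toward
## the bottom: rank positions drawn without replacement from truncated
## geometric weights (rate = concentration) from each end.
biased_ranking <- function(universe, top_genes, bottom_genes, rate) {
  n <- length(universe)
  ranking <- character(n)
  w_top <- (1 - rate)^(seq_len(n) - 1L)
  top_pos <- sample.int(n, length(top_genes), prob = w_top)
  avail <- setdiff(seq_len(n), top_pos)
  w_bot <- (1 - rate)^(n - avail)
  bottom_pos <- avail[sample.int(length(avail), length(bottom_genes), prob = w_bot)]
  ranking[top_pos] <- sample(top_genes)
  ranking[bottom_pos] <- sample(bottom_genes)
  free <- setdiff(seq_len(n), c(top_pos, bottom_pos))
  ranking[free] <- sample(setdiff(universe, c(top_genes, bottom_genes)))
  ranking
}

#' Generate the ranked-signature fixture panel
#'
#' Writes one RNK file per instance plus the instance manifest and the query
#' tag sets (GMT). Planted "active" drugs have the up-tags biased toward the
#' top ranks and the down-tags toward the bottom (truncated-geometric rank
#' bias with rate `concentration`); "reversed" drugs are biased the opposite
#' way; "inactive" drugs are uniform random permutations. The positive anchor
#' drugs are planted active and the negative anchors reversed.
#'
#' @param config A [synth_config()].
#' @param drug_panel Character vector of candidate drugs to draw the panel
#'   from (typically the cascade survivors); the planted active drugs must be
#'   members.
#' @param active_drugs Drugs to plant as active; defaults to the first
#'   `n_final_drugs` of `drug_panel`.
#' @param tags Optional list with `up`/`down` character vectors inside the
#'   signature universe; generated when omitted.
#' @param dir Output directory.
#' @return Invisibly, a list with `files` (manifest, tags GMT) and `truth`
#'   (active/reversed/inactive drug lists, panel, tag sets).
#' @export
generate_signatures <- function(config, drug_panel, dir, active_drugs = NULL,
                                tags = NULL) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(label_seed(config$seed, "signatures"))
  universe <- sprintf("G%05d", seq_len(config$sig_universe))
  if (is.null(tags)) {
    picks <- sample(universe, config$n_tags_up + config$n_tags_down)
    tags <- list(up = picks[seq_len(config$n_tags_up)],
                 down = picks[config$n_tags_up + seq_len(config$n_tags_down)])
  }
  if (!all(c(tags$up, tags$down) %in% universe)) {
    abort("Tag genes must lie inside the signature universe.")
  }
  if (is.null(active_drugs)) {
    active_drugs <- drug_panel[seq_len(config$n_final_drugs)]
  }
  if (!all(active_drugs %in% drug_panel)) {
    abort("`active_drugs` must be members of `drug_panel`.")
  }
  remaining <- sample(setdiff(drug_panel, active_drugs))
  reversed <- head(remaining, config$n_cmap_reversed)
  inactive <- head(setdiff(remaining, reversed), config$n_cmap_inactive)
  panel <- tibble(
    drug = c(active_drugs, reversed, inactive,
             config$anchors_pos, config$anchors_neg),
    mode = c(rep("active", length(active_drugs)),
             rep("reversed", length(reversed)),
             rep("inactive", length(inactive)),
             rep("active", length(config$anchors_pos)),
             rep("reversed", length(config$anchors_neg)))
  )
  inst <- panel[rep(seq_len(nrow(panel)), each = config$instances_per_drug), ]
  inst$instance_id <- sprintf("inst_%04d", seq_len(nrow(inst)))
  inst$cell_line <- sample(c("MCF7", "PC3", "HL60"), nrow(inst), replace = TRUE)
  inst$ranking <- map(inst$mode, function(mode) {
    switch(mode,
           active = biased_ranking(universe, tags$up, tags$down,
                                   config$concentration),
           reversed = biased_ranking(universe, tags$down, tags$up,
                                     config$concentration),
           inactive = sample(universe))
  })
  manifest <- write_signatures(select(inst, "instance_id", "drug", "cell_line",
                                      "ranking"), dir)
  tags_path <- file.path(dir, "tags.gmt")
  write_gmt(list(QUERY_UP = tags$up, QUERY_DOWN = tags$down), tags_path)
  truth <- list(active_drugs = sort_cx(setdiff(active_drugs, config$anchors_pos)),
                reversed_drugs = sort_cx(reversed),
                inactive_drugs = sort_cx(inactive),
                anchors_pos = config$anchors_pos,
                anchors_neg = config$anchors_neg,
                panel_drugs = sort_cx(unique(panel$drug)),
                n_scored_drugs = dplyr::n_distinct(panel$drug),
                tags = tags)
  invisible(list(files = c(manifest = manifest, tags = tags_path),
                 truth = truth))
}

#' Generate the complete fixture tree with its ground-truth manifest
#'
#' Runs the three generators in sequence and writes `truth.json`: every
#' planted count and drug/gene list a downstream recovery test needs, so
#' expectations are read from the manifest rather than hard-coded.
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @return Invisibly, the combined truth list (also serialized to
#'   `dir/truth.json`).
#' @export
generate_fixtures <- function(config = synth_config(), dir) {
  ev <- generate_evidence(config, dir)
  ph <- generate_pharm(config, ev$truth, dir)
  sig_panel <- ph$truth$survivor_drugs
  sg <- generate_signatures(config, drug_panel = sig_panel,
                            dir = file.path(dir, "signatures"),
                            active_drugs = ph$truth$active_drugs)
  truth <- list(evidence = ev$truth[setdiff(names(ev$truth), "universe")],
                pharm = ph$truth, signatures = sg$truth,
                seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(truth, list(files = c(ev$files, ph$files, sg$files))))
}
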