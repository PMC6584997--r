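test_that("infeasible configurations are rejected at construction", {
  expect_error(synth_config(multi_source_overlap = 600), "overlap")
  expect_error(synth_config(n_assocs = 100), "n_assocs")
  expect_error(synth_config(concentration = 0), "concentration")
  expect_error(synth_config(n_patho_drugs = 10), "n_patho_drugs")
  expect_error(synth_config(n_universe = 900), "n_universe")
  expect_error(synth_config(trial_overlap = 900), "trial_overlap")
})

test_that("regeneration under the same seed is byte-identical", {
  cfg <- small_config(seed = 3L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(generate_fixtures(cfg, d1))
  suppressMessages(generate_fixtures(cfg, d2))
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  suppressMessages(generate_fixtures(small_config(seed = 4L), d3))
  expect_false(identical(readLines(file.path(d1, "gwas.tsv")),
                         readLines(file.path(d3, "gwas.tsv"))))
})

test_that("generated evidence parses cleanly with the planted per-source counts", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  ev <- suppressMessages(generate_evidence(cfg, dir))
  gw <- suppressMessages(parse_gwas_evidence(file.path(dir, "gwas.tsv")))
  expect_equal(nrow(attr(gw, "rejects")), 0L)
  expect_equal(dplyr::n_distinct(gw$gene), cfg$source_sizes[["GWAS"]])
  expect_true(all(gw$p_value >= min(cfg$gwas_p_range) &
                    gw$p_value <= max(cfg$gwas_p_range)))
  ph <- suppressMessages(parse_phewas_evidence(file.path(dir, "phewas.tsv")))
  expect_equal(nrow(attr(ph, "rejects")), 0L)
  expect_equal(dplyr::n_distinct(ph$gene), cfg$source_sizes[["PHEWAS"]])
  expect_true(all(ph$p_value >= min(cfg$phewas_p_range) &
                    ph$p_value <= max(cfg$phewas_p_range)))
  met <- parse_metabolite_table(file.path(dir, "metabolites.tsv"))
  expect_equal(nrow(met$evidence), cfg$source_sizes[["METABOLOMICS"]])
  tx <- parse_gene_list(file.path(dir, "transcriptome.txt"), "TRANSCRIPTOMICS")
  expect_equal(nrow(tx), cfg$source_sizes[["TRANSCRIPTOMICS"]])
  bm <- parse_gene_list(file.path(dir, "biomedical.tsv"), "BIOMEDICAL")
  expect_equal(nrow(bm), cfg$source_sizes[["BIOMEDICAL"]])

  # planted overlap is recovered by the integration accounting
  prof <- build_profiles(dplyr::bind_rows(gw, ph, met$evidence, tx, bm))
  expect_equal(multi_source_total(venn_counts(prof)), cfg$multi_source_overlap)
  expect_equal(nrow(prof), ev$truth$n_union)
  expect_equal(unified_gene_set(prof), ev$truth$union)
})

test_that("zero planted overlap yields pairwise-disjoint sources", {
  cfg <- small_config()
  cfg$multi_source_overlap <- 0L
  dir <- withr::local_tempdir()
  ev <- suppressMessages(generate_evidence(cfg, dir))
  sg <- ev$truth$source_genes
  combos <- utils::combn(names(sg), 2)
  for (k in seq_len(ncol(combos))) {
    expect_length(intersect(sg[[combos[1, k]]], sg[[combos[2, k]]]), 0L)
  }
  expect_equal(ev$truth$n_union, sum(lengths(sg)))
})

test_that("inactive drugs score near zero and actives near one", {
  cfg <- small_config()
  cfg$n_cmap_inactive <- 3L
  cfg$instances_per_drug <- 20L
  cfg$n_final_drugs <- 3L
  cfg$n_cmap_reversed <- 3L
  dir <- withr::local_tempdir()
  sg <- generate_signatures(cfg, drug_panel = sprintf("drug_%02d", 1:12),
                            dir = dir)
  sigs <- read_signatures(file.path(dir, "manifest.tsv"))
  tags <- sg$truth$tags
  res <- aggregate_drugs(connectivity_scores(sigs, tags$up, tags$down))
  inact <- res$mean[res$drug %in% sg$truth$inactive_drugs]
  expect_true(all(abs(inact) < 0.15))
  act <- res$mean[res$drug %in% sg$truth$active_drugs]
  expect_true(all(act > 0.8))
  rev <- res$mean[res$drug %in% sg$truth$reversed_drugs]
  expect_true(all(rev < -0.8))
})

test_that("planted actives are recovered by anchor selection with high sensitivity", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  sg <- generate_signatures(cfg, drug_panel = sprintf("drug_%02d", 1:30), dir = dir)
  sigs <- read_signatures(file.path(dir, "manifest.tsv"))
  tags <- sg$truth$tags
  res <- aggregate_drugs(connectivity_scores(sigs, tags$up, tags$down))
  sel <- select_candidates(res, anchors_pos = cfg$anchors_pos,
                           anchors_neg = cfg$anchors_neg)
  retained <- sel$drug[sel$decision == "RETAINED"]
  sens <- mean(sg$truth$active_drugs %in% retained)
  expect_gte(sens, 0.9)
  expect_length(intersect(sg$truth$reversed_drugs, retained), 0L)
})
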