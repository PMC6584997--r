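mini_drug_targets <- function() {
  parse_drug_targets(drug_file(c(
    "Milrinone\tDB1\tapproved\tPDE3A\tenzyme\tinhibitor\tCHF",
    "DrugX\tDB2\texperimental\tPDE3A\tenzyme\tinhibitor\tNA",
    "DrugY\tDB3\tapproved\tZZZ9\tprotein\tbinder\tNA",
    "Gefitinib\tDB4\tapproved\tEGFR\tprotein\tantagonist\tNSCLC",
    "Estradiol\tDB5\tapproved\tESR1\tprotein\tagonist\tVasomotor symptoms"
  )))
}

test_that("drug mapping respects the approval-group and gene-set filters", {
  dt <- mini_drug_targets()
  cascade <- map_drugs(dt, c("PDE3A", "EGFR", "ESR1"))
  expect_setequal(unique(tidy(cascade)$drug), c("Milrinone", "Gefitinib", "Estradiol"))
  cc <- cascade_counts(cascade)
  expect_equal(cc$drugs[cc$stage == "map"], 3L)
  expect_equal(cc$targets[cc$stage == "map"], 3L)

  # empty gene set maps nothing
  expect_equal(nrow(tidy(map_drugs(dt, character()))), 0L)

  # trace completeness: every input drug decided exactly once at this stage
  tr <- cascade_trace(cascade)
  expect_setequal(tr$drug, unique(dt$drug))
  expect_equal(anyDuplicated(tr$drug), 0L)
  expect_equal(tr$reason[tr$drug == "DrugX"], "GROUP_EXCLUDED")
  expect_equal(tr$reason[tr$drug == "DrugY"], "NO_TARGET_IN_SET")
})

test_that("known-indication exclusion matches names case/punctuation-insensitively", {
  cascade <- map_drugs(mini_drug_targets(), c("PDE3A", "EGFR", "ESR1"))
  trials <- parse_trials(trial_file(c("GEFITINIB\tPhase 2\tMelanoma",
                                      "mil-rinone\tPhase 1\tMelanoma")))
  out <- exclude_known(cascade, trials)
  expect_equal(out$trial_overlap, 2L)
  expect_equal(unique(tidy(out)$drug), "Estradiol")

  # empty trial list retains everything
  none <- exclude_known(cascade, parse_trials(trial_file(character())))
  expect_equal(none$trial_overlap, 0L)
  expect_equal(nrow(tidy(none)), nrow(tidy(cascade)))
})

test_that("the strict concordance verdicts match the hand-written truth table", {
  truth <- tibble::tribble(
    ~direction, ~action,      ~verdict,
    "GOF", "INHIBITOR",  "CONCORDANT",
    "GOF", "ANTAGONIST", "CONCORDANT",
    "GOF", "BLOCKER",    "CONCORDANT",
    "GOF", "AGONIST",    "DISCORDANT",
    "GOF", "INDUCER",    "DISCORDANT",
    "GOF", "ACTIVATOR",  "DISCORDANT",
    "GOF", "SUBSTRATE",  "NEUTRAL",
    "GOF", "BINDER",     "NEUTRAL",
    "GOF", "UNKNOWN",    "NEUTRAL",
    "LOF", "INHIBITOR",  "DISCORDANT",
    "LOF", "ANTAGONIST", "DISCORDANT",
    "LOF", "BLOCKER",    "DISCORDANT",
    "LOF", "AGONIST",    "CONCORDANT",
    "LOF", "INDUCER",    "CONCORDANT",
    "LOF", "ACTIVATOR",  "CONCORDANT",
    "LOF", "SUBSTRATE",  "NEUTRAL",
    "LOF", "BINDER",     "NEUTRAL",
    "LOF", "UNKNOWN",    "NEUTRAL"
  )
  expect_equal(concordance(truth$direction, truth$action, "strict"),
               truth$verdict)
  # invalid enum values error by name
  expect_error(concordance("GAIN", "INHIBITOR"), "GAIN")
  expect_error(concordance("GOF", "POTENTIATOR"), "POTENTIATOR")
})

test_that("the lenient policy only softens discordant targets with a neutral co-action", {
  # single action: policies agree
  expect_equal(concordance("GOF", "AGONIST", "lenient"), "DISCORDANT")
  # action set {AGONIST, SUBSTRATE} on a GOF target: strict condemns, lenient softens
  cascade <- map_drugs(parse_drug_targets(drug_file(
    "DrugZ\tDB9\tapproved\tMYC\tprotein\tagonist; substrate\tNA"
  )), "MYC")
  ann <- parse_pathogenesis(patho_file("MYC\tGOF\tx\tOMIM"))
  expect_equal(nrow(tidy(pathogenesis_filter(cascade, ann, "strict"))), 0L)
  expect_equal(unique(tidy(pathogenesis_filter(cascade, ann, "lenient"))$drug),
               "DrugZ")
})

test_that("the concordance filter keeps drugs with a concordant or neutral annotated target", {
  dt <- parse_drug_targets(drug_file(c(
    "KeepMe\tDB1\tapproved\tPDE3A\tenzyme\tinhibitor\tx",     # GOF x inhibitor
    "NeutralOne\tDB2\tapproved\tNAT2\tenzyme\tsubstrate\tx",  # LOF x substrate
    "DropMe\tDB3\tapproved\tPDE3A\tenzyme\tagonist\tx",       # GOF x agonist
    "NoAnnot\tDB4\tapproved\tORPHAN1\tprotein\tinhibitor\tx"
  )))
  cascade <- map_drugs(dt, c("PDE3A", "NAT2", "ORPHAN1"))
  ann <- parse_pathogenesis(patho_file(c("PDE3A\tGOF\tx\tOMIM",
                                         "NAT2\tLOF\ty\tOMIM")))
  out <- pathogenesis_filter(cascade, ann, "strict")
  expect_setequal(unique(tidy(out)$drug), c("KeepMe", "NeutralOne"))
  tr <- cascade_trace(out)
  patho <- tr[tr$stage == "PATHOGENESIS", ]
  expect_equal(patho$reason[patho$drug == "DropMe"], "DISCORDANT")
  expect_equal(patho$reason[patho$drug == "NoAnnot"], "NO_ANNOTATION")
  # verdict columns on the retained rows
  expect_setequal(tidy(out)$verdict, c("CONCORDANT", "NEUTRAL"))
})

test_that("each cascade stage retains a subset of its input (monotonicity, fuzzed)", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    genes <- sprintf("T%02d", 1:12)
    dt <- tibble::tibble(
      drug = sprintf("d%02d", sample(1:15, n, replace = TRUE)),
      drug_id = NA_character_,
      group = sample(c("APPROVED", "EXPERIMENTAL"), n, replace = TRUE,
                     prob = c(0.8, 0.2)),
      target = sample(c(genes, "OFF1", "OFF2"), n, replace = TRUE),
      target_category = "PROTEIN",
      actions = as.list(sample(c("INHIBITOR", "AGONIST", "SUBSTRATE"), n,
                               replace = TRUE)),
      indication = NA_character_
    )
    trials <- tibble::tibble(drug = sprintf("d%02d", sample(1:15, 4)),
                             stage = NA, condition = NA)
    ann <- tibble::tibble(target = sample(genes, 6),
                          direction = sample(c("GOF", "LOF"), 6, replace = TRUE),
                          description = NA, provenance = NA)
    s1 <- map_drugs(dt, genes)
    s2 <- exclude_known(s1, trials)
    s3 <- pathogenesis_filter(s2, ann)
    expect_true(all(unique(tidy(s2)$drug) %in% unique(tidy(s1)$drug)))
    expect_true(all(unique(tidy(s3)$drug) %in% unique(tidy(s2)$drug)))
    # trace completeness at every stage: one decision per in-flight drug
    tr <- cascade_trace(s3)
    for (st in unique(tr$stage)) {
      expect_equal(anyDuplicated(tr$drug[tr$stage == st]), 0L)
    }
  }
})

test_that("planted cascade counts are recovered from a generated fixture", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  ev <- suppressMessages(generate_evidence(cfg, dir))
  ph <- generate_pharm(cfg, ev$truth, dir)
  genes <- unified_gene_set(build_profiles(dplyr::bind_rows(
    suppressMessages(parse_gwas_evidence(file.path(dir, "gwas.tsv"))),
    suppressMessages(parse_phewas_evidence(file.path(dir, "phewas.tsv"))),
    parse_metabolite_table(file.path(dir, "metabolites.tsv"))$evidence,
    parse_gene_list(file.path(dir, "transcriptome.txt"), "TRANSCRIPTOMICS"),
    parse_gene_list(file.path(dir, "biomedical.tsv"), "BIOMEDICAL")
  )))
  cascade <- map_drugs(parse_drug_targets(file.path(dir, "drug_targets.tsv")), genes)
  cc <- cascade_counts(cascade)
  expect_equal(cc$drugs[cc$stage == "map"], cfg$n_mapped_drugs)
  expect_equal(cc$targets[cc$stage == "map"], cfg$n_mapped_targets)
  cascade <- exclude_known(cascade, parse_trials(file.path(dir, "trials.tsv")))
  expect_equal(cascade$trial_overlap, cfg$trial_overlap)
  cascade <- pathogenesis_filter(
    cascade, parse_pathogenesis(file.path(dir, "pathogenesis.tsv")), "strict")
  cc <- cascade_counts(cascade)
  expect_equal(cc$drugs[cc$stage == "pathofilter"], cfg$n_patho_drugs)
  expect_equal(cc$targets[cc$stage == "pathofilter"], cfg$n_patho_targets)
  expect_setequal(unique(tidy(cascade)$drug), ph$truth$survivor_drugs)
})
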