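test_that("GWAS parsing filters by trait, explodes multi-gene cells and keeps p <= p_max", {
  path <- gwas_file(c(
    "Melanoma\tTERT\trs2853677\t4e-37\tEuropean\t123",
    "Lung cancer\tKRAS\trs100\t1e-10\tEuropean\t124",
    "melanoma\tTERT, CLPTM1L\trs200\t2e-8\tEuropean\t125",
    "Cutaneous malignant melanoma\tMC1R - TUBB3\trs300\t5e-9\tEast Asian\t126"
  ))
  out <- suppressMessages(parse_gwas_evidence(path, p_max = 8e-06))
  expect_equal(sort(out$gene), c("CLPTM1L", "MC1R", "TERT", "TERT", "TUBB3"))
  expect_true(all(out$source == "GWAS"))
  # exploded records share the SNP and p-value of their row
  pair <- out[out$snp_id == "rs200", ]
  expect_equal(nrow(pair), 2L)
  expect_equal(unique(pair$p_value), 2e-8)

  # trait-only filter: a non-matching trait contributes nothing
  expect_false("KRAS" %in% out$gene)

  # stricter p_max can only shrink the output (filter monotonicity)
  sizes <- vapply(c(1, 1e-7, 1e-8, 1e-20, 1e-40), function(p) {
    nrow(suppressMessages(parse_gwas_evidence(path, p_max = p)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("PheWAS threshold is inclusive and unparseable p-values are rejected row-wise", {
  path <- phewas_file(c(
    "rs1\tMelanoma\t1.106e-16\tTYR",
    "rs2\tSkin cancer\t0.05\tASIP",
    "rs3\tMelanoma\t0.06\tOCA2",
    "rs4\tMelanoma\tnot_a_number\tMITF"
  ))
  out <- suppressMessages(parse_phewas_evidence(path))
  expect_setequal(out$gene, c("TYR", "ASIP"))   # 0.05 kept, 0.06 dropped
  rej <- attr(out, "rejects")
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "not_a_number")
})

test_that("a missing mandatory column is reported by name", {
  path <- write_tmp(c("trait\tsnp\tp_value", "Melanoma\trs1\t1e-8"))
  expect_error(suppressMessages(parse_gwas_evidence(path)), "gene")
})

test_that("metabolite tables deduplicate pairs and yield one record per protein", {
  path <- metab_file(c(
    "Tyrosine\tCYP1B1\tenzyme",
    "Dopamine\tCYP1B1\tenzyme",
    "Dopamine\tCYP1B1\tenzyme",      # exact duplicate
    "Dopamine\tSLC22A5\ttransporter"
  ))
  out <- parse_metabolite_table(path)
  expect_equal(nrow(out$associations), 3L)
  expect_equal(nrow(out$evidence), 2L)
  expect_true(all(out$evidence$source == "METABOLOMICS"))
  expect_true(all(!is.na(out$evidence$metabolite)))

  # unknown role tokens downgrade to UNKNOWN with a warning
  path2 <- metab_file("Tyrosine\tTYR\tcofactor")
  expect_warning(out2 <- parse_metabolite_table(path2), "UNKNOWN")
  expect_equal(out2$associations$role, "UNKNOWN")

  # empty file with header
  empty <- parse_metabolite_table(metab_file(character()))
  expect_equal(nrow(empty$associations), 0L)
  expect_equal(nrow(empty$evidence), 0L)
})

test_that("gene lists harmonize, deduplicate and tag the requested source", {
  path <- write_tmp(c("tyr", "TYR ", " Tert"), ext = "txt")
  out <- parse_gene_list(path, "TRANSCRIPTOMICS")
  expect_setequal(out$gene, c("TYR", "TERT"))
  expect_true(all(out$source == "TRANSCRIPTOMICS"))
  expect_equal(nrow(parse_gene_list(write_tmp(character(), ext = "txt"),
                                    "BIOMEDICAL")), 0L)
  # a delimited file contributes its gene column only
  tab <- write_tmp(c("gene\tomim_id", "CDKN2A\t155600"))
  expect_equal(parse_gene_list(tab, "BIOMEDICAL")$gene, "CDKN2A")
})

test_that("drug-target records parse groups, categories and multi-action cells", {
  path <- drug_file(c(
    "Milrinone\tDB00235\tapproved\tPDE3A\tenzyme\tinhibitor\tCongestive heart failure",
    "Theophylline\tDB00277\tapproved\tCYP1A2\tenzyme\tinhibitor; substrate\tChronic asthma",
    "Mystery\tDB99999\texperimental\tEGFR\tprotein\t\tNA"
  ))
  out <- parse_drug_targets(path)
  expect_equal(out$group, c("APPROVED", "APPROVED", "EXPERIMENTAL"))
  expect_equal(out$actions[[2]], c("INHIBITOR", "SUBSTRATE"))
  expect_equal(out$actions[[3]], "UNKNOWN")   # empty cell, never dropped

  # same drug_id under two names is an input error
  dup <- drug_file(c(
    "DrugA\tDB1\tapproved\tTYR\tenzyme\tinhibitor\tx",
    "DrugB\tDB1\tapproved\tTERT\tenzyme\tinhibitor\tx"
  ))
  expect_error(parse_drug_targets(dup), "DB1")
})

test_that("pathogenesis parsing rejects conflicting GOF/LOF annotations by target", {
  ok <- parse_pathogenesis(patho_file(c(
    "TERT\tGOF\tTelomerase activation\tOMIM",
    "TERT\tGOF\tTelomerase activation\tOMIM",    # identical duplicate collapses
    "OCA2\tLOF\tPigmentation\tOMIM"
  )))
  expect_equal(nrow(ok), 2L)
  expect_error(
    parse_pathogenesis(patho_file(c("TERT\tGOF\tx\tOMIM", "TERT\tLOF\ty\tOMIM"))),
    "TERT"
  )
})

test_that("trial lists drop blank drug names with a warning", {
  path <- trial_file(c("Dacarbazine\tPhase 3\tMelanoma", "\tPhase 1\tMelanoma"))
  expect_warning(out <- parse_trials(path), "empty drug name")
  expect_equal(out$drug, "Dacarbazine")
})

test_that("evidence and drug-target tables round-trip through write and re-parse", {
  path <- gwas_file(c("Melanoma\tTERT\trs1\t4e-37\tEuropean\t1",
                      "Melanoma\tTYR\trs2\t1e-9\tEuropean\t2"))
  recs <- suppressMessages(parse_gwas_evidence(path))
  out_path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(recs, out_path)
  back <- read_evidence(out_path)
  expect_equal(as.data.frame(back), as.data.frame(recs[names(back)]),
               ignore_attr = TRUE)

  dt <- parse_drug_targets(drug_file(
    "Milrinone\tDB00235\tapproved\tPDE3A\tenzyme\tinhibitor|substrate\tCHF"))
  dt_path <- withr::local_tempfile(fileext = ".tsv")
  write_drug_targets(dt, dt_path)
  expect_equal(as.data.frame(parse_drug_targets(dt_path)), as.data.frame(dt),
               ignore_attr = TRUE)
})

test_that("every emitted symbol is in harmonization normal form", {
  path <- gwas_file(c("Melanoma\t tert , clptm1l\trs1\t1e-8\tEuropean\t1"))
  recs <- suppressMessages(parse_gwas_evidence(path))
  expect_true(all(recs$gene == toupper(trimws(recs$gene))))
  expect_setequal(recs$gene, c("TERT", "CLPTM1L"))
  # alias mapping applies after uppercasing
  expect_equal(harmonize_genes("cyp450_1b1", c(CYP450_1B1 = "CYP1B1")), "CYP1B1")
})
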