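## Readers for the five evidence-source table dialects plus the drug, trial and
## pathogenesis tables. Every reader returns plain tibbles in the shared record
## layouts; gene/protein symbols are harmonized on the way in.

GWAS_COLS <- list(
  trait = c("trait", "disease_trait", "disease/trait", "phenotype", "disease"),
  gene = c("gene", "mapped_gene", "gene_name", "reported_gene", "genes", "nearest_gene"),
  snp = c("snp", "snps", "snp_id", "rsid", "strongest_snp"),
  p_value = c("p_value", "p-value", "pvalue", "p", "p.value"),
  citation = c("pubmed_id", "pubmedid", "pmid", "citation", "link")
)

## Split multi-gene cells: comma/semicolon lists and intergenic "A - B" labels
## both yield one record per gene.
explode_genes <- function(x) {
  str_split(x, "[,;]|\\s+-\\s+")
}

parse_assoc_evidence <- function(path, keep, p_max, source, col_spec,
                                 keep_col, col_map, aliases) {
  spec <- merge_col_map(col_spec, col_map)
  df <- read_table_auto(path)
  idx <- resolve_columns(df, spec, mandatory = c(keep_col, "gene", "snp", "p_value"),
                         file = path)
  if (nrow(df) == 0L) {
    res <- empty_evidence()
    attr(res, "rejects") <- tibble(row = integer(), reason = character())
    return(res)
  }
  raw <- tibble(
    trait = col_or_na(df, idx[[keep_col]]),
    gene = col_or_na(df, idx$gene),
    snp_id = col_or_na(df, idx$snp),
    p_raw = col_or_na(df, idx$p_value),
    citation = col_or_na(df, idx$citation),
    row = seq_len(nrow(df))
  )
  raw$p_value <- suppressWarnings(as.numeric(raw$p_raw))
  bad_p <- !is.na(raw$p_raw) & is.na(raw$p_value) |
    (!is.na(raw$p_value) & (raw$p_value <= 0 | raw$p_value > 1))
  rejects <- tibble(row = raw$row[bad_p], reason = paste0("unparseable p-value: ", raw$p_raw[bad_p]))
  ok <- raw[!bad_p & !is.na(raw$p_value), , drop = FALSE]

  ok <- ok[tolower(str_squish(ok$trait)) %in% tolower(keep) & ok$p_value <= p_max, , drop = FALSE]
  out <- ok |>
    mutate(gene = explode_genes(.data$gene)) |>
    unnest(gene) |>
    mutate(gene = harmonize_genes(.data$gene, aliases)) |>
    filter(.data$gene != "") |>
    transmute(gene = .data$gene, source = source, trait = str_squish(.data$trait),
              p_value = .data$p_value, snp_id = .data$snp_id,
              metabolite = NA_character_, role = NA_character_,
              citation = .data$citation)
  inform(paste0(path, ": ", nrow(out), " ", source, " records accepted, ",
                nrow(rejects), " rows rejected."))
  attr(out, "rejects") <- rejects
  out
}

#' Parse GWAS catalog style evidence
#'
#' Reads a delimited table of SNP-trait associations (trait, mapped gene, SNP,
#' p-value columns; synonyms accepted), keeps the rows whose trait matches the
#' requested disease traits case-insensitively and whose p-value does not
#' exceed `p_max`, and emits one harmonized evidence record per gene. Cells
#' listing several genes (comma/semicolon separated, or intergenic
#' `"GENE1 - GENE2"` labels) are exploded into one record each.
#'
#' Rows with an unparseable p-value are skipped and collected into a rejects
#' report attached as `attr(x, "rejects")`.
#'
#' @param path Path to a TSV/CSV file.
#' @param traits Character vector of disease/trait names to retain
#'   (case-insensitive exact match after whitespace squishing).
#' @param p_max Inclusive upper bound on the association p-value. The default 1
#'   applies no filter: catalog extracts are usually already thresholded, and
#'   the observed range is reported rather than enforced.
#' @param col_map Optional named list of extra column-name synonyms, e.g.
#'   `list(gene = "MAPPED_GENE(S)")`.
#' @param aliases Optional symbol alias map, see [harmonize_genes()].
#'
#' @return A tibble of evidence records (`gene`, `source`, `trait`, `p_value`,
#'   `snp_id`, `metabolite`, `role`, `citation`) with `source = "GWAS"`.
#' @seealso [parse_phewas_evidence()], [build_profiles()]
#' @export
parse_gwas_evidence <- function(path,
                                traits = c("melanoma", "cutaneous malignant melanoma"),
                                p_max = 1, col_map = NULL, aliases = NULL) {
  stopifnot(length(traits) >= 1, is.numeric(p_max), length(p_max) == 1L)
  parse_assoc_evidence(path, traits, p_max, "GWAS", GWAS_COLS, "trait",
                       col_map, aliases)
}

#' Parse PheWAS catalog style evidence
#'
#' Same contract as [parse_gwas_evidence()], but the retained column is the
#' PheWAS phenotype and the default p-value ceiling is 0.05 (inclusive), the
#' upper end of the catalog's significant range.
#'
#' @inheritParams parse_gwas_evidence
#' @param phenotypes Phenotype names to retain (case-insensitive).
#' @return A tibble of evidence records with `source = "PHEWAS"`.
#' @export
parse_phewas_evidence <- function(path,
                                  phenotypes = c("melanoma", "skin cancer"),
                                  p_max = 0.05, col_map = NULL, aliases = NULL) {
  stopifnot(length(phenotypes) >= 1, is.numeric(p_max), length(p_max) == 1L)
  spec <- GWAS_COLS
  spec$trait <- c("phenotype", "phewas_phenotype", spec$trait)
  parse_assoc_evidence(path, phenotypes, p_max, "PHEWAS", spec, "trait",
                       col_map, aliases)
}

#' Parse a metabolite-protein association table
#'
#' Reads HMDB-derived metabolite-to-protein associations with their role
#' (enzyme/transporter), deduplicates them, and derives one METABOLOMICS
#' evidence record per unique protein.
#'
#' @inheritParams parse_gwas_evidence
#' @return A list with components `associations` (tibble `metabolite`,
#'   `protein`, `role`) and `evidence` (one evidence record per unique
#'   protein; the `metabolite` field carries the first associated metabolite
#'   alphabetically).
#' @export
parse_metabolite_table <- function(path, col_map = NULL, aliases = NULL) {
  spec <- merge_col_map(list(
    metabolite = c("metabolite", "metabolite_name", "compound"),
    protein = c("protein", "gene", "protein_name", "symbol", "gene_name"),
    role = c("role", "type", "protein_type", "function")
  ), col_map)
  df <- read_table_auto(path)
  idx <- resolve_columns(df, spec, mandatory = c("metabolite", "protein"), file = path)
  if (nrow(df) == 0L) {
    return(list(associations = tibble(metabolite = character(), protein = character(),
                                      role = character()),
                evidence = empty_evidence()))
  }
  role <- str_to_upper(str_squish(col_or_na(df, idx$role)))
  role[is.na(role) | role == ""] <- "UNKNOWN"
  unknown <- setdiff(unique(role), METABOLITE_ROLES)
  if (length(unknown)) {
    warn(paste0("Unknown role token(s) mapped to UNKNOWN: ",
                paste(unknown, collapse = ", ")))
    role[role %in% unknown] <- "UNKNOWN"
  }
  assoc <- tibble(
    metabolite = str_squish(as.character(df[[idx$metabolite]])),
    protein = harmonize_genes(df[[idx$protein]], aliases),
    role = role
  ) |>
    filter(.data$metabolite != "", .data$protein != "") |>
    distinct(.data$metabolite, .data$protein, .data$role)
  ev <- assoc |>
    arrange(.data$protein, .data$metabolite) |>
    group_by(.data$protein) |>
    summarise(metabolite = first(.data$metabolite), role = first(.data$role),
              .groups = "drop") |>
    transmute(gene = .data$protein, source = "METABOLOMICS", trait = NA_character_,
              p_value = NA_real_, snp_id = NA_character_,
              metabolite = .data$metabolite, role = .data$role,
              citation = NA_character_)
  list(associations = assoc, evidence = ev)
}

#' Parse a plain gene list
#'
#' One symbol per line (or a one-column table); harmonized and deduplicated,
#' tagged with the given evidence source. Used for the differentially
#' expressed transcriptome list and the OMIM-derived biomedical gene set.
#'
#' @inheritParams parse_gwas_evidence
#' @param source One of `"TRANSCRIPTOMICS"` or `"BIOMEDICAL"` (any evidence
#'   source is accepted).
#' @return A tibble of evidence records.
#' @export
parse_gene_list <- function(path, source, aliases = NULL) {
  assert_sources(source)
  stopifnot(length(source) == 1L)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("[\t,]", lines[[1]])) {
    ## delimited table: take its gene column (or the first column)
    df <- read_table_auto(path)
    idx <- resolve_columns(df, list(gene = c("gene", "symbol", "gene_name",
                                             "genes", "protein")),
                           mandatory = character(), file = path)
    lines <- if (is.na(idx$gene)) as.character(df[[1]]) else col_or_na(df, idx$gene)
  } else if (length(lines) && grepl("^(gene|symbol|gene_name)s?$",
                                    trimws(lines[[1]]), ignore.case = TRUE)) {
    ## one-column list with a header
    lines <- lines[-1]
  }
  lines <- lines[!is.na(lines)]
  genes <- unique(harmonize_genes(lines[str_squish(lines) != ""], aliases))
  if (!length(genes)) return(empty_evidence())
  tibble(gene = genes, source = source, trait = NA_character_,
         p_value = NA_real_, snp_id = NA_character_, metabolite = NA_character_,
         role = NA_character_, citation = NA_character_)
}

#' Parse a drug-target table
#'
#' Reads DrugBank-style drug-target records: drug name and accession,
#' approval group, target symbol and category, action mode(s) and current
#' indication. Multi-action cells split on comma/semicolon/pipe into an action
#' set (list-column); unmapped action tokens become `UNKNOWN` with a warning
#' rather than being dropped, so downstream counts are unaffected.
#'
#' @inheritParams parse_gwas_evidence
#' @return A tibble (`drug`, `drug_id`, `group`, `target`, `target_category`,
#'   `actions` list-column, `indication`), one row per drug-target link.
#' @export
parse_drug_targets <- function(path, col_map = NULL, aliases = NULL) {
  spec <- merge_col_map(list(
    drug = c("drug", "drug_name", "name"),
    drug_id = c("drug_id", "drugbank_id", "id", "accession"),
    group = c("group", "groups", "drug_group", "status"),
    target = c("target", "target_name", "gene", "symbol", "gene_name"),
    target_category = c("target_category", "category", "target_type"),
    actions = c("actions", "action", "action_mode", "mode_of_action"),
    indication = c("indication", "indications", "current_indication")
  ), col_map)
  df <- read_table_auto(path)
  idx <- resolve_columns(df, spec, mandatory = c("drug", "group", "target"), file = path)
  out <- tibble(
    drug = str_squish(col_or_na(df, idx$drug)),
    drug_id = str_squish(col_or_na(df, idx$drug_id)),
    group = str_to_upper(str_squish(col_or_na(df, idx$group))),
    target = harmonize_genes(col_or_na(df, idx$target), aliases),
    target_category = str_to_upper(str_squish(col_or_na(df, idx$target_category))),
    actions_raw = col_or_na(df, idx$actions),
    indication = col_or_na(df, idx$indication)
  )
  bad_group <- setdiff(unique(out$group), c(DRUG_GROUPS, NA))
  if (length(bad_group)) {
    abort(paste0("Unknown drug group(s): ", paste(bad_group, collapse = ", ")))
  }
  out$target_category[is.na(out$target_category)] <- "PROTEIN"
  bad_cat <- setdiff(unique(out$target_category), TARGET_CATEGORIES)
  if (length(bad_cat)) {
    abort(paste0("Unknown target category(s): ", paste(bad_cat, collapse = ", ")))
  }
  acts <- map(str_split(out$actions_raw, "[,;|]"), function(a) {
    a <- str_to_upper(str_squish(a))
    a <- a[!is.na(a) & a != ""]
    if (!length(a)) return("UNKNOWN")
    sort_cx(unique(a))
  })
  unknown <- setdiff(unique(unlist(acts)), DRUG_ACTIONS)
  if (length(unknown)) {
    warn(paste0("Unknown action token(s) mapped to UNKNOWN: ",
                paste(unknown, collapse = ", ")))
    acts <- map(acts, function(a) {
      a[a %in% unknown] <- "UNKNOWN"
      sort_cx(unique(a))
    })
  }
  out$actions <- acts
  out$actions_raw <- NULL
  conflict <- out |>
    distinct(.data$drug_id, .data$drug) |>
    filter(!is.na(.data$drug_id)) |>
    count(.data$drug_id) |>
    filter(.data$n > 1L)
  if (nrow(conflict)) {
    abort(paste0("Multiple drug names share one drug_id: ",
                 paste(conflict$drug_id, collapse = ", ")))
  }
  relocate(out, "drug", "drug_id", "group", "target", "target_category",
           "actions", "indication")
}

#' Parse a trial (known indication) drug list
#'
#' @inheritParams parse_gwas_evidence
#' @return A tibble (`drug`, `stage`, `condition`); blank drug names are
#'   dropped with a warning.
#' @export
parse_trials <- function(path, col_map = NULL) {
  spec <- merge_col_map(list(
    drug = c("drug", "drug_name", "intervention", "name"),
    stage = c("stage", "phase", "status", "phase_status"),
    condition = c("condition", "disease", "indication")
  ), col_map)
  df <- read_table_auto(path)
  idx <- resolve_columns(df, spec, mandatory = "drug", file = path)
  out <- tibble(
    drug = str_squish(col_or_na(df, idx$drug)),
    stage = col_or_na(df, idx$stage),
    condition = col_or_na(df, idx$condition)
  )
  blank <- is.na(out$drug) | out$drug == ""
  if (any(blank)) {
    warn(paste0(sum(blank), " trial rows with empty drug name dropped."))
  }
  out[!blank, , drop = FALSE]
}

#' Parse a pathogenesis (GOF/LOF) annotation table
#'
#' One annotation per target: the pathogenic direction of the gene's
#' contribution to melanoma (gain or loss of function), a free-text
#' description, and the provenance of the call (e.g. an OMIM-derived flag).
#' Duplicate rows carrying conflicting directions for the same target are an
#' input error; identical duplicates are collapsed.
#'
#' @inheritParams parse_gwas_evidence
#' @return A tibble (`target`, `direction`, `description`, `provenance`).
#' @export
parse_pathogenesis <- function(path, col_map = NULL, aliases = NULL) {
  spec <- merge_col_map(list(
    target = c("target", "gene", "symbol", "gene_name"),
    direction = c("direction", "pathogenesis", "gof_lof", "role"),
    description = c("description", "annotation", "details"),
    provenance = c("provenance", "source", "origin")
  ), col_map)
  df <- read_table_auto(path)
  idx <- resolve_columns(df, spec, mandatory = c("target", "direction"), file = path)
  out <- tibble(
    target = harmonize_genes(col_or_na(df, idx$target), aliases),
    direction = str_to_upper(str_squish(col_or_na(df, idx$direction))),
    description = col_or_na(df, idx$description),
    provenance = col_or_na(df, idx$provenance)
  )
  bad <- setdiff(unique(out$direction), PATHOGENESIS_DIRECTIONS)
  if (length(bad)) {
    abort(paste0("Pathogenesis direction must be GOF or LOF; got: ",
                 paste(bad, collapse = ", ")))
  }
  conflict <- out |>
    distinct(.data$target, .data$direction) |>
    count(.data$target) |>
    filter(.data$n > 1L)
  if (nrow(conflict)) {
    abort(paste0("Conflicting GOF/LOF annotations for target(s): ",
                 paste(sort_cx(conflict$target), collapse = ", ")))
  }
  distinct(out, .data$target, .keep_all = TRUE)
}

#' Write and re-read harmonized record tables
#'
#' `write_evidence()` / `read_evidence()` round-trip the shared evidence-record
#' layout as TSV; `write_drug_targets()` collapses the action set to a
#' `|`-separated cell so the file re-parses through [parse_drug_targets()]
#' identically. `write_rejects()` writes the rejects report attached to a
#' parser result.
#'
#' @param records A tibble of evidence records (or drug-target records).
#' @param path Output file path.
#' @return `path`, invisibly (readers return tibbles).
#' @export
write_evidence <- function(records, path) {
  readr::write_tsv(records[, names(empty_evidence())], path)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  df <- read_table_auto(path)
  need <- names(empty_evidence())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Missing evidence column(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(df[, need])
  out$p_value <- suppressWarnings(as.numeric(out$p_value))
  assert_sources(out$source)
  out
}

#' @rdname write_evidence
#' @export
write_drug_targets <- function(records, path) {
  flat <- records |>
    mutate(actions = map_chr(.data$actions, paste, collapse = "|"))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_evidence
#' @export
write_rejects <- function(records, path) {
  rej <- attr(records, "rejects") %||% tibble(row = integer(), reason = character())
  readr::write_tsv(rej, path)
  invisible(path)
}
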