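## End-to-end orchestration: ingest -> integrate -> metnet -> map -> exclude
## -> pathofilter -> connectivity -> select, with a stage-count audit and a
## final candidate report.

pipeline_defaults <- function() {
  list(
    gwas_traits = c("melanoma", "cutaneous malignant melanoma"),
    gwas_p_max = 1,
    phewas_phenotypes = c("melanoma", "skin cancer"),
    phewas_p_max = 0.05,
    groups_allowed = "APPROVED",
    policy = "strict",
    anchors_pos = c("paclitaxel", "vinblastine"),
    anchors_neg = "selegiline",
    min_abs_mean = 0
  )
}

#' Pipeline configuration for a generated fixture directory
#'
#' Convenience constructor: points a pipeline configuration at the file layout
#' written by [generate_fixtures()].
#'
#' @param dir A directory produced by [generate_fixtures()].
#' @param ... Overrides merged over the defaults (see [run_pipeline()]).
#' @return A configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(dir, ...) {
  cfg <- modifyList(pipeline_defaults(), list(...))
  cfg$paths <- list(
    gwas = file.path(dir, "gwas.tsv"),
    phewas = file.path(dir, "phewas.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    transcriptome = file.path(dir, "transcriptome.txt"),
    biomedical = file.path(dir, "biomedical.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    trials = file.path(dir, "trials.tsv"),
    pathogenesis = file.path(dir, "pathogenesis.tsv"),
    signature_manifest = file.path(dir, "signatures", "manifest.tsv"),
    tags_gmt = file.path(dir, "signatures", "tags.gmt")
  )
  cfg
}

#' Run the full drug-repurposing pipeline
#'
#' Executes every stage in order and returns a report object carrying the
#' stage-count audit (`stage`, `drugs`, `targets`), the final candidate table
#' with connectivity scores, and all intermediate results. Empty evidence
#' yields an empty report with a warning rather than an error.
#'
#' @param config A configuration list (or path to a YAML file): a `paths`
#'   element naming the input files (`gwas`, `phewas`, `metabolites`,
#'   `transcriptome`, `biomedical`, `drug_targets`, `trials`, `pathogenesis`,
#'   `signature_manifest`, `tags_gmt`; the last two may be omitted to stop
#'   after the concordance filter) plus optional parameters `gwas_traits`,
#'   `gwas_p_max`, `phewas_phenotypes`, `phewas_p_max`, `groups_allowed`,
#'   `policy`, `anchors_pos`, `anchors_neg`, `min_abs_mean`. See
#'   [pipeline_config()] for fixture trees.
#' @return A `pipeline_report` object; see [tidy()] / [glance()] and
#'   [write_report()].
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_defaults(), config)
  paths <- cfg$paths
  if (is.null(paths)) abort("`config$paths` is required.")
  need <- c("gwas", "phewas", "metabolites", "transcriptome", "biomedical",
            "drug_targets", "trials", "pathogenesis")
  for (nm in need) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      abort(paste0("Stage input missing: '", nm, "' (",
                   paths[[nm]] %||% "unset", ")."))
    }
  }

  ## ingest
  met <- parse_metabolite_table(paths$metabolites)
  records <- bind_rows(
    parse_gwas_evidence(paths$gwas, traits = cfg$gwas_traits,
                        p_max = cfg$gwas_p_max),
    parse_phewas_evidence(paths$phewas, phenotypes = cfg$phewas_phenotypes,
                          p_max = cfg$phewas_p_max),
    met$evidence,
    parse_gene_list(paths$transcriptome, "TRANSCRIPTOMICS"),
    parse_gene_list(paths$biomedical, "BIOMEDICAL")
  )
  if (nrow(records) == 0L) {
    warn("No evidence records parsed; returning an empty report.")
    return(structure(list(
      stage_counts = tibble(stage = "ingest", drugs = NA_integer_,
                            targets = 0L),
      candidates = tibble(), config_echo = cfg), class = "pipeline_report"))
  }
  counts <- tibble(stage = "ingest", drugs = NA_integer_,
                   targets = n_distinct(records$gene))

  ## integrate
  profiles <- build_profiles(records)
  venn <- venn_counts(profiles)
  genes <- unified_gene_set(profiles)
  counts <- bind_rows(counts, tibble(stage = "integrate", drugs = NA_integer_,
                                     targets = length(genes)))

  ## metabolite-protein network
  net <- build_network(met$associations)
  net_stats <- network_stats(net)
  counts <- bind_rows(counts, tibble(stage = "metnet", drugs = NA_integer_,
                                     targets = net_stats$n_proteins))

  ## drug cascade
  drug_targets <- parse_drug_targets(paths$drug_targets)
  cascade <- map_drugs(drug_targets, genes, groups_allowed = cfg$groups_allowed)
  cascade <- exclude_known(cascade, parse_trials(paths$trials))
  cascade <- pathogenesis_filter(cascade, parse_pathogenesis(paths$pathogenesis),
                                 policy = cfg$policy)
  counts <- bind_rows(counts, cascade_counts(cascade))

  ## connectivity + selection
  results <- NULL
  selection <- NULL
  survivors <- unique(cascade$candidates$drug)
  if (!is.null(paths$signature_manifest)) {
    if (!file.exists(paths$signature_manifest)) {
      abort(paste0("Stage input missing: 'signature_manifest' (",
                   paths$signature_manifest, ")."))
    }
    signatures <- read_signatures(paths$signature_manifest)
    tags <- tags_from_gmt(read_gmt(paths$tags_gmt))
    scores <- connectivity_scores(signatures, up = tags$up, down = tags$down)
    results <- aggregate_drugs(scores)
    counts <- bind_rows(counts, tibble(stage = "connectivity",
                                       drugs = nrow(results),
                                       targets = NA_integer_))
    selection <- select_candidates(results, anchors_pos = cfg$anchors_pos,
                                   anchors_neg = cfg$anchors_neg,
                                   min_abs_mean = cfg$min_abs_mean,
                                   drugs = survivors)
    retained <- selection$drug[selection$decision == "RETAINED"]
    final <- cascade$candidates |>
      filter(.data$drug %in% retained) |>
      inner_join(select(selection, "drug", "mean", "enrichment", "n_instances"),
                 by = "drug") |>
      arrange(.data$drug, .data$target)
    counts <- bind_rows(counts, tibble(stage = "select",
                                       drugs = n_distinct(final$drug),
                                       targets = n_distinct(final$target)))
  } else {
    final <- cascade$candidates
  }

  structure(list(stage_counts = counts, candidates = final,
                 profiles = profiles, venn = venn, network = net,
                 network_stats = net_stats, cascade = cascade,
                 connectivity = results, selection = selection,
                 config_echo = cfg),
            class = "pipeline_report")
}

#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) x$candidates

#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  x$stage_counts |>
    tidyr::pivot_wider(names_from = "stage", values_from = c("drugs", "targets"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$stage_counts)
  if (nrow(x$candidates)) {
    cat("final candidates:", n_distinct(x$candidates$drug), "drugs /",
        n_distinct(x$candidates$target), "targets\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the stage-count audit and the candidate table as TSV, the selection
#' decisions as TSV, the Venn counts and configuration echo as JSON, and the
#' cascade audit trace as TSV. Byte-identical across repeated runs on the
#' same inputs.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$stage_counts, file.path(dir, "stage_counts.tsv"))
  cand <- report$candidates
  if (nrow(cand) && "actions" %in% names(cand)) {
    cand <- mutate(cand, actions = map_chr(.data$actions, paste, collapse = "|"))
  }
  readr::write_tsv(cand, file.path(dir, "candidates.tsv"))
  if (!is.null(report$selection)) {
    readr::write_tsv(report$selection, file.path(dir, "selection.tsv"))
  }
  if (!is.null(report$venn)) {
    jsonlite::write_json(report$venn, file.path(dir, "venn_counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$cascade)) {
    cascade_trace(report$cascade, file.path(dir, "cascade_trace.tsv"))
  }
  echo <- report$config_echo
  echo$paths <- lapply(echo$paths, as.character)
  jsonlite::write_json(echo, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
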