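## Checks over the packaged candidate-table fixture (the published 35-drug
## panel, exploded to one row per drug-target pair with the drug-level
## literature-evidence annotation repeated) and over locally downloaded
## supplementary files, where available.

#' Path to the packaged candidate-table fixture
#'
#' @return Path to `table1.tsv` inside the installed package.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "melanoseek", mustWork = TRUE)
}

#' Summary checks over the candidate-table fixture
#'
#' Counts computed purely from the fixture: unique drugs, unique harmonized
#' target symbols, drugs with/without literature evidence, and the
#' pathogenesis/action concordance tally of every drug-target pair under both
#' the strict and lenient policies.
#'
#' @param path Fixture path; defaults to the packaged transcription.
#' @return A `table1_summary` list: `n_drugs`, `n_unique_targets`,
#'   `n_with_evidence`, `n_without_evidence`, `pairs` (the parsed fixture with
#'   per-pair verdicts), and `concordance_tally` (tibble `policy`, `verdict`,
#'   `n`). Use [glance()] for the one-row form.
#' @export
table1_checks <- function(path = table1_path()) {
  df <- read_table_auto(path)
  need <- c("drug", "indication", "stage", "target", "actions", "direction",
            "evidence")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Malformed candidate-table fixture; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  pairs <- as_tibble(df) |>
    mutate(target = harmonize_genes(.data$target),
           direction = str_to_upper(.data$direction),
           action_set = map(str_split(.data$actions, "[,;|]"),
                            ~ str_to_upper(str_squish(.x))),
           evidence_present = !is.na(.data$evidence) & .data$evidence != "NA",
           verdict_strict = map2_chr(.data$direction, .data$action_set,
                                     target_verdict, policy = "strict"),
           verdict_lenient = map2_chr(.data$direction, .data$action_set,
                                      target_verdict, policy = "lenient"))
  by_drug <- pairs |>
    group_by(.data$drug) |>
    summarise(evidence = any(.data$evidence_present), .groups = "drop")
  tally <- bind_rows(
    pairs |> count(.data$verdict_strict) |>
      transmute(policy = "strict", verdict = .data$verdict_strict, n = .data$n),
    pairs |> count(.data$verdict_lenient) |>
      transmute(policy = "lenient", verdict = .data$verdict_lenient, n = .data$n)
  )
  structure(list(
    n_drugs = nrow(by_drug),
    n_unique_targets = n_distinct(pairs$target),
    n_with_evidence = sum(by_drug$evidence),
    n_without_evidence = sum(!by_drug$evidence),
    pairs = pairs,
    concordance_tally = tally
  ), class = "table1_summary")
}

#' @method glance table1_summary
#' @export
glance.table1_summary <- function(x, ...) {
  tibble(n_drugs = x$n_drugs, n_unique_targets = x$n_unique_targets,
         n_with_evidence = x$n_with_evidence,
         n_without_evidence = x$n_without_evidence)
}

#' @export
print.table1_summary <- function(x, ...) {
  cat("<table1_summary>\n")
  cat("  drugs:", x$n_drugs, " unique targets:", x$n_unique_targets, "\n")
  cat("  with literature evidence:", x$n_with_evidence,
      " without:", x$n_without_evidence, "\n")
  invisible(x)
}

#' Checks against locally downloaded supplementary files
#'
#' The study's frozen result files are distributed through an external
#' repository and are not bundled; when a local copy exists this function
#' recomputes the headline counts from them. Expected layout under `dir`:
#' `file1_unified_genes.tsv` (columns `gene` and `sources`, the latter a
#' `+`-separated provenance list) and `file6_final_targets.tsv` (columns
#' `target`, `method`).
#'
#' @param dir Directory holding the downloaded files.
#' @return A one-row tibble: `n_unified` (unique genes in the unified set),
#'   `n_multi_source` (genes with two or more sources),
#'   `n_metabolomics_targets` (final targets attributed to the metabolomics
#'   method).
#' @export
supplementary_checks <- function(dir) {
  f1 <- file.path(dir, "file1_unified_genes.tsv")
  f6 <- file.path(dir, "file6_final_targets.tsv")
  for (f in c(f1, f6)) {
    if (!file.exists(f)) {
      abort(paste0("Supplementary file not found: ", f,
                   " (download the study's supplementary files locally first)."))
    }
  }
  genes <- read_table_auto(f1)
  if (!all(c("gene", "sources") %in% names(genes))) {
    abort("file1_unified_genes.tsv must have 'gene' and 'sources' columns.")
  }
  genes <- genes |>
    mutate(gene = harmonize_genes(.data$gene),
           n_sources = lengths(str_split(.data$sources, "\\+"))) |>
    distinct(.data$gene, .keep_all = TRUE)
  finals <- read_table_auto(f6)
  if (!all(c("target", "method") %in% names(finals))) {
    abort("file6_final_targets.tsv must have 'target' and 'method' columns.")
  }
  tibble(
    n_unified = nrow(genes),
    n_multi_source = sum(genes$n_sources >= 2L),
    n_metabolomics_targets = finals |>
      filter(tolower(.data$method) == "metabolomics") |>
      distinct(.data$target) |>
      nrow()
  )
}
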