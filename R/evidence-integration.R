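## Merge harmonized evidence records into per-gene provenance profiles, the
## multi-source (Venn) accounting, and the unified melanoma gene/protein set.

#' Build per-gene evidence profiles
#'
#' Collapses harmonized evidence records into one profile per unique gene:
#' which of the five sources reported it, how many records each source
#' contributed, and the best (minimum) association p-value per source where
#' p-values apply (GWAS and PheWAS only).
#'
#' @param records A tibble of evidence records, e.g. rows bound from the
#'   `parse_*` readers.
#' @return A tibble with one row per gene: `gene`, `sources` (list-column of
#'   source names in canonical order), `n_sources`, `n_records` (list-column,
#'   named integer per source), `best_p` (list-column, named numeric per
#'   source, GWAS/PheWAS only). Sorted by symbol.
#' @examples
#' recs <- tibble::tibble(
#'   gene = c("TYR", "TYR", "TERT"), source = c("GWAS", "PHEWAS", "GWAS"),
#'   trait = NA, p_value = c(1e-8, 1e-10, 4e-37), snp_id = NA,
#'   metabolite = NA, role = NA, citation = NA
#' )
#' build_profiles(recs)
#' @export
build_profiles <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(tibble(gene = character(), sources = list(), n_sources = integer(),
                  n_records = list(), best_p = list()))
  }
  assert_sources(records$source)
  records |>
    group_by(.data$gene) |>
    summarise(
      sources = list(intersect(EVIDENCE_SOURCES, unique(.data$source))),
      n_records = list({
        tab <- table(.data$source)
        setNames(as.integer(tab), names(tab))[intersect(EVIDENCE_SOURCES, names(tab))]
      }),
      best_p = list({
        keep <- .data$source %in% c("GWAS", "PHEWAS") & !is.na(.data$p_value)
        if (!any(keep)) {
          setNames(numeric(0), character(0))
        } else {
          mins <- c(tapply(.data$p_value[keep], .data$source[keep], min))
          mins[intersect(c("GWAS", "PHEWAS"), names(mins))]
        }
      }),
      .groups = "drop"
    ) |>
    mutate(n_sources = lengths(.data$sources)) |>
    select("gene", "sources", "n_sources", "n_records", "best_p") |>
    arrange(.data$gene)
}

source_combo_label <- function(sources) {
  paste(intersect(EVIDENCE_SOURCES, sources), collapse = "+")
}

#' Multi-source membership counts
#'
#' Counts genes by the exact combination of sources that reported them, over
#' all 31 non-empty subsets of the five sources (zero counts included, so the
#' counts always partition the gene set).
#'
#' @param profiles Output of [build_profiles()].
#' @return A tibble (`combo`, `n_sources`, `n`), one row per source subset,
#'   with `sum(n) == nrow(profiles)`.
#' @seealso [multi_source_total()]
#' @export
venn_counts <- function(profiles) {
  combos <- unlist(lapply(seq_along(EVIDENCE_SOURCES), function(k) {
    apply(utils::combn(EVIDENCE_SOURCES, k), 2L, paste, collapse = "+")
  }))
  sizes <- unlist(lapply(seq_along(EVIDENCE_SOURCES), function(k) {
    rep(k, choose(length(EVIDENCE_SOURCES), k))
  }))
  observed <- if (nrow(profiles)) {
    table(map_chr(profiles$sources, source_combo_label))
  } else {
    table(character())
  }
  n <- as.integer(observed[combos])
  n[is.na(n)] <- 0L
  tibble(combo = combos, n_sources = sizes, n = n)
}

#' @rdname venn_counts
#' @param counts Output of [venn_counts()].
#' @return `multi_source_total()`: the number of genes reported by two or more
#'   sources.
#' @export
multi_source_total <- function(counts) {
  sum(counts$n[counts$n_sources >= 2L])
}

#' The unified melanoma gene/protein set
#'
#' @param profiles Output of [build_profiles()].
#' @param min_sources Minimum number of distinct sources required to keep a
#'   gene (1 = union of all sources).
#' @return Lexicographically sorted character vector of gene symbols.
#' @export
unified_gene_set <- function(profiles, min_sources = 1L) {
  if (!is.numeric(min_sources) || length(min_sources) != 1L || min_sources < 1) {
    abort("`min_sources` must be a single integer >= 1.")
  }
  sort_cx(profiles$gene[profiles$n_sources >= min_sources])
}

#' Export the integration results
#'
#' Writes the unified set as a one-column TSV, a provenance sidecar TSV
#' (gene, `+`-joined sources, best GWAS/PheWAS p-values) and the Venn counts
#' as JSON.
#'
#' @param profiles Output of [build_profiles()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_integration <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes_path <- file.path(dir, "unified_genes.tsv")
  sidecar_path <- file.path(dir, "gene_provenance.tsv")
  venn_path <- file.path(dir, "venn_counts.json")
  readr::write_tsv(tibble(gene = unified_gene_set(profiles)), genes_path)
  sidecar <- profiles |>
    mutate(
      sources = map_chr(.data$sources, source_combo_label),
      best_p_gwas = map_dbl(.data$best_p, function(p) {
        if ("GWAS" %in% names(p)) p[["GWAS"]] else NA_real_
      }),
      best_p_phewas = map_dbl(.data$best_p, function(p) {
        if ("PHEWAS" %in% names(p)) p[["PHEWAS"]] else NA_real_
      })
    ) |>
    select("gene", "sources", "n_sources", "best_p_gwas", "best_p_phewas")
  readr::write_tsv(sidecar, sidecar_path)
  vc <- venn_counts(profiles)
  jsonlite::write_json(
    list(counts = vc, multi_source_total = multi_source_total(vc)),
    venn_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(genes_path, sidecar_path, venn_path))
}
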