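#' Harmonize gene and protein symbols
#'
#' Puts symbols into the pipeline's normal form: uppercase, interior whitespace
#' squeezed, flanking whitespace stripped, then (optionally) mapped through a
#' user-supplied alias table. All symbols entering the unified melanoma set go
#' through this function, so genes from GWAS/PheWAS and proteins from the
#' metabolomics tables share a single namespace.
#'
#' @param x Character vector of raw symbols.
#' @param aliases Optional named character vector mapping harmonized aliases to
#'   preferred symbols (e.g. `c(CYP450_1B1 = "CYP1B1")`). Applied after
#'   uppercasing, so keys must be uppercase.
#'
#' @return Character vector of harmonized symbols.
#' @examples
#' harmonize_genes(c(" tyr", "Tert "))
#' @export
harmonize_genes <- function(x, aliases = NULL) {
  out <- str_to_upper(str_squish(as.character(x)))
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(names(aliases) == "")) {
      abort("`aliases` must be a fully named character vector.")
    }
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

## Case/punctuation-insensitive normal form used for drug-name joins
## (trial lists carry no accession ids, so matching is name-level).
normalize_drug_name <- function(x) {
  str_replace_all(tolower(as.character(x)), "[^a-z0-9]", "")
}

## Locale-independent lexicographic sort, so output ordering is deterministic
## across machines.
sort_cx <- function(x) sort(x, method = "radix")

## Read a delimited table, sniffing the delimiter from the extension first and
## the header line second (.tsv/.txt -> tab, .csv -> comma, otherwise whichever
## of tab/comma appears in the header).
read_table_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  delim <- if (ext == "csv") {
    ","
  } else if (ext %in% c("tsv", "txt", "rnk", "gmt", "sif")) {
    "\t"
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (grepl("\t", first)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

## Resolve mandatory/optional columns against a synonym map. `spec` is a named
## list: element name = canonical name, value = character vector of accepted
## header synonyms (matched case-insensitively after squashing non-alnum to _).
resolve_columns <- function(df, spec, mandatory, file = "input") {
  norm <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  have <- norm(names(df))
  out <- list()
  for (canon in names(spec)) {
    idx <- which(have %in% norm(spec[[canon]]))
    if (length(idx) == 0L) {
      if (canon %in% mandatory) {
        abort(paste0("Missing mandatory column '", canon, "' in ", file,
                     " (accepted names: ", paste(spec[[canon]], collapse = ", "), ")."))
      }
      out[[canon]] <- NA_integer_
    } else {
      out[[canon]] <- idx[[1L]]
    }
  }
  out
}

col_or_na <- function(df, idx) {
  if (is.na(idx)) rep(NA_character_, nrow(df)) else as.character(df[[idx]])
}

## Merge a user column map (canonical -> synonym vector) into defaults.
merge_col_map <- function(default, user) {
  if (is.null(user)) return(default)
  for (nm in names(user)) default[[nm]] <- unique(c(user[[nm]], default[[nm]]))
  default
}

## Empty evidence tibble: the shared record layout for all five sources.
empty_evidence <- function() {
  tibble(gene = character(), source = character(), trait = character(),
         p_value = numeric(), snp_id = character(), metabolite = character(),
         role = character(), citation = character())
}

assert_sources <- function(source) {
  bad <- setdiff(unique(source), EVIDENCE_SOURCES)
  if (length(bad)) {
    abort(paste0("Unknown evidence source: ", paste(bad, collapse = ", ")))
  }
}
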