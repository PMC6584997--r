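## RNK / GMT / manifest readers and writers for ranked drug-response
## signatures and up/down tag-set queries.

#' Read and write RNK-style ranked signatures
#'
#' An RNK file is a headerless two-column table (gene, score); the ranking is
#' by decreasing score, position 1 = most up-regulated. `write_rnk()` emits
#' scores `n..1` so the file round-trips to the identical ranking.
#'
#' @param path File path.
#' @return `read_rnk()`: a character vector, the gene ranking.
#' @export
read_rnk <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene", "score"),
                        col_types = "cd", progress = FALSE)
  if (anyNA(df$score)) abort(paste0("Unparseable score(s) in RNK file: ", path))
  df$gene[order(-df$score)]
}

#' @rdname read_rnk
#' @param ranking Character vector of genes, best rank first.
#' @export
write_rnk <- function(ranking, path) {
  readr::write_tsv(tibble(gene = ranking, score = rev(seq_along(ranking))),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then the member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[str_squish(lines) != ""]
  parts <- str_split(lines, "\t")
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(paste0("Malformed GMT line ", which(bad)[1], " in ", path))
  setNames(map(parts, ~ .x[-(1:2)]), map_chr(parts, 1))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(names(sets) != ""))
  writeLines(map_chr(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }), path)
  invisible(path)
}

## Split a GMT list into an up/down tag pair by the _UP/_DOWN name suffixes.
tags_from_gmt <- function(sets) {
  up_i <- grep("_UP$", names(sets))
  down_i <- grep("_DOWN$", names(sets))
  if (length(up_i) != 1L || length(down_i) != 1L) {
    abort("Expected exactly one *_UP and one *_DOWN set in the tag GMT.")
  }
  list(up = sets[[up_i]], down = sets[[down_i]])
}

#' Read a signature panel via its instance manifest
#'
#' The manifest is a TSV with columns `instance_id`, `drug`, `cell_line`,
#' `file`; each `file` is an RNK path relative to the manifest's directory.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return Tibble (`instance_id`, `drug`, `cell_line`, `ranking` list-column).
#' @export
read_signatures <- function(manifest_path) {
  man <- read_table_auto(manifest_path)
  need <- c("instance_id", "drug", "cell_line", "file")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    abort(paste0("Manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  man |>
    as_tibble() |>
    mutate(ranking = map(.data$file, ~ read_rnk(file.path(base, .x)))) |>
    select("instance_id", "drug", "cell_line", "ranking")
}

#' Write a signature panel (RNK files plus manifest)
#'
#' @param signatures Tibble (`instance_id`, `drug`, `cell_line`, `ranking`).
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_signatures <- function(signatures, dir) {
  dir.create(file.path(dir, "rnk"), showWarnings = FALSE, recursive = TRUE)
  files <- file.path("rnk", paste0(signatures$instance_id, ".rnk"))
  purrr::walk2(signatures$ranking, file.path(dir, files), write_rnk)
  man <- signatures |>
    select("instance_id", "drug", "cell_line") |>
    mutate(file = files)
  path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, path)
  invisible(path)
}
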