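## Bipartite metabolite-protein network: construction from deduplicated
## associations, summary statistics, and SIF/GraphML export-import. igraph is
## the container; metabolite and protein nodes live in disjoint classes even
## when their labels collide (internal ids are class-prefixed).

met_id <- function(x) if (length(x)) paste0("m|", x) else character(0)
prot_id <- function(x) if (length(x)) paste0("p|", x) else character(0)

#' Build the bipartite metabolite-protein network
#'
#' @param assocs Tibble of associations (`metabolite`, `protein`, `role`), as
#'   returned in `parse_metabolite_table()$associations`. Duplicate
#'   (metabolite, protein, role) triples are collapsed; the same pair under
#'   two roles yields parallel edges.
#' @return A `metnet` object (an igraph graph with vertex attributes `label`
#'   and `class` in {metabolite, protein}, and edge attribute `role`).
#' @examples
#' net <- build_network(tibble::tibble(
#'   metabolite = c("Tyrosine", "Tyrosine"), protein = c("TYR", "TH"),
#'   role = c("ENZYME", "ENZYME")
#' ))
#' network_stats(net)
#' @export
build_network <- function(assocs) {
  stopifnot(all(c("metabolite", "protein", "role") %in% names(assocs)))
  assocs <- distinct(as_tibble(assocs), .data$metabolite, .data$protein, .data$role)
  mets <- sort_cx(unique(assocs$metabolite))
  prots <- sort_cx(unique(assocs$protein))
  vertices <- tibble(
    name = c(met_id(mets), prot_id(prots)),
    label = c(mets, prots),
    class = c(rep("metabolite", length(mets)), rep("protein", length(prots)))
  )
  edges <- tibble(from = met_id(assocs$metabolite), to = prot_id(assocs$protein),
                  role = assocs$role)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  igraph::V(g)$type <- igraph::V(g)$class == "protein"
  class(g) <- c("metnet", class(g))
  g
}

metnet_edges <- function(net) {
  if (igraph::gsize(net) == 0L) {
    return(tibble(metabolite = character(), protein = character(), role = character()))
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  lab <- setNames(igraph::V(net)$label, igraph::V(net)$name)
  cls <- setNames(igraph::V(net)$class, igraph::V(net)$name)
  swap <- cls[el[, 1]] != "metabolite"
  met <- ifelse(swap, el[, 2], el[, 1])
  prot <- ifelse(swap, el[, 1], el[, 2])
  tibble(metabolite = unname(lab[met]), protein = unname(lab[prot]),
         role = igraph::E(net)$role) |>
    arrange(.data$metabolite, .data$protein, .data$role)
}

#' Summary statistics of a metabolite-protein network
#'
#' @param net A `metnet` object.
#' @return A one-row tibble: node counts per class, edge count, degree extrema
#'   per class, and the number of connected components.
#' @export
network_stats <- function(net) {
  cls <- igraph::V(net)$class
  deg <- igraph::degree(net)
  deg_rng <- function(keep) {
    if (!any(keep)) c(NA_integer_, NA_integer_) else range(deg[keep])
  }
  m <- deg_rng(cls == "metabolite")
  p <- deg_rng(cls == "protein")
  tibble(
    n_metabolites = sum(cls == "metabolite"),
    n_proteins = sum(cls == "protein"),
    n_edges = igraph::gsize(net),
    min_metabolite_degree = m[1], max_metabolite_degree = m[2],
    min_protein_degree = p[1], max_protein_degree = p[2],
    n_components = if (igraph::gorder(net)) igraph::components(net)$no else 0L
  )
}

## Display labels: class prefixes ("m:", "p:") are added only where a
## metabolite and a protein share the same label.
display_labels <- function(net) {
  lab <- igraph::V(net)$label
  cls <- igraph::V(net)$class
  clash <- intersect(lab[cls == "metabolite"], lab[cls == "protein"])
  out <- lab
  hit <- lab %in% clash
  out[hit] <- paste0(ifelse(cls[hit] == "metabolite", "m:", "p:"), lab[hit])
  out
}

strip_class_prefix <- function(x) sub("^[mp]:", "", x)

#' Export / import a metabolite-protein network
#'
#' SIF lines are `metabolite<TAB>role<TAB>protein` with the role token in
#' lowercase; GraphML carries the node attribute `class` and edge attribute
#' `role`. Re-importing an exported file reproduces an identical network.
#' Labels shared by a metabolite and a protein are disambiguated with `m:` /
#' `p:` prefixes on export and stripped on import.
#'
#' @param net A `metnet` object.
#' @param path Output (or input) file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `export_network()`: `path` invisibly. `import_network()`: a
#'   `metnet` object.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tolower(format[[1]])
  if (!format %in% c("sif", "graphml")) {
    abort(paste0("Unknown export format: ", format, " (use 'sif' or 'graphml')."))
  }
  disp <- setNames(display_labels(net), igraph::V(net)$name)
  if (format == "sif") {
    ed <- metnet_edges(net)
    cls <- setNames(igraph::V(net)$class, igraph::V(net)$label)
    ## re-apply prefixes on the label scale
    lab_m <- disp[met_id(ed$metabolite)]
    lab_p <- disp[prot_id(ed$protein)]
    writeLines(paste(lab_m, tolower(ed$role), lab_p, sep = "\t"), path)
  } else {
    g <- net
    igraph::V(g)$name <- unname(disp)
    class(g) <- setdiff(class(g), "metnet")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- tolower(format[[1]])
  if (!format %in% c("sif", "graphml")) {
    abort(paste0("Unknown import format: ", format, " (use 'sif' or 'graphml')."))
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[str_squish(lines) != ""]
    parts <- str_split(lines, "\t")
    bad <- lengths(parts) != 3L
    if (any(bad)) abort(paste0("Malformed SIF line(s): ", which(bad)[1]))
    assocs <- tibble(
      metabolite = strip_class_prefix(map_chr(parts, 1)),
      role = str_to_upper(map_chr(parts, 2)),
      protein = strip_class_prefix(map_chr(parts, 3))
    )
    return(build_network(assocs))
  }
  g <- igraph::read_graph(path, format = "graphml")
  cls <- igraph::vertex_attr(g, "class")
  lab <- strip_class_prefix(igraph::vertex_attr(g, "name"))
  el <- igraph::as_edgelist(g, names = FALSE)
  swap <- cls[el[, 1]] != "metabolite"
  met <- ifelse(swap, el[, 2], el[, 1])
  prot <- ifelse(swap, el[, 1], el[, 2])
  build_network(tibble(metabolite = lab[met], protein = lab[prot],
                       role = igraph::edge_attr(g, "role")))
}

#' @method tidy metnet
#' @export
tidy.metnet <- function(x, ...) metnet_edges(x)

#' @method glance metnet
#' @export
glance.metnet <- function(x, ...) network_stats(x)

#' @export
print.metnet <- function(x, ...) {
  s <- network_stats(x)
  cat("<metnet> bipartite metabolite-protein network\n")
  cat("  metabolites:", s$n_metabolites, " proteins:", s$n_proteins,
      " edges:", s$n_edges, " components:", s$n_components, "\n")
  invisible(x)
}
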