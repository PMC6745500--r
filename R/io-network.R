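#' Write a bait-prey network as GEXF plus node/edge TSVs
#'
#' Emits three files sharing a common prefix: `<prefix>.gexf` (GEXF 1.2,
#' undirected, no layout coordinates), `<prefix>_nodes.tsv` (id, kind,
#' kap1fc, class) and `<prefix>_edges.tsv` (source, target, weight).
#'
#' @param nodes Tibble with columns `id`, `kind` (`"bait"`/`"prey"`) and
#'   optionally `kap1fc` (numeric) and `class` (character).
#' @param edges Tibble with columns `source`, `target`, `weight`.
#' @param prefix Output path prefix.
#' @return Character vector of the three file paths, invisibly.
#' @export
write_network <- function(nodes, edges, prefix) {
  stopifnot(all(c("id", "kind") %in% names(nodes)),
            all(c("source", "target", "weight") %in% names(edges)))
  if (!("kap1fc" %in% names(nodes))) nodes$kap1fc <- NA_real_
  if (!("class" %in% names(nodes))) nodes$class <- NA_character_

  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "kind", type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "kap1fc", type = "double")
  xml2::xml_add_child(attrs, "attribute", id = "2", title = "class", type = "string")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nodes_el, "node",
                              id = nodes$id[i], label = nodes$id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = nodes$kind[i])
    if (!is.na(nodes$kap1fc[i])) {
      xml2::xml_add_child(av, "attvalue", `for` = "1",
                          value = format(nodes$kap1fc[i], digits = 15))
    }
    if (!is.na(nodes$class[i])) {
      xml2::xml_add_child(av, "attvalue", `for` = "2", value = nodes$class[i])
    }
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(edges))) {
    xml2::xml_add_child(edges_el, "edge",
                        id = as.character(i - 1L),
                        source = edges$source[i],
                        target = edges$target[i],
                        weight = format(edges$weight[i], digits = 15))
  }
  paths <- c(
    gexf = paste0(prefix, ".gexf"),
    nodes = paste0(prefix, "_nodes.tsv"),
    edges = paste0(prefix, "_edges.tsv")
  )
  xml2::write_xml(doc, paths[["gexf"]])
  readr::write_tsv(nodes[, c("id", "kind", "kap1fc", "class")],
                   paths[["nodes"]], progress = FALSE)
  readr::write_tsv(edges[, c("source", "target", "weight")],
                   paths[["edges"]], progress = FALSE)
  invisible(paths)
}

#' Reload network edges written by [write_network()]
#'
#' @param path Path to a `*_edges.tsv` file.
#' @return Tibble with columns `source`, `target`, `weight`.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    source = readr::col_character(),
                    target = readr::col_character(),
                    weight = readr::col_double()
                  ))
}
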