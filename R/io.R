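# Network I/O: nodes.csv / segments.csv / network.json schema.
#
# nodes.csv:    node_id,x_m,y_m,z_m,is_root
# segments.csv: segment_id,node_a,node_b,diameter_m,length_m
# network.json: units declaration, provenance, seed (schema v1)

#' Write a network to a directory
#'
#' Writes `nodes.csv`, `segments.csv` and `network.json` (metadata:
#' declared units, schema version, optional seed/provenance).
#'
#' @param graph a `vascular_graph`.
#' @param path output directory (created if needed).
#' @param meta optional named list merged into the metadata file.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, meta = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nd <- data.frame(node_id = graph$nodes$id,
                   x_m = graph$nodes$x, y_m = graph$nodes$y,
                   z_m = graph$nodes$z,
                   is_root = graph$nodes$is_root)
  sg <- data.frame(segment_id = graph$segments$id,
                   node_a = graph$segments$node_a,
                   node_b = graph$segments$node_b,
                   diameter_m = graph$segments$diameter,
                   length_m = graph$segments$length)
  utils::write.csv(nd, file.path(path, "nodes.csv"), row.names = FALSE)
  utils::write.csv(sg, file.path(path, "segments.csv"), row.names = FALSE)
  md <- utils::modifyList(
    list(schema_version = 1L, units = "SI",
         n_nodes = nrow(nd), n_segments = nrow(sg)),
    meta)
  jsonlite::write_json(md, file.path(path, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from a directory
#'
#' Reads the `nodes.csv` / `segments.csv` / `network.json` schema
#' written by [write_network()]. Files declaring micrometer units in
#' the metadata (`units = "um"`) are converted to SI on load.
#' Degree-2 chains are merged via [build_network()].
#'
#' @param path directory containing the three files.
#' @param reduce merge degree-2 chains (default TRUE).
#' @return a `vascular_graph`.
#' @export
read_network <- function(path, reduce = TRUE) {
  fn <- file.path(path, "nodes.csv")
  fs <- file.path(path, "segments.csv")
  if (!file.exists(fn)) stop("missing nodes.csv in ", path, call. = FALSE)
  if (!file.exists(fs)) stop("missing segments.csv in ", path,
                             call. = FALSE)
  nd <- utils::read.csv(fn)
  sg <- utils::read.csv(fs)
  need_n <- c("node_id", "x_m", "y_m", "z_m", "is_root")
  need_s <- c("segment_id", "node_a", "node_b", "diameter_m", "length_m")
  miss <- setdiff(need_n, names(nd))
  if (length(miss)) stop("nodes.csv missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_s, names(sg))
  if (length(miss)) stop("segments.csv missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  scale <- 1
  fj <- file.path(path, "network.json")
  if (file.exists(fj)) {
    md <- jsonlite::read_json(fj, simplifyVector = TRUE)
    if (identical(md$units, "um")) scale <- 1e-6
  }
  nodes <- data.frame(id = nd$node_id, x = nd$x_m * scale,
                      y = nd$y_m * scale, z = nd$z_m * scale)
  segments <- data.frame(id = sg$segment_id, node_a = sg$node_a,
                         node_b = sg$node_b,
                         diameter = sg$diameter_m * scale,
                         length = sg$length_m * scale)
  roots <- nd$node_id[as.logical(nd$is_root)]
  if (reduce) build_network(nodes, segments, roots)
  else vascular_graph(nodes, segments, roots)
}
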