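# Graph data model for arterial networks.
#
# A network is a set of nodes with 3D positions and cylindrical
# segments with a mean diameter and a path length, stored in plain
# data frames. Segments may be unoriented or oriented (mother end ->
# daughter end); orientation is established from root proximity or
# from solved flow directions.

#' Construct a vascular network graph
#'
#' Low-level constructor: validates tables and returns a
#' `vascular_graph` without topological clean-up. Most users should
#' call [build_network()], which additionally merges degree-2 chains.
#'
#' @param nodes data frame with columns `id` (integer, unique), `x`,
#'   `y`, `z` (positions, meters) and optionally `is_root` (logical).
#' @param segments data frame with columns `id` (integer, unique),
#'   `node_a`, `node_b` (node ids), `diameter` (m), `length` (m) and
#'   optionally `orientation` (`"unoriented"`, `"a_to_b"`, `"b_to_a"`).
#' @param roots integer vector of root node ids (non-empty).
#' @param validate check invariants (connectivity, terminal degrees).
#' @return an object of class `vascular_graph`: a list with elements
#'   `nodes`, `segments`, `roots`.
#' @export
vascular_graph <- function(nodes, segments, roots, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  need_n <- c("id", "x", "y", "z")
  need_s <- c("id", "node_a", "node_b", "diameter", "length")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("nodes table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_s, names(segments))
  if (length(miss)) stop("segments table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  nodes$id <- as.integer(nodes$id)
  segments$id <- as.integer(segments$id)
  segments$node_a <- as.integer(segments$node_a)
  segments$node_b <- as.integer(segments$node_b)
  roots <- sort(unique(as.integer(roots)))
  if (length(roots) == 0L) stop("root set must be non-empty", call. = FALSE)

  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(segments$id)) {
    stop("duplicate segment id(s): ",
         paste(unique(segments$id[duplicated(segments$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    stop("node positions must be finite", call. = FALSE)
  }
  bad <- setdiff(c(segments$node_a, segments$node_b), nodes$id)
  if (length(bad)) {
    ref <- segments$id[segments$node_a %in% bad | segments$node_b %in% bad]
    stop("segment(s) ", paste(ref, collapse = ", "),
         " reference nonexistent node id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(segments$node_a == segments$node_b)) {
    stop("self-loop segment(s): ",
         paste(segments$id[segments$node_a == segments$node_b],
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(segments$diameter) | segments$diameter <= 0)) {
    stop("segment diameters must be positive", call. = FALSE)
  }
  if (any(!is.finite(segments$length) | segments$length <= 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  if (!all(roots %in% nodes$id)) {
    stop("root id(s) not in node table: ",
         paste(setdiff(roots, nodes$id), collapse = ", "), call. = FALSE)
  }
  nodes$is_root <- nodes$id %in% roots
  if (is.null(segments$orientation)) segments$orientation <- "unoriented"
  # quality condition: length should exceed diameter; flag, never drop
  segments$short_flag <- segments$length < segments$diameter
  if (is.null(segments$orient_flag)) segments$orient_flag <- FALSE

  g <- structure(list(nodes = nodes, segments = segments, roots = roots),
                 class = "vascular_graph")
  if (validate) validate_graph(g)
  g
}

validate_graph <- function(graph) {
  deg <- node_degrees(graph)
  comp <- reachable_from_roots(graph)
  if (!all(comp)) {
    stop("node(s) unreachable from the root set: ",
         paste(utils::head(graph$nodes$id[!comp], 10), collapse = ", "),
         call. = FALSE)
  }
  term <- deg == 1L & !graph$nodes$is_root
  if (any(deg[graph$nodes$is_root] < 1L)) {
    stop("root node(s) with degree 0", call. = FALSE)
  }
  if (any(deg == 1L & graph$nodes$is_root & length(graph$nodes$id) > 1 &
          FALSE)) {
    # roots of degree 1 are legal (an inlet stub)
  }
  invisible(graph)
}

# per-node degree, aligned with graph$nodes rows
node_degrees <- function(graph) {
  idx <- match(c(graph$segments$node_a, graph$segments$node_b),
               graph$nodes$id)
  tabulate(idx, nbins = nrow(graph$nodes))
}

reachable_from_roots <- function(graph) {
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)$membership
  root_comp <- unique(comp[match(graph$roots, graph$nodes$id)])
  comp %in% root_comp
}

# igraph view of the network; vertices ordered as graph$nodes rows,
# edges as graph$segments rows, with `weight` = segment length.
as_igraph <- function(graph) {
  el <- cbind(match(graph$segments$node_a, graph$nodes$id),
              match(graph$segments$node_b, graph$nodes$id))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, nrow(graph$nodes) -
                                       igraph::vcount(ig)))
  igraph::E(ig)$weight <- graph$segments$length
  ig
}

#' Build a validated network from node and segment tables
#'
#' Validates the I/O schema, merges chains of degree-2 nodes into
#' single segments (diameter = length-weighted mean of the merged
#' parts, length = sum) and returns the reduced `vascular_graph`.
#' Degree-2 nodes are mid-segmental sampling points, not branch
#' points, and must not appear in a reduced network.
#'
#' @inheritParams vascular_graph
#' @param root_ids integer vector of root node ids.
#' @return a `vascular_graph` with no internal degree-2 nodes.
#' @export
build_network <- function(nodes, segments, root_ids) {
  g <- vascular_graph(nodes, segments, root_ids, validate = TRUE)
  merge_degree2(g)
}

# Merge maximal chains through non-root degree-2 nodes.
merge_degree2 <- function(graph) {
  deg <- node_degrees(graph)
  mid <- deg == 2L & !graph$nodes$is_root
  if (!any(mid)) return(graph)

  nid <- graph$nodes$id
  seg <- graph$segments
  # adjacency: for each node index, incident segment rows
  inc <- vector("list", length(nid))
  for (k in seq_len(nrow(seg))) {
    ia <- match(seg$node_a[k], nid); ib <- match(seg$node_b[k], nid)
    inc[[ia]] <- c(inc[[ia]], k); inc[[ib]] <- c(inc[[ib]], k)
  }
  used <- logical(nrow(seg))
  out <- list()
  keep_idx <- which(!mid)
  for (i in keep_idx) {
    for (k in inc[[i]]) {
      if (used[k]) next
      # walk from keep-node i through degree-2 nodes
      used[k] <- TRUE
      cur_node <- i
      cur_seg <- k
      len <- seg$length[k]
      dsum <- seg$diameter[k] * seg$length[k]
      first_id <- seg$id[k]
      nxt <- if (match(seg$node_a[k], nid) == i) match(seg$node_b[k], nid)
             else match(seg$node_a[k], nid)
      while (mid[nxt]) {
        cand <- setdiff(inc[[nxt]], cur_seg)
        if (length(cand) != 1L) break # defensive; degree-2 guarantees 1
        cur_seg <- cand
        used[cur_seg] <- TRUE
        len <- len + seg$length[cur_seg]
        dsum <- dsum + seg$diameter[cur_seg] * seg$length[cur_seg]
        prev <- nxt
        nxt <- if (match(seg$node_a[cur_seg], nid) == prev)
          match(seg$node_b[cur_seg], nid) else match(seg$node_a[cur_seg], nid)
      }
      out[[length(out) + 1L]] <- data.frame(
        id = first_id, last_id = seg$id[cur_seg],
        node_a = nid[i], node_b = nid[nxt],
        diameter = dsum / len, length = len,
        orientation = "unoriented", stringsAsFactors = FALSE)
    }
  }
  if (any(!used)) {
    stop("degenerate cycle of degree-2 nodes involving segment(s): ",
         paste(seg$id[!used], collapse = ", "), call. = FALSE)
  }
  merged <- do.call(rbind, out)
  # each merged chain is discovered once from each end; its end
  # segments identify it uniquely (chains are segment-disjoint)
  key <- paste(pmin(merged$id, merged$last_id),
               pmax(merged$id, merged$last_id))
  merged <- merged[!duplicated(key), , drop = FALSE]
  merged$last_id <- NULL
  merged$id <- seq_len(nrow(merged))
  keep_nodes <- graph$nodes[!mid, , drop = FALSE]
  vascular_graph(keep_nodes, merged, graph$roots, validate = TRUE)
}

#' Classify branch nodes by degree
#'
#' Counts terminal nodes (degree 1, non-root), bifurcations (internal
#' degree 3), trifurcations (degree 4) and higher-order junctions
#' (degree >= 5) among non-root nodes, with the corresponding
#' fractions of branch nodes.
#'
#' @param graph a reduced `vascular_graph` (no internal degree-2 nodes).
#' @return list with `counts`, `fractions` (over branch nodes of
#'   degree >= 3) and `n_nonroot`.
#' @export
classify_nodes <- function(graph) {
  deg <- node_degrees(graph)
  nr <- !graph$nodes$is_root
  if (any(deg[nr] == 2L)) {
    stop("graph contains internal degree-2 nodes; call build_network()",
         call. = FALSE)
  }
  counts <- c(
    terminal     = sum(nr & deg == 1L),
    bifurcation  = sum(nr & deg == 3L),
    trifurcation = sum(nr & deg == 4L),
    higher       = sum(nr & deg >= 5L)
  )
  branch <- counts[c("bifurcation", "trifurcation", "higher")]
  fr <- if (sum(branch) > 0) branch / sum(branch) else branch * NA_real_
  list(counts = counts, fractions = fr, n_nonroot = sum(nr))
}

#' Count independent loops (arcades)
#'
#' Cycle-space dimension E - V + C of the network, where C is the
#' number of connected components. Zero for a tree.
#'
#' @param graph a `vascular_graph`.
#' @return integer loop count.
#' @export
count_loops <- function(graph) {
  n_comp <- igraph::components(as_igraph(graph))$no
  nrow(graph$segments) - nrow(graph$nodes) + n_comp
}

#' Along-network distance from each node to its nearest root
#'
#' Shortest path length (sum of segment lengths) from every node to
#' the closest root, in meters.
#'
#' @param graph a `vascular_graph`.
#' @return numeric vector aligned with `graph$nodes` rows, named by
#'   node id.
#' @export
root_proximity <- function(graph) {
  ig <- as_igraph(graph)
  d <- igraph::distances(ig, v = match(graph$roots, graph$nodes$id),
                         weights = igraph::E(ig)$weight)
  prox <- apply(d, 2, min)
  if (any(!is.finite(prox))) {
    stop("node(s) unreachable from any root: ",
         paste(graph$nodes$id[!is.finite(prox)], collapse = ", "),
         call. = FALSE)
  }
  names(prox) <- graph$nodes$id
  prox
}

#' Orient segments from root proximity or solved flows
#'
#' Establishes a mother -> daughter direction on every segment. With
#' `flows` given (signed, in the node_a -> node_b sense, e.g. from
#' [solve_pressures()]), orientation follows the flow sign;
#' segments with flow indistinguishable from zero fall back to root
#' proximity and are flagged. Without flows, the endpoint closer to a
#' root (along the network) is the mother end; exact ties go to the
#' lower node id and are flagged.
#'
#' @param graph a `vascular_graph`.
#' @param flows optional numeric vector of signed flows aligned with
#'   `graph$segments` rows.
#' @param zero_tol relative tolerance below which a flow is treated
#'   as zero (fraction of the maximum absolute flow).
#' @return the graph with `orientation` and `orient_flag` columns set.
#' @export
orient_segments <- function(graph, flows = NULL, zero_tol = 1e-12) {
  prox <- root_proximity(graph)
  pa <- prox[match(graph$segments$node_a, graph$nodes$id)]
  pb <- prox[match(graph$segments$node_b, graph$nodes$id)]
  by_prox <- ifelse(pa < pb, "a_to_b",
             ifelse(pb < pa, "b_to_a",
                    ifelse(graph$segments$node_a < graph$segments$node_b,
                           "a_to_b", "b_to_a")))
  tie <- pa == pb
  if (is.null(flows)) {
    graph$segments$orientation <- by_prox
    graph$segments$orient_flag <- tie
  } else {
    stopifnot(length(flows) == nrow(graph$segments))
    thr <- zero_tol * max(abs(flows), 0)
    zero <- abs(flows) <= thr
    graph$segments$orientation <- ifelse(!zero & flows > 0, "a_to_b",
                                  ifelse(!zero & flows < 0, "b_to_a",
                                         by_prox))
    graph$segments$orient_flag <- zero | (tie & zero)
  }
  graph
}

# mother ("from") and daughter ("to") node ids of oriented segments
oriented_endpoints <- function(graph) {
  o <- graph$segments$orientation
  if (any(o == "unoriented")) {
    stop("graph is not oriented; call orient_segments()", call. = FALSE)
  }
  list(from = ifelse(o == "a_to_b", graph$segments$node_a,
                     graph$segments$node_b),
       to   = ifelse(o == "a_to_b", graph$segments$node_b,
                     graph$segments$node_a))
}

#' Extract oriented bifurcation records
#'
#' One record per internal node with exactly one mother and exactly
#' two daughter segments. Each record carries the mother diameter
#' `d_M`, the larger and smaller daughter diameters `d_L`, `d_S`, the
#' daughter symmetry `S = d_S/d_L` and the area growth
#' `A = (d_L^2 + d_S^2)/d_M^2`. Trifurcations and higher-order
#' junctions are excluded and counted in the `excluded` attribute.
#'
#' @param graph an oriented `vascular_graph`.
#' @return data frame of class `bifurcation_records` with columns
#'   `node_id`, `d_M`, `d_L`, `d_S`, `S`, `A`; attribute `excluded`
#'   gives counts of skipped junction types.
#' @export
extract_bifurcations <- function(graph) {
  ep <- oriented_endpoints(graph)
  deg <- node_degrees(graph)
  nid <- graph$nodes$id
  n_in  <- tabulate(match(ep$to, nid), nbins = length(nid))
  n_out <- tabulate(match(ep$from, nid), nbins = length(nid))
  is_bif <- deg == 3L & !graph$nodes$is_root & n_in == 1L & n_out == 2L
  n_tri <- sum(deg == 4L & !graph$nodes$is_root)
  n_high <- sum(deg >= 5L & !graph$nodes$is_root)
  n_anom <- sum(deg == 3L & !graph$nodes$is_root & !is_bif)

  idx <- which(is_bif)
  if (length(idx) == 0L) {
    rec <- data.frame(node_id = integer(), d_M = numeric(),
                      d_L = numeric(), d_S = numeric(),
                      S = numeric(), A = numeric())
  } else {
    bif_ids <- nid[idx]
    to_i <- match(ep$to, nid)
    from_i <- match(ep$from, nid)
    mother_seg <- match(idx, to_i) # exactly one incoming each
    d_M <- graph$segments$diameter[mother_seg]
    # two outgoing daughters per node: gather via split
    dd <- split(graph$segments$diameter[from_i %in% idx],
                from_i[from_i %in% idx])
    ord <- match(as.character(idx), names(dd))
    d_mat <- t(vapply(dd[ord], function(v) sort(v, decreasing = TRUE),
                      numeric(2)))
    rec <- data.frame(node_id = bif_ids, d_M = d_M,
                      d_L = d_mat[, 1], d_S = d_mat[, 2],
                      S = d_mat[, 2] / d_mat[, 1],
                      A = (d_mat[, 1]^2 + d_mat[, 2]^2) / d_M^2)
    rownames(rec) <- NULL
  }
  attr(rec, "excluded") <- c(trifurcation = n_tri, higher = n_high,
                             anomalous = n_anom)
  class(rec) <- c("bifurcation_records", "data.frame")
  rec
}

#' @export
print.vascular_graph <- function(x, ...) {
  cl <- classify_nodes_safe(x)
  cat("<vascular_graph>\n")
  cat(sprintf("  nodes: %d  segments: %d  roots: %d  loops: %d\n",
              nrow(x$nodes), nrow(x$segments), length(x$roots),
              count_loops(x)))
  cat(sprintf("  diameter range: %.1f - %.1f um\n",
              1e6 * min(x$segments$diameter),
              1e6 * max(x$segments$diameter)))
  if (!is.null(cl)) {
    cat(sprintf("  terminals: %d  bifurcations: %d  trifurcations: %d\n",
                cl$counts["terminal"], cl$counts["bifurcation"],
                cl$counts["trifurcation"]))
  }
  invisible(x)
}

classify_nodes_safe <- function(x) {
  tryCatch(classify_nodes(x), error = function(e) NULL)
}

#' @export
summary.vascular_graph <- function(object, ...) {
  d_um <- object$segments$diameter * 1e6
  l_um <- object$segments$length * 1e6
  out <- list(
    n_nodes = nrow(object$nodes),
    n_segments = nrow(object$segments),
    n_roots = length(object$roots),
    n_loops = count_loops(object),
    classification = classify_nodes_safe(object),
    diameter_um = stats::quantile(d_um, c(0.1, 0.25, 0.5, 0.75, 0.9)),
    length_um = stats::quantile(l_um, c(0.1, 0.25, 0.5, 0.75, 0.9))
  )
  class(out) <- "summary.vascular_graph"
  out
}

#' @export
print.summary.vascular_graph <- function(x, ...) {
  cat(sprintf("Vascular network: %d nodes, %d segments, %d root(s), %d loop(s)\n",
              x$n_nodes, x$n_segments, x$n_roots, x$n_loops))
  cat("Diameter quantiles (um):\n"); print(round(x$diameter_um, 1))
  cat("Length quantiles (um):\n"); print(round(x$length_um, 1))
  invisible(x)
}
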