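# Fixtures built in code, and independent oracles used against the
# package's solver and Voronoi labeling.

# Y-graph: root(1) - junction(2) - terminals(3,4)
make_y_graph <- function(d = c(100, 80, 60) * 1e-6,
                         l = c(1, 1, 1) * 1e-3) {
  nodes <- data.frame(id = 1:4,
                      x = c(0, 0, -1, 1) * 1e-3,
                      y = c(0, 1, 2, 2) * 1e-3, z = 0)
  segs <- data.frame(id = 1:3, node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                     diameter = d, length = l)
  build_network(nodes, segs, 1)
}

# bridge diamond: trunk 1-2, equal arms 2-3 / 2-4, bridge 3-4, and
# terminal outlets 3-5 / 4-6; fully symmetric, one loop, no degree-2
# nodes
make_diamond <- function(d_arms = c(80e-6, 80e-6)) {
  nodes <- data.frame(id = 1:6,
                      x = c(0, 0, -1, 1, -1, 1) * 1e-3,
                      y = c(0, 1, 2, 2, 3, 3) * 1e-3, z = 0)
  segs <- data.frame(id = 1:6,
                     node_a = c(1, 2, 2, 3, 3, 4),
                     node_b = c(2, 3, 4, 4, 5, 6),
                     diameter = c(120e-6, d_arms[1], d_arms[2],
                                  50e-6, 60e-6, 60e-6),
                     length = rep(1e-3, 6))
  build_network(nodes, segs, 1)
}

# random rooted tree grown by sequential attachment, with diameters
# shrinking (noisily) away from the root
random_tree_graph <- function(n_segments, seed) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0)
  segs <- data.frame(id = integer(), node_a = integer(),
                     node_b = integer(), diameter = numeric(),
                     length = numeric())
  d_at <- c(200e-6) # diameter scale at each node
  for (k in seq_len(n_segments)) {
    parent <- if (k == 1L) 1L else sample(nodes$id, 1L)
    child <- k + 1L
    d <- d_at[parent] * runif(1, 0.6, 0.95)
    d <- max(d, 10e-6)
    nodes <- rbind(nodes, data.frame(id = child, x = runif(1), y = runif(1),
                                     z = runif(1)))
    segs <- rbind(segs, data.frame(id = k, node_a = parent, node_b = child,
                                   diameter = d,
                                   length = runif(1, 0.2e-3, 2e-3)))
    d_at[child] <- d
  }
  vascular_graph(nodes, segs, roots = 1L)
}

# --- independent series/parallel reduction oracle ------------------
# Recursive two-pass solve of a TREE with constant viscosity mu and
# per-terminal distal conductance G_dist (reservoir at P_cap).
# Returns node pressures (named by id) and per-segment flows in the
# mother -> daughter sense, aligned with graph$segments rows.
oracle_tree_solve <- function(graph, P_in, P_cap, mu, G_dist) {
  seg <- graph$segments
  root <- graph$roots[1]
  Gseg <- pi * seg$diameter^4 / (128 * mu * seg$length)
  kids <- function(node, from_seg) {
    which((seg$node_a == node | seg$node_b == node) &
            seq_len(nrow(seg)) != from_seg)
  }
  other <- function(s, node) {
    if (seg$node_a[s] == node) seg$node_b[s] else seg$node_a[s]
  }
  Geq <- numeric(nrow(seg)) # inlet-to-reservoir conductance per segment
  reduce <- function(node, from_seg) {
    ks <- kids(node, from_seg)
    if (length(ks) == 0L) return(G_dist[[as.character(node)]])
    gsub <- 0
    for (s in ks) {
      g_below <- reduce(other(s, node), s)
      Geq[s] <<- 1 / (1 / Gseg[s] + 1 / g_below)
      gsub <- gsub + Geq[s]
    }
    gsub
  }
  G_root <- reduce(root, 0L)
  P <- c()
  Q <- numeric(nrow(seg))
  walk <- function(node, from_seg, p_here) {
    P[as.character(node)] <<- p_here
    for (s in kids(node, from_seg)) {
      Q[s] <<- Geq[s] * (p_here - P_cap)
      p_child <- p_here - Q[s] / Gseg[s]
      walk(other(s, node), s, p_child)
    }
  }
  walk(root, 0L, P_in)
  list(P = P[as.character(graph$nodes$id)], Q = Q, G_root = G_root)
}

# small helper: tree from degenerate (deterministic) stats
degenerate_stats <- function(S = 1, A = 1, ld = 10,
                             classes = diameter_classes()) {
  k <- nrow(classes)
  branching_statistics(
    classes,
    symmetry = rep(list(list(type = "fixed", value = S)), k),
    area_growth = list(type = "fixed", value = A),
    length_ratio = rep(list(list(type = "fixed", value = ld)), k))
}

# self-similar tree under scaling exponent gamma with S = 1:
# every daughter diameter is d_M * 2^(-1/gamma)
murray_like_tree <- function(d_root, gamma, n_generations, ld = 10,
                             seed = 1) {
  cap <- d_root * 2^(-n_generations / gamma)
  st <- degenerate_stats(S = 1, A = area_growth_from_scaling(1, gamma),
                         ld = ld)
  generate_tree(d_root, st, seed = seed,
                capillary_bounds = c(cap * 0.9, cap * (1 + 1e-9)))
}

terminal_ids <- function(graph) {
  deg <- table(factor(c(graph$segments$node_a, graph$segments$node_b),
                      levels = graph$nodes$id))
  graph$nodes$id[deg == 1 & !graph$nodes$is_root]
}

terminal_table <- function(graph) {
  ids <- terminal_ids(graph)
  i <- match(ids, graph$nodes$id)
  data.frame(id = ids, x = graph$nodes$x[i], y = graph$nodes$y[i],
             z = graph$nodes$z[i])
}
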