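# Stochastic generation of in silico arterial trees, and an embedded
# "heart-like" network fixture (loops, trifurcations, transmural
# terminal-density gradient) for end-to-end testing.

#' Generate one stochastic arterial tree
#'
#' Starting from a single root segment, each branching step draws a
#' daughter symmetry S from the mother's diameter-class sampler, sets
#' the daughters' diameters to match the class area-growth model
#' (d_L = d_M sqrt(A/(1+S^2)), d_S = S d_L — the unique inversion of
#' the symmetry and area-growth definitions), and draws each
#' daughter's length from the length-to-diameter sampler of the
#' daughter's own class. A segment stops branching once its diameter
#' is at or below the upper capillary bound; diameters are not
#' clamped, so the achieved terminal-diameter distribution straddles
#' the capillary band from above.
#'
#' @param root_diameter root segment diameter, meters (> upper
#'   capillary bound).
#' @param stats a [branching_statistics()] object.
#' @param seed integer RNG seed; generation is a pure function of
#'   (seed, arguments).
#' @param capillary_bounds target capillary diameter band, meters;
#'   branching stops at or below the upper bound.
#' @param max_generations safety cap on tree depth.
#' @param min_diameter smallest admissible daughter diameter, meters.
#'   Symmetry draws that would create a thinner daughter are redrawn
#'   (the in vivo viscosity law is singular at 1.1 um, so hemodynamic
#'   quantities are undefined below it); after 20 redraws the
#'   daughter is floored at this value.
#' @return a `synthetic_tree` (also a `vascular_graph`): oriented
#'   tree with a `generation` column on segments and metadata in
#'   `attr(, "meta")`.
#' @export
generate_tree <- function(root_diameter, stats, seed = 1L,
                          capillary_bounds = c(5.0e-6, 7.5e-6),
                          max_generations = 100L,
                          min_diameter = 2e-6) {
  cap <- capillary_bounds[2]
  if (root_diameter <= cap) {
    stop("root diameter must exceed the upper capillary bound",
         call. = FALSE)
  }
  with_seed(seed, {
    gen_segments <- list()
    # root segment: node 1 (root) -> node 2
    l0 <- root_diameter * sample_length_ratio(root_diameter, stats)
    gen_segments[[1]] <- data.frame(
      node_a = 1L, node_b = 2L, diameter = root_diameter, length = l0,
      generation = 0L)
    next_node <- 3L
    active <- gen_segments[[1]]
    g <- 0L
    while (nrow(active) > 0L) {
      grow <- active$diameter > cap
      active <- active[grow, , drop = FALSE]
      if (nrow(active) == 0L) break
      g <- g + 1L
      if (g > max_generations) {
        stop("tree exceeded ", max_generations,
             " generations without reaching the capillary bound",
             call. = FALSE)
      }
      n <- nrow(active)
      dM <- active$diameter
      S <- sample_symmetry(dM, stats)
      A <- eval_area_growth(dM, S, stats)
      dL <- dM * sqrt(A / (1 + S^2))
      dS <- S * dL
      tries <- 0L
      while (any(bad <- dS < min_diameter) && tries < 20L) {
        S[bad] <- sample_symmetry(dM[bad], stats)
        A[bad] <- eval_area_growth(dM[bad], S[bad], stats)
        dL[bad] <- dM[bad] * sqrt(A[bad] / (1 + S[bad]^2))
        dS[bad] <- S[bad] * dL[bad]
        tries <- tries + 1L
      }
      dS <- pmax(dS, min_diameter)
      dd <- c(dL, dS)
      ll <- dd * sample_length_ratio(dd, stats)
      parent <- rep(active$node_b, 2L)
      child <- next_node + seq_len(2L * n) - 1L
      next_node <- next_node + 2L * n
      newseg <- data.frame(node_a = parent, node_b = child,
                           diameter = dd, length = ll, generation = g)
      gen_segments[[g + 1L]] <- newseg
      active <- newseg
    }
    seg <- do.call(rbind, gen_segments)
    seg$id <- seq_len(nrow(seg))
    seg$orientation <- "a_to_b"
    # cheap 3D embedding: random-walk directions from the root
    nn <- max(seg$node_b)
    dirs <- matrix(stats::rnorm(3L * nn), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pos <- matrix(0, nn, 3)
    ord <- order(seg$generation)
    for (k in ord) {
      pos[seg$node_b[k], ] <- pos[seg$node_a[k], ] +
        seg$length[k] * dirs[seg$node_b[k], ]
    }
    nodes <- data.frame(id = seq_len(nn), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], is_root = seq_len(nn) == 1L)
    gr <- vascular_graph(nodes, seg, roots = 1L, validate = FALSE)
    gr$segments$orientation <- "a_to_b"
    attr(gr, "meta") <- list(seed = seed, root_diameter = root_diameter,
                             capillary_bounds = capillary_bounds,
                             n_generations = max(seg$generation))
    class(gr) <- c("synthetic_tree", class(gr))
    gr
  })
}

#' Generate an ensemble of stochastic trees
#'
#' Independent trees with root diameters drawn uniformly from
#' `root_diameter_range`; each tree's RNG stream is a deterministic
#' sub-seed of the master seed (Lehmer split keyed by tree index), so
#' ensembles are reproducible and order-independent.
#'
#' @param n_trees number of trees (default 50).
#' @param root_diameter_range root diameter band, meters.
#' @param stats a [branching_statistics()] object.
#' @param seed master seed.
#' @param capillary_bounds passed to [generate_tree()].
#' @return list of `synthetic_tree` objects.
#' @export
generate_ensemble <- function(n_trees = 50L, stats,
                              root_diameter_range = c(300e-6, 400e-6),
                              seed = 1L,
                              capillary_bounds = c(5.0e-6, 7.5e-6)) {
  stopifnot(n_trees >= 1L)
  roots <- with_seed(derive_seed(seed, 0L), {
    stats::runif(n_trees, root_diameter_range[1], root_diameter_range[2])
  })
  lapply(seq_len(n_trees), function(i) {
    generate_tree(roots[i], stats, seed = derive_seed(seed, i),
                  capillary_bounds = capillary_bounds)
  })
}

#' Describe a rectangular myocardial slab
#'
#' A box domain for embedded fixtures: one coordinate is the
#' transmural (depth) axis, normalized 0 at the epicardial face and
#' 1 at the endocardial face.
#'
#' @param extents 3-vector of box edge lengths, meters.
#' @param transmural_axis which coordinate (1, 2 or 3) is depth.
#' @param voxel voxel edge length for gridded analyses, meters.
#' @return object of class `domain_slab`.
#' @export
domain_slab <- function(extents, transmural_axis = 3L, voxel = 30e-6) {
  stopifnot(length(extents) == 3L, all(extents > 0), voxel > 0,
            transmural_axis %in% 1:3)
  structure(list(extents = extents,
                 transmural_axis = as.integer(transmural_axis),
                 voxel = voxel),
            class = "domain_slab")
}

# depth-gradient position sampler: density proportional to
# 1 + (g - 1) * depth, depth in [0,1] (g = endo:epi density ratio)
sample_slab_positions <- function(n, domain, gradient) {
  u <- stats::runif(n)
  if (abs(gradient - 1) < 1e-12) {
    t <- u
  } else {
    a <- (gradient - 1) / 2
    # invert CDF (t + a t^2) / (1 + a) = u
    t <- (-1 + sqrt(1 + 4 * a * u * (1 + a))) / (2 * a)
  }
  pos <- matrix(stats::runif(2L * n), ncol = 2)
  ax <- domain$transmural_axis
  out <- matrix(0, n, 3)
  out[, ax] <- t * domain$extents[ax]
  out[, setdiff(1:3, ax)] <- pos %*% diag(domain$extents[setdiff(1:3, ax)])
  out
}

#' Generate an embedded heart-like network fixture
#'
#' Builds a spatially embedded arterial network inside a slab:
#' terminal positions are placed with density increasing along the
#' transmural axis by the requested endo:epi gradient; a binary tree
#' is grown over the terminals by recursive bisection (internal nodes
#' at subset centroids); diameters are assigned bottom-up from the
#' branching statistics' area-growth model; then the requested
#' fractions of trifurcations (contraction of a bifurcation into its
#' parent bifurcation) and loops (chords between nearby nodes of
#' similar caliber) are injected. Segment path lengths always exceed
#' the Euclidean endpoint distance.
#'
#' This emulator is a test fixture: its only contract is to exhibit
#' the measured network's qualitative structure (about 90%
#' bifurcations, some trifurcations, arcade loops, transmural
#' terminal gradient), not its anatomy.
#'
#' @param domain a [domain_slab()].
#' @param target_terminals number of terminal nodes (>= 2).
#' @param stats a [branching_statistics()] object (area-growth model
#'   used for bottom-up diameter assignment).
#' @param loop_fraction loops as a fraction of branch nodes, in [0,1).
#' @param trifurcation_fraction trifurcations as a fraction of branch
#'   nodes, in [0,1).
#' @param gradient endo:epi terminal density ratio (2 means twice as
#'   dense subendocardially).
#' @param terminal_diameter_range terminal segment diameter band,
#'   meters.
#' @param seed RNG seed.
#' @return a `vascular_graph` with positions; attribute `meta` holds
#'   the injected loop and trifurcation counts.
#' @export
generate_embedded_network <- function(domain, target_terminals, stats,
                                      loop_fraction = 0.0,
                                      trifurcation_fraction = 0.0,
                                      gradient = 1.0,
                                      terminal_diameter_range = c(30e-6, 60e-6),
                                      seed = 1L) {
  stopifnot(target_terminals >= 2L,
            loop_fraction >= 0, loop_fraction < 1,
            trifurcation_fraction >= 0, trifurcation_fraction < 1)
  n_vox <- prod(pmax(1, floor(domain$extents / domain$voxel)))
  if (target_terminals > n_vox) {
    stop("requested terminal density infeasible for the domain size",
         call. = FALSE)
  }
  with_seed(seed, {
    P <- sample_slab_positions(target_terminals, domain, gradient)

    # --- recursive bisection tree over terminal positions ---------
    n_total <- 2L * target_terminals # generous allocation
    pos <- matrix(0, 2L * n_total, 3)
    parent <- integer(0)
    node_count <- 0L
    new_node <- function(p) {
      node_count <<- node_count + 1L
      pos[node_count, ] <<- p
      node_count
    }
    edges <- list(); n_edges <- 0L
    add_edge <- function(a, b) {
      force(a); force(b) # force before reading the shared counter
      n_edges <<- n_edges + 1L
      edges[[n_edges]] <<- c(a, b)
    }
    build <- function(idx) {
      if (length(idx) == 1L) return(new_node(P[idx, ]))
      ctr <- colMeans(P[idx, , drop = FALSE])
      me <- new_node(ctr)
      rng <- apply(P[idx, , drop = FALSE], 2, function(v) diff(range(v)))
      ax <- which.max(rng)
      v <- P[idx, ax]
      med <- stats::median(v)
      left <- idx[v <= med]
      right <- idx[v > med]
      if (length(left) == 0L || length(right) == 0L) {
        o <- order(v)
        left <- idx[o[seq_len(floor(length(idx) / 2))]]
        right <- setdiff(idx, left)
      }
      add_edge(me, build(left))
      add_edge(me, build(right))
      me
    }
    top <- build(seq_len(target_terminals))
    # root node on the epicardial face above the top node
    root_pos <- pos[top, ]
    root_pos[domain$transmural_axis] <- 0
    root <- new_node(root_pos)
    add_edge(root, top)

    E <- do.call(rbind, edges[seq_len(n_edges)])
    pos <- pos[seq_len(node_count), , drop = FALSE]
    is_term <- !(seq_len(node_count) %in% E[, 1])

    # --- bottom-up diameters ---------------------------------------
    diam <- numeric(node_count) # diameter of the segment ABOVE the node
    diam[is_term] <- stats::runif(sum(is_term),
                                  terminal_diameter_range[1],
                                  terminal_diameter_range[2])
    children <- split(E[, 2], E[, 1])
    assign_d <- function(v) {
      ch <- children[[as.character(v)]]
      if (is.null(ch)) return(diam[v])
      dd <- vapply(ch, assign_d, numeric(1))
      if (length(dd) == 1L) { diam[v] <<- dd[1]; return(diam[v]) }
      dL <- max(dd); dS <- min(dd)
      S <- dS / dL
      dm0 <- sqrt(dL^2 + dS^2)
      A <- eval_area_growth(dm0, S, stats)
      diam[v] <<- sqrt((dL^2 + dS^2) / A)
      diam[v]
    }
    assign_d(root)

    dist <- sqrt(rowSums((pos[E[, 1], , drop = FALSE] -
                          pos[E[, 2], , drop = FALSE])^2))
    tort <- stats::runif(nrow(E), 1.05, 1.25)
    seg <- data.frame(node_a = E[, 1], node_b = E[, 2],
                      diameter = diam[E[, 2]],
                      length = pmax(dist * tort, diam[E[, 2]] * 1.5,
                                    1e-6))

    # --- trifurcation injection ------------------------------------
    # contract a bifurcation node into its parent bifurcation: the
    # parent becomes a degree-4 node (1 mother + 3 daughters)
    par_of <- integer(node_count)
    par_of[E[, 2]] <- E[, 1]
    n_children <- lengths(children)[as.character(seq_len(node_count))]
    n_children[is.na(n_children)] <- 0L
    is_bif <- n_children == 2L & seq_len(node_count) != root
    B0 <- sum(is_bif)
    m_target <- round(trifurcation_fraction * B0 / (1 + trifurcation_fraction))
    removed_nodes <- integer(0)
    if (m_target > 0L) {
      cand <- which(is_bif & is_bif[pmax(par_of, 1L)] & par_of != root &
                      par_of > 0L)
      cand <- cand[sample.int(length(cand))]
      used <- logical(node_count)
      chosen <- integer(0)
      for (v in cand) {
        if (length(chosen) >= m_target) break
        p <- par_of[v]
        if (used[v] || used[p]) next
        chosen <- c(chosen, v)
        used[v] <- TRUE; used[p] <- TRUE
      }
      for (v in chosen) {
        p <- par_of[v]
        # reparent v's children to p (their path now runs through the
        # absorbed junction: lengths accumulate), drop segment p->v
        drop <- seg$node_a == p & seg$node_b == v
        l_pv <- seg$length[drop]
        ci <- seg$node_a == v
        seg$node_a[ci] <- p
        seg$length[ci] <- seg$length[ci] + l_pv
        seg <- seg[!drop, , drop = FALSE]
      }
      removed_nodes <- chosen
    }

    keep <- setdiff(seq_len(node_count), removed_nodes)
    nodes <- data.frame(id = keep, x = pos[keep, 1], y = pos[keep, 2],
                        z = pos[keep, 3], is_root = keep == root)

    # --- loop (arcade) injection -----------------------------------
    n_branch <- sum(!is_term[keep]) # internal nodes
    k_loops <- round(loop_fraction * n_branch)
    if (k_loops > 0L) {
      internal <- keep[!is_term[keep] & keep != root]
      picks <- internal[sample.int(length(internal),
                                   min(k_loops, length(internal)))]
      exist <- paste(pmin(seg$node_a, seg$node_b),
                     pmax(seg$node_a, seg$node_b))
      added <- 0L
      for (v in picks) {
        if (added >= k_loops) break
        others <- setdiff(internal, v)
        dv <- sqrt(rowSums((pos[others, , drop = FALSE] -
                            matrix(pos[v, ], length(others), 3,
                                   byrow = TRUE))^2))
        for (w in others[order(dv)][seq_len(min(8, length(others)))]) {
          key <- paste(min(v, w), max(v, w))
          if (key %in% exist) next
          dch <- min(diam[v], diam[w])
          dd <- sqrt(sum((pos[v, ] - pos[w, ])^2))
          seg <- rbind(seg, data.frame(
            node_a = v, node_b = w, diameter = dch,
            length = max(dd * 1.1, dch * 1.5, 1e-6)))
          exist <- c(exist, key)
          added <- added + 1L
          break
        }
      }
      k_loops <- added
    }

    seg$id <- seq_len(nrow(seg))
    gr <- vascular_graph(nodes, seg, roots = root, validate = TRUE)
    gr <- orient_segments(gr)
    attr(gr, "meta") <- list(seed = seed, n_loops = k_loops,
                             n_trifurcations = length(removed_nodes),
                             gradient = gradient, domain = domain)
    gr
  })
}
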