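# Steady-state network hemodynamics: diameter-dependent in vivo
# blood viscosity, Poiseuille segment conductances, sparse Kirchhoff
# pressure solve, derived flow / velocity / wall-shear-stress fields.

#' Blood viscosity model
#'
#' Parameters of the empirical in vivo viscosity law (Fåhraeus-
#' Lindqvist effect): discharge hematocrit and plasma viscosity.
#'
#' @param hematocrit discharge hematocrit H_d, in [0, 0.9].
#' @param mu_plasma plasma viscosity, Pa s.
#' @return object of class `viscosity_model`.
#' @export
viscosity_model <- function(hematocrit = 0.4, mu_plasma = 1.2e-3) {
  stopifnot(hematocrit >= 0, hematocrit <= 0.9, mu_plasma > 0)
  structure(list(hematocrit = hematocrit, mu_plasma = mu_plasma),
            class = "viscosity_model")
}

#' Relative apparent blood viscosity in a vessel
#'
#' The empirical in vivo viscosity law: with d the diameter in
#' micrometers,
#' \deqn{\mu_{rel} = \left[1 + (\mu^*_{0.45} - 1)
#'   \frac{(1-H_d)^C - 1}{(1-0.45)^C - 1}
#'   \left(\frac{d}{d-1.1}\right)^2\right]
#'   \left(\frac{d}{d-1.1}\right)^2}
#' with \eqn{\mu^*_{0.45} = 6 e^{-0.085 d} + 3.2 - 2.44 e^{-0.06
#' d^{0.645}}} and \eqn{C = (0.8 + e^{-0.075 d})(-1 + 1/(1 +
#' 10^{-11} d^{12})) + 1/(1 + 10^{-11} d^{12})}. The relative value
#' tends to 3.2 in large vessels at H_d = 0.45 and collapses to
#' \eqn{(d/(d-1.1))^2} at zero hematocrit.
#'
#' @param d vessel diameter, meters (> 1.1 um; the law is singular at
#'   d = 1.1 um).
#' @param model a [viscosity_model()] (only the hematocrit is used).
#' @return dimensionless viscosity relative to plasma.
#' @export
relative_viscosity <- function(d, model = viscosity_model()) {
  d_um <- d * 1e6
  if (any(d_um <= 1.1)) {
    stop("viscosity law undefined at or below d = 1.1 um", call. = FALSE)
  }
  H <- model$hematocrit
  mu45 <- 6 * exp(-0.085 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  w <- 1 / (1 + 1e-11 * d_um^12)
  C <- (0.8 + exp(-0.075 * d_um)) * (-1 + w) + w
  f <- (d_um / (d_um - 1.1))^2
  hterm <- if (H == 0) 0 else ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)
  (1 + (mu45 - 1) * hterm * f) * f
}

#' Absolute blood viscosity in a vessel
#'
#' `mu_plasma * relative_viscosity(d)`, in Pa s.
#'
#' @inheritParams relative_viscosity
#' @return viscosity, Pa s.
#' @export
blood_viscosity <- function(d, model = viscosity_model()) {
  model$mu_plasma * relative_viscosity(d, model)
}

#' Poiseuille conductance of a cylindrical segment
#'
#' G = pi d^4 / (128 mu l), in m^3/(Pa s).
#'
#' @param d diameter, m; `l` length, m; `mu` viscosity, Pa s.
#' @return hydraulic conductance.
#' @export
segment_conductance <- function(d, l, mu) {
  if (any(d <= 0) || any(l <= 0) || any(mu <= 0)) {
    stop("d, l and mu must be positive", call. = FALSE)
  }
  pi * d^4 / (128 * mu * l)
}

#' Pressure boundary conditions with terminal distal conductances
#'
#' Root nodes are held at the inlet pressure; every terminal node is
#' connected to a virtual capillary reservoir at the capillary
#' pressure through its distal conductance. An infinite distal
#' conductance pins the terminal directly at capillary pressure.
#'
#' @param P_in inlet pressure, Pa (default 90 mmHg).
#' @param P_cap capillary reservoir pressure, Pa (default 20 mmHg).
#' @param G_dist named numeric vector of distal conductances,
#'   m^3/(Pa s), names = terminal node ids; or a single value
#'   recycled to all terminals (use `Inf` to pin terminals at
#'   P_cap).
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(P_in = mmHg_to_Pa(90),
                                P_cap = mmHg_to_Pa(20),
                                G_dist = Inf) {
  if (P_in <= P_cap) stop("P_in must exceed P_cap", call. = FALSE)
  if (any(G_dist <= 0)) stop("distal conductances must be positive",
                             call. = FALSE)
  structure(list(P_in = P_in, P_cap = P_cap, G_dist = G_dist),
            class = "boundary_conditions")
}

# per-segment viscosity and conductance for a graph
graph_conductances <- function(graph, viscosity) {
  if (is.numeric(viscosity)) {
    mu <- rep(viscosity, nrow(graph$segments))
  } else {
    mu <- blood_viscosity(graph$segments$diameter, viscosity)
  }
  list(mu = mu,
       G = segment_conductance(graph$segments$diameter,
                               graph$segments$length, mu))
}

#' Solve steady-state network pressures and flows
#'
#' Applies conservation of mass at every junction (Kirchhoff's
#' current law) with Poiseuille segment conductances, yielding a
#' sparse symmetric positive-definite linear system for the unknown
#' node pressures. Root nodes are Dirichlet-pinned at the inlet
#' pressure; terminals attach to the capillary reservoir through
#' their distal conductance (terminals with infinite distal
#' conductance are pinned at capillary pressure). Loops and
#' trifurcations are handled natively.
#'
#' @param graph a `vascular_graph`.
#' @param bc a [boundary_conditions()].
#' @param viscosity a [viscosity_model()], or a single numeric
#'   viscosity in Pa s for a constant-viscosity solve.
#' @return object of class `hemodynamic_state`: list with `nodes`
#'   (id, `P` in Pa), `segments` (id, endpoint ids, `G`, `mu`, signed
#'   flow `Q` in the node_a -> node_b sense, `tau`, `v`),
#'   `terminals` (id, `G_dist`, outflow `Q_out`), the boundary
#'   conditions and the achieved residual.
#' @export
solve_pressures <- function(graph, bc, viscosity = viscosity_model()) {
  nid <- graph$nodes$id
  n <- length(nid)
  deg <- node_degrees(graph)
  is_term <- deg == 1L & !graph$nodes$is_root
  term_ids <- nid[is_term]

  gd <- bc$G_dist
  if (length(gd) == 1L && is.null(names(gd))) {
    gd <- stats::setNames(rep(gd, length(term_ids)), term_ids)
  }
  if (!all(as.character(term_ids) %in% names(gd))) {
    stop("missing distal conductance for terminal node(s): ",
         paste(setdiff(term_ids, as.integer(names(gd))), collapse = ", "),
         call. = FALSE)
  }
  gd <- gd[as.character(term_ids)]

  gc <- graph_conductances(graph, viscosity)
  G <- gc$G
  ia <- match(graph$segments$node_a, nid)
  ib <- match(graph$segments$node_b, nid)

  fixed <- graph$nodes$is_root
  P_fixed <- rep(NA_real_, n)
  P_fixed[fixed] <- bc$P_in
  pin_term <- is_term & nid %in% term_ids[!is.finite(gd)]
  fixed <- fixed | pin_term
  P_fixed[pin_term] <- bc$P_cap

  free <- which(!fixed)
  fmap <- integer(n); fmap[free] <- seq_along(free)

  # Laplacian assembly over free nodes
  both_free <- !fixed[ia] & !fixed[ib]
  i_off <- c(fmap[ia[both_free]], fmap[ib[both_free]])
  j_off <- c(fmap[ib[both_free]], fmap[ia[both_free]])
  x_off <- c(-G[both_free], -G[both_free])
  diag_i <- c(fmap[ia[!fixed[ia]]], fmap[ib[!fixed[ib]]])
  diag_x <- c(G[!fixed[ia]], G[!fixed[ib]])
  # terminal reservoir coupling on the diagonal (finite G_dist only)
  term_free <- match(term_ids[is.finite(gd)], nid)
  term_free <- term_free[!fixed[term_free]]
  gd_fin <- gd[is.finite(gd)]
  diag_i <- c(diag_i, fmap[term_free])
  diag_x <- c(diag_x, as.numeric(gd_fin))
  A <- Matrix::sparseMatrix(
    i = c(i_off, diag_i), j = c(j_off, diag_i),
    x = c(x_off, diag_x), dims = c(length(free), length(free)),
    symmetric = FALSE)

  # RHS: fixed-pressure neighbors + reservoir
  b <- numeric(length(free))
  add_b <- function(b, idx, val) {
    agg <- rowsum(val, idx)
    b[as.integer(rownames(agg))] <- b[as.integer(rownames(agg))] + agg[, 1]
    b
  }
  sel <- fixed[ia] & !fixed[ib]
  if (any(sel)) b <- add_b(b, fmap[ib[sel]], G[sel] * P_fixed[ia[sel]])
  sel <- fixed[ib] & !fixed[ia]
  if (any(sel)) b <- add_b(b, fmap[ia[sel]], G[sel] * P_fixed[ib[sel]])
  if (length(term_free)) {
    b <- add_b(b, fmap[term_free], as.numeric(gd_fin) * bc$P_cap)
  }

  P <- P_fixed
  if (length(free)) {
    sol <- tryCatch(
      as.numeric(Matrix::solve(A, b)),
      error = function(e) {
        stop("singular pressure system (isolated subnetwork?): ",
             conditionMessage(e), call. = FALSE)
      })
    P[free] <- sol
  }

  Q <- G * (P[ia] - P[ib])
  dP <- abs(P[ia] - P[ib])
  tau <- dP * graph$segments$diameter / (4 * graph$segments$length)
  v <- 2 * abs(Q) / (pi * (graph$segments$diameter / 2)^2)

  # net segment inflow per node (positive = into the node)
  net <- numeric(n)
  agg_a <- rowsum(Q, ia); net[as.integer(rownames(agg_a))] <-
    net[as.integer(rownames(agg_a))] - agg_a[, 1]
  agg_b <- rowsum(Q, ib); net[as.integer(rownames(agg_b))] <-
    net[as.integer(rownames(agg_b))] + agg_b[, 1]

  # terminal outflow through the distal conductance; pinned terminals
  # discharge their net segment inflow into the reservoir
  Pt <- P[match(term_ids, nid)]
  Q_out <- ifelse(is.finite(gd), gd * (Pt - bc$P_cap),
                  net[match(term_ids, nid)])

  # Kirchhoff residual at free nodes (terminal outflow included)
  net[match(term_ids, nid)] <- net[match(term_ids, nid)] - Q_out
  internal <- !fixed
  resid <- if (any(internal)) max(abs(net[internal])) / max(abs(Q)) else 0

  structure(list(
    nodes = data.frame(id = nid, P = P),
    segments = data.frame(id = graph$segments$id,
                          node_a = graph$segments$node_a,
                          node_b = graph$segments$node_b,
                          diameter = graph$segments$diameter,
                          length = graph$segments$length,
                          mu = gc$mu, G = G, Q = Q, tau = tau, v = v),
    terminals = data.frame(id = term_ids, G_dist = as.numeric(gd),
                           Q_out = Q_out),
    bc = bc, residual = resid),
    class = "hemodynamic_state")
}

#' @export
print.hemodynamic_state <- function(x, ...) {
  Qin <- inlet_flow(x)
  cat("<hemodynamic_state>\n")
  cat(sprintf("  nodes: %d  segments: %d  terminals: %d\n",
              nrow(x$nodes), nrow(x$segments), nrow(x$terminals)))
  cat(sprintf("  inlet: %.1f mmHg  capillary: %.1f mmHg  inflow: %.3g ml/min\n",
              Pa_to_mmHg(x$bc$P_in), Pa_to_mmHg(x$bc$P_cap),
              Qin * units_si$m3s_to_mlmin))
  cat(sprintf("  Kirchhoff residual: %.2e (relative)\n", x$residual))
  invisible(x)
}

#' Total inlet flow of a solved state
#'
#' Net flow leaving the root node set, m^3/s.
#'
#' @param state a `hemodynamic_state`.
#' @param graph optional graph (roots are recovered from the state's
#'   node table otherwise).
#' @return inlet flow, m^3/s.
#' @export
inlet_flow <- function(state, graph = NULL) {
  roots <- if (!is.null(graph)) graph$roots else
    state$nodes$id[state$nodes$P == max(state$nodes$P)][1]
  sum(state$segments$Q[state$segments$node_a %in% roots]) -
    sum(state$segments$Q[state$segments$node_b %in% roots])
}

#' Wall shear stress of solved segments
#'
#' tau = |P_i - P_j| d / (4 l), reported as a magnitude in Pa.
#' Algebraically identical to 32 mu Q / (pi d^3) under Poiseuille
#' flow.
#'
#' @param state a `hemodynamic_state`.
#' @return numeric vector, Pa, aligned with `state$segments`.
#' @export
wall_shear_stress <- function(state) state$segments$tau

#' Centerline velocity of solved segments
#'
#' v = 2 Q / (pi (d/2)^2): twice the mean velocity, the peak of the
#' parabolic Poiseuille profile. m/s.
#'
#' @param state a `hemodynamic_state`.
#' @return numeric vector, m/s.
#' @export
centerline_velocity <- function(state) state$segments$v

#' Downstream (distal) conductance of every segment in a tree
#'
#' One reverse-topological sweep: the distal conductance of a
#' terminal segment is its own Poiseuille conductance (its far end is
#' the capillary reservoir); for an internal segment it is the series
#' combination of its own conductance with the parallel sum of its
#' children's distal conductances. Only defined on loop-free
#' networks; for looped graphs use a full [solve_pressures()] and
#' inlet flow / pressure drop instead.
#'
#' @param tree a loop-free `vascular_graph` (oriented or not; an
#'   unoriented tree is oriented by root proximity first).
#' @param viscosity a [viscosity_model()] or a constant viscosity,
#'   Pa s.
#' @return numeric vector of distal conductances, m^3/(Pa s),
#'   aligned with `tree$segments` rows.
#' @export
downstream_conductance <- function(tree, viscosity = viscosity_model()) {
  if (count_loops(tree) > 0) {
    stop("downstream_conductance requires a loop-free network",
         call. = FALSE)
  }
  if (any(tree$segments$orientation == "unoriented")) {
    tree <- orient_segments(tree)
  }
  ep <- oriented_endpoints(tree)
  G <- graph_conductances(tree, viscosity)$G
  nid <- tree$nodes$id
  from_i <- match(ep$from, nid)
  to_i <- match(ep$to, nid)

  # level-by-level reverse sweep (hop depth of the distal endpoint),
  # vectorized within each level
  ig <- as_igraph(tree)
  hop <- igraph::distances(ig, v = match(tree$roots, nid),
                           weights = NA)
  hop <- apply(hop, 2, min)
  lev <- hop[to_i]
  G_sub <- rep(0, length(nid))     # parallel sum of children below node
  has_child <- rep(FALSE, length(nid))
  G_down <- numeric(length(G))
  for (g in sort(unique(lev), decreasing = TRUE)) {
    k <- which(lev == g)
    child <- has_child[to_i[k]]
    G_down[k] <- ifelse(child, 1 / (1 / G[k] + 1 / G_sub[to_i[k]]),
                        G[k])  # terminal: far end is the reservoir
    agg <- rowsum(G_down[k], from_i[k])
    at <- as.integer(rownames(agg))
    G_sub[at] <- G_sub[at] + agg[, 1]
    has_child[at] <- TRUE
  }
  G_down
}
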