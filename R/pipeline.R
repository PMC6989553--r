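# End-to-end pipeline driver: generate (or load) a network, build the
# distal-conductance model from an in silico ensemble, impute, solve,
# and summarize morphometry, hemodynamic profiles and perfusion.

#' Pipeline run configuration
#'
#' Validated bundle of physical and numerical settings for
#' [run_pipeline()]. Pressures are given in mmHg (converted
#' internally to Pa).
#'
#' @param seed master RNG seed.
#' @param P_in_mmHg,P_cap_mmHg boundary pressures.
#' @param hematocrit discharge hematocrit.
#' @param mu_plasma plasma viscosity, Pa s.
#' @param density tissue density, kg/m^3.
#' @param impute_mode terminal-conductance imputation mode.
#' @param n_runs stochastic runs for the variability analysis
#'   (0 skips it).
#' @param truncation_band_um perfusion truncation band, micrometers.
#' @param n_trees in silico ensemble size for the conductance model.
#' @param ensemble_root_range_um root-diameter band of the ensemble,
#'   micrometers.
#' @param capillary_bounds_um capillary diameter band, micrometers.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, P_in_mmHg = 90, P_cap_mmHg = 20,
                       hematocrit = 0.4, mu_plasma = 1.2e-3,
                       density = 1.05e3,
                       impute_mode = c("median", "powerfit", "stochastic"),
                       n_runs = 0L,
                       truncation_band_um = c(100, 200),
                       n_trees = 50L,
                       ensemble_root_range_um = c(300, 400),
                       capillary_bounds_um = c(5.0, 7.5)) {
  impute_mode <- match.arg(impute_mode)
  if (P_in_mmHg <= P_cap_mmHg) {
    stop("inlet pressure must exceed capillary pressure", call. = FALSE)
  }
  stopifnot(hematocrit >= 0, hematocrit <= 0.9, mu_plasma > 0,
            density > 0, all(truncation_band_um > 0),
            truncation_band_um[1] < truncation_band_um[2])
  structure(list(seed = as.integer(seed), P_in_mmHg = P_in_mmHg,
                 P_cap_mmHg = P_cap_mmHg, hematocrit = hematocrit,
                 mu_plasma = mu_plasma, density = density,
                 impute_mode = impute_mode, n_runs = as.integer(n_runs),
                 truncation_band_um = truncation_band_um,
                 n_trees = as.integer(n_trees),
                 ensemble_root_range_um = ensemble_root_range_um,
                 capillary_bounds_um = capillary_bounds_um),
            class = "run_config")
}

#' Run the full analysis pipeline on a network
#'
#' Sequence: (1) morphometry of the input network (node
#' classification, loops, bifurcation statistics, scaling exponent);
#' (2) generation of the in silico tree ensemble and construction of
#' the distal-conductance model; (3) terminal imputation and the
#' Kirchhoff pressure solve; (4) diameter-binned hemodynamic
#' profiles; (5) optionally the stochastic variability analysis; (6)
#' if a grid is supplied, Voronoi perfusion territories and regional
#' summaries. Deterministic under a fixed config.
#'
#' @param graph a `vascular_graph` (e.g. from [read_network()] or
#'   [generate_embedded_network()]).
#' @param config a [run_config()].
#' @param stats branching statistics for the ensemble (default
#'   [reference_statistics()]).
#' @param grid optional [voxel_grid()] for the perfusion stage.
#' @return a named list (`report_bundle`) with elements
#'   `classification`, `n_loops`, `bifurcations`, `gamma`,
#'   `class_summaries`, `conductance_model`, `bc`, `state`,
#'   `profiles`, and optionally `variability`, `territories`,
#'   `regional`, plus `config`.
#' @export
run_pipeline <- function(graph, config = run_config(),
                         stats = reference_statistics(), grid = NULL) {
  P_in <- mmHg_to_Pa(config$P_in_mmHg)
  P_cap <- mmHg_to_Pa(config$P_cap_mmHg)
  visc <- viscosity_model(config$hematocrit, config$mu_plasma)

  if (any(graph$segments$orientation == "unoriented")) {
    graph <- orient_segments(graph)
  }
  out <- list(config = config)
  out$classification <- classify_nodes(graph)
  out$n_loops <- count_loops(graph)
  out$bifurcations <- extract_bifurcations(graph)
  out$gamma <- if (nrow(out$bifurcations) >= 10)
    estimate_gamma(out$bifurcations, n_boot = 200,
                   seed = derive_seed(config$seed, 101L)) else NULL
  out$class_summaries <- class_summaries(graph)

  ens <- generate_ensemble(
    n_trees = config$n_trees, stats = stats,
    root_diameter_range = config$ensemble_root_range_um * 1e-6,
    seed = derive_seed(config$seed, 202L),
    capillary_bounds = config$capillary_bounds_um * 1e-6)
  out$conductance_model <- build_conductance_model(
    ens, visc, diameter_range = c(30e-6, 400e-6))

  out$bc <- impute_terminal_conductance(
    graph, out$conductance_model, mode = config$impute_mode,
    seed = derive_seed(config$seed, 303L), P_in = P_in, P_cap = P_cap)
  out$state <- solve_pressures(graph, out$bc, visc)
  out$profiles <- diameter_binned_profiles(out$state)

  if (config$n_runs >= 2L) {
    out$variability <- stochastic_ensemble_analysis(
      graph, out$conductance_model, n_runs = config$n_runs,
      seed = derive_seed(config$seed, 404L), viscosity = visc,
      P_in = P_in, P_cap = P_cap)
  }

  if (!is.null(grid)) {
    deg <- node_degrees(graph)
    is_term <- deg == 1L & !graph$nodes$is_root
    terminals <- data.frame(id = graph$nodes$id[is_term],
                            x = graph$nodes$x[is_term],
                            y = graph$nodes$y[is_term],
                            z = graph$nodes$z[is_term])
    labels <- voronoi_assign(grid, terminals)
    # perfusion works on the loop-free analysis subtree
    ag <- if (count_loops(graph) > 0) spanning_subtree(graph) else graph
    trunc <- truncation_segments(
      ag, d_low = config$truncation_band_um[1] * 1e-6,
      d_high = config$truncation_band_um[2] * 1e-6)
    out$territories <- territory_perfusion(out$state, labels, trunc,
                                           grid, config$density)
    terminals$depth <- terminal_depths(grid, terminals)
    out$regional <- regional_summary(out$territories, terminals, grid)
  }
  class(out) <- "report_bundle"
  out
}

#' Transmural depth of points from the grid's depth field
#'
#' Looks up the normalized depth of each point at its enclosing voxel
#' (points outside the grid are clamped to the nearest voxel).
#'
#' @param grid a [voxel_grid()].
#' @param points data frame with `x`, `y`, `z` (meters).
#' @return numeric vector of depths in [0, 1].
#' @export
terminal_depths <- function(grid, points) {
  P <- as.matrix(points[, c("x", "y", "z")])
  ijk <- sweep(P, 2, grid$origin, `-`) / grid$spacing
  ijk <- ceiling(ijk)
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), grid$dims[a])
  grid$depth[ijk]
}

# drop loop chords: breadth-first spanning subtree from the roots
# (segments are adopted in root-proximity order, so trunk segments
# win over arcade chords)
spanning_subtree <- function(graph) {
  nid <- graph$nodes$id
  seg <- graph$segments
  ia <- match(seg$node_a, nid); ib <- match(seg$node_b, nid)
  visited <- graph$nodes$is_root
  keep <- logical(nrow(seg))
  ord <- order(seg$length) # short chords adopted late is irrelevant; any
  repeat {
    added <- FALSE
    for (k in ord) {
      if (keep[k]) next
      va <- visited[ia[k]]; vb <- visited[ib[k]]
      if (xor(va, vb)) {
        keep[k] <- TRUE
        visited[ia[k]] <- TRUE; visited[ib[k]] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  g2 <- vascular_graph(graph$nodes, seg[keep, , drop = FALSE],
                       graph$roots, validate = TRUE)
  orient_segments(g2)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  loops: %d\n", x$n_loops))
  cat(sprintf("  bifurcations: %d", nrow(x$bifurcations)))
  if (!is.null(x$gamma)) cat(sprintf("  gamma: %.3f", x$gamma$gamma))
  cat("\n")
  cat(sprintf("  inlet flow: %.3g ml/min\n",
              inlet_flow(x$state) * units_si$m3s_to_mlmin))
  if (!is.null(x$territories)) {
    cat(sprintf("  territories: %d, median perfusion %.2f ml/min/g\n",
                nrow(x$territories),
                stats::median(x$territories$perfusion_ml_min_g,
                              na.rm = TRUE)))
  }
  invisible(x)
}
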