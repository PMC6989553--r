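# Voronoi perfusion territories on a voxel grid, truncation-segment
# identification and transmural/regional summaries.

#' Construct a voxel grid over a myocardial domain
#'
#' Isotropic voxel grid with a myocardium mask and a per-voxel
#' normalized transmural depth (0 at the epicardial surface, 1 at the
#' endocardial surface).
#'
#' @param origin 3-vector, meters (corner of voxel (1,1,1)).
#' @param spacing isotropic voxel edge, meters.
#' @param dims integer 3-vector of voxel counts.
#' @param mask logical array of `dims` (default: all TRUE).
#' @param depth numeric array of `dims` with transmural depth in
#'   [0, 1], or NULL to derive it linearly along `depth_axis`.
#' @param depth_axis coordinate axis used when `depth` is NULL.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims, mask = NULL, depth = NULL,
                       depth_axis = 3L) {
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(dims) == 3L, spacing > 0,
            all(dims >= 1L))
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims), any(mask))
  if (is.null(depth)) {
    idx <- slice.index(array(0, dims), depth_axis)
    depth <- (idx - 0.5) / dims[depth_axis]
  }
  stopifnot(all(dim(depth) == dims))
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 mask = mask, depth = depth),
            class = "voxel_grid")
}

#' Build the grid for a slab domain
#'
#' @param domain a [domain_slab()].
#' @param spacing voxel edge, meters (defaults to the slab's voxel
#'   size).
#' @return a [voxel_grid()] with the slab's transmural axis as the
#'   depth axis.
#' @export
slab_grid <- function(domain, spacing = domain$voxel) {
  dims <- pmax(1L, as.integer(floor(domain$extents / spacing)))
  voxel_grid(origin = c(0, 0, 0), spacing = spacing, dims = dims,
             depth_axis = domain$transmural_axis)
}

# centers of the masked voxels, n x 3 matrix (meters)
voxel_centers <- function(grid) {
  idx <- which(grid$mask, arr.ind = TRUE)
  sweep(idx - 0.5, 2, rep(grid$spacing, 3), `*`) +
    matrix(grid$origin, nrow(idx), 3, byrow = TRUE)
}

#' Assign masked voxels to their nearest terminal node
#'
#' Euclidean nearest-neighbor labeling of every masked voxel center
#' against the terminal positions (3D Voronoi tessellation restricted
#' to the mask). Exact ties go to the lowest terminal id.
#'
#' @param grid a [voxel_grid()].
#' @param terminals data frame with columns `id`, `x`, `y`, `z`
#'   (terminal node ids and positions, meters).
#' @param chunk voxels per distance-matrix block (memory control).
#' @return integer vector of terminal ids, one per masked voxel (in
#'   `which(grid$mask)` order).
#' @export
voronoi_assign <- function(grid, terminals, chunk = 50000L) {
  if (nrow(terminals) == 0L) stop("no terminal nodes to assign",
                                  call. = FALSE)
  term <- terminals[order(terminals$id), , drop = FALSE]
  Tm <- as.matrix(term[, c("x", "y", "z")])
  V <- voxel_centers(grid)
  n <- nrow(V)
  lab <- integer(n)
  t2 <- rowSums(Tm^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    D <- -2 * V[s:e, , drop = FALSE] %*% t(Tm)
    D <- sweep(D, 2, t2, `+`) # ||v - t||^2 - ||v||^2, same argmin
    # which.min takes the first (lowest-id) minimum: deterministic ties
    lab[s:e] <- term$id[max.col(-D, ties.method = "first")]
  }
  lab
}

#' Identify truncation segments in a diameter band
#'
#' The truncation segments are the first segments along each
#' root-to-terminal path whose diameter drops below `d_high`. Every
#' terminal maps to exactly one truncation segment; truncation
#' segments whose diameter is also below `d_low` are flagged as
#' below-band but retained.
#'
#' @param graph an oriented, loop-free `vascular_graph`.
#' @param d_low,d_high truncation diameter band, meters (default
#'   100-200 um).
#' @return list with `segments` (data frame: segment id, diameter,
#'   `below_band` flag) and `terminal_map` (data frame: terminal node
#'   id -> truncation segment id).
#' @export
truncation_segments <- function(graph, d_low = 100e-6, d_high = 200e-6) {
  if (count_loops(graph) > 0) {
    stop("truncation analysis requires a loop-free subtree", call. = FALSE)
  }
  if (any(graph$segments$orientation == "unoriented")) {
    graph <- orient_segments(graph)
  }
  ep <- oriented_endpoints(graph)
  nid <- graph$nodes$id
  from_i <- match(ep$from, nid); to_i <- match(ep$to, nid)
  prox <- root_proximity(graph)
  ord <- order(prox[to_i]) # proximal first
  trunc_at <- rep(NA_integer_, length(nid)) # truncation seg carried by node
  seg_trunc <- rep(NA_integer_, nrow(graph$segments))
  for (k in ord) {
    inherited <- trunc_at[from_i[k]]
    if (is.na(inherited) && graph$segments$diameter[k] < d_high) {
      inherited <- graph$segments$id[k]
    }
    seg_trunc[k] <- inherited
    trunc_at[to_i[k]] <- inherited
  }
  deg <- node_degrees(graph)
  is_term <- deg == 1L & !graph$nodes$is_root
  terminal_map <- data.frame(terminal = nid[is_term],
                             truncation_segment = trunc_at[is_term])
  ids <- sort(unique(stats::na.omit(terminal_map$truncation_segment)))
  dvec <- graph$segments$diameter[match(ids, graph$segments$id)]
  list(segments = data.frame(id = ids, diameter = dvec,
                             below_band = dvec < d_low),
       terminal_map = terminal_map)
}

#' Perfusion territories of truncation segments
#'
#' The territory of a truncation segment is the union of the Voronoi
#' cells of the terminals it feeds. Perfusion is the flow through the
#' truncation segment divided by the territory mass (volume times
#' tissue density), in ml/min/g.
#'
#' @param state a solved `hemodynamic_state`.
#' @param labels per-masked-voxel terminal labels from
#'   [voronoi_assign()].
#' @param truncation output of [truncation_segments()].
#' @param grid the [voxel_grid()] used for the labeling.
#' @param density tissue density, kg/m^3 (default 1.05 g/cm^3).
#' @return data frame of class `perfusion_territories`: one row per
#'   truncation segment with voxel count, volume (m^3), mass (kg),
#'   flow (m^3/s), perfusion (ml/min/g), below-band flag and the
#'   mean transmural depth of the territory. Territories with zero
#'   voxels carry NA perfusion and `empty = TRUE`.
#' @export
territory_perfusion <- function(state, labels, truncation, grid,
                                density = 1.05e3) {
  tmap <- truncation$terminal_map
  vox_trunc <- tmap$truncation_segment[match(labels, tmap$terminal)]
  vol_vox <- grid$spacing^3
  depth_masked <- grid$depth[grid$mask]

  ids <- truncation$segments$id
  counts <- as.numeric(table(factor(vox_trunc, levels = ids)))
  mean_depth <- vapply(ids, function(i) {
    s <- !is.na(vox_trunc) & vox_trunc == i
    if (any(s)) mean(depth_masked[s]) else NA_real_
  }, numeric(1))
  Q <- abs(state$segments$Q[match(ids, state$segments$id)])
  vol <- counts * vol_vox
  mass <- vol * density
  perf <- ifelse(mass > 0,
                 (Q * units_si$m3s_to_mlmin) / (mass * 1e3), NA_real_)
  out <- data.frame(truncation_segment = ids, n_voxels = counts,
                    volume_m3 = vol, mass_kg = mass, flow_m3s = Q,
                    perfusion_ml_min_g = perf,
                    below_band = truncation$segments$below_band,
                    mean_depth = mean_depth,
                    empty = counts == 0)
  class(out) <- c("perfusion_territories", "data.frame")
  out
}

#' Regional (transmural) summary of terminals and perfusion
#'
#' Splits the wall into depth thirds — subepicardium [0, 1/3),
#' midmyocardium [1/3, 2/3), subendocardium [2/3, 1] — and reports
#' per-region terminal density (per cm^3 of masked tissue) and
#' perfusion quantiles of the territories whose mean depth falls in
#' the region.
#'
#' @param territories a `perfusion_territories` data frame.
#' @param terminals data frame with terminal positions and a `depth`
#'   column (normalized transmural depth per terminal).
#' @param grid the [voxel_grid()].
#' @return data frame with one row per region.
#' @export
regional_summary <- function(territories, terminals, grid) {
  breaks <- c(0, 1 / 3, 2 / 3, 1 + 1e-9)
  region_of <- function(t) cut(t, breaks, right = FALSE,
                               labels = c("subepicardium", "midmyocardium",
                                          "subendocardium"))
  depth_masked <- grid$depth[grid$mask]
  vol_cm3 <- as.numeric(table(region_of(depth_masked))) *
    grid$spacing^3 * 1e6
  n_term <- as.numeric(table(region_of(terminals$depth)))
  reg_t <- region_of(territories$mean_depth)
  qs <- function(v, p) if (length(v)) stats::quantile(v, p, names = FALSE)
                       else NA_real_
  rows <- lapply(1:3, function(r) {
    lab <- levels(reg_t)[r]
    perf <- territories$perfusion_ml_min_g[!is.na(reg_t) &
                                             as.integer(reg_t) == r]
    perf <- perf[!is.na(perf)]
    data.frame(region = lab,
               volume_cm3 = vol_cm3[r],
               n_terminals = n_term[r],
               terminal_density_cm3 = if (vol_cm3[r] > 0)
                 n_term[r] / vol_cm3[r] else NA_real_,
               n_territories = length(perf),
               perfusion_median = qs(perf, 0.5),
               perfusion_q1 = qs(perf, 0.25),
               perfusion_q3 = qs(perf, 0.75),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
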