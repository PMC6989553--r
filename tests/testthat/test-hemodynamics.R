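# Viscosity law, Poiseuille conductance, Kirchhoff solve, derived
# fields, downstream conductance, and solver invariants.

test_that("in vivo viscosity law matches its printed sub-expressions", {
  # large-vessel limit at H_d = 0.45: relative viscosity -> 3.2
  expect_equal(relative_viscosity(1e-2, viscosity_model(0.45)), 3.2,
               tolerance = 1e-3)
  expect_equal(relative_viscosity(1e-1, viscosity_model(0.45)), 3.2,
               tolerance = 1e-4)
  # zero hematocrit: only the (d/(d-1.1))^2 factor remains
  d <- c(5, 10, 50, 300) * 1e-6
  expect_equal(relative_viscosity(d, viscosity_model(0)),
               (d * 1e6 / (d * 1e6 - 1.1))^2, tolerance = 1e-12)
  # direct evaluation at d = 10 um, H = 0.45: bracket is
  # 1 + (mu*45 - 1) * f with the squared ESL factor f applied twice
  mu45_10 <- 6 * exp(-0.85) + 3.2 - 2.44 * exp(-0.06 * 10^0.645)
  f10 <- (10 / 8.9)^2
  expect_equal(relative_viscosity(10e-6, viscosity_model(0.45)),
               (1 + (mu45_10 - 1) * f10) * f10, tolerance = 1e-9)
  expect_error(relative_viscosity(1e-6), "1.1 um")
})

test_that("viscosity shape: steep rise toward capillaries, plateau above", {
  vm <- viscosity_model(0.4)
  # the apparent viscosity drops from the capillary domain to a
  # minimum in the arteriolar range, then climbs toward the
  # large-vessel plateau
  d_small <- seq(3e-6, 45e-6, length.out = 100)
  expect_true(all(diff(relative_viscosity(d_small, vm)) < 0))
  # climb from the arteriolar minimum into the conduit arteries,
  # flattening onto the large-vessel plateau
  d_big <- seq(55e-6, 1500e-6, length.out = 100)
  expect_true(all(diff(relative_viscosity(d_big, vm)) > 0))
  plateau <- relative_viscosity(c(2e-3, 5e-3, 1e-2), vm)
  expect_lt(diff(range(plateau)) / mean(plateau), 0.005)
  # higher hematocrit, higher viscosity
  expect_true(all(relative_viscosity(d_big, viscosity_model(0.45)) >
                  relative_viscosity(d_big, vm)))
})

test_that("segment conductance is Poiseuille with d^4 and 1/l scaling", {
  G <- segment_conductance(100e-6, 1e-3, 3e-3)
  expect_equal(G, pi * 1e-16 / (128 * 3e-3 * 1e-3), tolerance = 1e-12)
  expect_equal(segment_conductance(200e-6, 1e-3, 3e-3) / G, 16)
  expect_equal(segment_conductance(100e-6, 2e-3, 3e-3) / G, 0.5)
  expect_error(segment_conductance(-1, 1, 1), "positive")
})

test_that("two-resistor divider matches the closed form", {
  nodes <- data.frame(id = 1:2, x = c(0, 1e-3), y = 0, z = 0)
  segs <- data.frame(id = 1, node_a = 1, node_b = 2,
                     diameter = 100e-6, length = 1e-3)
  g <- vascular_graph(nodes, segs, 1)
  mu <- 3e-3
  Gs <- segment_conductance(100e-6, 1e-3, mu)
  Gd <- Gs / 2
  bc <- boundary_conditions(G_dist = Gd)
  st <- solve_pressures(g, bc, viscosity = mu)
  # series conductance Gs*Gd/(Gs+Gd); P at node 2 from the divider
  Geq <- 1 / (1 / Gs + 1 / Gd)
  Q <- Geq * (bc$P_in - bc$P_cap)
  expect_equal(st$segments$Q, Q, tolerance = 1e-12)
  expect_equal(st$nodes$P[2], bc$P_in - Q / Gs, tolerance = 1e-12)
  expect_equal(st$terminals$Q_out, Q, tolerance = 1e-12)
})

test_that("symmetric Y splits the mother flow equally", {
  g <- make_y_graph(d = c(100, 70, 70) * 1e-6)
  bc <- boundary_conditions(G_dist = Inf)
  st <- solve_pressures(g, bc, viscosity = 3e-3)
  q <- st$segments$Q
  expect_equal(q[2], q[3], tolerance = 1e-12)
  expect_equal(q[1], q[2] + q[3], tolerance = 1e-12)
})

test_that("diamond loop with equal arms has a dead bridge and equal flows", {
  g <- make_diamond()
  bc <- boundary_conditions(G_dist = Inf)
  st <- solve_pressures(g, bc, viscosity = 3e-3)
  arms <- which(st$segments$node_a == 2 & st$segments$node_b %in% c(3, 4))
  expect_equal(st$segments$Q[arms[1]], st$segments$Q[arms[2]],
               tolerance = 1e-12)
  # symmetric arms: no pressure difference across the bridge
  bridge <- which(st$segments$node_a == 3 & st$segments$node_b == 4)
  i3 <- match(3, st$nodes$id); i4 <- match(4, st$nodes$id)
  expect_equal(st$nodes$P[i3], st$nodes$P[i4], tolerance = 1e-9)
  expect_lt(abs(st$segments$Q[bridge]) / max(abs(st$segments$Q)), 1e-9)
  expect_lt(st$residual, 1e-12)
})

test_that("derived fields match their formulas and the Poiseuille identity", {
  # tau = dP d / (4 l) oracle
  dP <- mmHg_to_Pa(1)
  expect_equal(dP * 1e-4 / (4 * 1e-3), 3.33305, tolerance = 1e-4)
  g <- make_y_graph()
  st <- solve_pressures(g, boundary_conditions(G_dist = Inf),
                        viscosity = 3e-3)
  seg <- st$segments
  # wall shear stress from pressure drop equals 32 mu Q / (pi d^3)
  expect_equal(wall_shear_stress(st),
               32 * seg$mu * abs(seg$Q) / (pi * seg$diameter^3),
               tolerance = 1e-12)
  # centerline velocity: Q = 1 ml/min in d = 1 mm -> ~4.24 cm/s
  Q <- 1 / units_si$m3s_to_mlmin
  v_cl <- 2 * Q / (pi * (0.5e-3)^2)
  expect_equal(v_cl * 100, 4.24, tolerance = 1e-2)
  expect_equal(centerline_velocity(st),
               2 * abs(seg$Q) / (pi * (seg$diameter / 2)^2))
})

test_that("pressure profile is monotone from root to terminals on trees", {
  st <- reference_statistics()
  tr <- generate_tree(60e-6, st, seed = 21)
  sol <- solve_pressures(tr, boundary_conditions(G_dist = Inf))
  ep <- coronet:::oriented_endpoints(tr)
  Pa <- sol$nodes$P[match(ep$from, sol$nodes$id)]
  Pb <- sol$nodes$P[match(ep$to, sol$nodes$id)]
  expect_true(all(Pa >= Pb - 1e-9))
  expect_true(all(sol$nodes$P >= sol$bc$P_cap - 1e-9 &
                  sol$nodes$P <= sol$bc$P_in + 1e-9))
})

test_that("pressures are invariant to plasma viscosity on pressure BCs", {
  # with pressure boundary conditions and distal conductances scaling
  # with the same mu_plasma, all conductances scale uniformly and the
  # pressure field is unchanged
  tr <- generate_tree(40e-6, reference_statistics(), seed = 31)
  for (mp in c(1.2e-3, 2.4e-3)) {
    vm <- viscosity_model(0.4, mu_plasma = mp)
    sol <- solve_pressures(tr, boundary_conditions(G_dist = Inf), vm)
    if (mp == 1.2e-3) P1 <- sol$nodes$P else P2 <- sol$nodes$P
  }
  expect_equal(P1, P2, tolerance = 1e-9)
})

test_that("downstream conductance follows resistor algebra", {
  mu <- 3e-3
  # single segment: its own conductance
  nodes <- data.frame(id = 1:2, x = c(0, 1e-3), y = 0, z = 0)
  segs <- data.frame(id = 1, node_a = 1, node_b = 2,
                     diameter = 100e-6, length = 1e-3)
  g1 <- vascular_graph(nodes, segs, 1)
  expect_equal(downstream_conductance(g1, mu),
               segment_conductance(100e-6, 1e-3, mu))
  # symmetric Y with identical conductances: series(G, 2G) = 2G/3
  g <- make_y_graph(d = rep(100e-6, 3), l = rep(1e-3, 3))
  G <- segment_conductance(100e-6, 1e-3, mu)
  gd <- downstream_conductance(g, mu)
  expect_equal(gd[1], 2 * G / 3, tolerance = 1e-12)
  expect_equal(gd[2:3], rep(G, 2))
  expect_error(downstream_conductance(make_diamond(), mu), "loop-free")
})

test_that("solver matches the reduction oracle on random trees", {
  mu <- 3.5e-3
  P_in <- mmHg_to_Pa(90); P_cap <- mmHg_to_Pa(20)
  worst <- 0
  for (s in 1:25) {
    g <- random_tree_graph(sample(20:200, 1), seed = 1000 + s)
    tids <- terminal_ids(g)
    set.seed(s)
    Gd <- stats::setNames(10^runif(length(tids), -14, -12), tids)
    bc <- boundary_conditions(P_in, P_cap, Gd)
    st <- solve_pressures(g, bc, viscosity = mu)
    or <- oracle_tree_solve(g, P_in, P_cap, mu, as.list(Gd))
    g2 <- orient_segments(g)
    sgn <- ifelse(g2$segments$orientation == "a_to_b", 1, -1)
    scale_P <- P_in - P_cap
    expect_lt(max(abs(st$nodes$P - or$P)) / scale_P, 1e-9)
    expect_lt(max(abs(sgn * st$segments$Q - or$Q)) / max(abs(or$Q)), 1e-9)
    worst <- max(worst,
                 abs(inlet_flow(st, g) / (P_in - P_cap) - or$G_root) /
                   or$G_root)
  }
  expect_lt(worst, 1e-9)
})

test_that("downstream conductance equals full-solve equivalent conductance", {
  st <- reference_statistics()
  for (s in 1:5) {
    tr <- generate_tree(runif(1, 30e-6, 60e-6), st, seed = 500 + s)
    gd <- downstream_conductance(tr)
    bc <- boundary_conditions(G_dist = Inf)
    sol <- solve_pressures(tr, bc)
    Geq <- inlet_flow(sol, tr) / (bc$P_in - bc$P_cap)
    root_seg <- which(tr$segments$node_a == 1)
    expect_equal(gd[root_seg], Geq, tolerance = 1e-9)
  }
})

test_that("energy balance closes across segments and terminals", {
  g <- generate_embedded_network(domain_slab(c(5e-3, 5e-3, 5e-3)),
                                 150, reference_statistics(), seed = 3)
  mu <- 3e-3
  tids <- terminal_ids(g)
  set.seed(4)
  bc <- boundary_conditions(
    G_dist = stats::setNames(10^runif(length(tids), -14, -13), tids))
  st <- solve_pressures(g, bc, viscosity = mu)
  seg <- st$segments
  Pa <- st$nodes$P[match(seg$node_a, st$nodes$id)]
  Pb <- st$nodes$P[match(seg$node_b, st$nodes$id)]
  diss_seg <- sum((Pa - Pb) * seg$Q)
  Pt <- st$nodes$P[match(st$terminals$id, st$nodes$id)]
  diss_term <- sum((Pt - bc$P_cap) * st$terminals$Q_out)
  total <- (bc$P_in - bc$P_cap) * inlet_flow(st, g)
  expect_equal(diss_seg + diss_term, total, tolerance = 1e-8)
})

test_that("mass is conserved on loop- and trifurcation-bearing graphs", {
  dom <- domain_slab(c(6e-3, 6e-3, 6e-3))
  g <- generate_embedded_network(dom, 250, reference_statistics(),
                                 loop_fraction = 0.05,
                                 trifurcation_fraction = 0.08, seed = 12)
  tids <- terminal_ids(g)
  bc <- boundary_conditions(G_dist = stats::setNames(
    rep(1e-13, length(tids)), tids))
  st <- solve_pressures(g, bc)
  expect_lt(st$residual, 1e-8)
})
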