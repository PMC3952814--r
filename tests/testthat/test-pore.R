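# Clearance lattice and maximum-bottleneck path analysis.

test_that("clearance field equals the brute-force nearest-bead scan", {
  # single bead at the origin: node (3,4,0) clears 5 A; subtract mode 3 A
  fr <- assembly_frame(list(chain_record("A", "A", matrix(0, 1, 3))),
                       bath_geometry(c(6, 6, 6), periodic = FALSE))
  g <- build_clearance_grid(fr, spacing = 1)
  expect_equal(g$clearance[4, 5, 1], 5)
  gs <- build_clearance_grid(fr, spacing = 1, bead_radius_mode = "subtract",
                             radii = c(default = 2.0))
  expect_equal(gs$clearance[4, 5, 1], 3)
  # random 50-bead frame vs all-beads scan on a 10^3 grid
  set.seed(9)
  beads <- matrix(runif(150, 0, 18), 50, 3)
  fr2 <- assembly_frame(list(chain_record("B", strrep("A", 50), beads)),
                        bath_geometry(c(18, 18, 18), periodic = FALSE))
  g2 <- build_clearance_grid(fr2, spacing = 2)
  expect_equal(g2$clearance,
               oracle_clearance(beads, g2$origin, 2, g2$dims, g2$cap))
  # empty frame: clearances capped at the domain diagonal
  ge <- build_clearance_grid(assembly_frame(list(),
                                            bath_geometry(c(10, 10, 10))),
                             spacing = 5)
  expect_true(all(ge$clearance == sqrt(3 * 100)))
  expect_error(build_clearance_grid(assembly_frame(list()), 2), "domain")
  expect_error(build_clearance_grid(fr, spacing = -1), "spacing")
})

test_that("widest path follows min-along-path and max-over-paths", {
  # single 1x1x4 corridor: bottleneck is the minimum clearance
  g <- clearance_grid(array(c(5, 9, 4, 7), c(1, 1, 4)))
  res <- widest_bottleneck_path(g, 1, 4)
  expect_equal(res$bottleneck_radius, 4)
  expect_equal(min(g$clearance[res$witness_nodes]), 4)
  # two disjoint corridors with bottlenecks 3 and 6: the wider one wins
  field <- array(0, c(3, 1, 4))
  field[1, 1, ] <- c(8, 3, 8, 8)
  field[3, 1, ] <- c(8, 6, 8, 8)
  g2 <- clearance_grid(field)
  idx <- function(ix, iz) ix + 3 * ((iz - 1) * 1)
  res2 <- widest_bottleneck_path(g2, c(idx(1, 1), idx(3, 1)),
                                 c(idx(1, 4), idx(3, 4)))
  expect_equal(res2$bottleneck_radius, 6)
  expect_error(widest_bottleneck_path(g2, integer(0), 1), "non-empty")
  expect_error(widest_bottleneck_path(g2, 1, 1), "disjoint")
})

test_that("widest path equals the threshold-percolation oracle", {
  set.seed(77)
  for (rep in 1:25) {
    dims <- sample(8:12, 3, replace = TRUE)
    clear <- round(runif(prod(dims), 0, 10), 2)
    g <- clearance_grid(array(clear, dims))
    sources <- which(fgassembly:::.grid_index_arrays(g)$iz == 1L)
    sinks <- which(fgassembly:::.grid_index_arrays(g)$iz == dims[3])
    for (conn in c(6L, 26L)) {
      res <- widest_bottleneck_path(g, sources, sinks, conn)
      expect_identical(res$bottleneck_radius,
                       oracle_widest_bottleneck(clear, dims, sources,
                                                sinks, conn))
    }
    # 26-connectivity can never be narrower than 6-connectivity
    expect_gte(widest_bottleneck_path(g, sources, sinks,
                                      26L)$bottleneck_radius,
               widest_bottleneck_path(g, sources, sinks,
                                      6L)$bottleneck_radius)
  }
})

test_that("channel phantoms are recovered within one lattice spacing", {
  for (R in c(5, 10, 20, 40)) {
    ph <- make_channel_phantom(R)
    res <- axial_pore_size(ph$frame, spacing = 2)
    expect_lte(abs(res$bottleneck_radius - R), 2)
  }
  # serial bottlenecks: the smaller governs
  ph2 <- make_channel_phantom(12, second_radius = 8)
  expect_lte(abs(axial_pore_size(ph2$frame, 2)$bottleneck_radius - 8), 2)
  # solid wall: no permeating clearance
  ph0 <- make_channel_phantom(0)
  expect_equal(axial_pore_size(ph0$frame, 2)$bottleneck_radius, 0)
  # empty frame in a 100 A box: bounded by the domain, not the structure
  empty <- assembly_frame(list(), bath_geometry(c(100, 100, 100),
                                                periodic = FALSE))
  expect_gte(axial_pore_size(empty, spacing = 10)$bottleneck_radius, 50)
})

test_that("radial probing recovers ring-bore phantoms", {
  rg <- make_channel_phantom(20, geometry = "ring")
  res <- radial_pore_size(rg$frame, spacing = 2)
  expect_lte(abs(res$bottleneck_radius - 20), 2)
  rg10 <- make_channel_phantom(10, geometry = "ring")
  expect_lte(abs(radial_pore_size(rg10$frame, 2)$bottleneck_radius - 10), 2)
  solid <- make_channel_phantom(0, geometry = "ring")
  expect_lt(radial_pore_size(solid$frame, 2)$bottleneck_radius, 2)
  expect_error(radial_pore_size(make_channel_phantom(5)$frame, 2), "ring")
})

test_that("adding obstacles never widens the bottleneck", {
  set.seed(41)
  ph <- make_channel_phantom(12)
  base <- axial_pore_size(ph$frame, spacing = 2)$bottleneck_radius
  fr <- ph$frame
  prev <- base
  for (k in 1:10) {
    extra <- chain_record(sprintf("e%d", k), "A",
                          matrix(c(runif(2, 10, 54), runif(1, 2, 38)), 1, 3))
    fr <- assembly_frame(c(fr$chains, list(extra)), fr$geometry)
    now <- axial_pore_size(fr, spacing = 2)$bottleneck_radius
    expect_lte(now, prev + 1e-12)
    prev <- now
  }
})

test_that("recovered radius converges as the lattice is refined", {
  ph <- make_channel_phantom(10)
  errs <- vapply(c(4, 2, 1), function(s)
    abs(axial_pore_size(ph$frame, spacing = s)$bottleneck_radius - 10),
    numeric(1))
  expect_lte(errs[2], errs[1] + 1e-9)
  expect_lte(errs[3], errs[2] + 1e-9)
  expect_lte(errs[3], 1)
})

test_that("pore statistics aggregate the trailing window", {
  ph <- make_channel_phantom(12)
  st <- pore_size_stats(list(ph$frame, ph$frame, ph$frame), spacing = 2)
  expect_equal(st$std, 0)
  expect_equal(st$mean, 12)
  frames <- lapply(c(10, 12, 14), function(R) make_channel_phantom(R)$frame)
  st2 <- pore_size_stats(frames, spacing = 2)
  expect_lte(abs(st2$mean - 12), 2)
  expect_lte(abs(st2$std - 2), 2)
  expect_equal(st2$per_frame, c(10, 12, 14), tolerance = 0.2)
  expect_error(pore_size_stats(frames, window = 5, spacing = 2), "window")
})

test_that("pore maps export the nodes above the clearance threshold", {
  # wide channel: exported nodes form one connected axial component
  ph <- make_channel_phantom(40)
  g <- build_clearance_grid(ph$frame, spacing = 2)
  path <- tempfile(fileext = ".pdb")
  xyz <- export_pore_map(g, min_radius = 35, path)
  expect_gt(nrow(xyz), 0)
  expect_true(file.exists(path))
  span <- range(xyz[, 3])
  expect_lt(span[1], 5)
  expect_gt(span[2], 35)
  # adjacency graph of exported nodes (6-connectivity) has one component
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  ids <- setNames(seq_len(nrow(xyz)), key(xyz))
  edges <- NULL
  for (d in list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))) {
    nb <- ids[key(sweep(xyz, 2, d, "+"))]
    ok <- !is.na(nb)
    edges <- rbind(edges, cbind(which(ok), unname(nb[ok])))
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_equal(igraph::components(gr)$no, 1)
  # solid block: empty map
  block <- make_channel_phantom(0)
  gb <- build_clearance_grid(block$frame, spacing = 2)
  xyz0 <- export_pore_map(gb, min_radius = 35, path)
  expect_identical(nrow(xyz0), 0L)
})
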