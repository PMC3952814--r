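# Extended-chain construction, SAW growth constraints, tether geometries,
# mutant transform and motif annotation.

test_that("extended chain places residues on the stated line", {
  ch <- build_extended_chain("AAA", c(0, 0, 0), c(0, 0, 1), 3.7)
  expect_equal(ch$coords[, 3], c(0, 3.7, 7.4))
  expect_equal(ch$coords[, 1:2], matrix(0, 3, 2))
  long <- build_extended_chain(strrep("A", 614), c(0, 0, 0), c(0, 0, 1))
  expect_equal(sqrt(sum((long$coords[614, ] - long$coords[1, ])^2)),
               613 * 3.7)
  # collinearity of an oblique direction
  d <- c(1, 2, 2) / 3
  ob <- build_extended_chain(strrep("A", 20), c(5, 5, 5), d)
  disp <- sweep(ob$coords, 2, ob$coords[1, ])
  expect_lt(max(abs(disp - outer((0:19) * 3.7, d))), 1e-9)
  expect_error(build_extended_chain("AA", c(0, 0, 0), c(0, 0, 0)), "zero")
})

test_that("extended-chain Rg matches the closed form b*sqrt((N^2-1)/12)", {
  for (N in c(2, 10, 614)) {
    ch <- build_extended_chain(strrep("A", N), c(0, 0, 0), c(0, 0, 1))
    expect_equal(radius_of_gyration(ch), 3.7 * sqrt((N^2 - 1) / 12),
                 tolerance = 1e-9)
  }
})

test_that("SAW chains satisfy bond, angle and clash constraints", {
  set.seed(11)
  p <- saw_params()
  for (rep in 1:5) {
    ch <- grow_saw_chain(synthetic_fg_sequence(100), matrix(0, 1, 3), p)
    x <- ch$coords
    d <- sqrt(rowSums(diff(x)^2))
    expect_lt(max(abs(d - p$bond_length)), 1e-6)
    v1 <- x[1:98, ] - x[2:99, ]
    v2 <- x[3:100, ] - x[2:99, ]
    ang <- acos(pmax(-1, pmin(1, rowSums(v1 * v2) /
                                sqrt(rowSums(v1^2) * rowSums(v2^2)))))
    expect_lt(max(abs(ang * 180 / pi - p$bend_angle)), 1e-4)
    D <- as.matrix(dist(x))
    sep <- abs(row(D) - col(D))
    expect_gte(min(D[sep > p$sequence_separation_exempt]), p$clash_cutoff)
  }
})

test_that("SAW growth respects obstacles and the half-space constraint", {
  set.seed(3)
  p <- saw_params()
  # dense obstacle shell of radius 10 A around the seed: no legal placement
  sp <- fgassembly:::.sphere_points(500) * 10
  expect_error(grow_saw_chain("AAAAA", matrix(0, 1, 3), saw_params(
    max_chain_restarts = 3), obstacles = sp),
    class = "fg_growth_failure")
  err <- tryCatch(grow_saw_chain("AAAAA", matrix(0, 1, 3),
                                 saw_params(max_chain_restarts = 3),
                                 obstacles = sp),
                  fg_growth_failure = identity)
  expect_lte(err$deepest_residue, 5L)
  # two-residue chains always succeed without obstacles
  for (rep in 1:10)
    expect_s3_class(grow_saw_chain("AA", matrix(0, 1, 3), p),
                    "chain_record")
  # obstacle clearance
  ob <- matrix(c(0, 0, 30), 1, 3)
  ch <- grow_saw_chain(synthetic_fg_sequence(50), matrix(0, 1, 3), p,
                       obstacles = ob)
  expect_gte(min(sqrt(rowSums(sweep(ch$coords, 2, ob[1, ])^2))),
             p$clash_cutoff)
  # half space
  ch2 <- grow_saw_chain(synthetic_fg_sequence(50), matrix(0, 1, 3), p,
                        zmin = 0)
  expect_gte(min(ch2$coords[, 3]), 0)
})

test_that("identical seeds give bit-identical SAW assemblies", {
  p <- saw_params(rng_seed = 99L)
  a <- grow_saw_chain(synthetic_fg_sequence(60), matrix(0, 1, 3), p)
  b <- grow_saw_chain(synthetic_fg_sequence(60), matrix(0, 1, 3), p)
  expect_identical(a$coords, b$coords)
  f1 <- place_array_assembly(2, 1, 60, mode = "saw",
                             sequence = synthetic_fg_sequence(40), seed = 5)
  f2 <- place_array_assembly(2, 1, 60, mode = "saw",
                             sequence = synthetic_fg_sequence(40), seed = 5)
  expect_identical(lapply(f1$chains, `[[`, "coords"),
                   lapply(f2$chains, `[[`, "coords"))
})

test_that("mean squared end-to-end distance grows superlinearly with N", {
  set.seed(21)
  p <- saw_params()
  msq <- vapply(c(25, 50, 100), function(N) {
    e2 <- replicate(30, {
      x <- grow_saw_chain(strrep("A", N), matrix(0, 1, 3), p)$coords
      sum((x[N, ] - x[1, ])^2)
    })
    mean(e2)
  }, numeric(1))
  # doubling N more than doubles <R^2> (excluded volume + stiffness)
  expect_gt(msq[2] / msq[1], 2)
  expect_gt(msq[3] / msq[2], 2)
})

test_that("ring builder emits the requested anchors and tethers", {
  seqs <- synthetic_fg_sequence(30)
  fr <- place_ring_assembly(120, 3, mode = "extended", sequence = seqs)
  a <- assembly_anchors(fr)
  expect_identical(nrow(a), 120L)
  expect_identical(length(fr$chains), 120L)
  # 40 anchors per row at three radii
  r <- round(sqrt(a[, 1]^2 + a[, 2]^2), 6)
  expect_identical(as.vector(table(r)), c(40L, 40L, 40L))
  # minimum pairwise anchor distance ~ 60 A (within 1%)
  dm <- as.matrix(dist(a)); diag(dm) <- Inf
  expect_lt(abs(min(dm) - 60) / 60, 0.01)
  # C-terminal residue fixed at the anchor, chain extended along +z
  ch <- fr$chains[[1]]
  expect_identical(ch$tether$residue, nchar(seqs))
  expect_equal(ch$coords[nchar(seqs), ], unname(a[1, ]))
  expect_equal(ch$coords[1, 3], (nchar(seqs) - 1) * 3.7)
  # one anchor per row at three radii
  fr3 <- place_ring_assembly(3, 3, mode = "extended", sequence = "AAA")
  a3 <- assembly_anchors(fr3)
  expect_identical(nrow(a3), 3L)
  expect_identical(length(unique(round(sqrt(a3[, 1]^2 + a3[, 2]^2), 6))), 3L)
  expect_error(place_ring_assembly(120, 3, inner_radius = 100,
                                   sequence = seqs), "too small")
  expect_error(place_ring_assembly(100, 3, sequence = seqs), "divisible")
})

test_that("array builder places anchors at exact grid nodes", {
  fr <- place_array_assembly(5, 5, 60, mode = "extended",
                             sequence = synthetic_fg_sequence(20))
  expect_identical(length(fr$chains), 25L)
  a <- assembly_anchors(fr)
  dm <- as.matrix(dist(a)); diag(dm) <- Inf
  expect_equal(min(dm), 60)
  expect_true(all(a[, 1:2] %% 60 == 0))
  one <- place_array_assembly(1, 1, 60, mode = "extended", sequence = "AA")
  expect_identical(length(one$chains), 1L)
  # SAW mode: adjacent chains respect the inter-chain clash rule
  set.seed(13)
  fr2 <- place_array_assembly(2, 1, 20, mode = "saw",
                              sequence = synthetic_fg_sequence(40))
  x1 <- fr2$chains[[1]]$coords; x2 <- fr2$chains[[2]]$coords
  cross <- sqrt(outer(rowSums(x1^2), rep(1, 40)) +
                  outer(rep(1, 40), rowSums(x2^2)) - 2 * x1 %*% t(x2))
  expect_gte(min(cross), 8)
  # +z half space at generation time
  expect_gte(min(x1[, 3]), 0)
})

test_that("bath builder satisfies minimum-image inter-chain constraints", {
  set.seed(17)
  box <- 80
  fr <- place_bath_assembly(2, box, sequence = synthetic_fg_sequence(30))
  expect_true(fr$geometry$periodic)
  x1 <- fr$chains[[1]]$coords; x2 <- fr$chains[[2]]$coords
  # brute force over the 27 image translations
  mind <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    sh <- sweep(x2, 2, c(i, j, k) * box, "+")
    cross <- sqrt(outer(rowSums(x1^2), rep(1, nrow(sh))) +
                    outer(rep(1, nrow(x1)), rowSums(sh^2)) -
                    2 * x1 %*% t(sh))
    mind <- min(mind, cross)
  }
  expect_gte(mind, 8 - 1e-9)
  expect_error(place_bath_assembly(120, 100,
                                   sequence = synthetic_fg_sequence(609)),
               "infeasible")
})

test_that("FG-to-AA transform removes every F and G and is idempotent", {
  expect_identical(mutate_fg_to_ala("FSFG"), "ASAA")
  expect_identical(mutate_fg_to_ala("NKT"), "NKT")
  s <- synthetic_fg_sequence(609)
  m <- mutate_fg_to_ala(s)
  expect_identical(nchar(m), nchar(s))
  expect_false(grepl("[FG]", m))
  expect_identical(mutate_fg_to_ala(m), m)
  expect_error(mutate_fg_to_ala("FXZ"), "invalid")
})

test_that("motif annotation follows the left-to-right precedence scan", {
  expect_identical(annotate_motifs("FSFG")$kind, "FxFG")
  expect_identical(annotate_motifs("FSFG")$start, 1L)
  glfg <- annotate_motifs("GLFG")
  expect_identical(glfg$kind, "FG")
  expect_identical(glfg$start, 3L)
  expect_identical(nrow(annotate_motifs("AAAA")), 0L)
  # FxFG precedence over FG at the same locus; non-overlap afterwards
  both <- annotate_motifs("FGFGAFG")
  expect_identical(both$kind, c("FxFG", "FG"))
  expect_identical(both$start, c(1L, 6L))
  # spans within bounds for the bundled sequence
  s <- synthetic_fg_sequence(609)
  mt <- annotate_motifs(s)
  expect_true(all(mt$end <= 609))
  expect_true(all(diff(mt$start) > 0))
})
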