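# Residue distances, contact graph, components, bundle decomposition,
# thickness distributions and propensities.

test_that("residue distance is min-over-beads and minimum-image aware", {
  a <- chain_record("A", "A", matrix(c(0, 0, 0), 1, 3))
  b <- chain_record("B", "A", matrix(c(3, 4, 0), 1, 3))
  fr <- assembly_frame(list(a, b))
  expect_equal(residue_distance(fr, "A", 1, "B", 1), 5)
  # extra bead closer than the backbone bead
  b2 <- chain_record("B", "A", matrix(c(3, 4, 0), 1, 3),
                     extra_beads = list(matrix(c(0, 1, 0), 1, 3)))
  fr2 <- assembly_frame(list(a, b2))
  expect_equal(residue_distance(fr2, "A", 1, "B", 1), 1)
  # periodic wrap: x = 1 and x = 9 in a 10 A box are 2 A apart
  pa <- chain_record("A", "A", matrix(c(1, 0, 0), 1, 3))
  pb <- chain_record("B", "A", matrix(c(9, 0, 0), 1, 3))
  fr3 <- assembly_frame(list(pa, pb), bath_geometry(10))
  expect_equal(residue_distance(fr3, "A", 1, "B", 1), 2)
  expect_error(residue_distance(fr, "C", 1, "B", 1), "unknown chain")
  expect_error(residue_distance(fr, "A", 5, "B", 1), "out of range")
})

test_that("contact graph matches forced geometries", {
  fr <- two_parallel_chains(10, 5)
  g <- build_contact_graph(fr, 6)
  contacts <- g$edges[g$edges$provenance == "interchain_contact", ]
  expect_identical(nrow(contacts), 10L) # corresponding residues only
  expect_true(all(abs(contacts$from - (contacts$to - 10L)) == 0))
  comps <- find_components(g)
  expect_identical(length(comps), 1L)
  expect_identical(sort(unique(comps[[1]]$chain)), c("A", "B"))
  # beyond the cutoff: nothing
  expect_identical(nrow(build_contact_graph(two_parallel_chains(10, 7),
                                            6)$edges), 0L)
  # strict inequality at exactly the cutoff
  expect_identical(nrow(build_contact_graph(two_parallel_chains(10, 6),
                                            6)$edges), 0L)
})

test_that("adjacency augmentation is applied once around each contact", {
  # single contact between A5 and B5 of two 10-residue chains
  far <- two_parallel_chains(10, 30)
  a <- far$chains[[1]]$coords
  b <- far$chains[[2]]$coords
  b[5, ] <- a[5, ] + c(5, 0, 0)
  b[-5, 1] <- 30
  fr <- assembly_frame(list(chain_record("A", strrep("A", 10), a),
                            chain_record("B", strrep("A", 10), b)))
  g <- build_contact_graph(fr, 6)
  contacts <- g$edges[g$edges$provenance == "interchain_contact", ]
  expect_identical(nrow(contacts), 1L)
  adj <- g$edges[g$edges$provenance == "sequence_adjacency", ]
  pairs <- sort(paste(adj$from, adj$to))
  # A5 is gid 5, B5 is gid 15
  expect_setequal(pairs, c("4 5", "5 6", "14 15", "15 16"))
})

test_that("components equal the brute-force union-find oracle", {
  set.seed(101)
  for (rep in 1:25) {
    fr <- random_frame(n_chains = 4, n_res = 40, spread = 25)
    comps <- find_components(build_contact_graph(fr, 6))
    expect_identical(lapply(comps, function(cp) sort(cp$gid)),
                     unname(oracle_components(fr, 6)))
  }
})

test_that("labels partition residues and edges grow monotonically in cutoff", {
  set.seed(55)
  fr <- random_frame(n_chains = 4, n_res = 40, spread = 22)
  prev_edges <- -1L
  prev_comps <- NULL
  for (cutoff in c(4, 6, 8, 10)) {
    g <- build_contact_graph(fr, cutoff)
    n_inter <- sum(g$edges$provenance == "interchain_contact")
    expect_gte(n_inter, prev_edges)
    prev_edges <- n_inter
    comps <- find_components(g)
    if (!is.null(prev_comps)) {
      # refinement: every previous component is inside one current component
      for (cp in prev_comps) {
        hit <- vapply(comps, function(cc) all(cp$gid %in% cc$gid),
                      logical(1))
        expect_identical(sum(hit), 1L)
      }
    }
    prev_comps <- comps
    dec <- decompose_bundles(fr, cutoff)
    expect_identical(nrow(dec$labels),
                     sum(vapply(fr$chains, function(ch) nrow(ch$coords),
                                integer(1))))
    n_bundle <- sum(dec$labels$label != "crosslink")
    n_cross <- sum(dec$labels$label == "crosslink")
    expect_identical(n_bundle + n_cross, nrow(dec$labels))
  }
})

test_that("decomposition handles touch points and isolated chains", {
  # two chains touching at exactly one residue pair
  far <- two_parallel_chains(10, 30)
  a <- far$chains[[1]]$coords
  b <- far$chains[[2]]$coords
  b[5, ] <- a[5, ] + c(5, 0, 0)
  b[-5, 1] <- 30
  fr <- assembly_frame(list(chain_record("A", strrep("A", 10), a),
                            chain_record("B", strrep("A", 10), b)))
  dec <- decompose_bundles(fr, 6)
  expect_identical(nrow(dec$bundles), 1L)
  expect_identical(dec$bundles$thickness, 2L)
  lab <- dec$labels
  expect_identical(sort(lab$resno[lab$chain == "A" & lab$label == "B1"]),
                   4:6)
  expect_true(all(lab$label[lab$chain == "A" & !(lab$resno %in% 4:6)] ==
                    "crosslink"))
  # an isolated coiled chain is all cross-linking region, zero bundles
  set.seed(2)
  lone <- assembly_frame(list(grow_saw_chain(synthetic_fg_sequence(50),
                                             matrix(0, 1, 3))))
  dec2 <- decompose_bundles(lone, 6)
  expect_identical(nrow(dec2$bundles), 0L)
  expect_true(all(dec2$labels$label == "crosslink"))
})

test_that("thickness distribution averages per-frame histograms", {
  # static frame with two thickness-3 bundles
  b1 <- make_planted_bundle(3, 12, origin = c(0, 0, 0))$frame
  b2 <- make_planted_bundle(3, 12, origin = c(100, 0, 0))$frame
  both <- assembly_frame(c(b1$chains,
                           lapply(b2$chains, function(ch) {
                             ch$chain_id <- paste0("q", ch$chain_id); ch
                           })))
  h <- thickness_distribution(both)
  expect_identical(names(h), "3")
  expect_equal(unname(h), 1)
  # frames with thickness multisets {2,2} and {4}: average of normalized
  # per-frame histograms is {2: 0.5, 4: 0.5}
  f1 <- assembly_frame(c(
    make_planted_bundle(2, 12, origin = c(0, 0, 0))$frame$chains,
    lapply(make_planted_bundle(2, 12, origin = c(100, 0, 0))$frame$chains,
           function(ch) { ch$chain_id <- paste0("q", ch$chain_id); ch })))
  f2 <- make_planted_bundle(4, 12)$frame
  h2 <- thickness_distribution(list(f1, f2), window = 2)
  expect_equal(h2, c("2" = 0.5, "4" = 0.5))
  # pooled mode weights by raw counts: {2: 2/3, 4: 1/3}
  h3 <- thickness_distribution(list(f1, f2), window = 2,
                               average = "pooled")
  expect_equal(h3, c("2" = 2 / 3, "4" = 1 / 3))
  expect_error(thickness_distribution(list(f1), window = 2), "window")
})

test_that("amino-acid propensities split F/G by motif membership", {
  # chain FGAG: the single contact sits on F1, so the FG motif (1-2) is
  # bundled (G2 absorbed by adjacency) while A3 and G4 stay crosslink
  a <- chain_record("A", "FGAG",
                    matrix(c(0, 0, 0, 0, 0, 3.7, 0, 0, 30, 0, 0, 33.7),
                           4, 3, byrow = TRUE))
  b <- chain_record("B", "AA",
                    matrix(c(5, 0, 0, 5, 0, -3.7), 2, 3, byrow = TRUE))
  fr <- assembly_frame(list(a, b))
  dec <- decompose_bundles(fr, 6)
  lab <- dec$labels
  expect_identical(lab$label[lab$chain == "A"],
                   c("B1", "B1", "crosslink", "crosslink"))
  prop <- aa_bundle_propensity(dec, fr)
  get <- function(cat) prop$fraction[prop$category == cat]
  expect_equal(get("FG"), 1)
  expect_equal(get("G*"), 0)
  expect_equal(get("A"), 2 / 3) # A3 crosslink, B1 and B2 bundled
  expect_identical(prop$n_total[prop$category == "F*"], 0L)
  expect_true(is.na(get("F*")))
  # all bundled => every present category 1.0; no bundles => all 0
  allb <- make_planted_bundle(3, 12)$frame
  p1 <- aa_bundle_propensity(decompose_bundles(allb, 6), allb)
  expect_true(all(p1$fraction[p1$n_total > 0] == 1))
  none <- make_planted_bundle(3, 12, lateral_spacing = 7)$frame
  p0 <- aa_bundle_propensity(decompose_bundles(none, 6), none)
  expect_true(all(p0$fraction[p0$n_total > 0] == 0))
})
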