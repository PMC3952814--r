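# Synthetic assemblies with planted ground truth: parallel-chain bundles,
# cross-linked brushes, and channel phantoms of known bottleneck radius.
# Walls are built from beads so the pore analysis is exercised through the
# same code path as real frames.

#' @keywords internal
planted_truth <- function(labels, thicknesses = NULL, crosslink_events = NULL,
                          pore_radius = NULL) {
  if (is.null(crosslink_events))
    crosslink_events <- data.frame(chain = character(0), start = integer(0),
                                   end = integer(0),
                                   bundle_left = character(0),
                                   bundle_right = character(0),
                                   stringsAsFactors = FALSE)
  if (is.null(thicknesses)) {
    bl <- labels$label[labels$label != "crosslink"]
    thicknesses <- vapply(sort(unique(bl)), function(b)
      length(unique(labels$chain[labels$label == b])), integer(1))
  }
  structure(list(labels = labels, thicknesses = thicknesses,
                 crosslink_events = crosslink_events,
                 pore_radius = pore_radius),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth: %d bundle(s)%s%s>\n", length(x$thicknesses),
              if (nrow(x$crosslink_events))
                sprintf(", %d crosslink event(s)", nrow(x$crosslink_events))
              else "",
              if (!is.null(x$pore_radius))
                sprintf(", pore radius %g A", x$pore_radius) else ""))
  invisible(x)
}

# Hexagonal lattice sites of pitch `pitch`, sorted by distance from the
# centre then angle; every non-central site is adjacent (distance `pitch`)
# to an earlier site.
.hex_sites <- function(n, pitch) {
  rng <- -6:6
  g <- expand.grid(i = rng, j = rng)
  xy <- cbind(g$i * pitch + g$j * pitch / 2, g$j * pitch * sqrt(3) / 2)
  o <- order(round(sqrt(rowSums(xy^2)), 9), atan2(xy[, 2], xy[, 1]))
  xy[o, , drop = FALSE][seq_len(n), , drop = FALSE]
}

#' Planted parallel-chain bundle
#'
#' `k_chains` straight parallel chains on a close-packed (hexagonal)
#' lattice of pitch `lateral_spacing` around `axis`.  The recorded truth
#' labels every residue as one bundle of thickness `k_chains` when the
#' spacing is below the contact cutoff and at least two chains are present;
#' otherwise everything is a cross-linking region.
#'
#' @param k_chains number of chains.
#' @param n_residues residues per chain.
#' @param axis chain direction (unit vector; default z).
#' @param lateral_spacing lattice pitch, Angstrom.
#' @param origin position of the first residue of the central chain.
#' @param contact_cutoff cutoff the truth is planted for (default 6).
#' @param bond_length bead spacing along the chain, Angstrom.
#' @return `list(frame =, truth =)`.
#' @export
make_planted_bundle <- function(k_chains, n_residues, axis = c(0, 0, 1),
                                lateral_spacing = 5, origin = c(0, 0, 0),
                                contact_cutoff = 6, bond_length = 3.7) {
  stopifnot(k_chains >= 1, lateral_spacing > 0)
  axis <- axis / sqrt(sum(axis^2))
  basis <- .perp_basis(axis)
  sites <- .hex_sites(k_chains, lateral_spacing)
  sequence <- synthetic_fg_sequence(n_residues)
  chains <- lapply(seq_len(k_chains), function(k) {
    start <- origin + sites[k, 1] * basis$e1 + sites[k, 2] * basis$e2
    build_extended_chain(sequence, start, axis, bond_length,
                         chain_id = sprintf("p%02d", k))
  })
  frame <- assembly_frame(chains)
  bundled <- k_chains >= 2 && lateral_spacing < contact_cutoff
  labels <- do.call(rbind, lapply(chains, function(ch)
    data.frame(chain = ch$chain_id, resno = seq_len(n_residues),
               label = if (bundled) "B1" else "crosslink",
               stringsAsFactors = FALSE)))
  list(frame = frame, truth = planted_truth(labels))
}

#' Planted cross-linked brush
#'
#' Several parallel-chain bundles plus cross-link chains that run inside a
#' bundle, traverse free space well above all bundles, and descend into a
#' (possibly identical) bundle.  The recorded truth uses the package's
#' residue addressing and encodes the contact-graph region rule exactly:
#' the first and last traversal residues -- immediate sequence neighbours of
#' contact residues -- are bundle members; the remaining traversal residues
#' are the cross-linking region.
#'
#' @param bundle_specs list of `list(k_chains =, n_residues =, center =
#'   c(x, y))`; bundle centres must be far enough apart (pairwise distance
#'   greater than twice the bundle lateral extent plus cutoff plus margin).
#' @param crosslink_specs list of `list(from =, to =)` bundle indices (may
#'   be equal for a loop-back cross-link).
#' @param pitch lateral chain pitch inside bundles, Angstrom (must be below
#'   the cutoff).
#' @param contact_cutoff cutoff the truth is planted for.
#' @param margin clearance margin of traversal residues beyond the cutoff,
#'   Angstrom.
#' @param bond_length bead spacing, Angstrom.
#' @return `list(frame =, truth =)`.
#' @export
make_crosslinked_brush <- function(bundle_specs, crosslink_specs = list(),
                                   pitch = 5, contact_cutoff = 6, margin = 4,
                                   bond_length = 3.7) {
  nb <- length(bundle_specs)
  stopifnot(nb >= 1, pitch < contact_cutoff)
  centers <- lapply(bundle_specs, function(s) as.numeric(s$center))
  n_extra <- vapply(seq_len(nb), function(bi)
    sum(vapply(crosslink_specs, function(s) sum(c(s$from, s$to) == bi),
               numeric(1))), numeric(1))
  extent <- vapply(seq_len(nb), function(bi) {
    k <- bundle_specs[[bi]]$k_chains + n_extra[bi]
    max(sqrt(rowSums(.hex_sites(k, pitch)^2)))
  }, numeric(1))
  if (nb >= 2) {
    for (a in seq_len(nb - 1)) for (b in (a + 1):nb) {
      d <- sqrt(sum((centers[[a]] - centers[[b]])^2))
      need <- extent[a] + extent[b] + contact_cutoff + margin
      if (d <= need)
        stop(sprintf(
          "infeasible geometry: bundles %d and %d are %.1f A apart, need > %.1f A",
          a, b, d, need), call. = FALSE)
    }
  }
  chains <- list()
  labels <- NULL
  events <- NULL
  used_sites <- vector("list", nb) # per-bundle count of occupied hex sites
  heights <- numeric(nb)
  for (bi in seq_len(nb)) {
    sp <- bundle_specs[[bi]]
    sites <- .hex_sites(sp$k_chains + n_extra[bi], pitch)
    seqs <- synthetic_fg_sequence(sp$n_residues)
    heights[bi] <- (sp$n_residues - 1) * bond_length
    for (k in seq_len(sp$k_chains)) {
      id <- sprintf("b%dc%02d", bi, k)
      start <- c(centers[[bi]] + sites[k, ], 0)
      chains[[length(chains) + 1L]] <-
        build_extended_chain(seqs, start, c(0, 0, 1), bond_length, id)
      labels <- rbind(labels, data.frame(
        chain = id, resno = seq_len(sp$n_residues),
        label = sprintf("B%d", bi), stringsAsFactors = FALSE))
    }
    used_sites[[bi]] <- sp$k_chains
  }
  hmax <- max(heights)
  for (xi in seq_along(crosslink_specs)) {
    sp <- crosslink_specs[[xi]]
    a <- sp$from; b <- sp$to
    clr <- contact_cutoff + margin + 8 * (xi - 1)
    zarc <- hmax + clr
    sites_a <- .hex_sites(bundle_specs[[a]]$k_chains + n_extra[a], pitch)
    site_a <- sites_a[used_sites[[a]] + 1L, ]
    used_sites[[a]] <- used_sites[[a]] + 1L
    sites_b <- .hex_sites(bundle_specs[[b]]$k_chains + n_extra[b], pitch)
    site_b <- sites_b[used_sites[[b]] + 1L, ]
    used_sites[[b]] <- used_sites[[b]] + 1L
    pa <- centers[[a]] + site_a
    pb <- centers[[b]] + site_b
    na <- bundle_specs[[a]]$n_residues
    nbres <- bundle_specs[[b]]$n_residues
    up <- cbind(pa[1], pa[2], seq(0, (na - 1) * bond_length,
                                  by = bond_length))
    top_a <- c(pa, zarc)
    top_b <- c(pb, zarc)
    waypoints <- if (a == b || sqrt(sum((pa - pb)^2)) < 6 * bond_length) {
      out <- c(20, 0)
      rbind(top_a, c(pa + out, zarc), c(pb + out, zarc), top_b)
    } else rbind(top_a, top_b)
    arc <- NULL
    for (w in seq_len(nrow(waypoints) - 1)) {
      p0 <- waypoints[w, ]; p1 <- waypoints[w + 1, ]
      len <- sqrt(sum((p1 - p0)^2))
      nstep <- max(2L, ceiling(len / bond_length))
      tt <- seq(0, 1, length.out = nstep + 1L)
      seg <- outer(1 - tt, p0) + outer(tt, p1)
      arc <- rbind(arc, if (w == 1L) seg else seg[-1, , drop = FALSE])
    }
    nbres <- as.integer(nbres)
    down <- cbind(pb[1], pb[2], seq((nbres - 1) * bond_length, 0,
                                    by = -bond_length))
    coords <- rbind(up, arc, down)
    id <- sprintf("x%02d", xi)
    n_tot <- nrow(coords)
    seqs <- synthetic_fg_sequence(n_tot)
    chains[[length(chains) + 1L]] <- chain_record(id, seqs, coords)
    arc_idx <- as.integer(na) + seq_len(nrow(arc))
    lab <- rep("crosslink", n_tot)
    lab[seq_len(as.integer(na))] <- sprintf("B%d", a)
    lab[arc_idx[1]] <- sprintf("B%d", a)       # absorbed by adjacency rule
    lab[n_tot - nbres + seq_len(nbres)] <- sprintf("B%d", b)
    lab[arc_idx[length(arc_idx)]] <- sprintf("B%d", b)
    labels <- rbind(labels, data.frame(chain = id, resno = seq_len(n_tot),
                                       label = lab, stringsAsFactors = FALSE))
    events <- rbind(events, data.frame(
      chain = id, start = arc_idx[2], end = arc_idx[length(arc_idx) - 1L],
      bundle_left = sprintf("B%d", a), bundle_right = sprintf("B%d", b),
      stringsAsFactors = FALSE))
  }
  frame <- assembly_frame(chains)
  list(frame = frame, truth = planted_truth(labels, crosslink_events = events))
}

#' Channel phantom with known bottleneck radius
#'
#' Bead walls forming a channel whose narrowest cross-section has a known
#' clearance radius.  `slab` geometry: one (or, with `second_radius`, two
#' serial) plane wall(s) perpendicular to z spanning the whole box, each
#' with a circular hole; the smaller hole governs the recoverable pore
#' size.  `ring` geometry: a cylindrical shell around z with a circular
#' aperture, probed radially.  Walls are aligned with the default 2 A
#' lattice so the planted clearance at the hole centre is exact; a hole
#' radius of 0 is a solid wall.
#'
#' @param bottleneck_radius hole radius, Angstrom.
#' @param wall_bead_spacing bead pitch within walls, Angstrom (default 2).
#' @param geometry "slab" or "ring".
#' @param second_radius optional second slab hole radius (serial
#'   bottlenecks; ignored for rings).
#' @return `list(frame =, truth =)`, truth carrying `pore_radius`.
#' @export
make_channel_phantom <- function(bottleneck_radius, wall_bead_spacing = 2,
                                 geometry = c("slab", "ring"),
                                 second_radius = NULL) {
  geometry <- match.arg(geometry)
  R <- bottleneck_radius
  s <- wall_bead_spacing
  stopifnot(R >= 0, s > 0)
  rim_circle <- function(center, radius, n_min = 24L) {
    if (radius <= 0) return(NULL)
    n <- max(n_min, ceiling(2 * pi * radius / (s / 2)))
    ang <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
          center[3])
  }
  if (geometry == "slab") {
    half <- 2 * ceiling((R + 20) / 2)      # grid-aligned lateral half-width
    L <- 2 * half
    Lz <- 40
    slab <- function(zw, radius) {
      g <- as.matrix(expand.grid(x = seq(0, L, by = s),
                                 y = seq(0, L, by = s)))
      r <- sqrt((g[, 1] - half)^2 + (g[, 2] - half)^2)
      keep <- g[r >= radius, , drop = FALSE]
      rbind(cbind(keep, zw), rim_circle(c(half, half, zw), radius))
    }
    walls <- list(slab(20, R))
    radii <- R
    if (!is.null(second_radius)) {
      walls <- c(walls, list(slab(28, second_radius)))
      radii <- c(radii, second_radius)
    }
    chains <- lapply(seq_along(walls), function(k)
      chain_record(sprintf("w%d", k),
                   strrep("G", nrow(walls[[k]])), walls[[k]]))
    frame <- assembly_frame(chains, bath_geometry(c(L, L, Lz),
                                                  periodic = FALSE))
    truth <- planted_truth(
      labels = do.call(rbind, lapply(chains, function(ch)
        data.frame(chain = ch$chain_id, resno = seq_len(nrow(ch$coords)),
                   label = "crosslink", stringsAsFactors = FALSE))),
      thicknesses = integer(0), pore_radius = min(radii))
    return(list(frame = frame, truth = truth))
  }
  # ring: cylindrical shell of radius R_wall around z with an aperture of
  # radius R centred at (R_wall, 0, 0)
  R_wall <- max(40, 2 * ceiling(R))
  zh <- R + 20
  ang <- seq(0, 2 * pi, by = s / R_wall)
  ang <- ang[-length(ang)]
  zz <- seq(-zh, zh, by = s)
  g <- expand.grid(ang = ang, z = zz)
  pts <- cbind(R_wall * cos(g$ang), R_wall * sin(g$ang), g$z)
  C <- c(R_wall, 0, 0)
  d2C <- sqrt(rowSums((pts - matrix(C, nrow(pts), 3, byrow = TRUE))^2))
  pts <- pts[d2C >= R, , drop = FALSE]
  rim <- NULL
  if (R > 0) {
    th <- seq(-pi, pi, length.out = 720L)
    ok <- 2 * R_wall^2 * (1 - cos(th)) <= R^2
    th <- th[ok]
    zoff <- sqrt(pmax(0, R^2 - 2 * R_wall^2 * (1 - cos(th))))
    rim <- rbind(cbind(R_wall * cos(th), R_wall * sin(th), zoff),
                 cbind(R_wall * cos(th), R_wall * sin(th), -zoff))
  }
  wall <- rbind(pts, rim)
  ch <- chain_record("w1", strrep("G", nrow(wall)), wall)
  frame <- assembly_frame(list(ch),
                          ring_geometry(inner_radius = R_wall,
                                        row_spacing = 0, n_rows = 1,
                                        anchor_spacing = s))
  truth <- planted_truth(
    labels = data.frame(chain = "w1", resno = seq_len(nrow(wall)),
                        label = "crosslink", stringsAsFactors = FALSE),
    thicknesses = integer(0), pore_radius = R)
  list(frame = frame, truth = truth)
}

#' Gaussian coordinate jitter
#'
#' Displaces every bead (and tether anchor, so the tether invariant is
#' preserved) by i.i.d. Gaussian noise.  Constraints are NOT re-enforced;
#' planted truth labels carry over unchanged.
#'
#' @param frame an [assembly_frame()].
#' @param sigma displacement standard deviation per coordinate, Angstrom.
#' @param seed optional RNG seed.
#' @return a jittered [assembly_frame()].
#' @export
jitter_frame <- function(frame, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(frame)
  chains <- lapply(frame$chains, function(ch) {
    coords <- ch$coords + matrix(rnorm(length(ch$coords), 0, sigma),
                                 nrow(ch$coords), 3)
    teth <- ch$tether
    if (!is.null(teth)) teth$anchor <- coords[teth$residue, ]
    extra <- ch$extra_beads
    if (!is.null(extra))
      extra <- lapply(extra, function(eb) {
        if (is.null(eb)) NULL
        else eb + matrix(rnorm(length(eb), 0, sigma), nrow(eb), 3)
      })
    chain_record(ch$chain_id, ch$sequence, coords, tether = teth,
                 motifs = ch$motifs, extra_beads = extra)
  })
  out <- assembly_frame(chains, frame$geometry, frame$time_label)
  attr(out, "anchors") <- attr(frame, "anchors")
  out
}
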