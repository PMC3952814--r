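# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive implementations kept apart from the package code.

# All-pairs inter-chain contact pairs (strict cutoff), optionally periodic.
oracle_contact_pairs <- function(frame, cutoff) {
  ids <- vapply(frame$chains, function(ch) ch$chain_id, character(1))
  tab <- do.call(rbind, lapply(seq_along(frame$chains), function(k) {
    ch <- frame$chains[[k]]
    data.frame(chain = k, resno = seq_len(nrow(ch$coords)))
  }))
  tab$gid <- seq_len(nrow(tab))
  box <- if (!is.null(frame$geometry) && frame$geometry$type == "bath" &&
             frame$geometry$periodic) frame$geometry$box
  out <- NULL
  for (a in seq_len(nrow(tab) - 1)) for (b in (a + 1):nrow(tab)) {
    if (tab$chain[a] == tab$chain[b]) next
    d <- residue_distance(frame, ids[tab$chain[a]], tab$resno[a],
                          ids[tab$chain[b]], tab$resno[b])
    if (d < cutoff) out <- rbind(out, c(tab$gid[a], tab$gid[b]))
  }
  out
}

# Union-find connected components over contact pairs plus one round of
# sequence-adjacency augmentation; returns a list of sorted gid vectors.
oracle_components <- function(frame, cutoff) {
  nres <- vapply(frame$chains, function(ch) nrow(ch$coords), integer(1))
  ntot <- sum(nres)
  chain_of <- rep(seq_along(nres), nres)
  res_of <- unlist(lapply(nres, seq_len))
  pairs <- oracle_contact_pairs(frame, cutoff)
  if (is.null(pairs)) return(list())
  edges <- pairs
  for (g in unique(c(pairs))) {
    if (res_of[g] > 1L) edges <- rbind(edges, c(g - 1L, g))
    if (res_of[g] < nres[chain_of[g]]) edges <- rbind(edges, c(g, g + 1L))
  }
  parent <- seq_len(ntot)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (q in seq_len(nrow(edges))) {
    ra <- find(edges[q, 1]); rb <- find(edges[q, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(ntot), find, integer(1))
  used <- sort(unique(c(edges)))
  comps <- split(used, roots[used])
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  lapply(comps, sort)
}

# Threshold-percolation widest-path oracle: the bottleneck is the largest
# threshold t such that source connects to sink through nodes with
# clearance >= t (plain queue BFS at each candidate threshold).
oracle_widest_bottleneck <- function(clear, dims, sources, sinks,
                                     connectivity = 6) {
  n <- prod(dims)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  is_sink <- logical(n); is_sink[sinks] <- TRUE
  connects <- function(t) {
    ok <- clear >= t
    if (!any(ok[sources])) return(FALSE)
    seen <- logical(n)
    queue <- sources[ok[sources]]
    seen[queue] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      if (is_sink[u]) return(TRUE)
      u0 <- u - 1L
      ux <- u0 %% dims[1]; uy <- (u0 %/% dims[1]) %% dims[2]
      uz <- u0 %/% (dims[1] * dims[2])
      for (q in seq_len(nrow(offs))) {
        vx <- ux + offs$dx[q]; vy <- uy + offs$dy[q]; vz <- uz + offs$dz[q]
        if (vx < 0 || vx >= dims[1] || vy < 0 || vy >= dims[2] ||
            vz < 0 || vz >= dims[3]) next
        v <- vx + dims[1] * (vy + dims[2] * vz) + 1L
        if (!seen[v] && ok[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
      }
    }
    FALSE
  }
  if (!connects(-Inf)) return(0)
  cand <- sort(unique(clear))
  lo <- 1L; hi <- length(cand) # invariant: connects at cand[lo]
  if (!connects(cand[1])) return(0)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (connects(cand[mid])) lo <- mid else hi <- mid - 1L
  }
  cand[lo]
}

# Brute-force clearance field: min distance from every node to every bead.
oracle_clearance <- function(beads, origin, spacing, dims, cap) {
  out <- array(cap, dim = dims)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (iz in seq_len(dims[3])) {
      p <- origin + (c(ix, iy, iz) - 1) * spacing
      if (nrow(beads))
        out[ix, iy, iz] <- min(cap, sqrt(min(colSums((t(beads) - p)^2))))
    }
  out
}

# Two parallel straight chains along z, `sep` apart in x.
two_parallel_chains <- function(n = 10, sep = 5, bond = 3.7) {
  seqs <- strrep("A", n)
  a <- build_extended_chain(seqs, c(0, 0, 0), c(0, 0, 1), bond, "A")
  b <- build_extended_chain(seqs, c(sep, 0, 0), c(0, 0, 1), bond, "B")
  assembly_frame(list(a, b))
}

# Random compact multi-chain frame (random-walk chains, for oracle tests).
random_frame <- function(n_chains = 4, n_res = 40, step = 3.7,
                         spread = 12) {
  chains <- lapply(seq_len(n_chains), function(k) {
    start <- runif(3, 0, spread)
    steps <- matrix(rnorm(3 * (n_res - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * step
    coords <- rbind(start, start + apply(steps, 2, cumsum))
    chain_record(sprintf("r%02d", k), strrep("A", n_res), coords)
  })
  assembly_frame(chains)
}

expect_same_labels <- function(dec, truth) {
  m <- merge(dec$labels, truth$labels, by = c("chain", "resno"),
             suffixes = c("_found", "_true"))
  expect_equal(nrow(m), nrow(truth$labels))
  expect_identical(sum(m$label_found != m$label_true), 0L)
}
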