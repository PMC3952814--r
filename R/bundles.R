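# Contact-graph bundle analysis: residue contact graph (inter-chain
# distance < 6 A, strict, plus one round of sequence-adjacency
# augmentation), connected components, bundle/cross-link labelling,
# thickness distributions and amino-acid bundle propensities.

#' Minimum distance between two residues
#'
#' The residue-residue distance is the minimum Euclidean distance over all
#' bead pairs of the two residues (reducing to the backbone bead distance
#' in the single-bead model), minimum-image if the frame is periodic.
#'
#' @param frame an [assembly_frame()].
#' @param chain_a,res_a,chain_b,res_b residue addresses (chain id, 1-based
#'   residue index).
#' @return distance in Angstrom.
#' @export
residue_distance <- function(frame, chain_a, res_a, chain_b, res_b) {
  box <- .frame_box(frame)
  pick <- function(chain_id, res) {
    ids <- vapply(frame$chains, function(ch) ch$chain_id, character(1))
    k <- match(chain_id, ids)
    if (is.na(k)) stop("unknown chain id: ", chain_id, call. = FALSE)
    ch <- frame$chains[[k]]
    if (res < 1L || res > nrow(ch$coords))
      stop("residue ", res, " out of range for chain ", chain_id,
           call. = FALSE)
    beads <- ch$coords[res, , drop = FALSE]
    if (!is.null(ch$extra_beads) && !is.null(ch$extra_beads[[res]]))
      beads <- rbind(beads, ch$extra_beads[[res]])
    beads
  }
  a <- pick(chain_a, res_a)
  b <- pick(chain_b, res_b)
  dmin <- Inf
  for (i in seq_len(nrow(a))) {
    d <- .mi(b - matrix(a[i, ], nrow(b), 3, byrow = TRUE), box)
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  dmin
}

#' Residue contact graph of a frame
#'
#' Every inter-chain residue pair whose minimum bead-bead distance is
#' strictly below `cutoff` becomes an `interchain_contact` edge; in
#' addition, the immediate sequence neighbours (residue index +-1) of each
#' contact endpoint are joined to that endpoint by `sequence_adjacency`
#' edges.  The augmentation is applied once, not transitively.  Neighbour
#' search uses a cell list; the result equals the all-pairs definition.
#'
#' @param frame an [assembly_frame()].
#' @param cutoff contact distance, Angstrom (default 6; strict inequality,
#'   ties at exactly `cutoff` are non-contacts).
#' @return object of class `contact_graph`: list with `nodes` (residue
#'   address table), `edges` (columns `from`, `to` as global residue ids,
#'   `provenance`), and the cutoff.
#' @export
build_contact_graph <- function(frame, cutoff = 6.0) {
  stopifnot(inherits(frame, "assembly_frame"), cutoff > 0)
  nodes <- .residue_table(frame)
  beads <- .frame_beads(frame)
  box <- .frame_box(frame)
  pairs <- cpp_contact_pairs(beads$xyz, beads$gid, beads$chain_idx, cutoff,
                             if (is.null(box)) numeric(0) else box)
  edges <- data.frame(from = integer(0), to = integer(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                        provenance = "interchain_contact",
                        stringsAsFactors = FALSE)
    endpoints <- unique(c(pairs[, 1], pairs[, 2]))
    adj_from <- integer(0); adj_to <- integer(0)
    for (g in endpoints) {
      ch <- nodes$chain_idx[g]
      res <- nodes$resno[g]
      nres <- sum(nodes$chain_idx == ch)
      if (res > 1L) { adj_from <- c(adj_from, g - 1L); adj_to <- c(adj_to, g) }
      if (res < nres) { adj_from <- c(adj_from, g); adj_to <- c(adj_to, g + 1L) }
    }
    if (length(adj_from)) {
      adj <- unique(data.frame(from = adj_from, to = adj_to,
                               provenance = "sequence_adjacency",
                               stringsAsFactors = FALSE))
      edges <- rbind(edges, adj)
    }
  }
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf(
    "<contact_graph: %d residues, %d contact + %d adjacency edges (cutoff %g A)>\n",
    nrow(x$nodes), sum(x$edges$provenance == "interchain_contact"),
    sum(x$edges$provenance == "sequence_adjacency"), x$cutoff))
  invisible(x)
}

#' Connected components of a contact graph
#'
#' Maximal connected sets of the nodes incident to at least one edge
#' (isolated residues are excluded: by the region rule they belong to the
#' cross-linking region).  Components are ordered by their smallest global
#' residue id.
#'
#' @param graph a [build_contact_graph()] result.
#' @return list of data.frames with columns `chain`, `resno`, `gid`.
#' @export
find_components <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  if (!nrow(graph$edges)) return(list())
  used <- sort(unique(c(graph$edges$from, graph$edges$to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$from),
               to = as.character(graph$edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(used)))
  comp <- igraph::components(g)
  members <- split(used, comp$membership[as.character(used)])
  members <- unname(members[order(vapply(members, min, numeric(1)))])
  lapply(members, function(gids)
    graph$nodes[graph$nodes$gid %in% gids,
                c("chain", "resno", "gid"), drop = FALSE])
}

#' Bundle decomposition of a frame
#'
#' Components of the contact graph spanning at least `min_chains` distinct
#' chains are bundles (a bundle is a cluster of multiple chains; its
#' thickness is the number of distinct chains involved).  All remaining
#' residues -- isolated ones and single-chain components -- are labelled
#' `crosslink`.  Cross-link events are maximal crosslink-labelled runs of
#' one chain whose two flanking sequence neighbours both belong to bundles
#' (possibly the same bundle).
#'
#' @param frame an [assembly_frame()].
#' @param cutoff contact cutoff, Angstrom.
#' @param min_chains minimum distinct chains for bundlehood (default 2).
#' @return object of class `bundle_decomposition`: list with `components`,
#'   `bundles` (data.frame `bundle_id`, `thickness`, `n_residues`,
#'   `anisotropy`), `labels` (data.frame `chain`, `resno`, `label`),
#'   `crosslink_events` (data.frame `chain`, `start`, `end`,
#'   `bundle_left`, `bundle_right`).
#' @export
decompose_bundles <- function(frame, cutoff = 6.0, min_chains = 2L) {
  graph <- build_contact_graph(frame, cutoff)
  comps <- find_components(graph)
  nodes <- graph$nodes
  labels <- rep("crosslink", nrow(nodes))
  is_bundle <- vapply(comps, function(cp)
    length(unique(cp$chain)) >= min_chains, logical(1))
  bundles <- comps[is_bundle]
  bundle_ids <- if (length(bundles)) sprintf("B%d", seq_along(bundles))
                else character(0)
  for (k in seq_along(bundles)) labels[bundles[[k]]$gid] <- bundle_ids[k]
  anis <- vapply(seq_along(bundles), function(k) {
    xyz <- do.call(rbind, lapply(seq_len(nrow(bundles[[k]])), function(q) {
      i <- bundles[[k]]$gid[q]
      frame$chains[[nodes$chain_idx[i]]]$coords[nodes$resno[i], , drop = FALSE]
    }))
    if (nrow(xyz) < 2L) return(1)
    ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
    ev[1] / max(sum(ev), .Machine$double.eps)
  }, numeric(1))
  bundle_df <- data.frame(
    bundle_id = bundle_ids,
    thickness = vapply(bundles, function(cp) length(unique(cp$chain)),
                       integer(1)),
    n_residues = vapply(bundles, nrow, integer(1)),
    anisotropy = anis, stringsAsFactors = FALSE)
  # cross-link events
  ev <- data.frame(chain = character(0), start = integer(0), end = integer(0),
                   bundle_left = character(0), bundle_right = character(0),
                   stringsAsFactors = FALSE)
  for (k in seq_along(frame$chains)) {
    sel <- which(nodes$chain_idx == k)
    lab <- labels[sel]
    n <- length(lab)
    r <- rle(lab == "crosslink")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in seq_along(r$values)) {
      if (!r$values[q]) next
      s <- starts[q]; e <- ends[q]
      if (s == 1L || e == n) next
      left <- lab[s - 1L]; right <- lab[e + 1L]
      if (left == "crosslink" || right == "crosslink") next
      ev <- rbind(ev, data.frame(chain = frame$chains[[k]]$chain_id,
                                 start = s, end = e, bundle_left = left,
                                 bundle_right = right,
                                 stringsAsFactors = FALSE))
    }
  }
  structure(list(components = comps, bundles = bundle_df,
                 labels = data.frame(chain = nodes$chain, resno = nodes$resno,
                                     label = labels,
                                     stringsAsFactors = FALSE),
                 crosslink_events = ev, cutoff = cutoff,
                 min_chains = as.integer(min_chains)),
            class = "bundle_decomposition")
}

#' @export
print.bundle_decomposition <- function(x, ...) {
  cat(sprintf(
    "<bundle_decomposition: %d bundle(s), thickness %s; %d cross-link event(s)>\n",
    nrow(x$bundles),
    if (nrow(x$bundles)) paste(x$bundles$thickness, collapse = ",") else "-",
    nrow(x$crosslink_events)))
  invisible(x)
}

#' Bundle thickness distribution over a trajectory window
#'
#' Per-frame thickness histograms over the trailing `window` frames,
#' normalized to sum 1 per frame and averaged so that every frame carries
#' equal weight (`average = "frame"`); `average = "pooled"` instead pools
#' raw bundle counts over the window before normalizing.
#'
#' @param x an [fg_trajectory()], a list of frames, or a single frame.
#' @param window number of trailing frames (default: the trajectory's
#'   analysis window).
#' @param cutoff,min_chains passed to [decompose_bundles()].
#' @param average "frame" or "pooled".
#' @return named numeric vector: names are thicknesses, values frequencies
#'   summing to 1 (empty if no bundles anywhere in the window).
#' @export
thickness_distribution <- function(x, window = NULL, cutoff = 6.0,
                                   min_chains = 2L,
                                   average = c("frame", "pooled")) {
  average <- match.arg(average)
  frames <- .as_frame_list(x)
  if (is.null(window))
    window <- if (inherits(x, "fg_trajectory")) x$analysis_window
              else length(frames)
  window <- as.integer(window)
  if (window < 1L || window > length(frames))
    stop("window must be in [1, n_frames]", call. = FALSE)
  frames <- tail(frames, window)
  counts <- lapply(frames, function(fr) {
    th <- decompose_bundles(fr, cutoff, min_chains)$bundles$thickness
    if (!length(th)) return(numeric(0))
    tab <- table(th)
    setNames(as.numeric(tab), names(tab))
  })
  bins <- sort(unique(as.integer(unlist(lapply(counts, names)))))
  if (!length(bins)) return(setNames(numeric(0), character(0)))
  mat <- sapply(counts, function(ct) {
    v <- setNames(numeric(length(bins)), as.character(bins))
    v[names(ct)] <- ct
    v
  })
  mat <- matrix(mat, nrow = length(bins))
  if (average == "frame") {
    sums <- colSums(mat)
    norm <- sweep(mat, 2, pmax(sums, 1), "/")
    keep <- sums > 0
    out <- if (any(keep)) rowMeans(norm[, keep, drop = FALSE])
           else rep(0, length(bins))
    out <- out / sum(out)
  } else {
    tot <- rowSums(mat)
    out <- tot / sum(tot)
  }
  setNames(out, as.character(bins))
}

.as_frame_list <- function(x) {
  if (inherits(x, "fg_trajectory")) x$frames
  else if (inherits(x, "assembly_frame")) list(x)
  else if (is.list(x)) x
  else stop("expected a trajectory, frame list, or frame", call. = FALSE)
}

#' Amino-acid bundle propensity
#'
#' For each residue category, the fraction of that category's residues that
#' are bundle-labelled.  Phenylalanine and glycine are split by motif
#' membership: `F*`/`G*` are the F/G not part of any FG or FxFG motif,
#' while the `FG` and `FxFG` categories collect the F and G residues of the
#' respective motifs (the `x` of FxFG is counted in its own amino-acid
#' category).
#'
#' @param decomposition a [decompose_bundles()] result.
#' @param frame the frame it was computed from.
#' @return data.frame with columns `category`, `n_total`, `n_bundle`,
#'   `fraction` (NA fraction for absent categories).
#' @export
aa_bundle_propensity <- function(decomposition, frame) {
  stopifnot(inherits(decomposition, "bundle_decomposition"))
  labs <- decomposition$labels
  cat_of <- character(nrow(labs))
  for (k in seq_along(frame$chains)) {
    ch <- frame$chains[[k]]
    letters <- strsplit(ch$sequence, "")[[1]]
    res_cat <- letters
    if (nrow(ch$motifs)) {
      for (q in seq_len(nrow(ch$motifs))) {
        span <- ch$motifs$start[q]:ch$motifs$end[q]
        fg <- span[letters[span] %in% c("F", "G")]
        res_cat[fg] <- ch$motifs$kind[q]
      }
    }
    res_cat[res_cat == "F"] <- "F*"
    res_cat[res_cat == "G"] <- "G*"
    cat_of[labs$chain == ch$chain_id] <-
      res_cat[labs$resno[labs$chain == ch$chain_id]]
  }
  cats <- c(setdiff(AA_LETTERS, c("F", "G")), "F*", "G*", "FG", "FxFG")
  in_bundle <- labs$label != "crosslink"
  out <- data.frame(category = cats,
                    n_total = vapply(cats, function(cc) sum(cat_of == cc),
                                     integer(1)),
                    stringsAsFactors = FALSE)
  out$n_bundle <- vapply(cats, function(cc) sum(cat_of == cc & in_bundle),
                         integer(1))
  out$fraction <- ifelse(out$n_total > 0, out$n_bundle / out$n_total, NA_real_)
  rownames(out) <- NULL
  out
}
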