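# Tethered-ring, tethered-array and free-bath assembly builders.  In all
# tethered geometries the C-terminal residue of each chain is fixed at its
# anchor point (the geometric abstraction of the cysteine-gold linkage) and
# chains extend into the +z half-space.

.chain_ids <- function(n) {
  if (n <= length(PDB_CHAIN_ALPHABET)) PDB_CHAIN_ALPHABET[seq_len(n)]
  else sprintf("c%03d", seq_len(n))
}

# Build one tethered chain whose C-terminal residue sits at `anchor`.
# extended: straight along +z.  saw: grown from the anchor with z >= zmin.
.tethered_chain <- function(sequence, anchor, mode, params, obstacles,
                            chain_id, zmin = 0) {
  n <- nchar(sequence)
  if (mode == "extended") {
    coords <- build_extended_chain(sequence, anchor, c(0, 0, 1),
                                   params$bond_length)$coords
  } else {
    coords <- grow_saw_chain(sequence, matrix(anchor, 1, 3), params,
                             obstacles = obstacles, zmin = zmin,
                             chain_id = chain_id)$coords
  }
  coords <- coords[n:1, , drop = FALSE] # C-terminus (residue n) at anchor
  chain_record(chain_id, sequence, coords,
               tether = list(anchor = coords[n, ], residue = n))
}

#' Tethered ring assembly
#'
#' Chains are grafted on concentric rings (ring axis z, tether plane z = 0),
#' `n_chains / n_rows` anchors per row.  By default the inner radius is
#' computed from the requested anchor spacing (`r = n_per_row *
#' anchor_spacing / (2*pi)`), so adjacent anchors on the inner row are one
#' `anchor_spacing` apart and the minimum anchor-anchor distance equals the
#' requested spacing; outer rows sit `row_spacing` further out.  In
#' `extended` mode chains grow straight along +z; in `saw` mode chains are
#' grown sequentially in randomized order, each seeing all previously grown
#' chains as obstacles.
#'
#' @param n_chains number of chains (divisible by `n_rows`).
#' @param n_rows number of concentric anchor rows.
#' @param anchor_spacing target spacing of adjacent same-row anchors, Angstrom.
#' @param inner_radius radius of the innermost row; `NULL` (default)
#'   computes it from `anchor_spacing`.
#' @param row_spacing radial gap between rows, Angstrom.
#' @param mode "extended" or "saw".
#' @param sequence chain sequence (default: bundled synthetic FG-rich 609-mer).
#' @param params a [saw_params()].
#' @param append_cys number of cysteines appended at the C-terminus to
#'   represent the gold-binding linker (5 reproduces the 614-residue
#'   construct).
#' @param seed optional RNG seed.
#' @return an [assembly_frame()] with ring geometry.
#' @export
place_ring_assembly <- function(n_chains = 120L, n_rows = 3L,
                                anchor_spacing = 60, inner_radius = NULL,
                                row_spacing = 60, mode = c("extended", "saw"),
                                sequence = synthetic_fg_sequence(609L),
                                params = saw_params(), append_cys = 0L,
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n_chains <- as.integer(n_chains); n_rows <- as.integer(n_rows)
  if (n_chains %% n_rows != 0L)
    stop("n_chains must be divisible by n_rows", call. = FALSE)
  n_per <- n_chains %/% n_rows
  if (is.null(inner_radius))
    inner_radius <- n_per * anchor_spacing / (2 * pi)
  if (2 * pi * inner_radius < n_per * anchor_spacing * 0.999)
    stop(sprintf(
      "ring too small: inner radius %.1f A fits only %.1f anchors at %.1f A spacing",
      inner_radius, 2 * pi * inner_radius / anchor_spacing, anchor_spacing),
      call. = FALSE)
  if (append_cys > 0L)
    sequence <- paste0(sequence, strrep("C", append_cys))
  anchors <- do.call(rbind, lapply(seq_len(n_rows), function(row) {
    r <- inner_radius + (row - 1L) * row_spacing
    ang <- 2 * pi * (seq_len(n_per) - 1L) / n_per
    cbind(r * cos(ang), r * sin(ang), 0)
  }))
  ids <- .chain_ids(n_chains)
  chains <- vector("list", n_chains)
  order_idx <- if (mode == "saw") sample.int(n_chains) else seq_len(n_chains)
  grown <- NULL
  for (i in order_idx) {
    ch <- .tethered_chain(sequence, anchors[i, ], mode, params, grown, ids[i])
    chains[[i]] <- ch
    if (mode == "saw") grown <- rbind(grown, ch$coords)
  }
  frame <- assembly_frame(chains,
                          ring_geometry(inner_radius, row_spacing, n_rows,
                                        anchor_spacing))
  attr(frame, "anchors") <- anchors
  frame
}

#' Tethered 2D array assembly
#'
#' `nx * ny` chains end-tethered on a square grid in the z = 0 plane at
#' exact grid nodes; remaining residues lie in the +z half-space at
#' generation time.  SAW chains are grown sequentially in randomized order
#' with all previously grown chains as obstacles.
#'
#' @inheritParams place_ring_assembly
#' @param nx,ny grid dimensions.
#' @param grid_spacing grid pitch, Angstrom.
#' @return an [assembly_frame()] with array geometry.
#' @export
place_array_assembly <- function(nx = 5L, ny = 5L, grid_spacing = 60,
                                 mode = c("saw", "extended"),
                                 sequence = synthetic_fg_sequence(609L),
                                 params = saw_params(), append_cys = 0L,
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L)
  if (append_cys > 0L)
    sequence <- paste0(sequence, strrep("C", append_cys))
  anchors <- as.matrix(expand.grid(x = (seq_len(nx) - 1L) * grid_spacing,
                                   y = (seq_len(ny) - 1L) * grid_spacing))
  anchors <- cbind(anchors, z = 0)
  n_chains <- nx * ny
  ids <- .chain_ids(n_chains)
  chains <- vector("list", n_chains)
  order_idx <- if (mode == "saw") sample.int(n_chains) else seq_len(n_chains)
  grown <- NULL
  for (i in order_idx) {
    ch <- .tethered_chain(sequence, anchors[i, ], mode, params, grown, ids[i])
    chains[[i]] <- ch
    if (mode == "saw") grown <- rbind(grown, ch$coords)
  }
  frame <- assembly_frame(chains, array_geometry(nx, ny, grid_spacing))
  attr(frame, "anchors") <- anchors
  frame
}

#' Free-floating chains in a periodic bath
#'
#' Chain seeds are placed uniformly at random in the box with random
#' orientations and grown as self-avoiding worm-like chains; all
#' inter-chain distances respect the clash cutoff under the minimum-image
#' convention.
#'
#' @inheritParams place_ring_assembly
#' @param n_chains number of chains.
#' @param box_edge box edge length(s), Angstrom (default 725).
#' @param max_packing refuse to attempt generation when the excluded-volume
#'   packing fraction (beads times a clash-radius sphere over the box
#'   volume) exceeds this threshold.
#' @return an [assembly_frame()] with periodic bath geometry.
#' @export
place_bath_assembly <- function(n_chains = 120L, box_edge = 725,
                                sequence = synthetic_fg_sequence(609L),
                                params = saw_params(), seed = NULL,
                                max_packing = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  n_chains <- as.integer(n_chains)
  box <- as.numeric(box_edge)
  if (length(box) == 1L) box <- rep(box, 3L)
  n_res <- nchar(sequence)
  packing <- n_chains * n_res * (4 / 3) * pi * (params$clash_cutoff / 2)^3 /
    prod(box)
  if (packing > max_packing)
    stop(sprintf(
      "infeasible density: excluded-volume packing fraction %.3f exceeds %.2f",
      packing, max_packing), call. = FALSE)
  ids <- .chain_ids(n_chains)
  chains <- vector("list", n_chains)
  grown <- NULL
  for (i in seq_len(n_chains)) {
    seedpos <- runif(3) * box
    ch <- grow_saw_chain(sequence, matrix(seedpos, 1, 3), params,
                         obstacles = grown, box = box, chain_id = ids[i])
    chains[[i]] <- ch
    grown <- rbind(grown, ch$coords)
  }
  assembly_frame(chains, bath_geometry(box, periodic = TRUE))
}

#' Anchor positions of a tethered assembly
#'
#' @param frame a frame built by [place_ring_assembly()] or
#'   [place_array_assembly()] (or any frame with tethered chains).
#' @return matrix of anchor positions, one row per tethered chain.
#' @export
assembly_anchors <- function(frame) {
  a <- attr(frame, "anchors")
  if (!is.null(a)) return(a)
  do.call(rbind, lapply(frame$chains, function(ch)
    if (!is.null(ch$tether)) matrix(ch$tether$anchor, 1, 3)))
}
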