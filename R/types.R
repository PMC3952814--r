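#' One polymer chain in single-bead-per-residue representation
#'
#' @param chain_id short identifier, unique within a frame.
#' @param sequence one-letter amino-acid string.
#' @param coords numeric matrix, one row per residue, columns x,y,z in
#'   Angstrom (the backbone bead).
#' @param tether optional `list(anchor = c(x, y, z), residue = i)`; the
#'   anchored residue's coordinate must equal the anchor exactly.
#' @param motifs optional motif table as returned by [annotate_motifs()];
#'   computed from `sequence` when `NULL`.
#' @param extra_beads optional list, one element per residue, each a matrix
#'   of additional bead coordinates (e.g. side-chain beads) or `NULL`.
#' @return object of class `chain_record`.
#' @export
chain_record <- function(chain_id, sequence, coords, tether = NULL,
                         motifs = NULL, extra_beads = NULL) {
  letters <- .check_sequence(sequence)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("`coords` must have 3 columns", call. = FALSE)
  if (nrow(coords) != length(letters))
    stop("length(coords) must equal length(sequence): ", nrow(coords),
         " vs ", length(letters), call. = FALSE)
  if (any(!is.finite(coords)))
    stop("non-finite coordinates", call. = FALSE)
  dimnames(coords) <- NULL
  if (is.null(motifs)) motifs <- annotate_motifs(sequence)
  if (nrow(motifs)) {
    if (any(motifs$start < 1L) || any(motifs$end > length(letters)))
      stop("motif indices outside [1, length(sequence)]", call. = FALSE)
    o <- order(motifs$start)
    if (any(motifs$start[o][-1] <= motifs$end[o][-nrow(motifs)]))
      stop("motif spans overlap", call. = FALSE)
  }
  if (!is.null(tether)) {
    stopifnot(is.list(tether), length(tether$anchor) == 3L,
              length(tether$residue) == 1L)
    tether$residue <- as.integer(tether$residue)
    if (tether$residue < 1L || tether$residue > nrow(coords))
      stop("tether residue index out of range", call. = FALSE)
    if (!identical(unname(as.numeric(tether$anchor)),
                   unname(coords[tether$residue, ])))
      stop("anchored residue coordinate must equal the anchor exactly",
           call. = FALSE)
  }
  if (!is.null(extra_beads) && length(extra_beads) != nrow(coords))
    stop("`extra_beads` must have one element per residue", call. = FALSE)
  structure(list(chain_id = as.character(chain_id), sequence = sequence,
                 coords = coords, tether = tether, motifs = motifs,
                 extra_beads = extra_beads),
            class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record %s: %d residues%s, %d motif(s)>\n", x$chain_id,
              nrow(x$coords), if (is.null(x$tether)) "" else
                sprintf(", tethered at residue %d", x$tether$residue),
              nrow(x$motifs)))
  invisible(x)
}

#' Assembly geometry descriptors
#'
#' `ring_geometry()`, `array_geometry()` and `bath_geometry()` describe the
#' arrangement an [assembly_frame()] was built in.  The ring axis is z; the
#' brush axis for arrays and baths is z.  Only bath geometries can be
#' periodic (minimum-image convention for all inter-residue distances).
#'
#' @param inner_radius,row_spacing,n_rows,anchor_spacing ring parameters, Angstrom.
#' @param nx,ny,grid_spacing array parameters; spacing in Angstrom.
#' @param box edge lengths in Angstrom (scalar or length 3).
#' @param periodic logical periodic flag for bath boxes.
#' @return list with class `fg_geometry`.
#' @export
ring_geometry <- function(inner_radius, row_spacing = 60, n_rows = 3,
                          anchor_spacing = 60) {
  stopifnot(inner_radius > 0, row_spacing >= 0, n_rows >= 1,
            anchor_spacing > 0)
  structure(list(type = "ring", inner_radius = inner_radius,
                 row_spacing = row_spacing, n_rows = as.integer(n_rows),
                 anchor_spacing = anchor_spacing), class = "fg_geometry")
}

#' @rdname ring_geometry
#' @export
array_geometry <- function(nx, ny, grid_spacing = 60) {
  stopifnot(nx >= 1, ny >= 1, grid_spacing > 0)
  structure(list(type = "array", nx = as.integer(nx), ny = as.integer(ny),
                 grid_spacing = grid_spacing), class = "fg_geometry")
}

#' @rdname ring_geometry
#' @export
bath_geometry <- function(box, periodic = TRUE) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(box) == 3L, all(box > 0))
  structure(list(type = "bath", box = box, periodic = isTRUE(periodic)),
            class = "fg_geometry")
}

#' One time point of a multi-chain assembly
#'
#' @param chains list of [chain_record()] objects with unique chain ids.
#' @param geometry a geometry descriptor ([ring_geometry()],
#'   [array_geometry()], [bath_geometry()]) or `NULL` for an open,
#'   non-periodic frame.
#' @param time_label scalar frame label (frame index or time in ns).
#' @return object of class `assembly_frame`.
#' @export
assembly_frame <- function(chains = list(), geometry = NULL, time_label = 0) {
  stopifnot(is.list(chains))
  for (ch in chains)
    if (!inherits(ch, "chain_record"))
      stop("all elements of `chains` must be chain_record objects",
           call. = FALSE)
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids))
    stop("chain ids must be unique within a frame", call. = FALSE)
  if (!is.null(geometry) && !inherits(geometry, "fg_geometry"))
    stop("`geometry` must be an fg_geometry or NULL", call. = FALSE)
  structure(list(chains = chains, geometry = geometry,
                 time_label = time_label),
            class = "assembly_frame")
}

#' @export
print.assembly_frame <- function(x, ...) {
  nres <- sum(vapply(x$chains, function(ch) nrow(ch$coords), integer(1)))
  cat(sprintf("<assembly_frame: %d chain(s), %d residues, geometry %s>\n",
              length(x$chains), nres,
              if (is.null(x$geometry)) "open" else x$geometry$type))
  invisible(x)
}

#' Ordered frames sharing one chain topology
#'
#' @param frames list of [assembly_frame()] objects with identical chain
#'   ids, sequences and residue counts, in time order.
#' @param analysis_window number of trailing frames used for averaged
#'   statistics (the "last 30 ns" convention expressed as a frame count).
#' @return object of class `fg_trajectory`.
#' @export
fg_trajectory <- function(frames, analysis_window = length(frames)) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  ref <- .topology_signature(frames[[1]])
  for (k in seq_along(frames)) {
    if (!inherits(frames[[k]], "assembly_frame"))
      stop("all frames must be assembly_frame objects", call. = FALSE)
    if (!identical(.topology_signature(frames[[k]]), ref))
      stop("frame ", k, " has a different chain topology than frame 1",
           call. = FALSE)
  }
  analysis_window <- as.integer(analysis_window)
  if (analysis_window < 1L || analysis_window > length(frames))
    stop("analysis_window must be in [1, n_frames]", call. = FALSE)
  structure(list(frames = frames, analysis_window = analysis_window),
            class = "fg_trajectory")
}

.topology_signature <- function(frame) {
  lapply(frame$chains, function(ch) list(ch$chain_id, ch$sequence))
}

#' @export
print.fg_trajectory <- function(x, ...) {
  cat(sprintf("<fg_trajectory: %d frame(s), analysis window %d>\n",
              length(x$frames), x$analysis_window))
  invisible(x)
}

# --- internal frame helpers -------------------------------------------------

# All beads of a frame (backbone plus extra), with residue bookkeeping.
# Returns list(xyz, chain_idx, resno, gid, kind) where gid is the global
# 1-based residue index (chains in order, residues in order).
.frame_beads <- function(frame) {
  xyz <- NULL; chain_idx <- integer(0); resno <- integer(0)
  gid <- integer(0); kind <- character(0)
  off <- 0L
  for (k in seq_along(frame$chains)) {
    ch <- frame$chains[[k]]
    n <- nrow(ch$coords)
    letters <- strsplit(ch$sequence, "")[[1]]
    xyz <- rbind(xyz, ch$coords)
    chain_idx <- c(chain_idx, rep(k, n))
    resno <- c(resno, seq_len(n))
    gid <- c(gid, off + seq_len(n))
    kind <- c(kind, letters)
    if (!is.null(ch$extra_beads)) {
      for (r in seq_len(n)) {
        eb <- ch$extra_beads[[r]]
        if (!is.null(eb) && nrow(eb)) {
          xyz <- rbind(xyz, eb)
          chain_idx <- c(chain_idx, rep(k, nrow(eb)))
          resno <- c(resno, rep(r, nrow(eb)))
          gid <- c(gid, rep(off + r, nrow(eb)))
          kind <- c(kind, rep(letters[r], nrow(eb)))
        }
      }
    }
    off <- off + n
  }
  if (is.null(xyz)) xyz <- matrix(numeric(0), 0, 3)
  list(xyz = xyz, chain_idx = chain_idx, resno = resno, gid = gid,
       kind = kind)
}

# Residue address table: one row per residue, global id order.
.residue_table <- function(frame) {
  out <- do.call(rbind, lapply(seq_along(frame$chains), function(k) {
    ch <- frame$chains[[k]]
    data.frame(chain = ch$chain_id, resno = seq_len(nrow(ch$coords)),
               chain_idx = k, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chain = character(0), resno = integer(0),
                      chain_idx = integer(0))
  out$gid <- seq_len(nrow(out))
  out
}

.frame_box <- function(frame) {
  g <- frame$geometry
  if (!is.null(g) && g$type == "bath" && isTRUE(g$periodic)) g$box else NULL
}

# minimum-image displacement
.mi <- function(d, box) {
  if (is.null(box)) return(d)
  sweep(d, 2, box, function(x, L) x - L * round(x / L))
}
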