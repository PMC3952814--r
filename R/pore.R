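# Lattice pore characterization: per-node clearance radius (largest
# clash-free sphere centred there, computed as the nearest-bead distance),
# and maximum-bottleneck (widest) path search between source and sink
# regions with a max-heap Dijkstra variant.

#' Clearance-radius lattice over a frame
#'
#' Maps the frame into a cubic lattice and stores at every node the radius
#' of the largest sphere that can be centred there without steric clash:
#' the exact distance to the nearest protein bead ("point" mode, the
#' default) or that distance minus the bead radius, clamped at zero
#' ("subtract" mode).  For bath geometries the lattice spans the box; for
#' other frames it spans the bead bounding box plus one margin layer (the
#' margin can be excluded from path searches to keep the original walls of
#' the generation volume as barriers).
#'
#' @param frame an [assembly_frame()].
#' @param spacing lattice spacing, Angstrom (default 2).
#' @param bead_radius_mode "point" or "subtract".
#' @param radii named per-bead-kind radii (one-letter residue codes), with
#'   a "default" entry; used only in subtract mode.
#' @param domain optional `list(origin =, lengths =)` overriding the
#'   lattice domain (required for an empty frame without a bath box).
#' @return object of class `clearance_grid`: origin, spacing, dims,
#'   3D `clearance` array, margin layer count per dimension, and `cap`
#'   (the domain diagonal used for unbounded nodes).
#' @export
build_clearance_grid <- function(frame, spacing = 2.0,
                                 bead_radius_mode = c("point", "subtract"),
                                 radii = c(default = 2.3), domain = NULL) {
  bead_radius_mode <- match.arg(bead_radius_mode)
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  beads <- .frame_beads(frame)
  g <- frame$geometry
  if (!is.null(domain)) {
    origin <- as.numeric(domain$origin)
    lengths <- as.numeric(domain$lengths)
    margin <- c(0L, 0L, 0L)
  } else if (!is.null(g) && g$type == "bath") {
    origin <- c(0, 0, 0)
    lengths <- g$box
    margin <- c(0L, 0L, 0L)
  } else if (nrow(beads$xyz) > 0L) {
    lo <- apply(beads$xyz, 2, min)
    hi <- apply(beads$xyz, 2, max)
    origin <- floor(lo / spacing) * spacing - spacing
    lengths <- ceiling(hi / spacing) * spacing + spacing - origin
    margin <- c(1L, 1L, 1L)
  } else {
    stop("empty frame without bath box: supply `domain`", call. = FALSE)
  }
  dims <- pmax(2L, as.integer(floor(lengths / spacing + 1e-9)) + 1L)
  cap <- sqrt(sum(lengths^2))
  r <- numeric(0)
  if (bead_radius_mode == "subtract" && nrow(beads$xyz)) {
    if (!("default" %in% names(radii)))
      stop("`radii` must contain a \"default\" entry", call. = FALSE)
    r <- unname(ifelse(beads$kind %in% names(radii), radii[beads$kind],
                       radii[["default"]]))
  }
  clr <- cpp_clearance(beads$xyz, r, origin, spacing, dims, cap)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 clearance = array(clr, dim = dims), margin = margin,
                 cap = cap, bead_radius_mode = bead_radius_mode,
                 geometry = g),
            class = "clearance_grid")
}

#' Construct a clearance grid from a raw field
#'
#' Mainly for testing the path search on hand-made clearance fields.
#'
#' @param clearance 3D numeric array of clearance radii.
#' @param origin lattice origin, Angstrom.
#' @param spacing lattice spacing, Angstrom.
#' @return a `clearance_grid`.
#' @export
clearance_grid <- function(clearance, origin = c(0, 0, 0), spacing = 1.0) {
  clearance <- as.array(clearance)
  if (length(dim(clearance)) != 3L)
    stop("`clearance` must be a 3D array", call. = FALSE)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dim(clearance), clearance = clearance,
                 margin = c(0L, 0L, 0L),
                 cap = max(clearance), bead_radius_mode = "point",
                 geometry = NULL),
            class = "clearance_grid")
}

#' @export
print.clearance_grid <- function(x, ...) {
  cat(sprintf("<clearance_grid: %dx%dx%d nodes, spacing %g A>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

.grid_node_coords <- function(grid, nodes) {
  d <- grid$dims
  nodes0 <- nodes - 1L
  ix <- nodes0 %% d[1]
  iy <- (nodes0 %/% d[1]) %% d[2]
  iz <- nodes0 %/% (d[1] * d[2])
  cbind(grid$origin[1] + ix * grid$spacing,
        grid$origin[2] + iy * grid$spacing,
        grid$origin[3] + iz * grid$spacing)
}

.grid_index_arrays <- function(grid) {
  d <- grid$dims
  n <- prod(d)
  i0 <- seq_len(n) - 1L
  list(ix = i0 %% d[1] + 1L, iy = (i0 %/% d[1]) %% d[2] + 1L,
       iz = i0 %/% (d[1] * d[2]) + 1L)
}

#' Widest (maximum-bottleneck) lattice path
#'
#' Finds the source-to-sink lattice path maximizing the minimum node
#' clearance along the path -- the radius of the largest sphere that can
#' pass -- using a Dijkstra variant with a max-heap on the
#' best-known-bottleneck value.  Ties are broken by node index so the
#' witness path is reproducible.
#'
#' @param grid a [build_clearance_grid()] result.
#' @param source_nodes,sink_nodes 1-based linear node indices (disjoint,
#'   non-empty).
#' @param connectivity 6 (face neighbours, default) or 26.
#' @param blocked optional node indices excluded from all paths.
#' @return object of class `pore_result`: `bottleneck_radius`,
#'   `witness_path` (matrix of node coordinates, source to sink),
#'   `witness_nodes`, `reached`, `spacing` (reported accuracy is one
#'   lattice spacing).
#' @export
widest_bottleneck_path <- function(grid, source_nodes, sink_nodes,
                                   connectivity = 6L, blocked = integer(0)) {
  stopifnot(inherits(grid, "clearance_grid"),
            connectivity %in% c(6L, 26L))
  source_nodes <- unique(as.integer(source_nodes))
  sink_nodes <- unique(as.integer(sink_nodes))
  if (!length(source_nodes) || !length(sink_nodes))
    stop("source and sink must be non-empty", call. = FALSE)
  if (length(intersect(source_nodes, sink_nodes)))
    stop("source and sink must be disjoint", call. = FALSE)
  res <- cpp_widest_path(as.numeric(grid$clearance), grid$dims,
                         source_nodes - 1L, sink_nodes - 1L,
                         as.integer(connectivity),
                         unique(as.integer(blocked)) - 1L)
  nodes <- res$path + 1L
  bott <- if (res$reached) res$bottleneck else 0.0
  if (res$reached) # witness invariant: min clearance on path == bottleneck
    stopifnot(abs(min(grid$clearance[nodes]) - bott) < 1e-12)
  structure(list(bottleneck_radius = bott,
                 witness_nodes = nodes,
                 witness_path = .grid_node_coords(grid, nodes),
                 reached = res$reached, spacing = grid$spacing,
                 per_frame = bott, mean = bott, std = NA_real_),
            class = "pore_result")
}

#' @export
print.pore_result <- function(x, ...) {
  cat(sprintf("<pore_result: bottleneck %.2f A (+- %g A lattice)%s>\n",
              x$bottleneck_radius, x$spacing,
              if (!is.na(x$std)) sprintf(", mean %.2f sd %.2f over %d frames",
                                         x$mean, x$std, length(x$per_frame))
              else ""))
  invisible(x)
}

#' Axial pore size of a frame
#'
#' Source is the full entry face of the lattice (lowest layer along the
#' axis), sink the exit face; the widest-bottleneck path between them gives
#' the radius of the largest sphere that can pass through the structure
#' along the axis.  For lattices derived from a bead bounding box the one
#' added margin layer in the two transverse directions is excluded from
#' paths, so the walls of the original generation volume act as barriers.
#'
#' @param frame an [assembly_frame()].
#' @param spacing lattice spacing, Angstrom.
#' @param axis "z" (default), "x" or "y".
#' @param connectivity 6 or 26.
#' @param grid optional precomputed [build_clearance_grid()].
#' @param ... passed to [build_clearance_grid()].
#' @return a `pore_result`.
#' @export
axial_pore_size <- function(frame, spacing = 2.0, axis = "z",
                            connectivity = 6L, grid = NULL, ...) {
  if (is.null(grid)) grid <- build_clearance_grid(frame, spacing, ...)
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be x, y or z", call. = FALSE)
  idx <- .grid_index_arrays(grid)
  along <- list(idx$ix, idx$iy, idx$iz)[[ax]]
  d <- grid$dims
  source_nodes <- which(along == 1L)
  sink_nodes <- which(along == d[ax])
  blocked <- integer(0)
  trans <- setdiff(1:3, ax)
  for (t in trans) {
    if (grid$margin[t] > 0L) {
      tv <- list(idx$ix, idx$iy, idx$iz)[[t]]
      blocked <- c(blocked, which(tv <= grid$margin[t] |
                                    tv > d[t] - grid$margin[t]))
    }
  }
  blocked <- setdiff(blocked, c(source_nodes, sink_nodes))
  widest_bottleneck_path(grid, setdiff(source_nodes, blocked),
                         setdiff(sink_nodes, blocked),
                         connectivity, blocked)
}

#' Radial pore size of a ring-like frame
#'
#' For ring geometries the probe moves radially: source nodes lie in the
#' inner cylindrical core (radius `core_fraction` of the ring inner
#' radius around the z axis), sink nodes beyond the outermost bead radius.
#' The margin layers along z are excluded so the probe cannot escape over
#' the top of the structure.
#'
#' @param frame an [assembly_frame()] with ring geometry.
#' @param spacing lattice spacing, Angstrom.
#' @param connectivity 6 or 26.
#' @param core_fraction source core radius as a fraction of the ring inner
#'   radius (default 0.25).
#' @param grid optional precomputed grid.
#' @param ... passed to [build_clearance_grid()].
#' @return a `pore_result`.
#' @export
radial_pore_size <- function(frame, spacing = 2.0, connectivity = 6L,
                             core_fraction = 0.25, grid = NULL, ...) {
  g <- frame$geometry
  if (is.null(g) || g$type != "ring")
    stop("radial pore analysis requires ring geometry", call. = FALSE)
  if (is.null(grid)) grid <- build_clearance_grid(frame, spacing, ...)
  idx <- .grid_index_arrays(grid)
  d <- grid$dims
  x <- grid$origin[1] + (idx$ix - 1L) * grid$spacing
  y <- grid$origin[2] + (idx$iy - 1L) * grid$spacing
  r <- sqrt(x^2 + y^2)
  beads <- .frame_beads(frame)
  r_out <- max(sqrt(beads$xyz[, 1]^2 + beads$xyz[, 2]^2)) + grid$spacing / 2
  source_nodes <- which(r <= core_fraction * g$inner_radius)
  sink_nodes <- which(r >= r_out)
  blocked <- integer(0)
  if (grid$margin[3] > 0L)
    blocked <- which(idx$iz <= grid$margin[3] |
                       idx$iz > d[3] - grid$margin[3])
  source_nodes <- setdiff(source_nodes, blocked)
  sink_nodes <- setdiff(sink_nodes, c(blocked, source_nodes))
  widest_bottleneck_path(grid, source_nodes, sink_nodes, connectivity,
                         blocked)
}

#' Pore-size statistics over a trajectory window
#'
#' Per-frame bottleneck radii over the trailing `window` frames, with their
#' mean and sample standard deviation.
#'
#' @param x an [fg_trajectory()] or list of frames (phantom series with
#'   differing wall topologies are accepted as plain lists).
#' @param window number of trailing frames (default: the analysis window,
#'   or all frames for a list).
#' @param mode "axial" or "radial".
#' @param spacing lattice spacing, Angstrom.
#' @param ... passed to [axial_pore_size()] / [radial_pore_size()].
#' @return a `pore_result` with `per_frame`, `mean` and `std`.
#' @export
pore_size_stats <- function(x, window = NULL, mode = c("axial", "radial"),
                            spacing = 2.0, ...) {
  mode <- match.arg(mode)
  frames <- .as_frame_list(x)
  if (is.null(window))
    window <- if (inherits(x, "fg_trajectory")) x$analysis_window
              else length(frames)
  window <- as.integer(window)
  if (window < 1L) stop("empty analysis window", call. = FALSE)
  if (window > length(frames))
    stop("window (", window, ") exceeds the number of frames (",
         length(frames), ")", call. = FALSE)
  frames <- tail(frames, window)
  vals <- vapply(frames, function(fr) {
    res <- if (mode == "axial") axial_pore_size(fr, spacing, ...)
           else radial_pore_size(fr, spacing, ...)
    res$bottleneck_radius
  }, numeric(1))
  structure(list(bottleneck_radius = mean(vals), witness_nodes = NULL,
                 witness_path = NULL, reached = TRUE, spacing = spacing,
                 per_frame = vals, mean = mean(vals),
                 std = if (length(vals) > 1L) sd(vals) else 0),
            class = "pore_result")
}

#' Export a pore map as PDB pseudo-atoms
#'
#' Writes all lattice nodes with clearance at least `min_radius` as HETATM
#' pseudo-atoms for visualization of the pores that can accommodate
#' spheres of that radius.
#'
#' @param grid a [build_clearance_grid()] result.
#' @param min_radius clearance threshold, Angstrom (default 35, i.e. pores
#'   that fit a 7 nm sphere).
#' @param path output PDB path.
#' @return invisibly, the matrix of exported node coordinates.
#' @export
export_pore_map <- function(grid, min_radius = 35, path) {
  stopifnot(inherits(grid, "clearance_grid"))
  nodes <- which(as.numeric(grid$clearance) >= min_radius)
  xyz <- .grid_node_coords(grid, nodes)
  if (nrow(xyz)) {
    .pdb_check_coords(xyz)
    bio3d::write.pdb(file = path, type = rep("HETATM", nrow(xyz)),
                     xyz = as.numeric(t(xyz)),
                     resno = seq_len(nrow(xyz)),
                     resid = rep("POR", nrow(xyz)),
                     chain = rep("P", nrow(xyz)),
                     elety = rep("O", nrow(xyz)),
                     eleno = seq_len(nrow(xyz)))
  } else {
    writeLines(c("REMARK 300 FGASSEMBLY EMPTY PORE MAP", "END"), path)
  }
  invisible(xyz)
}
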