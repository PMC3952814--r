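# Brush height and radius of gyration.

#' Brush height
#'
#' Per-chain end-to-end distance of the backbone beads along the brush
#' axis: `|z(last bead) - z(first bead)|` (z is the tether axis for ring,
#' array and bath geometries).  Appended tether residues, when present,
#' count as backbone beads.
#'
#' @param x an [assembly_frame()] or [fg_trajectory()].
#' @param chain_subset optional character vector of chain ids.
#' @return for a frame: `list(per_chain = named numeric, mean =)`; for a
#'   trajectory: `list(per_frame = matrix frames x chains, mean = numeric
#'   per-frame means)`.
#' @export
brush_height <- function(x, chain_subset = NULL) {
  if (inherits(x, "fg_trajectory")) {
    per <- t(vapply(x$frames, function(fr)
      brush_height(fr, chain_subset)$per_chain,
      brush_height(x$frames[[1]], chain_subset)$per_chain))
    return(list(per_frame = per, mean = rowMeans(per)))
  }
  stopifnot(inherits(x, "assembly_frame"))
  chains <- x$chains
  if (!is.null(chain_subset)) {
    ids <- vapply(chains, function(ch) ch$chain_id, character(1))
    chains <- chains[ids %in% chain_subset]
  }
  if (!length(chains)) stop("no chains selected", call. = FALSE)
  per <- vapply(chains, function(ch)
    abs(ch$coords[nrow(ch$coords), 3] - ch$coords[1, 3]), numeric(1))
  names(per) <- vapply(chains, function(ch) ch$chain_id, character(1))
  list(per_chain = per, mean = mean(per))
}

#' Radius of gyration
#'
#' Root-mean-square bead distance from the unweighted centroid.
#'
#' @param x a [chain_record()] or a coordinate matrix.
#' @return Rg in Angstrom.
#' @export
#' @examples
#' radius_of_gyration(build_extended_chain(strrep("A", 10), c(0, 0, 0)))
radius_of_gyration <- function(x) {
  coords <- if (inherits(x, "chain_record")) x$coords else as.matrix(x)
  stopifnot(nrow(coords) >= 1L, ncol(coords) == 3L)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Write an analysis result as JSON
#'
#' Standard results schema:
#' `{analysis, parameters, per_frame, mean, std}`.
#'
#' @param analysis analysis name string.
#' @param parameters named list of parameters.
#' @param per_frame numeric vector of per-frame values.
#' @param path output path.
#' @param extra optional named list of additional fields.
#' @return invisibly, the written list.
#' @export
write_result_json <- function(analysis, parameters, per_frame, path,
                              extra = NULL) {
  out <- c(list(analysis = analysis, parameters = parameters,
                per_frame = per_frame,
                mean = mean(per_frame),
                std = if (length(per_frame) > 1L) sd(per_frame) else 0),
           extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
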