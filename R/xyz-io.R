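# Extended-XYZ trajectory I/O.  Per frame: a bead-count line, then a comment
# line with key=value tokens (time, chain segmentation, geometry, window,
# tethers), then one line per bead: one-letter residue code and x y z at six
# decimals.  Only backbone beads are carried by this format.

.xyz_comment <- function(frame, window = NULL) {
  ids <- vapply(frame$chains, function(ch) ch$chain_id, character(1))
  lens <- vapply(frame$chains, function(ch) nrow(ch$coords), integer(1))
  toks <- c(sprintf("time=%s", format(frame$time_label, digits = 15)),
            sprintf("chains=%s", paste(sprintf("%s:%d", ids, lens),
                                       collapse = ",")),
            sprintf("geometry=%s", .serialize_geometry(frame$geometry)))
  teth <- vapply(frame$chains, function(ch) {
    if (is.null(ch$tether)) return(NA_character_)
    sprintf("%s:%d:%.6f:%.6f:%.6f", ch$chain_id, ch$tether$residue,
            ch$tether$anchor[1], ch$tether$anchor[2], ch$tether$anchor[3])
  }, character(1))
  teth <- teth[!is.na(teth)]
  if (length(teth))
    toks <- c(toks, sprintf("tethers=%s", paste(teth, collapse = ",")))
  if (!is.null(window)) toks <- c(toks, sprintf("window=%d", window))
  paste(toks, collapse = " ")
}

#' Write a trajectory as extended XYZ
#'
#' @param traj an [fg_trajectory()] (or a single [assembly_frame()], written
#'   as a one-frame trajectory).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_trajectory_xyz <- function(traj, path) {
  if (inherits(traj, "assembly_frame")) traj <- fg_trajectory(list(traj))
  stopifnot(inherits(traj, "fg_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    frame <- traj$frames[[k]]
    letters <- unlist(lapply(frame$chains,
                             function(ch) strsplit(ch$sequence, "")[[1]]))
    xyz <- do.call(rbind, lapply(frame$chains, function(ch) ch$coords))
    n <- if (is.null(xyz)) 0L else nrow(xyz)
    writeLines(as.character(n), con)
    writeLines(.xyz_comment(frame, if (k == 1L) traj$analysis_window), con)
    if (n > 0L)
      writeLines(sprintf("%s %.6f %.6f %.6f", letters, xyz[, 1], xyz[, 2],
                         xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Frames are returned in file order; every frame must have the same bead
#' count and chain segmentation as the first (an error names the offending
#' frame index otherwise).  Chains and residues are never reordered.
#'
#' @param path file path.
#' @return an [fg_trajectory()].
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  window <- NULL
  ref_seg <- NULL
  k <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("frame ", k, ": invalid bead-count line", call. = FALSE)
    if (pos + 1L > length(lines))
      stop("frame ", k, ": missing comment line", call. = FALSE)
    kv <- list()
    for (tok in strsplit(lines[pos + 1L], " ", fixed = TRUE)[[1]]) {
      eq <- regmatches(tok, regexpr("=", tok), invert = TRUE)[[1]]
      if (length(eq) == 2L) kv[[eq[1]]] <- eq[2]
    }
    if (is.null(kv$chains))
      stop("frame ", k, ": comment line lacks chain segmentation",
           call. = FALSE)
    seg <- do.call(rbind, lapply(strsplit(kv$chains, ",")[[1]], function(s) {
      p <- strsplit(s, ":", fixed = TRUE)[[1]]
      data.frame(id = p[1], len = as.integer(p[2]), stringsAsFactors = FALSE)
    }))
    if (sum(seg$len) != n)
      stop("frame ", k, ": chain segmentation does not sum to bead count",
           call. = FALSE)
    if (pos + 1L + n > length(lines))
      stop("frame ", k, ": truncated (expected ", n, " bead lines)",
           call. = FALSE)
    if (is.null(ref_seg)) ref_seg <- seg
    else if (!identical(seg, ref_seg) || n != sum(ref_seg$len))
      stop("frame ", k, ": bead count/segmentation differs from frame 1",
           call. = FALSE)
    body <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(trimws(body), "\\s+")
    letters <- vapply(parts, `[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    tethers <- list()
    if (!is.null(kv$tethers)) {
      for (s in strsplit(kv$tethers, ",")[[1]]) {
        p <- strsplit(s, ":", fixed = TRUE)[[1]]
        tethers[[p[1]]] <- list(anchor = as.numeric(p[3:5]),
                                residue = as.integer(p[2]))
      }
    }
    chains <- list()
    off <- 0L
    for (q in seq_len(nrow(seg))) {
      len <- seg$len[q]
      idx <- off + seq_len(len)
      teth <- tethers[[seg$id[q]]]
      coords <- xyz[idx, , drop = FALSE]
      if (!is.null(teth)) coords[teth$residue, ] <- teth$anchor
      chains[[q]] <- chain_record(seg$id[q],
                                  paste(letters[idx], collapse = ""),
                                  coords, tether = teth)
      off <- off + len
    }
    geometry <- if (!is.null(kv$geometry)) .parse_geometry(kv$geometry)
    frames[[k]] <- assembly_frame(chains, geometry,
                                  as.numeric(kv$time %||% (k - 1)))
    if (k == 1L && !is.null(kv$window)) window <- as.integer(kv$window)
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  fg_trajectory(frames, window %||% length(frames))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
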