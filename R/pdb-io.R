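# PDB single-frame I/O.  One ATOM record per backbone bead (atom name CA),
# extra beads as atom name SC, tether anchors as HETATM with residue name ANC.
# Frame metadata (geometry, time label, chain-id map) is carried in
# REMARK 300 lines so that write -> read round-trips the frame.

PDB_CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

.pdb_check_coords <- function(xyz) {
  if (any(xyz > 9999.999 + 5e-4) || any(xyz < -999.999 - 5e-4))
    stop("coordinate exceeds PDB fixed-column field width ",
         "(allowed range -999.999..9999.999 Angstrom)", call. = FALSE)
}

.serialize_geometry <- function(g) {
  if (is.null(g)) return("open")
  switch(g$type,
    ring = sprintf("ring;inner_radius=%g;row_spacing=%g;n_rows=%d;anchor_spacing=%g",
                   g$inner_radius, g$row_spacing, g$n_rows, g$anchor_spacing),
    array = sprintf("array;nx=%d;ny=%d;grid_spacing=%g", g$nx, g$ny,
                    g$grid_spacing),
    bath = sprintf("bath;box=%g,%g,%g;periodic=%d", g$box[1], g$box[2],
                   g$box[3], as.integer(g$periodic)))
}

.parse_geometry <- function(s) {
  if (is.na(s) || s == "open") return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  type <- parts[1]
  kv <- list()
  for (p in parts[-1]) {
    eq <- regmatches(p, regexpr("=", p), invert = TRUE)[[1]]
    kv[[eq[1]]] <- eq[2]
  }
  switch(type,
    ring = ring_geometry(as.numeric(kv$inner_radius),
                         as.numeric(kv$row_spacing),
                         as.integer(kv$n_rows),
                         as.numeric(kv$anchor_spacing)),
    array = array_geometry(as.integer(kv$nx), as.integer(kv$ny),
                           as.numeric(kv$grid_spacing)),
    bath = bath_geometry(as.numeric(strsplit(kv$box, ",")[[1]]),
                         as.integer(kv$periodic) == 1L),
    stop("unknown geometry type in file: ", type, call. = FALSE))
}

#' Write an assembly frame as PDB
#'
#' One ATOM record per backbone bead (atom name CA, one-letter sequence
#' mapped to three-letter residue names), optional extra beads as SC atoms,
#' and tether anchor positions as HETATM records with residue name ANC
#' (the HETATM residue number is the anchored residue index).  Coordinates
#' are written at the PDB fixed precision of 3 decimals.  Frames with more
#' than 62 chains (the PDB chain-id alphabet) are split into several files
#' with suffix `_partNN` before the extension.
#'
#' @param frame an [assembly_frame()].
#' @param path output file path.
#' @return invisibly, the vector of files written.
#' @export
write_assembly_pdb <- function(frame, path) {
  stopifnot(inherits(frame, "assembly_frame"))
  nch <- length(frame$chains)
  if (nch > length(PDB_CHAIN_ALPHABET)) {
    per <- length(PDB_CHAIN_ALPHABET)
    idx <- split(seq_len(nch), ceiling(seq_len(nch) / per))
    base <- sub("\\.pdb$", "", path)
    files <- character(0)
    for (k in seq_along(idx)) {
      sub_frame <- assembly_frame(frame$chains[idx[[k]]], frame$geometry,
                                  frame$time_label)
      f <- sprintf("%s_part%02d.pdb", base, k)
      write_assembly_pdb(sub_frame, f)
      files <- c(files, f)
    }
    return(invisible(files))
  }
  remarks <- c(
    sprintf("REMARK 300 FGASSEMBLY TIME %s",
            format(frame$time_label, digits = 15)),
    sprintf("REMARK 300 FGASSEMBLY GEOMETRY %s",
            .serialize_geometry(frame$geometry)))
  if (nch > 0) {
    map <- sprintf("%s=%s", PDB_CHAIN_ALPHABET[seq_len(nch)],
                   vapply(frame$chains, function(ch) ch$chain_id,
                          character(1)))
    for (grp in split(map, ceiling(seq_along(map) / 8)))
      remarks <- c(remarks, paste("REMARK 300 FGASSEMBLY CHAINMAP",
                                  paste(grp, collapse = " ")))
  }
  if (nch == 0L) {
    writeLines(c(remarks, "END"), path)
    return(invisible(path))
  }
  xyz <- NULL; resno <- integer(0); resid <- character(0)
  chain <- character(0); elety <- character(0); type <- character(0)
  for (k in seq_len(nch)) {
    ch <- frame$chains[[k]]
    n <- nrow(ch$coords)
    letters3 <- bio3d::aa123(strsplit(ch$sequence, "")[[1]])
    xyz <- rbind(xyz, ch$coords)
    resno <- c(resno, seq_len(n))
    resid <- c(resid, letters3)
    chain <- c(chain, rep(PDB_CHAIN_ALPHABET[k], n))
    elety <- c(elety, rep("CA", n))
    type <- c(type, rep("ATOM", n))
    if (!is.null(ch$extra_beads)) {
      for (r in seq_len(n)) {
        eb <- ch$extra_beads[[r]]
        if (!is.null(eb) && nrow(eb)) {
          xyz <- rbind(xyz, eb)
          resno <- c(resno, rep(r, nrow(eb)))
          resid <- c(resid, rep(letters3[r], nrow(eb)))
          chain <- c(chain, rep(PDB_CHAIN_ALPHABET[k], nrow(eb)))
          elety <- c(elety, rep("SC", nrow(eb)))
          type <- c(type, rep("ATOM", nrow(eb)))
        }
      }
    }
    if (!is.null(ch$tether)) {
      xyz <- rbind(xyz, matrix(ch$tether$anchor, 1, 3))
      resno <- c(resno, ch$tether$residue)
      resid <- c(resid, "ANC")
      chain <- c(chain, PDB_CHAIN_ALPHABET[k])
      elety <- c(elety, "CA")
      type <- c(type, "HETATM")
    }
  }
  .pdb_check_coords(xyz)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, type = type, xyz = as.numeric(t(xyz)),
                   resno = resno, resid = resid, chain = chain,
                   elety = elety, eleno = seq_along(resno))
  writeLines(c(remarks, readLines(tmp)), path)
  invisible(path)
}

#' Read an assembly frame from PDB
#'
#' Inverse of [write_assembly_pdb()] for files written by this package
#' (geometry and chain-id metadata are recovered from REMARK 300 lines;
#' plain PDB files are read with single-character chain ids and open
#' geometry).  Chains and residues are never reordered.
#'
#' @param path PDB file path.
#' @return an [assembly_frame()].
#' @export
read_assembly_pdb <- function(path) {
  lines <- readLines(path)
  rem <- lines[startsWith(lines, "REMARK 300 FGASSEMBLY")]
  time_label <- 0
  geometry <- NULL
  chain_map <- character(0)
  for (r in rem) {
    body <- sub("^REMARK 300 FGASSEMBLY ", "", r)
    if (startsWith(body, "TIME "))
      time_label <- as.numeric(sub("^TIME ", "", body))
    else if (startsWith(body, "GEOMETRY "))
      geometry <- .parse_geometry(sub("^GEOMETRY ", "", body))
    else if (startsWith(body, "CHAINMAP ")) {
      for (tok in strsplit(sub("^CHAINMAP ", "", body), " ")[[1]]) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
        chain_map[kv[1]] <- kv[2]
      }
    }
  }
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    return(assembly_frame(list(), geometry, time_label))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chains <- list()
  for (cc in unique(at$chain)) {
    sel <- at[at$chain == cc, , drop = FALSE]
    main <- sel[sel$type == "ATOM" & sel$elety == "CA", , drop = FALSE]
    side <- sel[sel$type == "ATOM" & sel$elety == "SC", , drop = FALSE]
    anc <- sel[sel$type == "HETATM" & sel$resid == "ANC", , drop = FALSE]
    if (!nrow(main)) next
    o <- order(main$resno)
    main <- main[o, , drop = FALSE]
    sequence <- paste(bio3d::aa321(main$resid), collapse = "")
    coords <- cbind(main$x, main$y, main$z)
    extra <- NULL
    if (nrow(side)) {
      extra <- vector("list", nrow(main))
      for (q in seq_len(nrow(side))) {
        r <- side$resno[q]
        extra[[r]] <- rbind(extra[[r]], c(side$x[q], side$y[q], side$z[q]))
      }
    }
    tether <- NULL
    if (nrow(anc) == 1L)
      tether <- list(anchor = c(anc$x, anc$y, anc$z), residue = anc$resno)
    id <- if (cc %in% names(chain_map)) chain_map[[cc]] else cc
    chains[[length(chains) + 1L]] <-
      chain_record(id, sequence, coords, tether = tether,
                   extra_beads = extra)
  }
  assembly_frame(chains, geometry, time_label)
}
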