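# Shrake-Rupley solvent accessible surface area on bead models, and the
# motif-accessibility comparison between bundle and cross-linking regions.

#' SASA parameters
#'
#' @param probe_radius solvent probe radius, Angstrom.  The default 2.6
#'   matches a coarse-grained water bead; 1.4 is the conventional atomic
#'   water probe.
#' @param radii named per-bead-kind radii (one-letter residue codes) with a
#'   "default" entry; coarse-grained backbone beads default to 2.3.
#' @param n_sphere_points quadrature points per bead (>= 92; default 960).
#' @return list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 2.6, radii = c(default = 2.3),
                        n_sphere_points = 960L) {
  stopifnot(probe_radius > 0, all(radii > 0), n_sphere_points >= 92L)
  if (!("default" %in% names(radii)))
    stop("`radii` must contain a \"default\" entry", call. = FALSE)
  structure(list(probe_radius = probe_radius, radii = radii,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_params")
}

# Near-uniform points on the unit sphere (golden-spiral quadrature).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley SASA of a bead frame
#'
#' Standard sphere-point algorithm: for every bead, the fraction of
#' quadrature points on the expanded sphere of radius `R_bead + probe`
#' falling outside all neighbouring expanded spheres, times the expanded
#' sphere area; per-residue areas sum over the residue's beads.  Distances
#' are plain Euclidean (periodic images are not considered).
#'
#' @param frame an [assembly_frame()].
#' @param params a [sasa_params()].
#' @return data.frame with columns `chain`, `resno`, `sasa` (Angstrom^2),
#'   one row per residue, in frame order.
#' @export
shrake_rupley_sasa <- function(frame, params = sasa_params()) {
  stopifnot(inherits(frame, "assembly_frame"),
            inherits(params, "sasa_params"))
  beads <- .frame_beads(frame)
  m <- nrow(beads$xyz)
  nodes <- .residue_table(frame)
  if (m == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      sasa = numeric(0)))
  lookup <- params$radii
  r <- ifelse(beads$kind %in% names(lookup), lookup[beads$kind],
              lookup[["default"]])
  r <- unname(as.numeric(r))
  if (any(is.na(r)))
    stop("missing radius for bead kind(s): ",
         paste(unique(beads$kind[is.na(r)]), collapse = ", "), call. = FALSE)
  p <- params$probe_radius
  pts <- .sphere_points(params$n_sphere_points)
  Rexp <- r + p
  area <- numeric(m)
  for (i in seq_len(m)) {
    ci <- beads$xyz[i, ]
    d2 <- rowSums(sweep(beads$xyz, 2, ci)^2)
    nb <- which(d2 < (Rexp[i] + Rexp)^2 & seq_len(m) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * Rexp[i]^2
      next
    }
    sp <- sweep(pts * Rexp[i], 2, ci, "+")
    exposed <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(sp[exposed, , drop = FALSE], 2,
                           beads$xyz[j, ])^2)
      exposed[exposed] <- dj2 >= Rexp[j]^2
    }
    area[i] <- 4 * pi * Rexp[i]^2 * sum(exposed) / nrow(sp)
  }
  per_res <- tapply(area, beads$gid, sum)
  out <- nodes[, c("chain", "resno")]
  out$sasa <- as.numeric(per_res[as.character(nodes$gid)])
  out
}

#' Motif accessibility by region
#'
#' Mean and standard deviation of the SASA of the first phenylalanine of
#' each FG and FxFG motif (the residue at the motif start index), grouped
#' by motif kind and by the region -- bundle or cross-linking -- the residue
#' belongs to.  Groups with no members are absent from the output.
#'
#' @param frame an [assembly_frame()].
#' @param decomposition a [decompose_bundles()] result for the same frame.
#' @param params a [sasa_params()].
#' @return data.frame with columns `kind`, `region`, `n`, `mean_sasa`,
#'   `sd_sasa`.
#' @export
motif_accessibility_report <- function(frame, decomposition,
                                       params = sasa_params()) {
  stopifnot(inherits(decomposition, "bundle_decomposition"))
  sasa <- shrake_rupley_sasa(frame, params)
  labs <- decomposition$labels
  rows <- NULL
  for (ch in frame$chains) {
    if (!nrow(ch$motifs)) next
    for (q in seq_len(nrow(ch$motifs))) {
      start <- ch$motifs$start[q]
      lab <- labs$label[labs$chain == ch$chain_id & labs$resno == start]
      region <- if (lab == "crosslink") "crosslink" else "bundle"
      val <- sasa$sasa[sasa$chain == ch$chain_id & sasa$resno == start]
      rows <- rbind(rows, data.frame(kind = ch$motifs$kind[q],
                                     region = region, sasa = val,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows))
    return(data.frame(kind = character(0), region = character(0),
                      n = integer(0), mean_sasa = numeric(0),
                      sd_sasa = numeric(0)))
  agg <- do.call(rbind, lapply(split(rows, paste(rows$kind, rows$region)),
                               function(gr)
    data.frame(kind = gr$kind[1], region = gr$region[1], n = nrow(gr),
               mean_sasa = mean(gr$sasa),
               sd_sasa = if (nrow(gr) > 1L) sd(gr$sasa) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$kind, agg$region), ]
}
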