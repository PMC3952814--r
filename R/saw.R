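# Worm-like-chain self-avoiding-walk generation: fixed bond length, fixed
# three-bead bend angle, free (uniform) dihedral, excluded-volume rejection.

#' Parameters of the self-avoiding-walk chain generator
#'
#' Defaults follow the coarse-grained coil conventions used for FG-domain
#' models: 3.7 Angstrom between neighbouring backbone beads, an 8 Angstrom
#' close-contact (excluded volume) cutoff, and a fixed 127 degree bend angle
#' for three adjacent beads (the MARTINI coil backbone angle; the angle is a
#' parameter because published coil conventions vary).
#'
#' The clash rule exempts pairs with sequence separation at most
#' `sequence_separation_exempt` (default 2): bonded neighbours sit at the
#' bond length and second neighbours are fixed by the bend angle, both well
#' inside the 8 Angstrom cutoff, so applying the cutoff to them would reject
#' every chain.
#'
#' @param bond_length fixed distance between consecutive beads, Angstrom.
#' @param bend_angle fixed angle subtended by three adjacent beads, degrees.
#' @param clash_cutoff close-contact rejection distance, Angstrom; pairs
#'   closer than this (strictly) are rejected.
#' @param sequence_separation_exempt pairs with |i-j| at most this value are
#'   exempt from the clash rule.
#' @param max_step_retries dihedral redraws per bead placement.
#' @param backtrack_depth beads removed when a placement is exhausted.
#' @param max_backtracks backtracks allowed per whole-chain attempt.
#' @param max_chain_restarts whole-chain restarts before giving up.
#' @param rng_seed optional integer seed applied on entry to the grower.
#' @return list of class `saw_params`.
#' @export
saw_params <- function(bond_length = 3.7, bend_angle = 127,
                       clash_cutoff = 8.0, sequence_separation_exempt = 2L,
                       max_step_retries = 50L, backtrack_depth = 5L,
                       max_backtracks = 30L, max_chain_restarts = 100L,
                       rng_seed = NULL) {
  stopifnot(bond_length > 0, bend_angle > 0, bend_angle < 180,
            clash_cutoff > 0, max_step_retries >= 1, backtrack_depth >= 1,
            max_chain_restarts >= 1)
  sequence_separation_exempt <- as.integer(sequence_separation_exempt)
  if (clash_cutoff > bond_length && sequence_separation_exempt < 1L)
    stop("clash_cutoff > bond_length requires sequence_separation_exempt >= 1",
         call. = FALSE)
  structure(list(bond_length = bond_length, bend_angle = bend_angle,
                 clash_cutoff = clash_cutoff,
                 sequence_separation_exempt = sequence_separation_exempt,
                 max_step_retries = as.integer(max_step_retries),
                 backtrack_depth = as.integer(backtrack_depth),
                 max_backtracks = as.integer(max_backtracks),
                 max_chain_restarts = as.integer(max_chain_restarts),
                 rng_seed = rng_seed),
            class = "saw_params")
}

#' Build a fully extended straight chain
#'
#' Residue i is placed at `anchor + (i-1) * bond_length * direction`.
#'
#' @param sequence one-letter amino-acid string.
#' @param anchor 3D position of residue 1, Angstrom.
#' @param direction unit vector of chain growth.
#' @param bond_length bead-bead distance, Angstrom.
#' @param chain_id chain identifier.
#' @return a [chain_record()].
#' @export
#' @examples
#' ch <- build_extended_chain("AAA", c(0, 0, 0), c(0, 0, 1))
#' ch$coords[, 3] # 0, 3.7, 7.4
build_extended_chain <- function(sequence, anchor = c(0, 0, 0),
                                 direction = c(0, 0, 1), bond_length = 3.7,
                                 chain_id = "A") {
  letters <- .check_sequence(sequence)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("zero direction vector", call. = FALSE)
  direction <- direction / nrm
  n <- length(letters)
  coords <- matrix(rep(as.numeric(anchor), each = n), n, 3) +
    (seq_len(n) - 1) * bond_length * matrix(rep(direction, each = n), n, 3)
  chain_record(chain_id, sequence, coords)
}

.unit_sphere_sample <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Orthonormal pair perpendicular to unit vector u.
.perp_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Grow a self-avoiding worm-like chain
#'
#' Beads are added one at a time: each new bead sits at the fixed bond
#' length from its predecessor, subtends the fixed bend angle with the two
#' preceding beads, and takes a dihedral position drawn uniformly on the
#' allowed circle.  A candidate is rejected if any intra-chain pair with
#' sequence separation greater than the exemption window, or any pair with
#' an obstacle bead, is closer than the clash cutoff (minimum-image if
#' `box` is given).  Exhausted placements backtrack; exhausted attempts
#' restart the chain; exhausted restarts raise a growth-failure condition
#' (class `fg_growth_failure`) reporting the deepest residue reached.
#'
#' @param sequence one-letter amino-acid string.
#' @param start_beads matrix of one or more fixed seed positions (the first
#'   beads of the chain); consecutive seeds must satisfy the bond length and
#'   seed pairs the clash rule.
#' @param params a [saw_params()].
#' @param obstacles optional matrix of bead positions of other chains; every
#'   grown bead must be at least the clash cutoff from every obstacle bead.
#' @param box optional length-3 periodic box edges (minimum-image
#'   distances).
#' @param zmin optional half-space constraint: grown beads must have
#'   z >= zmin (used for surface-tethered chains; ignored when `box` set).
#' @param chain_id chain identifier.
#' @return a [chain_record()].
#' @export
grow_saw_chain <- function(sequence, start_beads, params = saw_params(),
                           obstacles = NULL, box = NULL, zmin = NULL,
                           chain_id = "A") {
  letters <- .check_sequence(sequence)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  n <- length(letters)
  start_beads <- matrix(as.numeric(start_beads), ncol = 3)
  k0 <- nrow(start_beads)
  if (k0 < 1L) stop("need at least one seed position", call. = FALSE)
  if (k0 > n) stop("more seed positions than residues", call. = FALSE)
  b <- params$bond_length
  cutoff <- params$clash_cutoff
  exempt <- params$sequence_separation_exempt
  theta <- params$bend_angle * pi / 180
  ct <- cos(theta); st <- sin(theta)
  boxm <- if (!is.null(box)) {
    box <- as.numeric(box); if (length(box) == 1L) box <- rep(box, 3L); box
  }
  # seed validation
  if (k0 >= 2L) {
    d <- sqrt(rowSums(.mi(diff(start_beads), boxm)^2))
    if (any(abs(d - b) > 1e-6))
      stop("seed positions violate the bond length", call. = FALSE)
  }
  if (k0 >= 2L + exempt) {
    for (i in seq_len(k0 - exempt - 1L)) {
      d <- sqrt(rowSums(.mi(start_beads[(i + exempt + 1L):k0, , drop = FALSE] -
                              matrix(start_beads[i, ], k0 - i - exempt, 3,
                                     byrow = TRUE), boxm)^2))
      if (any(d < cutoff))
        stop("seed positions violate the clash cutoff", call. = FALSE)
    }
  }
  ob <- if (!is.null(obstacles) && NROW(obstacles) > 0)
    matrix(as.numeric(obstacles), ncol = 3)

  clash_free <- function(p, coords, i) {
    if (!is.null(zmin) && is.null(boxm) && p[3] < zmin) return(FALSE)
    jmax <- i - 1L - exempt
    if (jmax >= 1L) {
      d2 <- rowSums(.mi(coords[seq_len(jmax), , drop = FALSE] -
                          matrix(p, jmax, 3, byrow = TRUE), boxm)^2)
      if (any(d2 < cutoff^2)) return(FALSE)
    }
    if (!is.null(ob)) {
      d2 <- rowSums(.mi(ob - matrix(p, nrow(ob), 3, byrow = TRUE), boxm)^2)
      if (any(d2 < cutoff^2)) return(FALSE)
    }
    TRUE
  }

  deepest <- k0
  for (attempt in seq_len(params$max_chain_restarts)) {
    coords <- matrix(NA_real_, n, 3)
    coords[seq_len(k0), ] <- start_beads
    i <- k0 + 1L
    backtracks <- 0L
    failed <- FALSE
    while (i <= n) {
      placed <- FALSE
      for (try in seq_len(params$max_step_retries)) {
        if (i == 2L) {
          p <- coords[1, ] + b * .unit_sphere_sample()
        } else {
          u <- coords[i - 1L, ] - coords[i - 2L, ]
          if (!is.null(boxm)) u <- .mi(matrix(u, 1), boxm)[1, ]
          u <- u / sqrt(sum(u^2))
          basis <- .perp_basis(u)
          phi <- runif(1, 0, 2 * pi)
          p <- coords[i - 1L, ] +
            b * (-ct * u + st * (cos(phi) * basis$e1 + sin(phi) * basis$e2))
        }
        if (clash_free(p, coords, i)) {
          coords[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (placed) {
        if (i > deepest) deepest <- i
        i <- i + 1L
      } else {
        backtracks <- backtracks + 1L
        if (backtracks > params$max_backtracks) { failed <- TRUE; break }
        i <- max(k0 + 1L, i - params$backtrack_depth)
        coords[i:n, ] <- NA_real_
      }
    }
    if (!failed) {
      teth <- NULL
      return(chain_record(chain_id, sequence, coords, tether = teth))
    }
  }
  cond <- structure(
    class = c("fg_growth_failure", "error", "condition"),
    list(message = sprintf(
      "chain growth failed after %d restart(s); deepest residue reached: %d of %d",
      params$max_chain_restarts, deepest, n),
      call = sys.call(-1), deepest_residue = deepest, n_residues = n))
  stop(cond)
}
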