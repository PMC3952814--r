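#' @keywords internal
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters), AA_LETTERS)
  if (length(bad))
    stop("invalid amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  letters
}

#' Deterministic synthetic FG-rich sequence
#'
#' Builds a repeat sequence with FSFG and FG motifs separated by
#' serine/threonine/asparagine/glutamine-rich spacers, mimicking the
#' composition of yeast FG-nucleoporin domains.  The sequence is a fixed
#' (seed-free) tiling so that builders and tests are reproducible without
#' requiring any database download.
#'
#' @param n_residues sequence length (default 609, the length of a typical
#'   full FG domain).
#' @return one-letter amino-acid string of length `n_residues`.
#' @export
#' @examples
#' substr(synthetic_fg_sequence(30), 1, 10)
synthetic_fg_sequence <- function(n_residues = 609L) {
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 1L)
  unit <- "FSFGSANQTSNKFGSPQNTAGA" # FxFG + spacer + FG + spacer, 22 aa
  tiled <- strrep(unit, ceiling(n_residues / nchar(unit)))
  substr(tiled, 1L, n_residues)
}

#' Replace all phenylalanines and glycines by alanines
#'
#' The FG-to-AA mutant transform used to probe the role of FG motifs in
#' assembly: every F and every G becomes A, all other residues are
#' unchanged.
#'
#' @param sequence one-letter amino-acid string.
#' @return mutated sequence of identical length.
#' @export
#' @examples
#' mutate_fg_to_ala("FSFG") # "ASAA"
mutate_fg_to_ala <- function(sequence) {
  .check_sequence(sequence)
  chartr("FG", "AA", sequence)
}

#' Annotate FG and FxFG motifs
#'
#' Left-to-right non-overlapping scan.  An FxFG pattern (F, any, F, G) takes
#' precedence over a plain FG starting at the same position; remaining
#' adjacent F,G pairs are reported as FG.  The motif start index (the first
#' phenylalanine) is 1-based.
#'
#' @param sequence one-letter amino-acid string.
#' @return data.frame with columns `kind` ("FG" or "FxFG"), `start`, `end`.
#' @export
#' @examples
#' annotate_motifs("FSFG")  # one FxFG at 1
#' annotate_motifs("GLFG")  # one FG at 3
annotate_motifs <- function(sequence) {
  s <- .check_sequence(sequence)
  n <- length(s)
  kind <- character(0)
  start <- integer(0)
  i <- 1L
  while (i <= n) {
    if (i + 3L <= n && s[i] == "F" && s[i + 2L] == "F" && s[i + 3L] == "G") {
      kind <- c(kind, "FxFG"); start <- c(start, i); i <- i + 4L
    } else if (i + 1L <= n && s[i] == "F" && s[i + 1L] == "G") {
      kind <- c(kind, "FG"); start <- c(start, i); i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  data.frame(kind = kind, start = start,
             end = start + ifelse(kind == "FxFG", 3L, 1L),
             stringsAsFactors = FALSE)
}
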