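#' @importFrom rlang .data
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a protein sequence object
#'
#' A minimal container for a named amino-acid sequence. Residues are numbered
#' 1-based from the initiator methionine, matching the convention used for
#' residue labels such as L18 or C54 throughout the package.
#'
#' @param id Character label, e.g. an AGI code or \code{"LSU1"}.
#' @param residues One-letter amino-acid string (20-letter alphabet).
#' @return An object of class \code{protein_seq} with fields \code{id} and
#'   \code{residues}.
#' @export
protein_seq <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L)
    stop("sequence '", id, "' is empty", call. = FALSE)
  bad <- which(!strsplit(residues, "")[[1]] %in% AA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "' contains non-amino-acid character at position ",
         bad[1], call. = FALSE)
  structure(list(id = id, residues = residues), class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat("<protein_seq> ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

#' Length of a protein sequence
#' @param x A \code{protein_seq}.
#' @export
length.protein_seq <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order; ids are taken from the header line up
#' to the first whitespace. Sequences are validated against the 20-letter
#' amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A list of \code{protein_seq} objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set))
    out[[i]] <- protein_seq(ids[i], as.character(set[[i]]))
  out
}

#' Write protein sequences to a FASTA file
#' @param seqs List of \code{protein_seq}.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$residues)))
  writeLines(lines, path)
  invisible(path)
}

#' Coiled-coil region of a sequence
#'
#' An inclusive 1-based residue range. The default modeled span for LSU
#' proteins is residues 7--65, covering the predicted coiled-coil region
#' (residues 9--39 are predicted coiled-coil in all four LSUs, with a second,
#' more variable stretch around residues 50--63).
#'
#' @param start First residue (1-based, inclusive).
#' @param end Last residue (1-based, inclusive).
#' @return A \code{coil_region} object.
#' @export
coil_region <- function(start = 7L, end = 65L) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start >= end)
    stop("invalid coil region [", start, ", ", end, "]", call. = FALSE)
  structure(list(start = start, end = end), class = "coil_region")
}

region_length <- function(region) region$end - region$start + 1L

check_region <- function(seq, region) {
  if (region$end > nchar(seq$residues))
    stop("coil region [", region$start, ", ", region$end,
         "] exceeds length of sequence '", seq$id, "' (",
         nchar(seq$residues), ")", call. = FALSE)
  invisible(TRUE)
}

#' Leucine positions of a sequence
#'
#' @param seq A \code{protein_seq}.
#' @return Sorted integer vector of the 1-based positions holding 'L'.
#' @export
leucine_profile <- function(seq) {
  which(seq_chars(seq) == "L")
}

#' Positions conserved across leucine profiles
#'
#' Intersects a set of leucine profiles, yielding the positions at which every
#' protein carries a leucine. For the four Arabidopsis LSU proteins this
#' recovers the seven family-conserved leucines (L18, L29, L53, L57, L60, L65,
#' L78).
#'
#' @param profiles List of integer position vectors (as from
#'   \code{\link{leucine_profile}}).
#' @return Sorted integer vector of shared positions.
#' @export
conserved_positions <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 1L)
    stop("need at least one profile", call. = FALSE)
  sort(Reduce(intersect, profiles))
}

HEPTAD_LETTERS <- letters[1:7]

#' Assign heptad letters over a coil region
#'
#' Labels consecutive residues of the region with the cyclic heptad alphabet
#' a--g, starting at the letter indexed by \code{phase} (0 = 'a'). Positions
#' 'a' and 'd' form the hydrophobic core of a two-stranded coiled coil.
#'
#' @param seq A \code{protein_seq}.
#' @param region A \code{coil_region} valid for \code{seq}.
#' @param phase Integer 0--6; heptad letter of the first region residue.
#' @return Named character vector: names are residue positions, values
#'   heptad letters.
#' @export
assign_heptad <- function(seq, region, phase = 0L) {
  phase <- as.integer(phase)
  if (is.na(phase) || phase < 0L || phase > 6L)
    stop("phase must be an integer in 0..6", call. = FALSE)
  check_region(seq, region)
  idx <- region$start:region$end
  lets <- HEPTAD_LETTERS[((seq_along(idx) - 1L + phase) %% 7L) + 1L]
  stats::setNames(lets, idx)
}

#' Choose the heptad phase placing the most leucines at core positions
#'
#' Brute-forces the seven possible phases and returns the one maximizing the
#' number of region leucines assigned to 'a' or 'd'; ties are broken by the
#' lowest phase index.
#'
#' @inheritParams assign_heptad
#' @return Integer phase in 0..6.
#' @export
auto_phase <- function(seq, region) {
  leu <- leucine_profile(seq)
  leu <- leu[leu >= region$start & leu <= region$end]
  score <- vapply(0:6, function(ph) {
    h <- assign_heptad(seq, region, ph)
    sum(h[as.character(leu)] %in% c("a", "d"))
  }, integer(1))
  which.max(score) - 1L  # which.max returns the first maximum
}
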