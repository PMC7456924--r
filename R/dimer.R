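# Threading of sequence pairs onto a two-helix template over a grid of
# register shifts, leucine-zipper contact scoring, and best-model selection.

HYDROPHOBIC_AA <- c("L", "I", "V", "M", "F")
NEGATIVE_AA <- c("D", "E")
POSITIVE_AA <- c("K", "R")

#' Thread a sequence pair onto a coiled-coil template at a register shift
#'
#' Residue \code{region$start + k} of each sequence occupies template slot
#' \code{k + shift} of its helix (slots are 0-based). Residues shifted past
#' either template end are dropped (overhang truncation); no gaps are ever
#' introduced, so each chain occupies a contiguous run of slots. A model in
#' which fewer than \code{min_placed} residues remain on either helix is
#' degenerate and raises an error.
#'
#' @param seqA,seqB \code{protein_seq} objects for helix A and helix B.
#' @param region \code{coil_region} valid for both sequences.
#' @param template A \code{coiled_coil_template}.
#' @param shiftA,shiftB Integer register shifts (slots) for each helix.
#' @param min_placed Minimum placed residues per helix (default 7, one heptad).
#' @return A \code{dimer_model}: per-chain placement tables (residue position,
#'   amino acid, slot index), the shifts, and \code{delta_shift = shiftA -
#'   shiftB}.
#' @export
thread_dimer <- function(seqA, seqB, region, template,
                         shiftA = 0L, shiftB = 0L, min_placed = 7L) {
  check_region(seqA, region); check_region(seqB, region)
  placements <- function(seq, shift) {
    k <- 0:(region_length(region) - 1L)
    slot <- k + as.integer(shift)
    keep <- slot >= 0L & slot < template$n_slots
    pos <- region$start + k
    data.frame(pos = pos[keep],
               aa = seq_chars(seq)[pos[keep]],
               slot = slot[keep],
               stringsAsFactors = FALSE)
  }
  pa <- placements(seqA, shiftA)
  pb <- placements(seqB, shiftB)
  if (nrow(pa) < min_placed || nrow(pb) < min_placed)
    stop("degenerate model: fewer than ", min_placed,
         " residues placed at shift (", shiftA, ", ", shiftB, ")",
         call. = FALSE)
  structure(list(idA = seqA$id, idB = seqB$id,
                 shiftA = as.integer(shiftA), shiftB = as.integer(shiftB),
                 delta_shift = as.integer(shiftA) - as.integer(shiftB),
                 chainA = pa, chainB = pb,
                 region = region, template = template),
            class = "dimer_model")
}

#' @export
print.dimer_model <- function(x, ...) {
  cat("<dimer_model> ", x$idA, "-", x$idB,
      " shift (", x$shiftA, ", ", x$shiftB, "), delta ", x$delta_shift,
      ", placed ", nrow(x$chainA), "+", nrow(x$chainB), " residues\n", sep = "")
  invisible(x)
}

model_anchor_coords <- function(model, chain = c("A", "B")) {
  chain <- match.arg(chain)
  pl <- if (chain == "A") model$chainA else model$chainB
  model$template$helices[[chain]]$CB[pl$slot + 1L, , drop = FALSE]
}

# contacts between selected slots of the two helices (logical matrix subset)
cross_contacts <- function(template, slotsA, slotsB, cutoff) {
  cbA <- template$helices$A$CB[slotsA + 1L, , drop = FALSE]
  cbB <- template$helices$B$CB[slotsB + 1L, , drop = FALSE]
  if (nrow(cbA) == 0L || nrow(cbB) == 0L)
    return(matrix(FALSE, nrow(cbA), nrow(cbB)))
  d2 <- outer(rowSums(cbA^2), rowSums(cbB^2), "+") - 2 * tcrossprod(cbA, cbB)
  d2 <= cutoff^2 + 1e-9
}

#' Leucine-zipper contact score of a dimer model
#'
#' Counts, over both chains, the leucine residues whose side-chain anchor
#' (CB) lies within \code{cutoff} of the anchor of at least one leucine on
#' the opposite chain -- i.e. the number of leucine side chains that could
#' participate in an intermolecular leucine zipper.
#'
#' @param model A \code{dimer_model}.
#' @param cutoff Anchor-anchor contact distance in Angstrom (default 8.0).
#' @return Non-negative integer score.
#' @export
zipper_score <- function(model, cutoff = 8.0) {
  la <- model$chainA$slot[model$chainA$aa == "L"]
  lb <- model$chainB$slot[model$chainB$aa == "L"]
  if (length(la) == 0L || length(lb) == 0L) return(0L)
  ct <- cross_contacts(model$template, la, lb, cutoff)
  sum(apply(ct, 1, any)) + sum(apply(ct, 2, any))
}

#' Qualitative interface energy proxy of a dimer model
#'
#' A deterministic, explicitly qualitative stand-in for a physics-based
#' interface energy: -1 per intermolecular hydrophobic (L/I/V/M/F)
#' anchor-anchor contact within \code{cutoff}, +0.5 per like-charged and
#' -0.5 per opposite-charged intermolecular anchor contact. Lower is more
#' favorable. The value is a dimensionless heuristic, suitable only for
#' comparing models of the same pair, never as a free energy.
#'
#' @inheritParams zipper_score
#' @return A single numeric value (0 when there are no contacts).
#' @export
interface_energy_proxy <- function(model, cutoff = 8.0) {
  aaA <- model$chainA$aa; aaB <- model$chainB$aa
  ct <- cross_contacts(model$template, model$chainA$slot, model$chainB$slot,
                       cutoff)
  if (!any(ct)) return(0.0)
  idx <- which(ct, arr.ind = TRUE)
  a <- aaA[idx[, 1]]; b <- aaB[idx[, 2]]
  hyd <- a %in% HYDROPHOBIC_AA & b %in% HYDROPHOBIC_AA
  chg <- function(x) ifelse(x %in% NEGATIVE_AA, -1L,
                            ifelse(x %in% POSITIVE_AA, 1L, 0L))
  qa <- chg(a); qb <- chg(b)
  like <- qa != 0L & qa == qb
  opp <- qa != 0L & qb != 0L & qa != qb
  sum(-1 * hyd) + sum(0.5 * like) + sum(-0.5 * opp)
}

#' Scan all register-shift combinations of a sequence pair
#'
#' Threads the pair at every shift combination on the square grid
#' \code{[-half_width, +half_width]^2} (one-residue steps, no gaps) and
#' scores each model by its leucine-zipper contacts. With the default
#' half-width of 25 this evaluates 51 register shifts per helix, 2,601
#' models in total, covering about half a supercoil turn. Shifts at which a
#' chain would retain fewer than \code{min_placed} residues are recorded as
#' \code{-Inf} and excluded from selection.
#'
#' @inheritParams thread_dimer
#' @param half_width Grid half-width W; the grid has (2W+1)^2 cells.
#' @param cutoff Contact distance in Angstrom.
#' @return A \code{shift_grid}: score matrix (rows = shiftA, cols = shiftB,
#'   dimnames give the shifts) plus the pair ids and scan parameters.
#' @export
scan_register_shifts <- function(seqA, seqB, region, template,
                                 half_width = 25L, cutoff = 8.0,
                                 min_placed = 7L) {
  half_width <- as.integer(half_width)
  if (is.na(half_width) || half_width < 0L)
    stop("half_width must be a non-negative integer", call. = FALSE)
  check_region(seqA, region); check_region(seqB, region)
  shifts <- (-half_width):half_width
  L <- region_length(region)

  # per-shift slot occupancy, computed once per helix
  chain_info <- function(seq) {
    ch <- seq_chars(seq)[region$start:region$end]
    leu_k <- which(ch == "L") - 1L       # 0-based offsets of leucines
    lapply(shifts, function(s) {
      slots <- (0:(L - 1L)) + s
      keep <- slots >= 0L & slots < template$n_slots
      lslots <- leu_k + s
      lslots <- lslots[lslots >= 0L & lslots < template$n_slots]
      list(n_placed = sum(keep), leu_slots = lslots)
    })
  }
  infoA <- chain_info(seqA)
  infoB <- chain_info(seqB)

  # all-slot contact matrix, computed once
  all_ct <- cross_contacts(template, 0:(template$n_slots - 1L),
                           0:(template$n_slots - 1L), cutoff)

  score <- matrix(-Inf, length(shifts), length(shifts),
                  dimnames = list(shiftA = shifts, shiftB = shifts))
  for (ia in seq_along(shifts)) {
    a <- infoA[[ia]]
    if (a$n_placed < min_placed) next
    for (ib in seq_along(shifts)) {
      b <- infoB[[ib]]
      if (b$n_placed < min_placed) next
      if (length(a$leu_slots) == 0L || length(b$leu_slots) == 0L) {
        score[ia, ib] <- 0
        next
      }
      ct <- all_ct[a$leu_slots + 1L, b$leu_slots + 1L, drop = FALSE]
      score[ia, ib] <- sum(rowSums(ct) > 0L) + sum(colSums(ct) > 0L)
    }
  }
  structure(list(idA = seqA$id, idB = seqB$id, score = score,
                 half_width = half_width, cutoff = cutoff,
                 region = region, min_placed = min_placed),
            class = "shift_grid")
}

#' @export
print.shift_grid <- function(x, ...) {
  cat("<shift_grid> ", x$idA, "-", x$idB, ", ",
      nrow(x$score), "x", ncol(x$score), " shifts, max score ",
      max(x$score[is.finite(x$score)]), "\n", sep = "")
  invisible(x)
}

#' Number of models evaluated in a shift grid
#' @param grid A \code{shift_grid}.
#' @export
n_models <- function(grid) length(grid$score)

#' Select the best-scoring dimer models from a shift grid
#'
#' Returns every model attaining the maximal zipper score, rebuilt as full
#' \code{dimer_model} objects, ordered deterministically by
#' \code{|delta_shift|} ascending, then \code{shiftA}, then \code{shiftB}.
#' The set of optimal \code{delta_shift} values (the register-shift series,
#' e.g. 0/±4) is attached as attribute \code{"delta_shift_series"}.
#'
#' @param grid A \code{shift_grid}.
#' @param seqA,seqB The sequences that produced the grid.
#' @param template The template that produced the grid.
#' @return List of \code{dimer_model}s, each with a \code{zipper_score} field.
#' @export
select_best <- function(grid, seqA, seqB, template) {
  sc <- grid$score
  if (!any(is.finite(sc)))
    stop("all grid cells are degenerate; nothing to select", call. = FALSE)
  best <- max(sc[is.finite(sc)])
  idx <- which(sc == best, arr.ind = TRUE)
  shifts <- as.integer(rownames(sc))
  sA <- shifts[idx[, 1]]; sB <- shifts[idx[, 2]]
  ord <- order(abs(sA - sB), sA, sB)
  sA <- sA[ord]; sB <- sB[ord]
  models <- lapply(seq_along(sA), function(i) {
    m <- thread_dimer(seqA, seqB, grid$region, template, sA[i], sB[i],
                      grid$min_placed)
    m$zipper_score <- best
    m
  })
  attr(models, "delta_shift_series") <- sort(unique(sA - sB))
  attr(models, "best_score") <- best
  models
}

#' Scan all ordered pairs of a set of monomers
#'
#' Runs \code{\link{scan_register_shifts}} and \code{\link{select_best}} for
#' every ordered pair (including homodimers) of the given sequences -- for
#' the four LSU monomers this is the full set of 16 homo/heterodimers.
#'
#' @param seqs List of \code{protein_seq} (e.g. the four LSU monomers).
#' @inheritParams scan_register_shifts
#' @return A tibble with one row per ordered pair: ids, best zipper score,
#'   number of co-optimal models, optimal shifts of the first model, and the
#'   delta-shift series (list column).
#' @export
scan_all_pairs <- function(seqs, region, template,
                           half_width = 25L, cutoff = 8.0) {
  rows <- list()
  for (a in seq_along(seqs)) {
    for (b in seq_along(seqs)) {
      grid <- scan_register_shifts(seqs[[a]], seqs[[b]], region, template,
                                   half_width, cutoff)
      best <- select_best(grid, seqs[[a]], seqs[[b]], template)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        idA = seqs[[a]]$id, idB = seqs[[b]]$id,
        best_score = attr(best, "best_score"),
        n_best = length(best),
        shiftA = best[[1]]$shiftA, shiftB = best[[1]]$shiftB,
        delta_shift = best[[1]]$delta_shift,
        delta_shift_series = list(attr(best, "delta_shift_series")))
    }
  }
  dplyr::bind_rows(rows)
}

#' Export a shift grid as a TSV matrix
#'
#' Rows are shiftA values, columns shiftB; degenerate cells are written as
#' \code{NA}.
#'
#' @param grid A \code{shift_grid}.
#' @param path Output path.
#' @export
write_shift_grid <- function(grid, path) {
  m <- grid$score
  m[!is.finite(m)] <- NA
  df <- data.frame(shiftA = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a dimer model as a two-chain PDB file
#'
#' Chain A/B ATOM records with N, CA, C, O, CB per placed residue; residue
#' numbers are the original 1-based sequence positions, so labels such as
#' L60 can be located directly in a molecular viewer.
#'
#' @param model A \code{dimer_model} with at least one placed residue per
#'   chain.
#' @param path Output path.
#' @export
write_model_pdb <- function(model, path) {
  if (nrow(model$chainA) == 0L || nrow(model$chainB) == 0L)
    stop("cannot write an empty model", call. = FALSE)
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  lines <- character(0)
  serial <- 0L
  for (chain in c("A", "B")) {
    pl <- if (chain == "A") model$chainA else model$chainB
    hx <- model$template$helices[[chain]]
    for (i in seq_len(nrow(pl))) {
      atoms <- c("N", "CA", "C", "O")
      if (pl$aa[i] != "G") atoms <- c(atoms, "CB")
      for (at in atoms) {
        serial <- serial + 1L
        xyz <- hx[[at]][pl$slot[i] + 1L, ]
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, at, aa3[[pl$aa[i]]], chain, pl$pos[i],
          xyz[1], xyz[2], xyz[3], substr(at, 1, 1)))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write PDB to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
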