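# Ideal two-stranded parallel coiled-coil backbones via the Crick
# parameterization, plus PDB import of experimental two-helix templates.

#' Build an ideal parallel two-helix coiled-coil template
#'
#' Generates backbone (N, CA, C, O) and side-chain anchor (CB) coordinates for
#' two ideal alpha-helices wound left-handed around a common superhelical
#' axis, 180 degrees apart in superhelical phase (Crick parameterization).
#' The template is the geometric scaffold onto which sequence pairs are
#' threaded; it replaces an experimental two-helix structure so that no
#' download is required. Defaults are standard literature values for
#' two-stranded left-handed coiled coils.
#'
#' The CB anchor of each slot is placed radially outward from the local helix
#' axis, beyond the CA, so that slots whose minor-helix phase faces the
#' partner helix (core 'a'/'d' positions) carry anchors near the dimer
#' interface and all other slots point away from it.
#'
#' @param n_slots Number of residue slots per helix (>= 7).
#' @param supercoil_radius Superhelical radius R0 in Angstrom.
#' @param rise_per_residue Axial rise per residue in Angstrom.
#' @param residues_per_turn Residues per alpha-helical turn.
#' @param supercoil_pitch Superhelical pitch in Angstrom (left-handed).
#' @param helix_radius Minor-helix CA radius R1 in Angstrom.
#' @param cb_extension Radial CA-to-CB anchor extension in Angstrom.
#' @param heptad_phase0 Minor-helix phase (radians) of slot 0, measured from
#'   the inward (interface-facing) direction. The default, pi/7 (one half of
#'   the 'a'-to-'d' phase separation), places the 'a' and 'd' core positions
#'   symmetrically either side of the dimer seam.
#' @return A \code{coiled_coil_template}: list with \code{n_slots},
#'   \code{helices} (each a list of per-atom coordinate matrices),
#'   \code{orientation} ("parallel"), and the generating parameters.
#' @export
build_ideal_template <- function(n_slots = 59L,
                                 supercoil_radius = 4.9,
                                 rise_per_residue = 1.51,
                                 residues_per_turn = 3.62,
                                 supercoil_pitch = 150,
                                 helix_radius = 2.26,
                                 cb_extension = 1.5,
                                 heptad_phase0 = pi / 7) {
  n_slots <- as.integer(n_slots)
  if (is.na(n_slots) || n_slots < 7L)
    stop("n_slots must be >= 7", call. = FALSE)
  if (supercoil_radius <= 0 || rise_per_residue <= 0 ||
      residues_per_turn <= 0 || supercoil_pitch <= 0)
    stop("template parameters must be positive", call. = FALSE)

  i <- 0:(n_slots - 1L)
  z <- i * rise_per_residue
  # left-handed superhelix: phase decreases with rising z
  d_omega0 <- -2 * pi * rise_per_residue / supercoil_pitch
  alpha <- atan2(2 * pi * supercoil_radius, supercoil_pitch)
  # minor-helix phase advance in the rotating (interface) frame; the
  # supercoil correction keeps the heptad seam aligned with the interface
  d_omega1 <- 2 * pi / residues_per_turn - d_omega0

  one_helix <- function(phase0) {
    Omega <- phase0 + i * d_omega0
    axis <- cbind(supercoil_radius * cos(Omega),
                  supercoil_radius * sin(Omega), z)
    # Crick coordinates: minor circle tilted by the superhelix crossing
    # angle alpha; w measured from the inward (interface-facing) direction
    crick_point <- function(r) {
      w <- heptad_phase0 + i * d_omega1
      cbind(
        supercoil_radius * cos(Omega) -
          r * (cos(Omega) * cos(w) - cos(alpha) * sin(Omega) * sin(w)),
        supercoil_radius * sin(Omega) -
          r * (sin(Omega) * cos(w) + cos(alpha) * cos(Omega) * sin(w)),
        z - r * sin(alpha) * sin(w))
    }
    ca <- crick_point(helix_radius)
    cb <- crick_point(helix_radius + cb_extension)
    # approximate N and C along the chain direction; O off the C
    nxt <- rbind(ca[-1, , drop = FALSE], 2 * ca[n_slots, ] - ca[n_slots - 1L, ])
    prv <- rbind(2 * ca[1L, ] - ca[2L, ], ca[-n_slots, , drop = FALSE])
    unit <- function(m) m / sqrt(rowSums(m^2))
    n_at <- ca + 1.46 * unit(prv - ca)
    c_at <- ca + 1.52 * unit(nxt - ca)
    o_at <- c_at + 1.23 * unit(c_at - axis)
    list(N = n_at, CA = ca, C = c_at, O = o_at, CB = cb)
  }

  structure(list(
    n_slots = n_slots,
    helices = list(A = one_helix(0), B = one_helix(pi)),
    orientation = "parallel",
    params = list(supercoil_radius = supercoil_radius,
                  rise_per_residue = rise_per_residue,
                  residues_per_turn = residues_per_turn,
                  supercoil_pitch = supercoil_pitch,
                  helix_radius = helix_radius,
                  cb_extension = cb_extension,
                  heptad_phase0 = heptad_phase0)),
    class = "coiled_coil_template")
}

#' @export
print.coiled_coil_template <- function(x, ...) {
  cat("<coiled_coil_template> parallel, ", x$n_slots, " slots/helix\n", sep = "")
  invisible(x)
}

helix_axis_vector <- function(helix) {
  ca <- helix$CA
  v <- ca[nrow(ca), ] - ca[1L, ]
  v / sqrt(sum(v^2))
}

ca_ca_distances <- function(helix) {
  ca <- helix$CA
  sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
}

reconstruct_cb <- function(n_at, ca, c_at) {
  # ideal tetrahedral CB from backbone N/CA/C geometry
  unit <- function(v) v / sqrt(sum(v^2))
  b1 <- unit(n_at - ca)
  b2 <- unit(c_at - ca)
  bisector <- unit(b1 + b2)
  perp <- unit(pracma_cross(b1, b2))
  ca + 1.53 * (-bisector * sin(0.9551) + perp * cos(0.9551))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Load a two-chain coiled-coil template from a PDB file
#'
#' Reads two alpha-helical chains from a PDB structure (e.g. an experimental
#' parallel coiled-coil domain) and converts them into the same template
#' representation produced by \code{\link{build_ideal_template}}. Missing CB
#' atoms (glycine) are reconstructed from backbone geometry. Chains of
#' unequal usable length are truncated to the common length with a warning.
#'
#' @param path Path to a PDB file.
#' @param chainA,chainB Chain identifiers of the two helices.
#' @return A \code{coiled_coil_template}.
#' @export
load_template_pdb <- function(path, chainA = "A", chainB = "B") {
  if (!file.exists(path))
    stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)

  one_chain <- function(ch) {
    sel <- pdb$atom$chain == ch & pdb$atom$type == "ATOM"
    if (!any(sel))
      stop("chain '", ch, "' not found in ", path, call. = FALSE)
    at <- pdb$atom[sel, , drop = FALSE]
    resnos <- sort(unique(at$resno))
    coord <- function(resno, elety) {
      r <- at[at$resno == resno & at$elety == elety, , drop = FALSE]
      if (nrow(r) == 0) return(rep(NA_real_, 3))
      as.numeric(r[1, c("x", "y", "z")])
    }
    mats <- lapply(c("N", "CA", "C", "O", "CB"),
                   function(el) t(vapply(resnos, coord, numeric(3), elety = el)))
    names(mats) <- c("N", "CA", "C", "O", "CB")
    keep <- stats::complete.cases(mats$CA)
    mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
    for (k in which(!stats::complete.cases(mats$CB)))
      mats$CB[k, ] <- reconstruct_cb(mats$N[k, ], mats$CA[k, ], mats$C[k, ])
    gaps <- which(sqrt(rowSums((mats$CA[-1, , drop = FALSE] -
                                mats$CA[-nrow(mats$CA), , drop = FALSE])^2)) > 4.5)
    if (length(gaps))
      stop("chain '", ch, "' has a chain break after residue index ",
           gaps[1], " (CA-CA > 4.5 A)", call. = FALSE)
    mats
  }

  hA <- one_chain(chainA)
  hB <- one_chain(chainB)
  nA <- nrow(hA$CA); nB <- nrow(hB$CA)
  if (nA != nB) {
    warning("chains truncated to common length ", min(nA, nB))
    n <- min(nA, nB)
    hA <- lapply(hA, function(m) m[seq_len(n), , drop = FALSE])
    hB <- lapply(hB, function(m) m[seq_len(n), , drop = FALSE])
  }
  if (sum(helix_axis_vector(hA) * helix_axis_vector(hB)) <= 0)
    stop("template chains are antiparallel; a parallel template is required",
         call. = FALSE)
  structure(list(n_slots = nrow(hA$CA),
                 helices = list(A = hA, B = hB),
                 orientation = "parallel",
                 params = list(source = path)),
            class = "coiled_coil_template")
}
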