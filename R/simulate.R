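# Synthetic-data generation: LSU-like sequences with the family's leucine /
# cysteine / glutamate landmarks, TAP-MS intensity tables with planted
# partners, and interaction networks with planted hubs. Each generator is
# deterministic for a given seed.

#' Leucine landmark positions of the four Arabidopsis LSU proteins
#'
#' Seven leucines (L18, L29, L53, L57, L60, L65, L78) are conserved in all
#' four proteins; L25 is specific to LSU1/LSU3, L37 and L82 to LSU2/LSU4,
#' and L85 is present in LSU1-3. All four carry the conserved E51 and C54.
#'
#' @return Named list of integer position vectors (LSU1..LSU4).
#' @export
lsu_leucine_landmarks <- function() {
  list(LSU1 = c(18L, 25L, 29L, 53L, 57L, 60L, 65L, 78L, 85L),
       LSU2 = c(18L, 29L, 37L, 53L, 57L, 60L, 65L, 78L, 82L, 85L),
       LSU3 = c(18L, 25L, 29L, 53L, 57L, 60L, 65L, 78L, 85L),
       LSU4 = c(18L, 29L, 37L, 53L, 57L, 60L, 65L, 78L, 82L))
}

#' Generate four LSU-like synthetic sequences
#'
#' Builds ~100-residue helical sequences carrying the family's landmark
#' residues: leucine exactly at the per-protein landmark positions, E at 51
#' and C at 54, and an initiator methionine. Background positions are filled
#' with helix-favoring residues; within a +/-4-residue window of any landmark
#' the background is restricted to uncharged residues (A/Q) so that no
#' accidental zipper or helical charge-pair artifacts arise, and no
#' unintended leucine (or other strongly hydrophobic residue) appears
#' anywhere.
#'
#' @param seed Integer random seed (background residue choice only; the
#'   landmarks are fixed).
#' @param length Sequence length (>= 100).
#' @return Named list of four \code{protein_seq} with a \code{"landmarks"}
#'   attribute carrying the leucine manifest.
#' @export
make_lsu_like_sequences <- function(seed = 1L, length = 100L) {
  if (length < 100L) stop("length must be >= 100", call. = FALSE)
  landmarks <- lsu_leucine_landmarks()
  helix_bg <- c("A", "E", "K", "Q", "R")   # helix-favoring background
  neutral_bg <- c("A", "Q")                # near landmarks: uncharged only
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  seqs <- lapply(names(landmarks), function(nm) {
    leu <- landmarks[[nm]]
    fixed <- c(leu, 51L, 54L)
    near <- unique(unlist(lapply(fixed, function(p) (p - 4L):(p + 4L))))
    ch <- character(length)
    for (i in seq_len(length)) {
      pool <- if (i %in% near) neutral_bg else helix_bg
      ch[i] <- sample(pool, 1L)
    }
    ch[1L] <- "M"
    ch[51L] <- "E"
    ch[54L] <- "C"
    ch[leu] <- "L"
    protein_seq(nm, paste(ch, collapse = ""))
  })
  names(seqs) <- names(landmarks)
  attr(seqs, "landmarks") <- landmarks
  seqs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a TAP-MS protein-group intensity table
#'
#' Emulates the study design: four TAP-tagged baits (LSU1-TAP..LSU4-TAP)
#' plus a tag-only control line, each grown under four conditions (4d_nS,
#' 4d-S, 10d_nS, 10d-S), with three biological replicates for LSU1-TAP and
#' the control and two for the other baits. Background proteins have equal
#' expected intensity in probe and control purifications; each bait receives
#' \code{partners_per_bait} planted partners whose probe intensity is
#' multiplied by \code{fold_enrichment} in that bait's datasets.
#' Multiplicative log-normal noise (sd in log10 units) is applied per
#' replicate, followed by independent Bernoulli dropout to zero. Molecular
#' weights are drawn uniformly on 10-150 kDa. Bait proteins themselves are
#' planted as strongly enriched in their own lines.
#'
#' @param seed Integer random seed.
#' @param n_background Number of background (true-ratio-1) proteins.
#' @param partners_per_bait Planted partners per bait.
#' @param fold_enrichment Probe/control intensity ratio of planted partners.
#' @param noise_sd Log-normal noise sd in log10 units.
#' @param dropout Per-replicate probability of an intensity dropping to 0.
#' @param include_baits Also plant the four LSU bait proteins (detected in
#'   their own lines).
#' @return List with \code{table} (tibble: id, mw_kda, one column per
#'   sample), \code{design} (tibble: sample, bait, condition, replicate) and
#'   \code{truth} (tibble: partner id, bait).
#' @export
simulate_tapms <- function(seed = 1L, n_background = 100L,
                           partners_per_bait = 3L, fold_enrichment = 100,
                           noise_sd = 0.2, dropout = 0,
                           include_baits = TRUE) {
  stopifnot(fold_enrichment > 0, noise_sd >= 0, dropout >= 0, dropout <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  baits <- paste0("LSU", 1:4, "-TAP")
  conditions <- c("4d_nS", "4d-S", "10d_nS", "10d-S")
  reps <- c(`LSU1-TAP` = 3L, `LSU2-TAP` = 2L, `LSU3-TAP` = 2L,
            `LSU4-TAP` = 2L, `control-TAP` = 3L)
  design <- dplyr::bind_rows(lapply(names(reps), function(bt)
    tidyr::expand_grid(bait = bt, condition = conditions,
                       replicate = seq_len(reps[[bt]]))))
  design$sample <- paste(design$bait, design$condition, design$replicate,
                         sep = ".")
  design <- design[, c("sample", "bait", "condition", "replicate")]

  ids <- sprintf("BG%03d", seq_len(n_background))
  partner_ids <- sprintf("PART_%s_%d",
                         rep(sub("-TAP$", "", baits), each = partners_per_bait),
                         rep(seq_len(partners_per_bait), times = length(baits)))
  truth <- tibble::tibble(id = partner_ids,
                          bait = rep(baits, each = partners_per_bait))
  all_ids <- c(ids, partner_ids)
  if (include_baits) all_ids <- c(all_ids, sub("-TAP$", "", baits))

  n <- length(all_ids)
  base <- 10^stats::rnorm(n, mean = 6, sd = 0.5)
  mw <- stats::runif(n, 10, 150)

  intens <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(all_ids, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- base
    bt <- design$bait[j]
    if (bt != "control-TAP") {
      planted <- truth$id[truth$bait == bt]
      mu[match(planted, all_ids)] <- mu[match(planted, all_ids)] *
        fold_enrichment
      if (include_baits) {
        # each LSU co-purifies only in its own line (bait at high intensity);
        # the tag-only control and the other lines do not contain it
        self <- sub("-TAP$", "", bt)
        lsu_idx <- match(sub("-TAP$", "", baits), all_ids)
        mu[lsu_idx] <- 0
        mu[match(self, all_ids)] <- base[match(self, all_ids)] * 1000
      }
    } else if (include_baits) {
      mu[match(sub("-TAP$", "", baits), all_ids)] <- 0
    }
    x <- mu * 10^stats::rnorm(n, 0, noise_sd)
    x[mu == 0] <- 0
    if (dropout > 0)
      x[stats::runif(n) < dropout] <- 0
    intens[, j] <- x
  }

  table <- tibble::tibble(id = all_ids, mw_kda = mw) |>
    dplyr::bind_cols(tibble::as_tibble(intens))
  list(table = table, design = design, truth = truth)
}

#' Simulate an interaction network with planted LSU-enriched hubs
#'
#' Builds a simple undirected graph containing the four LSU baits, a
#' designated LSU-partner set (wired to the baits), planted hub nodes wired
#' to partners with probability \code{hub_p_partner} and to background with
#' probability \code{hub_p_background}, and background nodes wired uniformly
#' (Erdos-Renyi) with probability \code{p_background}. Planted hubs thus
#' have a high degree.LSU/degree.total ratio against a low-ratio background.
#'
#' @param seed Integer random seed.
#' @param n_background Number of background nodes.
#' @param n_partners Size of the LSU partner set.
#' @param n_hubs Number of planted hubs.
#' @param hub_p_partner Hub-to-partner attachment probability.
#' @param hub_p_background Hub-to-background attachment probability.
#' @param p_background Background-background attachment probability.
#' @return List with \code{network} (an \code{lsu_network}, see
#'   \code{\link{lsu_network}}) and \code{hubs} (planted hub ids).
#' @export
simulate_network <- function(seed = 1L, n_background = 150L,
                             n_partners = 25L, n_hubs = 5L,
                             hub_p_partner = 0.85, hub_p_background = 0.02,
                             p_background = 0.05) {
  stopifnot(n_partners >= 1L, n_hubs >= 1L,
            hub_p_partner >= 0, hub_p_partner <= 1,
            hub_p_background >= 0, hub_p_background <= 1,
            p_background >= 0, p_background <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  baits <- paste0("LSU", 1:4)
  partners <- sprintf("P%03d", seq_len(n_partners))
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  bg <- sprintf("N%04d", seq_len(n_background))
  nodes <- c(baits, partners, hubs, bg)

  edges <- list()
  add <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)

  # partners define the LSU interactome: each touches >= 1 bait
  for (p in partners)
    for (b in baits)
      if (stats::runif(1) < 0.5) add(b, p)
  for (p in partners) {
    if (!any(vapply(edges, function(e) p %in% e, logical(1))))
      add(sample(baits, 1L), p)
  }
  for (h in hubs) {
    for (p in partners) if (stats::runif(1) < hub_p_partner) add(h, p)
    for (x in bg) if (stats::runif(1) < hub_p_background) add(h, x)
  }
  nb <- length(bg)
  for (i in seq_len(nb - 1L))
    for (j in (i + 1L):nb)
      if (stats::runif(1) < p_background) add(bg[i], bg[j])
  # sprinkle background-partner edges at the background rate
  for (x in bg)
    for (p in partners)
      if (stats::runif(1) < p_background) add(x, p)

  em <- do.call(rbind, edges)
  net <- lsu_network(tibble::tibble(from = em[, 1], to = em[, 2]),
                     baits = baits, partners = partners)
  list(network = net, hubs = hubs)
}
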