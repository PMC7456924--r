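# Semi-quantitative TAP-MS scoring: protein abundance (mean intensity / MW),
# relative specificity (log10 median probe / median control, background 1),
# candidate calling, incidence across bait x condition datasets, and bait
# self-detection reporting.

CONTROL_BAIT <- "control-TAP"

#' Read a protein-group intensity table and its sample design
#'
#' Expects a MaxQuant-proteinGroups-style TSV with an \code{id} column (one
#' or more protein identifiers; ambiguous family groups carry "/" or a
#' trailing "s" in the name), a molecular-weight column \code{mw_kda}, and
#' one intensity column per sample. The design TSV maps every intensity
#' column to (bait, condition, replicate); baits are the four LSU-TAP lines
#' plus \code{control-TAP}. Contaminant and decoy rows (ids prefixed
#' \code{CON__} / \code{REV__}) are dropped with a message.
#'
#' @param path Intensity-table TSV path.
#' @param design_path Design TSV path (columns sample, bait, condition,
#'   replicate).
#' @param drop_prefixes Id prefixes identifying contaminant/decoy rows.
#' @return List with \code{table} and \code{design} tibbles.
#' @export
read_intensity_table <- function(path, design_path,
                                 drop_prefixes = c("CON__", "REV__")) {
  table <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  need <- c("sample", "bait", "condition", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$sample))
    stop("duplicated sample mapping in design: ",
         design$sample[duplicated(design$sample)][1], call. = FALSE)
  if (!all(c("id", "mw_kda") %in% names(table)))
    stop("table must have columns 'id' and 'mw_kda'", call. = FALSE)
  sample_cols <- setdiff(names(table), c("id", "mw_kda"))
  unmapped <- setdiff(sample_cols, design$sample)
  if (length(unmapped))
    stop("intensity column(s) not mapped in design: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  missing <- setdiff(design$sample, sample_cols)
  if (length(missing))
    stop("design sample(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(table$mw_kda) || any(is.na(table$mw_kda)) ||
      any(table$mw_kda <= 0))
    stop("molecular weight must be numeric and positive", call. = FALSE)
  drop <- Reduce(`|`, lapply(drop_prefixes,
                             function(p) startsWith(table$id, p)))
  if (any(drop)) {
    message("dropped ", sum(drop), " contaminant/decoy row(s)")
    table <- table[!drop, , drop = FALSE]
  }
  bad <- vapply(table[sample_cols],
                function(x) !is.numeric(x) || any(x < 0, na.rm = TRUE),
                logical(1))
  if (any(bad))
    stop("non-numeric or negative intensities in column(s): ",
         paste(sample_cols[bad], collapse = ", "), call. = FALSE)
  list(table = table, design = design)
}

#' Protein abundance: mean intensity over replicates divided by MW
#'
#' @param intensities Numeric vector of per-replicate intensities of one
#'   protein in one dataset (zeros are observed non-detections).
#' @param mw_kda Molecular weight in kDa (> 0).
#' @return Abundance in intensity units per kDa.
#' @export
abundance <- function(intensities, mw_kda) {
  stopifnot(mw_kda > 0)
  mean(intensities) / mw_kda
}

#' Relative specificity: log10 median probe over median control
#'
#' The statistic used to call candidate partners from TAP-MS data:
#' \code{log10(median(probe) / median(control))}, where undetected
#' replicates enter the median as observed zeros and the control median is
#' replaced by the arbitrary background level 1 when the protein is not
#' detected in the control (median 0). A protein undetected in every probe
#' replicate has no defined specificity and returns \code{NA} (the
#' "not detected" sentinel; never a candidate).
#'
#' @param probe Numeric vector of probe (bait-line) replicate intensities.
#' @param control Numeric vector of control-line replicate intensities.
#' @return Relative specificity in log10 units, or \code{NA_real_}.
#' @export
relative_specificity <- function(probe, control) {
  if (length(probe) < 1L)
    stop("need at least one probe replicate", call. = FALSE)
  mp <- stats::median(probe)
  if (mp <= 0 || all(probe == 0)) return(NA_real_)
  mc <- stats::median(control)
  if (!length(control) || is.na(mc) || mc <= 0) mc <- 1
  log10(mp / mc)
}

#' Score all protein groups and call candidate partners
#'
#' For every protein group and every (bait, condition) dataset, computes the
#' abundance and relative specificity against the same-condition control
#' purification, and calls the group a candidate partner when its relative
#' specificity strictly exceeds \code{threshold} (default 1, i.e. a
#' ten-fold-plus median enrichment over background). Detections of an LSU
#' protein in its own bait line are reported but flagged as bait, not
#' candidate partners.
#'
#' @param table,design As returned by \code{\link{read_intensity_table}} or
#'   \code{\link{simulate_tapms}}.
#' @param threshold Candidate threshold in log10 units (strict inequality).
#' @param lsu_ids Ids of the LSU proteins themselves (for bait flagging);
#'   groups matching \code{<bait id>} of the dataset's bait line are flagged.
#' @return Tibble with one row per (id, bait, condition): abundance,
#'   relative_specificity, candidate, is_bait.
#' @export
call_candidates <- function(table, design, threshold = 1.0,
                            lsu_ids = paste0("LSU", 1:4)) {
  probe_design <- design[design$bait != CONTROL_BAIT, , drop = FALSE]
  datasets <- unique(probe_design[, c("bait", "condition")])
  control_design <- design[design$bait == CONTROL_BAIT, , drop = FALSE]

  long <- list()
  ids <- table$id
  mw <- table$mw_kda
  for (d in seq_len(nrow(datasets))) {
    bt <- datasets$bait[d]; cond <- datasets$condition[d]
    probe_cols <- probe_design$sample[probe_design$bait == bt &
                                      probe_design$condition == cond]
    control_cols <- control_design$sample[control_design$condition == cond]
    pm <- as.matrix(table[, probe_cols, drop = FALSE])
    cm <- as.matrix(table[, control_cols, drop = FALSE])
    rs <- vapply(seq_along(ids), function(i)
      relative_specificity(pm[i, ], cm[i, ]), numeric(1))
    ab <- rowMeans(pm) / mw
    bait_lsu <- sub("-TAP$", "", bt)
    is_bait <- vapply(ids, function(x)
      bait_lsu %in% expand_group_ids(x, lsu_ids), logical(1))
    long[[d]] <- tibble::tibble(
      id = ids, bait = bt, condition = cond,
      abundance = ab, relative_specificity = rs,
      is_bait = unname(is_bait),
      candidate = !is.na(rs) & rs > threshold & !is_bait)
  }
  dplyr::bind_rows(long)
}

# ambiguous protein-group names: "LSU2/LSU4" covers both; a trailing "s"
# marks an unresolved family (expanded only against the provided id list)
expand_group_ids <- function(id, known_ids = character(0)) {
  parts <- strsplit(id, "/", fixed = TRUE)[[1]]
  out <- parts
  for (p in parts) {
    if (grepl("s$", p)) {
      stem <- sub("s$", "", p)
      hits <- known_ids[startsWith(known_ids, stem)]
      if (length(hits)) out <- c(out, hits)
    }
  }
  unique(out)
}

#' Candidate incidence across the 16 bait-by-condition datasets
#'
#' Counts, per protein group, the number of (bait, condition) datasets in
#' which it was called a candidate partner -- the incidence rate over the
#' study's 4 baits x 4 conditions = 16 biological sample sets. Bait
#' self-detections are excluded from partner incidence and summarized
#' separately.
#'
#' @param records Tibble from \code{\link{call_candidates}}.
#' @return List with \code{partners} (tibble id, incidence, per-bait
#'   breakdown columns, descending incidence), \code{baits} (tibble of bait
#'   self-detection counts) and \code{n_datasets}.
#' @export
incidence <- function(records) {
  datasets <- unique(records[, c("bait", "condition")])
  partners <- records |>
    dplyr::filter(!.data$is_bait) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(incidence = sum(.data$candidate), .groups = "drop")
  per_bait <- records |>
    dplyr::filter(!.data$is_bait) |>
    dplyr::group_by(.data$id, .data$bait) |>
    dplyr::summarise(n = sum(.data$candidate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "bait", values_from = "n",
                       values_fill = 0L)
  partners <- dplyr::left_join(partners, per_bait, by = "id") |>
    dplyr::filter(.data$incidence > 0L) |>
    dplyr::arrange(dplyr::desc(.data$incidence), .data$id)
  baits <- records |>
    dplyr::filter(.data$is_bait) |>
    dplyr::group_by(.data$id, .data$bait) |>
    dplyr::summarise(
      n_detected = sum(!is.na(.data$relative_specificity)),
      .groups = "drop")
  list(partners = partners, baits = baits, n_datasets = nrow(datasets))
}

#' Which LSU proteins were detected in which bait line and condition
#'
#' Reports, per bait line and condition, the LSU ids detected (intensity > 0
#' in at least one replicate). Ambiguous groups such as "LSU2/LSU4" are
#' listed under every member with an ambiguity flag.
#'
#' @param table,design As for \code{\link{call_candidates}}.
#' @param lsu_ids Ids of the four LSU proteins.
#' @return Tibble (bait, condition, lsu, group_id, ambiguous); zero rows if
#'   nothing is detected.
#' @export
bait_detection_report <- function(table, design,
                                  lsu_ids = paste0("LSU", 1:4)) {
  lsu_rows <- which(vapply(table$id, function(x)
    any(expand_group_ids(x, lsu_ids) %in% lsu_ids), logical(1)))
  probe_design <- design[design$bait != CONTROL_BAIT, , drop = FALSE]
  datasets <- unique(probe_design[, c("bait", "condition")])
  out <- list()
  for (d in seq_len(nrow(datasets))) {
    bt <- datasets$bait[d]; cond <- datasets$condition[d]
    cols <- probe_design$sample[probe_design$bait == bt &
                                probe_design$condition == cond]
    for (r in lsu_rows) {
      vals <- as.numeric(table[r, cols])
      if (!any(vals > 0)) next
      members <- intersect(expand_group_ids(table$id[r], lsu_ids), lsu_ids)
      out[[length(out) + 1L]] <- tibble::tibble(
        bait = bt, condition = cond, lsu = members,
        group_id = table$id[r], ambiguous = length(members) > 1L)
    }
  }
  if (!length(out))
    return(tibble::tibble(bait = character(0), condition = character(0),
                          lsu = character(0), group_id = character(0),
                          ambiguous = logical(0)))
  dplyr::bind_rows(out)
}
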