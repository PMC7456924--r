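# LSU interaction-network construction and hub-enrichment analysis:
# degree.LSU / degree.total ratios, hub ranking, and multi-hub membership.

#' Construct an LSU interaction network
#'
#' Wraps an undirected simple igraph graph together with two designated node
#' sets: the four LSU baits and the LSU partner set (direct LSU interactors,
#' "the LSU interactome"). Self-loops and duplicate edges (in either
#' orientation) are collapsed; the counts removed are reported via
#' \code{message}.
#'
#' @param edges Two-column data frame (from, to) of undirected edges.
#' @param baits Character vector of LSU bait node ids.
#' @param partners Character vector of LSU partner node ids; must be disjoint
#'   from \code{baits}.
#' @return An \code{lsu_network}: list with \code{graph} (igraph),
#'   \code{baits}, \code{partners}.
#' @export
lsu_network <- function(edges, baits = character(0), partners = character(0)) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (length(intersect(baits, partners)))
    stop("baits and partners must be disjoint", call. = FALSE)
  em <- as.matrix(edges[, 1:2])
  mode(em) <- "character"
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    em <- em[!loops, , drop = FALSE]
  }
  key <- apply(em, 1, function(r) paste(sort(r), collapse = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge(s)")
    em <- em[!dup, , drop = FALSE]
  }
  nodes <- unique(c(em[, 1], em[, 2], baits, partners))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2]),
    directed = FALSE, vertices = data.frame(name = nodes))
  structure(list(graph = g, baits = baits, partners = partners),
            class = "lsu_network")
}

#' @export
print.lsu_network <- function(x, ...) {
  cat("<lsu_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges; ",
      length(x$baits), " baits, ", length(x$partners), " partners\n", sep = "")
  invisible(x)
}

#' Read an interaction network from an edge-list file
#'
#' Accepts a two-column TSV (with or without header) or a SIF file
#' (\code{node relation node}). Optional one-id-per-line files designate the
#' LSU bait and partner sets.
#'
#' @param path Edge-list path.
#' @param baits_path,partners_path Optional node-set files.
#' @return An \code{lsu_network}.
#' @export
read_edge_list <- function(path, baits_path = NULL, partners_path = NULL) {
  if (!file.exists(path))
    stop("cannot read edge list: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first_fields <- strsplit(if (length(lines)) lines[1] else "", "\t")[[1]]
  header <- length(first_fields) >= 2L &&
    any(tolower(first_fields[1:2]) %in% c("from", "to", "source", "target"))
  if (header) lines <- lines[-1]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) == 2L) return(f)
    if (length(f) == 3L) return(f[c(1, 3)])  # SIF: node relation node
    stop("malformed edge row at line ", i + header, " of ", path,
         call. = FALSE)
  })
  em <- do.call(rbind, rows)
  edges <- if (is.null(em)) tibble::tibble(from = character(0),
                                           to = character(0))
  else tibble::tibble(from = em[, 1], to = em[, 2])
  read_set <- function(p) if (is.null(p)) character(0)
  else trimws(readLines(p))[nzchar(trimws(readLines(p)))]
  lsu_network(edges, baits = read_set(baits_path),
              partners = read_set(partners_path))
}

#' Per-node hub scores: degree.total, degree.LSU, and their ratio
#'
#' For every non-isolated node that is not itself an LSU bait, counts its
#' total neighbors (\code{degree_total}), its neighbors inside the LSU
#' partner set (\code{degree_lsu}), and their ratio -- the enrichment of the
#' node's neighborhood in LSU-interactome members.
#'
#' @param net An \code{lsu_network}.
#' @return Tibble (id, degree_total, degree_lsu, ratio), ordered by id.
#' @export
hub_scores <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0L)
    stop("empty network", call. = FALSE)
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  keep <- deg > 0L & !(ids %in% net$baits)
  partner_set <- net$partners
  dlsu <- vapply(which(keep), function(v) {
    nb <- igraph::neighbors(g, v)$name
    sum(unique(nb) %in% partner_set)
  }, integer(1))
  out <- tibble::tibble(id = ids[keep],
                        degree_total = unname(as.integer(deg[keep])),
                        degree_lsu = unname(dlsu))
  out$ratio <- out$degree_lsu / out$degree_total
  dplyr::arrange(out, .data$id)
}

#' Rank LSU-enriched hubs
#'
#' Filters hub scores to nodes with \code{degree_lsu >= min_degree_lsu},
#' selects the top \code{k} by ratio (ties at the boundary broken by higher
#' \code{degree_lsu}, then by id), and orders the selection by
#' \code{degree_lsu} descending with ties broken by id -- matching the
#' convention of selecting hubs by LSU-interactome enrichment but listing
#' them by their LSU degree.
#'
#' @param scores Tibble from \code{\link{hub_scores}}.
#' @param k Number of hubs to select (default 9).
#' @param min_degree_lsu Minimum LSU-degree to be hub-eligible (default 10).
#' @param by Ranking criterion for selection: \code{"ratio"} (default),
#'   \code{"degree_lsu"}.
#' @return Tibble of at most \code{k} rows in reporting order.
#' @export
rank_hubs <- function(scores, k = 9L, min_degree_lsu = 10L,
                      by = c("ratio", "degree_lsu")) {
  by <- match.arg(by)
  stopifnot(k >= 1L)
  elig <- dplyr::filter(scores, .data$degree_lsu >= min_degree_lsu)
  sel <- if (by == "ratio")
    dplyr::arrange(elig, dplyr::desc(.data$ratio),
                   dplyr::desc(.data$degree_lsu), .data$id)
  else
    dplyr::arrange(elig, dplyr::desc(.data$degree_lsu),
                   dplyr::desc(.data$ratio), .data$id)
  sel <- utils::head(sel, k)
  dplyr::arrange(sel, dplyr::desc(.data$degree_lsu), .data$id)
}

#' Count, per LSU partner, how many selected hubs it touches
#'
#' @param net An \code{lsu_network}.
#' @param hubs Character vector of selected hub ids (must be network nodes).
#' @return Tibble (id, n_hubs) over the LSU partner set, descending counts.
#' @export
hub_membership_counts <- function(net, hubs) {
  g <- net$graph
  ids <- igraph::V(g)$name
  if (!all(hubs %in% ids))
    stop("unknown hub id(s): ",
         paste(setdiff(hubs, ids), collapse = ", "), call. = FALSE)
  counts <- vapply(net$partners, function(p) {
    if (!p %in% ids) return(0L)
    nb <- igraph::neighbors(g, p)$name
    sum(hubs %in% nb)
  }, integer(1))
  out <- tibble::tibble(id = net$partners, n_hubs = unname(counts))
  dplyr::arrange(out, dplyr::desc(.data$n_hubs), .data$id)
}

#' Export a network with hub-score node attributes
#'
#' Writes GraphML (with degree_total / degree_lsu / ratio node attributes,
#' loadable by Cytoscape) and a SIF file alongside it.
#'
#' @param net An \code{lsu_network}.
#' @param scores Tibble from \code{\link{hub_scores}}.
#' @param path Output path for the GraphML file; the SIF file takes the same
#'   path with extension \code{.sif}.
#' @export
export_network <- function(net, scores, path) {
  g <- net$graph
  ids <- igraph::V(g)$name
  m <- match(ids, scores$id)
  g <- igraph::set_vertex_attr(g, "degree_total",
                               value = scores$degree_total[m])
  g <- igraph::set_vertex_attr(g, "degree_lsu", value = scores$degree_lsu[m])
  g <- igraph::set_vertex_attr(g, "ratio", value = scores$ratio[m])
  igraph::write_graph(g, path, format = "graphml")
  sif <- sub("\\.[^.]*$", ".sif", path)
  if (identical(sif, path)) sif <- paste0(path, ".sif")
  em <- igraph::as_edgelist(g)
  writeLines(if (nrow(em)) paste(em[, 1], "pp", em[, 2]) else character(0),
             sif)
  invisible(c(graphml = path, sif = sif))
}
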