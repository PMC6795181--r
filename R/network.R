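# Protein-protein interaction network handling: STRING-style edge-list
# parsing, combined-score filtering, DEG-seeded subnetwork extraction, and
# inter-set edge counting. Networks are undirected igraph objects with an
# integer `combined_score` edge attribute.

#' Read a STRING-style edge list
#'
#' Expects a TSV with header columns `protein1`, `protein2`,
#' `combined_score`. Duplicate unordered pairs are collapsed keeping the
#' maximum score; self-loops are dropped with a warning. Nodes appearing only
#' in dropped self-loops are excluded.
#'
#' @param path path to the TSV file.
#' @return An undirected igraph with edge attribute `combined_score`.
#' @export
read_edges <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("edge list ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  score_num <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score_num) | score_num != round(score_num))
  if (length(bad)) {
    stop("non-integer combined_score in ", path, " at data line(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  edge_network(data.frame(protein1 = df$protein1, protein2 = df$protein2,
                          combined_score = as.integer(score_num)))
}

#' Build an interaction network from an edge data.frame
#'
#' Applies the same cleaning rules as [read_edges()]: self-loops dropped
#' with a warning, duplicate unordered pairs collapsed keeping the maximum
#' combined score.
#'
#' @param edges data.frame with `protein1`, `protein2`, `combined_score`.
#' @param vertices optional character vector of vertex names to include even
#'   when isolated.
#' @return An undirected igraph with edge attribute `combined_score`.
#' @export
edge_network <- function(edges, vertices = NULL) {
  self <- edges$protein1 == edges$protein2
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from edge list")
    edges <- edges[!self, , drop = FALSE]
  }
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -edges$combined_score)
  first <- !duplicated(key[o])
  clean <- data.frame(protein1 = a[o][first], protein2 = b[o][first],
                      combined_score = edges$combined_score[o][first])
  vnames <- sort(unique(c(clean$protein1, clean$protein2, vertices)))
  igraph::graph_from_data_frame(clean, directed = FALSE,
                                vertices = data.frame(name = vnames))
}

#' Filter a network by combined score
#'
#' Keeps edges with `combined_score >= min_score` (inclusive) and drops
#' nodes left without any edge.
#'
#' @param net igraph with `combined_score` edge attribute.
#' @param min_score inclusive score threshold.
#' @return Filtered igraph.
#' @export
filter_by_score <- function(net, min_score = 900L) {
  keep <- igraph::E(net)[igraph::E(net)$combined_score >= min_score]
  sub <- igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
  igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
}

#' Seed-gene subnetwork (seeds plus their direct interactors)
#'
#' Node set = (seeds found in the network) plus all their direct neighbors;
#' edge set = the induced subgraph on that node set, so interactor-interactor
#' edges among retained nodes are included.
#'
#' @param net igraph network.
#' @param seeds character vector of seed gene ids; seeds absent from the
#'   network are counted and logged.
#' @param verbose emit log messages.
#' @return Induced igraph subgraph.
#' @export
seed_subnetwork <- function(net, seeds, verbose = TRUE) {
  vn <- igraph::V(net)$name
  present <- intersect(unique(seeds), vn)
  absent <- length(unique(seeds)) - length(present)
  if (absent > 0) {
    cx_log("seed_subnetwork: ", absent, " seed(s) not in the network",
           verbose = verbose)
  }
  if (length(present) == 0L) {
    stop("no seed gene is present in the network; nothing to build")
  }
  nb_idx <- unique(unlist(igraph::adjacent_vertices(net, present)))
  nodes <- union(present, vn[nb_idx])
  igraph::induced_subgraph(net, nodes)
}

#' Count edges between two gene sets
#'
#' Number of distinct network edges with one endpoint in `set_a` and the
#' other in `set_b`; each qualifying edge is counted exactly once even when
#' both endpoints lie in the intersection of the sets.
#'
#' @param net igraph network.
#' @param set_a,set_b character vectors of gene ids.
#' @return Non-negative integer.
#' @export
inter_set_edge_count <- function(net, set_a, set_b) {
  e <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(e) == 0L) return(0L)
  u <- e[, 1]; v <- e[, 2]
  ua <- u %in% set_a; ub <- u %in% set_b
  va <- v %in% set_a; vb <- v %in% set_b
  sum((ua & vb) | (ub & va))
}

#' Write a network as a STRING-style TSV edge list
#' @param net igraph with `combined_score` edge attribute.
#' @param path output path.
#' @param comments optional `#` header comments.
#' @export
write_edges <- function(net, path, comments = NULL) {
  e <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(protein1 = e[, 1], protein2 = e[, 2],
                   combined_score = igraph::E(net)$combined_score)
  write_tsv(df, path, comments)
}
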