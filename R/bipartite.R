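#' Binary bipartite graph
#'
#' Container for a binary bipartite network described by its biadjacency
#' matrix. Nodes are split into two layers, conventionally called *top* and
#' *bottom*; links only run between layers. The degree of a top node is its
#' row sum, the degree of a bottom node its column sum.
#'
#' @param biadjacency numeric matrix with entries in \{0, 1\}; rows are top
#'   nodes, columns bottom nodes. Dimnames, when present, become node ids.
#' @param top_nodes,bottom_nodes optional character vectors of node ids,
#'   overriding the dimnames.
#' @return An object of class `bipartite_graph`: a list with elements
#'   `top_nodes`, `bottom_nodes`, `biadjacency` (0/1 matrix), `k` (top degree
#'   sequence) and `h` (bottom degree sequence).
#' @examples
#' B <- matrix(c(1, 0, 0, 1), 2, 2)
#' g <- bipartite_graph(B)
#' g$k
#' @export
bipartite_graph <- function(biadjacency, top_nodes = NULL, bottom_nodes = NULL) {
  B <- as.matrix(biadjacency)
  if (!all(B %in% c(0, 1))) {
    stop("biadjacency must be binary (entries 0 or 1)")
  }
  storage.mode(B) <- "double"
  if (is.null(top_nodes)) {
    top_nodes <- rownames(B)
    if (is.null(top_nodes)) top_nodes <- paste0("t", seq_len(nrow(B)))
  }
  if (is.null(bottom_nodes)) {
    bottom_nodes <- colnames(B)
    if (is.null(bottom_nodes)) bottom_nodes <- paste0("b", seq_len(ncol(B)))
  }
  stopifnot(length(top_nodes) == nrow(B), length(bottom_nodes) == ncol(B))
  if (anyDuplicated(top_nodes) || anyDuplicated(bottom_nodes)) {
    stop("node ids must be unique within each layer")
  }
  dimnames(B) <- list(top_nodes, bottom_nodes)
  structure(
    list(
      top_nodes = as.character(top_nodes),
      bottom_nodes = as.character(bottom_nodes),
      biadjacency = B,
      k = rowSums(B),
      h = colSums(B)
    ),
    class = "bipartite_graph"
  )
}

#' Build a bipartite graph from an edge list
#'
#' @param top,bottom character vectors of equal length: one (top, bottom)
#'   pair per link. Repeated pairs collapse to a single binary link.
#' @param top_nodes,bottom_nodes optional full node universes (so that
#'   degree-0 nodes can be represented).
#' @return A [bipartite_graph()].
#' @export
bipartite_from_edges <- function(top, bottom, top_nodes = NULL, bottom_nodes = NULL) {
  stopifnot(length(top) == length(bottom))
  top <- as.character(top)
  bottom <- as.character(bottom)
  if (is.null(top_nodes)) top_nodes <- sort(unique(top))
  if (is.null(bottom_nodes)) bottom_nodes <- sort(unique(bottom))
  if (!all(top %in% top_nodes) || !all(bottom %in% bottom_nodes)) {
    stop("edge endpoints outside the declared node universes")
  }
  B <- matrix(0, length(top_nodes), length(bottom_nodes),
              dimnames = list(top_nodes, bottom_nodes))
  B[cbind(match(top, top_nodes), match(bottom, bottom_nodes))] <- 1
  bipartite_graph(B)
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "bipartite_graph: %d top x %d bottom nodes, %d links\n",
    length(x$top_nodes), length(x$bottom_nodes), sum(x$k)
  ))
  invisible(x)
}

#' Read a bipartite graph from a sparse triplet CSV
#'
#' The file must have (at least) columns `top_id` and `bottom_id`, one row
#' per link.
#'
#' @param path file path.
#' @return A [bipartite_graph()].
#' @export
read_bipartite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("top_id", "bottom_id") %in% names(df))) {
    stop("bipartite CSV needs columns top_id, bottom_id")
  }
  bipartite_from_edges(df$top_id, df$bottom_id)
}

#' Write a bipartite graph as a sparse triplet CSV
#'
#' @param g a [bipartite_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bipartite_csv <- function(g, path) {
  idx <- which(g$biadjacency == 1, arr.ind = TRUE)
  df <- data.frame(
    top_id = g$top_nodes[idx[, 1]],
    bottom_id = g$bottom_nodes[idx[, 2]],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$top_id, df$bottom_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
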