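#' Construct an interactome
#'
#' An interactome is an unweighted protein-protein / signalling network:
#' a set of node identifiers plus a set of edges, each optionally carrying
#' a direction flag (signalling resources mix directed and undirected
#' interactions).  On construction self-loops are removed, undirected
#' edges are stored once under a canonical endpoint ordering, and
#' duplicates are collapsed with a union-of-flags policy: if any record of
#' an unordered pair is directed, the pair is kept as its directed
#' record(s) (reciprocal directed edges are both retained); otherwise a
#' single undirected record is kept.
#'
#' @param edges data.frame with columns `from`, `to` and optionally a
#'   logical `directed` (default `FALSE`).
#' @param resource short label naming the source resource.
#' @param nodes optional character vector of additional (possibly
#'   isolated) node identifiers; the node set is the union of these and
#'   all edge endpoints.
#' @return An object of class `interactome`: a list with elements
#'   `resource` (character), `nodes` (character vector) and `edges`
#'   (data.frame `from`, `to`, `directed`).  The number of dropped
#'   self-loops is recorded in attribute `n_self_loops`.
#' @examples
#' net <- interactome(data.frame(from = c("A", "B"), to = c("B", "A")))
#' n_edges(net)  # 1: the two records are the same undirected edge
#' @export
interactome <- function(edges, resource = "interactome", nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges)))
    stop("`edges` must have columns `from` and `to`")
  if (nrow(edges) == 0)
    edges <- data.frame(from = character(), to = character(),
                        directed = logical())
  from <- as.character(edges$from)
  to   <- as.character(edges$to)
  if (any(!nzchar(from)) || any(!nzchar(to)) || anyNA(from) || anyNA(to))
    stop("node identifiers must be non-empty strings")
  directed <- if ("directed" %in% names(edges)) as.logical(edges$directed)
              else rep(FALSE, nrow(edges))
  directed[is.na(directed)] <- FALSE

  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]; to <- to[!loops]; directed <- directed[!loops]

  # canonical unordered key per record
  key <- ifelse(from < to, paste(from, to, sep = "\r"),
                paste(to, from, sep = "\r"))
  keep_from <- character(0); keep_to <- character(0); keep_dir <- logical(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (any(directed[idx])) {
      d <- idx[directed[idx]]
      ori <- !duplicated(paste(from[d], to[d], sep = "\r"))
      keep_from <- c(keep_from, from[d][ori])
      keep_to   <- c(keep_to, to[d][ori])
      keep_dir  <- c(keep_dir, rep(TRUE, sum(ori)))
    } else {
      i <- idx[1L]
      a <- min(from[i], to[i]); b <- max(from[i], to[i])
      keep_from <- c(keep_from, a); keep_to <- c(keep_to, b)
      keep_dir  <- c(keep_dir, FALSE)
    }
  }
  out_edges <- data.frame(from = keep_from, to = keep_to,
                          directed = keep_dir, stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(out_edges$from, out_edges$to,
                             as.character(nodes %||% character(0)))))
  structure(
    list(resource = resource, nodes = all_nodes, edges = out_edges),
    n_self_loops = n_loops,
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %s: %d nodes, %d edges (%d directed)\n",
              x$resource, length(x$nodes), nrow(x$edges),
              sum(x$edges$directed)))
  invisible(x)
}

#' Number of nodes / edges of a network object
#'
#' @param x an `interactome` or `tissue_network`.
#' @return integer count.
#' @export
n_nodes <- function(x) UseMethod("n_nodes")
#' @export
n_nodes.interactome <- function(x) length(x$nodes)
#' @export
n_nodes.tissue_network <- function(x) length(x$interactome$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(x) UseMethod("n_edges")
#' @export
n_edges.interactome <- function(x) nrow(x$edges)
#' @export
n_edges.tissue_network <- function(x) nrow(x$interactome$edges)

#' Convert a network object to an igraph graph
#'
#' All topology metrics are measured without taking edge direction into
#' account, so the default conversion is an undirected simple graph
#' (reciprocal directed records collapse to one undirected edge).
#'
#' @param x an `interactome` or `tissue_network`.
#' @param directed if `TRUE`, return a directed graph in which undirected
#'   records appear as reciprocal arc pairs (used for influencer
#'   detection).
#' @return an `igraph` object whose vertex names are the node identifiers.
#' @export
as_igraph <- function(x, directed = FALSE) UseMethod("as_igraph")

#' @export
as_igraph.interactome <- function(x, directed = FALSE) {
  e <- x$edges
  if (!directed) {
    g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = x$nodes)
    return(igraph::simplify(g, remove.multiple = TRUE,
                            remove.loops = TRUE))
  }
  und <- e[!e$directed, , drop = FALSE]
  dir <- e[e$directed, , drop = FALSE]
  arcs <- rbind(dir[, c("from", "to")],
                und[, c("from", "to")],
                data.frame(from = und$to, to = und$from))
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = x$nodes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' @export
as_igraph.tissue_network <- function(x, directed = FALSE)
  as_igraph(x$interactome, directed = directed)

# adjacency list (undirected) as named list of character vectors
adjacency_list <- function(x) {
  g <- as_igraph(x, directed = FALSE)
  adj <- igraph::as_adj_list(g, mode = "all")
  nm <- igraph::V(g)$name
  out <- lapply(adj, function(v) nm[as.integer(v)])
  names(out) <- nm
  out
}

# undirected one-step neighbourhood of `seed` nodes, seeds excluded
neighbour_set <- function(x, seeds) {
  g <- as_igraph(x, directed = FALSE)
  seeds <- intersect(seeds, igraph::V(g)$name)
  if (length(seeds) == 0) return(character(0))
  nb <- igraph::adjacent_vertices(g, v = seeds, mode = "all")
  nm <- igraph::V(g)$name
  setdiff(unique(nm[unlist(lapply(nb, as.integer))]), seeds)
}
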