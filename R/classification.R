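#' Classify network proteins into cancer-related / first-neighbour /
#' unaffected
#'
#' A protein is *cancer-related* when its gene is mutated in the given
#' cancer type and/or binary-differentially expressed; a *first
#' neighbour* directly interacts with at least one cancer-related protein
#' without being cancer-related itself (a DE protein adjacent to a
#' mutated one stays cancer-related only); everything else is
#' *unaffected*.  Edge direction is ignored for adjacency.
#'
#' @param network a [build_tissue_network()] result or an
#'   [interactome()].
#' @param mutated character vector of mutated gene identifiers.
#' @param de character vector of differentially expressed gene
#'   identifiers (e.g. from [call_differential_expression()]).
#' @return object of class `classification`: data.frame `(node, class,
#'   is_mutated, is_de)` whose classes partition the network node set,
#'   with attributes `resource` and (after [find_influencers()])
#'   `influencers`.
#' @examples
#' net <- interactome(data.frame(from = c("A", "B", "C"),
#'                               to = c("B", "C", "D")))
#' cl <- classify(net, mutated = "A", de = character(0))
#' table(cl$class)
#' @export
classify <- function(network, mutated, de = character(0)) {
  nodes <- if (inherits(network, "tissue_network"))
    network$interactome$nodes else network$nodes
  mutated <- unique(as.character(mutated))
  de <- unique(as.character(de))
  outside <- setdiff(c(mutated, de), nodes)
  if (length(outside))
    message(length(outside),
            " seed identifier(s) outside the network ignored")
  cr <- intersect(union(mutated, de), nodes)
  if (length(cr) == 0)
    stop("empty seed set: no mutated or differentially expressed gene is in the network")
  fn <- setdiff(neighbour_set(network, cr), cr)
  ua <- setdiff(nodes, union(cr, fn))
  cls <- rep("unaffected", length(nodes))
  names(cls) <- nodes
  cls[fn] <- "first_neighbour"
  cls[cr] <- "cancer_related"
  out <- data.frame(node = nodes, class = unname(cls[nodes]),
                    is_mutated = nodes %in% mutated & nodes %in% cr,
                    is_de = nodes %in% de & nodes %in% cr,
                    stringsAsFactors = FALSE)
  structure(out, class = c("classification", "data.frame"),
            resource = if (inherits(network, "tissue_network"))
              network$interactome$resource else network$resource)
}

class_nodes <- function(classification, label)
  classification$node[classification$class == label]

#' Find influencer proteins
#'
#' An influencer is an unaffected protein with a directed interaction
#' into a first neighbour -- two steps away from a cancer-related
#' protein, reachable only by integrating direction information.  By
#' default (matching the drug-target use case) the targeted first
#' neighbour must additionally be adjacent to a *differentially
#' expressed* cancer-related protein; turn `restrict_to_de_fn` off for
#' the looser definition covering all first neighbours.
#'
#' @param network a `tissue_network` or `interactome`.
#' @param classification a [classify()] result for that network.
#' @param restrict_to_de_fn require the targeted first neighbour to be
#'   adjacent to a DE cancer-related protein (default `TRUE`).
#' @return character vector of influencer node identifiers (a subset of
#'   the unaffected class).
#' @export
find_influencers <- function(network, classification,
                             restrict_to_de_fn = TRUE) {
  e <- if (inherits(network, "tissue_network"))
    network$interactome$edges else network$edges
  dir_e <- e[e$directed, , drop = FALSE]
  if (nrow(dir_e) == 0) {
    warning("network has no directed edge; influencer set is empty")
    return(character(0))
  }
  fn <- class_nodes(classification, "first_neighbour")
  ua <- class_nodes(classification, "unaffected")
  if (restrict_to_de_fn) {
    de_cr <- classification$node[classification$class == "cancer_related" &
                                   classification$is_de]
    fn <- intersect(fn, neighbour_set(network, de_cr))
  }
  hits <- dir_e$from %in% ua & dir_e$to %in% fn
  sort(unique(dir_e$from[hits]))
}

#' Consensus influencers across network resources
#'
#' Counts, by protein identity, in how many resource-specific analyses a
#' protein appeared as influencer (regardless of which first neighbour it
#' targets in each resource) and keeps proteins found in at least `k`
#' resources.
#'
#' @param per_resource list of influencer sets (character vectors), one
#'   per resource.
#' @param k minimum number of resources (default 3).
#' @return character vector of consensus influencer identifiers.
#' @export
consensus_influencers <- function(per_resource, k = 3) {
  if (k < 1) stop("config error: k must be >= 1")
  if (k > length(per_resource))
    stop("config error: k exceeds the number of resources (",
         length(per_resource), ")")
  counts <- table(unlist(lapply(per_resource, unique)))
  sort(names(counts)[counts >= k])
}

#' Split first neighbours by the alteration type of their cancer-related
#' interactors
#'
#' A first neighbour belongs to `fn_of_mutated` when adjacent to at least
#' one mutated cancer-related protein and to `fn_of_de` when adjacent to
#' at least one differentially expressed one; the two sets may overlap.
#'
#' @param classification a [classify()] result.
#' @param network the network it was computed on.
#' @return list with character vectors `fn_of_mutated` and `fn_of_de`.
#' @export
first_neighbour_split <- function(classification, network) {
  fn <- class_nodes(classification, "first_neighbour")
  mut_cr <- classification$node[classification$class == "cancer_related" &
                                  classification$is_mutated]
  de_cr <- classification$node[classification$class == "cancer_related" &
                                 classification$is_de]
  list(fn_of_mutated = intersect(fn, neighbour_set(network, mut_cr)),
       fn_of_de = intersect(fn, neighbour_set(network, de_cr)))
}

#' Write a per-node classification table
#'
#' @param classification a [classify()] result.
#' @param path output TSV path.
#' @param influencers optional influencer set to record as a column.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path,
                                 influencers = NULL) {
  out <- as.data.frame(classification)
  out$is_influencer <- out$node %in% (influencers %||% character(0))
  out$resource <- attr(classification, "resource") %||% NA_character_
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
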