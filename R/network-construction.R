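#' Discretize expression into on/off calls
#'
#' Summarizes each gene's expression per tissue state (arithmetic mean
#' across that state's samples by default), pools the per-state summaries
#' of the network genes, and calls a gene *not expressed* in a state when
#' its summary falls strictly below the threshold `tau = mu - sigma`,
#' where `mu` and `sigma` are the mean and standard deviation of the
#' pool.  This binary rule is deliberately insensitive to graded
#' over-expression: only presence/absence switches count downstream.
#'
#' @param profile an [expression_profile()].
#' @param network_genes gene identifiers defining the network universe
#'   over which `mu` and `sigma` are computed; defaults to all profiled
#'   genes.
#' @param summary per-state summary statistic, `"mean"` or `"median"`.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @param pooling `"combined"` pools both states' summaries into one
#'   threshold (default); `"per_state"` computes a separate threshold per
#'   state.
#' @return object of class `discretization`: list with `mu`, `sigma`,
#'   `tau` (scalars, or length-2 named vectors under per-state pooling)
#'   and `calls`, a data.frame `(gene, normal_value, cancer_value,
#'   expressed_normal, expressed_cancer)`.
#' @examples
#' m <- matrix(c(10, 10, 10, 2), ncol = 1,
#'             dimnames = list(c("a", "b", "c", "d"), NULL))
#' d <- discretize(expression_profile(m, m))
#' d$tau  # 4: mu = 8, sigma = 4 over the pooled summaries
#' @export
discretize <- function(profile, network_genes = NULL,
                       summary = c("mean", "median"),
                       sd_type = c("sample", "population"),
                       pooling = c("combined", "per_state")) {
  summary <- match.arg(summary)
  sd_type <- match.arg(sd_type)
  pooling <- match.arg(pooling)
  genes <- profile$genes
  if (!is.null(network_genes)) {
    genes <- intersect(genes, network_genes)
    if (length(genes) == 0)
      stop("no overlap between network genes and profiled genes")
  }
  summarize <- function(mat) {
    mat <- mat[genes, , drop = FALSE]
    if (summary == "mean") rowMeans(mat)
    else apply(mat, 1, median)
  }
  s_normal <- summarize(profile$normal)
  s_cancer <- summarize(profile$cancer)
  sdev <- function(x) {
    if (length(x) < 2) stop("degenerate input: cannot compute a standard deviation from a single value")
    if (sd_type == "sample") sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  if (pooling == "combined") {
    pool <- c(s_normal, s_cancer)
    mu <- mean(pool); sigma <- sdev(pool); tau <- mu - sigma
    tau_n <- tau_c <- tau
  } else {
    mu <- c(normal = mean(s_normal), cancer = mean(s_cancer))
    sigma <- c(normal = sdev(s_normal), cancer = sdev(s_cancer))
    tau <- mu - sigma
    tau_n <- tau[["normal"]]; tau_c <- tau[["cancer"]]
  }
  calls <- data.frame(
    gene = genes,
    normal_value = unname(s_normal),
    cancer_value = unname(s_cancer),
    expressed_normal = unname(s_normal) >= tau_n,
    expressed_cancer = unname(s_cancer) >= tau_c,
    stringsAsFactors = FALSE)
  structure(list(mu = mu, sigma = sigma, tau = tau, calls = calls,
                 summary = summary, sd_type = sd_type, pooling = pooling),
            class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("<discretization> %d genes; mu=%s sigma=%s tau=%s (%s/%s/%s)\n",
              nrow(x$calls), paste(signif(x$mu, 4), collapse = "/"),
              paste(signif(x$sigma, 4), collapse = "/"),
              paste(signif(x$tau, 4), collapse = "/"),
              x$summary, x$sd_type, x$pooling))
  invisible(x)
}

#' Call binary differential expression
#'
#' A gene is differentially expressed when its on/off call differs
#' between the normal and cancer states -- present only in normal tissue
#' and absent in cancer, or the other way around.  Genes expressed in
#' both states (even if over-expressed) or silent in both states are not
#' differentially expressed.
#'
#' @param disc a [discretize()] result.
#' @return character vector of DE gene identifiers.
#' @export
call_differential_expression <- function(disc) {
  stopifnot(inherits(disc, "discretization"))
  with(disc$calls, gene[expressed_normal != expressed_cancer])
}

#' Build the tissue-specific network
#'
#' Restricts an interactome to the proteins present in the tissue: a node
#' is present when expressed in the normal state, the cancer state or
#' both; an interaction is retained when both interactors are present
#' (by default in either state -- the union rule -- so the combined
#' network shows the network effect of switching genes; a stricter
#' per-state rule requires both endpoints expressed in the *same* state).
#'
#' @param interactome an [interactome()].
#' @param disc a [discretize()] result covering (a subset of) the
#'   interactome genes.
#' @param rule `"union"` (default) or `"per_state"`.
#' @param unmeasured treatment of network genes absent from the
#'   expression profile: `"absent"` (strict, default; they and their
#'   edges are dropped, with a message) or `"expressed"` (permissive).
#' @return object of class `tissue_network`: list with `interactome`
#'   (the retained network) and `presence`, a data.frame `(node,
#'   presence)` with presence in \{both, normal_only, cancer_only,
#'   absent\} over the original node set.
#' @export
build_tissue_network <- function(interactome, disc,
                                 rule = c("union", "per_state"),
                                 unmeasured = c("absent", "expressed")) {
  rule <- match.arg(rule)
  unmeasured <- match.arg(unmeasured)
  stopifnot(inherits(interactome, "interactome"),
            inherits(disc, "discretization"))
  calls <- disc$calls
  en <- setNames(calls$expressed_normal, calls$gene)
  ec <- setNames(calls$expressed_cancer, calls$gene)
  nodes <- interactome$nodes
  n_missing <- sum(!(nodes %in% calls$gene))
  fill <- unmeasured == "expressed"
  if (n_missing > 0 && !fill)
    message(n_missing, " network gene(s) without expression data treated as absent")
  gn <- ifelse(nodes %in% names(en), en[nodes], fill)
  gc_ <- ifelse(nodes %in% names(ec), ec[nodes], fill)
  presence <- ifelse(gn & gc_, "both",
              ifelse(gn, "normal_only",
              ifelse(gc_, "cancer_only", "absent")))
  pres <- data.frame(node = nodes, presence = presence,
                     stringsAsFactors = FALSE)
  present <- nodes[presence != "absent"]
  e <- interactome$edges
  if (rule == "union") {
    keep <- e$from %in% present & e$to %in% present
  } else {
    en_f <- setNames(gn, nodes); ec_f <- setNames(gc_, nodes)
    keep <- (en_f[e$from] & en_f[e$to]) | (ec_f[e$from] & ec_f[e$to])
  }
  kept <- e[keep, , drop = FALSE]
  if (nrow(kept) == 0)
    warning("tissue network is empty: no interaction retained")
  net <- interactome(kept, resource = interactome$resource,
                     nodes = present)
  structure(list(interactome = net, presence = pres),
            class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  tab <- table(x$presence$presence)
  cat(sprintf("<tissue_network> %s: %d present nodes, %d edges\n",
              x$interactome$resource, length(x$interactome$nodes),
              nrow(x$interactome$edges)))
  cat("  presence:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
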