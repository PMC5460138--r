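#' Compute node-level topology metrics
#'
#' Degree, betweenness centrality and local clustering coefficient on the
#' undirected, unweighted, loop-free graph (direction is never taken into
#' account for topology).  Betweenness follows the unnormalized
#' pair-count convention: for node v it sums, over unordered node pairs
#' \{s, t\} with s != t != v, the fraction of shortest s-t paths passing
#' through v.  The clustering coefficient of nodes with degree < 2 is
#' recorded as 0.
#'
#' @param network a `tissue_network`, `interactome` or igraph object.
#' @param normalized divide betweenness by the number of eligible pairs
#'   `(n-1)(n-2)/2` (default `FALSE`; ranks, and hence all rank-based
#'   tests, are unaffected).
#' @return data.frame `(node, degree, betweenness, clustering)`.
#' @examples
#' tri <- interactome(data.frame(from = c("A", "B", "C"),
#'                               to = c("B", "C", "A")))
#' compute_topology(tri)  # all clustering 1, all betweenness 0
#' @export
compute_topology <- function(network, normalized = FALSE) {
  g <- if (inherits(network, "igraph")) {
    igraph::simplify(igraph::as_undirected(network, mode = "collapse"))
  } else {
    as_igraph(network, directed = FALSE)
  }
  n <- igraph::vcount(g)
  deg <- igraph::degree(g, loops = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  data.frame(node = igraph::V(g)$name %||% as.character(seq_len(n)),
             degree = unname(deg),
             betweenness = unname(btw),
             clustering = unname(cc),
             stringsAsFactors = FALSE)
}

# Exact Wilcoxon rank-sum p by full enumeration of all C(n, nx)
# group assignments of the pooled (tied) ranks; valid with ties.
wilcox_exact_enumeration <- function(x, y,
                                     alternative = c("two.sided",
                                                     "greater", "less")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  idx <- combn(n, nx)
  w_all <- colSums(matrix(r[idx], nrow = nx))
  eps <- 1e-9
  switch(alternative,
         greater = mean(w_all >= w_obs - eps),
         less = mean(w_all <= w_obs + eps),
         two.sided = {
           mu <- nx * (n + 1) / 2
           mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
         })
}

#' Wilcoxon rank-sum comparison with automatic exact small-sample mode
#'
#' For groups of at most 10 observations each the p-value is computed by
#' exact enumeration over all group assignments (valid in the presence of
#' ties); larger groups use the tie-corrected normal approximation of
#' [stats::wilcox.test()].
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max largest group size for which enumeration is used.
#' @return list with `statistic` (rank-sum W of `x`), `p_value` and
#'   `method`.
#' @export
wilcox_compare <- function(x, y, alternative = "two.sided",
                           exact_max = 10L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1)
    stop("both groups must be non-empty")
  w <- sum(rank(c(x, y))[seq_along(x)])
  if (length(x) <= exact_max && length(y) <= exact_max) {
    p <- wilcox_exact_enumeration(x, y, alternative)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = FALSE,
                  correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, method = method)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", ""))))
}

#' Compare topology metrics between node classes
#'
#' For each class, each metric's distribution is compared against the
#' control group (the whole network by default, following the convention
#' that subsets are compared against the full network; or the unaffected
#' class) with a two-sided Wilcoxon rank-sum test and a two-sided
#' Kolmogorov-Smirnov test.  Classes with fewer than 2 members are
#' skipped with a warning.
#'
#' @param topology a [compute_topology()] table.
#' @param classification a [classify()] result.
#' @param control `"whole_network"` (default) or `"unaffected"`.
#' @param classes class labels to compare.
#' @param metrics metric columns to compare.
#' @param alternative passed to the Wilcoxon test.
#' @return data.frame, one row per class x metric: group sizes, medians
#'   and quartiles, Wilcoxon W and p, KS D and p, and a significance
#'   star string (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#' @export
compare_classes <- function(topology, classification,
                            control = c("whole_network", "unaffected"),
                            classes = c("cancer_related",
                                        "first_neighbour", "unaffected"),
                            metrics = c("degree", "betweenness",
                                        "clustering"),
                            alternative = "two.sided") {
  control <- match.arg(control)
  cls <- setNames(classification$class, classification$node)
  rows <- list()
  for (label in classes) {
    members <- topology$node[cls[topology$node] == label &
                               !is.na(cls[topology$node])]
    if (length(members) < 2) {
      warning("class '", label, "' has fewer than 2 members; skipped")
      next
    }
    ctrl_nodes <- if (control == "whole_network") topology$node
      else topology$node[cls[topology$node] == "unaffected" &
                           !is.na(cls[topology$node])]
    if (length(ctrl_nodes) < 2) {
      warning("control group has fewer than 2 members; skipped")
      next
    }
    for (m in metrics) {
      v <- setNames(topology[[m]], topology$node)
      x <- unname(v[members]); y <- unname(v[ctrl_nodes])
      wt <- wilcox_compare(x, y, alternative = alternative)
      kt <- suppressWarnings(ks.test(x, y))
      rows[[length(rows) + 1L]] <- data.frame(
        class = label, control = control, metric = m,
        n_class = length(x), n_control = length(y),
        median_class = median(x),
        q25_class = unname(quantile(x, 0.25)),
        q75_class = unname(quantile(x, 0.75)),
        median_control = median(y),
        wilcox_W = wt$statistic, wilcox_p = wt$p_value,
        ks_D = unname(kt$statistic), ks_p = kt$p.value,
        stars = significance_stars(wt$p_value),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||%
    data.frame(class = character(0))
}

gc_ratio <- function(g, nodes) {
  if (length(nodes) == 0) return(NA_real_)
  sub <- igraph::induced_subgraph(g, nodes)
  max(igraph::components(sub)$csize) / length(nodes)
}

#' Label-permutation giant-component test
#'
#' Measures whether a node class is more internally connected than
#' expected by chance: the observed statistic is the giant-component
#' ratio (fraction of the class inside the largest connected component of
#' the class-induced subgraph), and the null distribution is built by
#' perturbing the class annotation -- drawing `n_perm` uniformly random
#' node subsets of the same size and recomputing the ratio.  A Z-score
#' outlier statistic and both an upper-tail normal p and an upper-tail
#' empirical p `(1 + #\{null >= observed\}) / (n_perm + 1)` are reported;
#' when the null ratios are constant the Z-score is undefined and only
#' the empirical p applies.
#'
#' @param network a `tissue_network` or `interactome`.
#' @param classification a [classify()] result (or `NULL` when `nodes`
#'   is given directly).
#' @param class_label which class to test.
#' @param n_perm number of annotation perturbations (default 1000, at
#'   least 100).
#' @param rng_seed optional seed for reproducibility.
#' @param nodes direct specification of the node set to test, overriding
#'   `classification`/`class_label`.
#' @return object of class `permutation_result`: list with
#'   `class_label`, `ratio_observed`, `null_ratios`, `z`, `p_normal`,
#'   `p_empirical`, `n_perm`.
#' @export
giant_component_test <- function(network, classification = NULL,
                                 class_label = "first_neighbour",
                                 n_perm = 1000, rng_seed = NULL,
                                 nodes = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  g <- as_igraph(network, directed = FALSE)
  all_nodes <- igraph::V(g)$name
  if (is.null(nodes)) {
    stopifnot(!is.null(classification))
    nodes <- class_nodes(classification, class_label)
  }
  nodes <- intersect(nodes, all_nodes)
  if (length(nodes) == 0) stop("class '", class_label, "' is empty")
  r_obs <- gc_ratio(g, nodes)
  null <- with_rng(rng_seed, {
    vapply(seq_len(n_perm),
           function(i) gc_ratio(g, sample(all_nodes, length(nodes))),
           numeric(1))
  })
  m <- mean(null); s <- sd(null)
  z <- if (s > 0) (r_obs - m) / s else NA_real_
  p_norm <- if (is.na(z)) NA_real_ else pnorm(z, lower.tail = FALSE)
  p_emp <- (1 + sum(null >= r_obs)) / (n_perm + 1)
  structure(list(class_label = class_label, class_size = length(nodes),
                 ratio_observed = r_obs, null_ratios = null,
                 mean_null = m, sd_null = s, z = z,
                 p_normal = p_norm, p_empirical = p_emp,
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s (n=%d): ratio=%.3f null=%.3f+/-%.3f Z=%s p_emp=%.4g\n",
    x$class_label, x$class_size, x$ratio_observed, x$mean_null,
    x$sd_null, if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
    x$p_empirical))
  invisible(x)
}

#' Seed-randomization robustness analysis of first-neighbour selection
#'
#' Draws, `n_draws` times, a uniformly random seed set of the same size
#' as the real cancer-related set, lists its first neighbours with the
#' same rule as [classify()], and accumulates per-node occurrence counts.
#' The occurrence distributions of the real first neighbours are then
#' compared (Wilcoxon rank-sum) against the unaffected and the
#' cancer-related proteins: robustly identifiable first neighbours recur
#' even under random seeding.
#'
#' @param network a `tissue_network` or `interactome`.
#' @param classification a [classify()] result.
#' @param n_draws number of random seed sets (default 100).
#' @param rng_seed optional seed.
#' @return object of class `randomization_result`: list with
#'   `occurrence` (data.frame `node`, `count`, `class`), `n_draws` and
#'   `comparisons` (data.frame of Wilcoxon results, `NULL` when
#'   `n_draws = 0`).
#' @export
randomization_analysis <- function(network, classification,
                                   n_draws = 100, rng_seed = NULL) {
  g <- as_igraph(network, directed = FALSE)
  nodes <- igraph::V(g)$name
  cr <- class_nodes(classification, "cancer_related")
  if (length(cr) < 1) stop("cancer-related class is empty")
  adj <- adjacency_list(network)
  counts <- setNames(integer(length(nodes)), nodes)
  if (n_draws > 0) {
    counts <- with_rng(rng_seed, {
      cnt <- counts
      for (i in seq_len(n_draws)) {
        seeds <- sample(nodes, length(cr))
        fn <- setdiff(unique(unlist(adj[seeds], use.names = FALSE)),
                      seeds)
        cnt[fn] <- cnt[fn] + 1L
      }
      cnt
    })
  }
  cls <- setNames(classification$class, classification$node)
  occ <- data.frame(node = nodes, count = unname(counts[nodes]),
                    class = unname(cls[nodes]), stringsAsFactors = FALSE)
  comparisons <- NULL
  if (n_draws > 0) {
    cmp <- function(a, b) {
      x <- occ$count[occ$class == a]; y <- occ$count[occ$class == b]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      wt <- wilcox_compare(x, y)
      data.frame(group_a = a, group_b = b,
                 median_a = median(x), median_b = median(y),
                 wilcox_W = wt$statistic, wilcox_p = wt$p_value,
                 stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, Filter(Negate(is.null), list(
      cmp("first_neighbour", "unaffected"),
      cmp("first_neighbour", "cancer_related"))))
  }
  structure(list(occurrence = occ, n_draws = n_draws,
                 comparisons = comparisons),
            class = "randomization_result")
}

#' Per-class metric distribution plot
#'
#' Simple base-graphics boxplot of one topology metric by node class.
#'
#' @param topology a [compute_topology()] table.
#' @param classification a [classify()] result.
#' @param metric metric column to plot.
#' @param log use a log-scaled y axis (values shifted by 1).
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
plot_class_metric <- function(topology, classification,
                              metric = "degree", log = FALSE, ...) {
  cls <- setNames(classification$class, classification$node)
  v <- topology[[metric]]
  grp <- factor(cls[topology$node],
                levels = c("cancer_related", "first_neighbour",
                           "unaffected"))
  if (log) v <- v + 1
  invisible(graphics::boxplot(v ~ grp, ylab = metric,
                              log = if (log) "y" else "", ...))
}
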