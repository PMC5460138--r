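# Independent brute-force oracles used to verify the implementation.
# Everything here is pure base R and deliberately ignorant of igraph.

# All-pairs BFS topology oracle for tiny undirected graphs.
# edges: data.frame(from, to), no self-loops. Returns one row per node.
oracle_topology <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$from[i], edges$to[i]] <- 1L
    A[edges$to[i], edges$from[i]] <- 1L
  }
  deg <- rowSums(A)
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb, drop = FALSE]) / (k * (k - 1))
  }, numeric(1))
  # level-synchronous BFS: shortest-path distances and path counts
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- rep(0, n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in which(A[u, ] == 1L)) {
          if (!is.finite(d[w])) { d[w] <- d[u] + 1; nxt <- c(nxt, w) }
          if (d[w] == d[u] + 1) sg[w] <- sg[w] + sg[u]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d; sigma[s, ] <- sg
  }
  btw <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) {
      for (s in seq_len(n - 1)) {
        for (t in seq((s + 1), n)) {
          if (s == v || t == v || !is.finite(dist[s, t])) next
          if (dist[s, v] + dist[v, t] == dist[s, t])
            btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  data.frame(node = nodes, degree = unname(deg), betweenness = btw,
             clustering = cc, stringsAsFactors = FALSE)
}

# Erdos-Renyi edge data.frame on n labelled nodes
random_edge_df <- function(n, p, labels = sprintf("N%02d", seq_len(n))) {
  pairs <- t(combn(labels, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# connected-component sizes by BFS flood fill over an edge data.frame
oracle_components <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  sizes <- integer(0)
  for (v in nodes) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; size <- 0L
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]; size <- size + 1L
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

with_seed_sample <- function(x, size, seed) {
  set.seed(seed)
  sample(x, size)
}

# reference two-sided rank-sum permutation p via bitmask enumeration
# (independent of the package's combn-based path)
wilcox_exact_enumeration_ref <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  mu <- nx * (n + 1) / 2
  wobs <- sum(r[seq_len(nx)])
  ws <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != nx) next
    ws <- c(ws, sum(r[bits == 1]))
  }
  mean(abs(ws - mu) >= abs(wobs - mu) - 1e-9)
}

class_of <- function(classification, node)
  classification$class[classification$node == node]

# small synthetic study used by several classification tests
tiny_dataset <- function(seed = 1, n_nodes = 200, n_seed = 15, ...) {
  cfg <- synthetic_config(n_nodes = n_nodes, n_seed_proteins = n_seed,
                          rng_seed = seed, ...)
  generate_dataset(cfg)
}

# 20-row bioactivity fixture with hand-enumerated expected filter results
# (classes: CR = {T1, T2}, FN = {T3, T4}, UA = {T5, T6})
fixture_bioactivity <- function() {
  data.frame(
    compound_id = c("C01", "C01", "C02", "C03", "C04", "C05", "C05",
                    "C06", "C07", "C08", "C09", "C10", "C11", "C12",
                    "C13", "C14", "C15", "C16", "C17", "C18"),
    target_id = c("T1", "T3", "T1", "T3", "T4", "T2", "T4", "T5", "T3",
                  "T2", "T4", "T1", "T6", "T3", "T2", "T4", "T1", "T3",
                  "T5", "T2"),
    activity_type = c("IC50", "IC50", "Ki", "Kd", "IC50", "Ki", "Ki",
                      "IC50", "EC50", "IC50", "Kd", "IC50", "Ki",
                      "IC50", "Kd", "IC50", "Ki", "Ki", "Kd", "IC50"),
    value_nM = c(100, 450, 600, 500, 400, 50, 50, 100, 100, 501, 499,
                 10, 5000, 200, 100, 300, 450, 700, 350, 250),
    max_phase = c(4L, 4L, 4L, 4L, 3L, 4L, 4L, 4L, 4L, 4L, 2L, 1L, 3L,
                  4L, 4L, 4L, 3L, 4L, 1L, 4L),
    indication_class = NA_character_,
    stringsAsFactors = FALSE)
}

# classification over a fixed 3-path backbone graph T1..T6 used with the
# bioactivity fixture: CR = {T1,T2}, FN = {T3,T4}, UA = {T5,T6}
fixture_classification <- function() {
  net <- interactome(data.frame(
    from = c("T1", "T2", "T3", "T4"),
    to   = c("T3", "T4", "T5", "T6")))
  classify(net, mutated = c("T1", "T2"))
}
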