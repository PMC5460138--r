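#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic study in one validated object.  The
#' defaults describe a desk-scale analogue of a tissue-specific cancer
#' interactome study: a heavy-tailed 2000-node network, a census-style
#' list of 100 mutated seed proteins, bimodal (silent/expressed)
#' log-intensity expression with 10% of genes switching on/off between
#' normal and cancer tissue, GO biological-process annotations and a
#' ChEMBL-style bioactivity table.
#'
#' @param n_nodes number of proteins in the interactome.
#' @param attachment_edges edges added per node during
#'   preferential-attachment growth (controls density; `m = 1` yields a
#'   tree).
#' @param n_seed_proteins number of mutated "cancer-related" seed genes.
#' @param seed_centrality_bias exponent of the degree-proportional
#'   sampling weight for mutated seeds; 0 = uniform sampling, larger
#'   values favour hubs.
#' @param frac_de_genes fraction of genes that switch on/off between the
#'   normal and cancer states (ground-truth differential expression).
#' @param silent_fraction fraction of genes whose baseline state is the
#'   silent (low) expression mode.
#' @param expression_modes list with elements `silent` and `expressed`,
#'   each a `(location, scale)` pair on the log-intensity scale;
#'   the expressed location must exceed the silent one.
#' @param n_samples_per_group microarray samples per tissue state.
#' @param frac_directed fraction of edges carrying a direction flag
#'   (signalling resources mix directed and undirected interactions).
#' @param graph_model `"pa"` (preferential attachment, default) or
#'   `"configuration"` (static power-law fitness model; its largest
#'   connected component is returned).
#' @param n_go_terms size of the GO biological-process term pool.
#' @param go_terms_per_protein integer `(min, max)` range of terms
#'   assigned per protein.
#' @param n_compounds number of distinct compounds in the bioactivity
#'   table.
#' @param frac_phase4 probability that a compound reached clinical
#'   phase 4 (i.e. is an approved drug).
#' @param potency_range_nM `(min, max)` of the log-uniform bioactivity
#'   value distribution, in nM.
#' @param rng_seed integer seed; every generator is a pure function of
#'   `(config, rng_seed)`.
#' @return an object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_nodes = 200, n_seed_proteins = 10)
#' net <- generate_interactome(cfg)
#' @export
synthetic_config <- function(n_nodes = 2000,
                             attachment_edges = 3,
                             n_seed_proteins = 100,
                             seed_centrality_bias = 0,
                             frac_de_genes = 0.1,
                             silent_fraction = 0.3,
                             expression_modes = list(silent = c(4, 0.5),
                                                     expressed = c(8, 0.5)),
                             n_samples_per_group = 10,
                             frac_directed = 0.3,
                             graph_model = c("pa", "configuration"),
                             n_go_terms = 200,
                             go_terms_per_protein = c(1, 5),
                             n_compounds = 500,
                             frac_phase4 = 0.2,
                             potency_range_nM = c(1, 10000),
                             rng_seed = 1) {
  graph_model <- match.arg(graph_model)
  cfg <- list(n_nodes = as.integer(n_nodes),
              attachment_edges = as.integer(attachment_edges),
              n_seed_proteins = as.integer(n_seed_proteins),
              seed_centrality_bias = seed_centrality_bias,
              frac_de_genes = frac_de_genes,
              silent_fraction = silent_fraction,
              expression_modes = expression_modes,
              n_samples_per_group = as.integer(n_samples_per_group),
              frac_directed = frac_directed,
              graph_model = graph_model,
              n_go_terms = as.integer(n_go_terms),
              go_terms_per_protein = as.integer(go_terms_per_protein),
              n_compounds = as.integer(n_compounds),
              frac_phase4 = frac_phase4,
              potency_range_nM = potency_range_nM,
              rng_seed = as.integer(rng_seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  frac <- c(frac_de_genes = cfg$frac_de_genes,
            silent_fraction = cfg$silent_fraction,
            frac_directed = cfg$frac_directed,
            frac_phase4 = cfg$frac_phase4)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    stop("fractions must lie in [0, 1]: ", paste(names(frac)[bad],
         collapse = ", "))
  if (cfg$n_nodes <= 0 || cfg$attachment_edges <= 0)
    stop("n_nodes and attachment_edges must be positive")
  if (cfg$n_nodes < cfg$attachment_edges + 1)
    stop("invalid config: n_nodes must be at least attachment_edges + 1")
  if (cfg$n_seed_proteins < 0 || cfg$n_seed_proteins >= cfg$n_nodes)
    stop("invalid config: n_seed_proteins must lie in [0, n_nodes)")
  if (cfg$seed_centrality_bias < 0)
    stop("seed_centrality_bias must be >= 0")
  m <- cfg$expression_modes
  if (!all(c("silent", "expressed") %in% names(m)))
    stop("expression_modes needs `silent` and `expressed` entries")
  if (m$expressed[1] <= m$silent[1])
    stop("expressed-mode location must exceed silent-mode location")
  if (any(c(m$silent[2], m$expressed[2]) < 0))
    stop("mode scales must be non-negative")
  if (length(cfg$go_terms_per_protein) != 2 ||
      cfg$go_terms_per_protein[1] > cfg$go_terms_per_protein[2] ||
      cfg$go_terms_per_protein[1] < 0)
    stop("go_terms_per_protein must be a non-decreasing (min, max) pair")
  if (cfg$go_terms_per_protein[2] > cfg$n_go_terms)
    stop("go_terms_per_protein max exceeds n_go_terms")
  if (length(cfg$potency_range_nM) != 2 ||
      any(cfg$potency_range_nM <= 0) ||
      cfg$potency_range_nM[1] > cfg$potency_range_nM[2])
    stop("potency_range_nM must be a positive (min, max) pair")
  invisible(cfg)
}

node_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Generate a synthetic interactome
#'
#' Grows an undirected preferential-attachment graph (guaranteeing the
#' heavy-tailed degree distribution that drives the friendship-paradox
#' behaviour of first neighbours), then flags a random fraction of edges
#' as directed with random orientation.  A static power-law fitness model
#' is available as `graph_model = "configuration"`.
#'
#' @param config a [synthetic_config()].
#' @param resource resource label attached to the result.
#' @return an [interactome()].
#' @export
generate_interactome <- function(config, resource = "synthetic") {
  validate_synthetic_config(config)
  with_rng(config$rng_seed, {
    if (config$graph_model == "pa") {
      g <- igraph::sample_pa(config$n_nodes, power = 1,
                             m = config$attachment_edges,
                             directed = FALSE)
    } else {
      g <- igraph::sample_fitness_pl(
        config$n_nodes,
        no.of.edges = config$n_nodes * config$attachment_edges,
        exponent.out = 2.5)
      comp <- igraph::components(g)
      g <- igraph::induced_subgraph(
        g, which(comp$membership == which.max(comp$csize)))
      g <- igraph::simplify(g)
    }
    igraph::V(g)$name <- node_ids(igraph::vcount(g))
    e <- igraph::as_data_frame(g, what = "edges")
    ne <- nrow(e)
    dir <- runif(ne) < config$frac_directed
    flip <- runif(ne) < 0.5
    edges <- data.frame(
      from = ifelse(dir & flip, e$to, e$from),
      to   = ifelse(dir & flip, e$from, e$to),
      directed = dir, stringsAsFactors = FALSE)
    interactome(edges, resource = resource,
                nodes = igraph::V(g)$name)
  })
}

#' Construct an expression profile
#'
#' @param normal,cancer numeric matrices (genes x samples) with identical
#'   row names (gene identifiers), at least one column each, all values
#'   finite.
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(normal, cancer) {
  stopifnot(is.matrix(normal), is.matrix(cancer))
  if (is.null(rownames(normal)) || is.null(rownames(cancer)) ||
      !identical(rownames(normal), rownames(cancer)))
    stop("normal and cancer matrices must share identical gene row names")
  if (ncol(normal) < 1 || ncol(cancer) < 1)
    stop("each state needs at least one sample")
  if (!all(is.finite(normal)) || !all(is.finite(cancer)))
    stop("expression values must be finite")
  structure(list(normal = normal, cancer = cancer,
                 genes = rownames(normal)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes; %d normal / %d cancer samples\n",
              length(x$genes), ncol(x$normal), ncol(x$cancer)))
  invisible(x)
}

#' Generate synthetic expression profiles with ground-truth DE labels
#'
#' Each gene is drawn from one of two Gaussian modes on a log-intensity
#' scale (mimicking RMA-normalized array intensities): a silent and an
#' expressed mode.  A gene is a ground-truth switching (differentially
#' expressed) gene with probability `frac_de_genes`; switching genes are
#' in the expressed mode in one state and the silent mode in the other.
#'
#' @param config a [synthetic_config()].
#' @param interactome an [interactome()] whose nodes define the gene
#'   universe.
#' @return an `expression_profile` with attribute `truth`, a data.frame
#'   `(gene, expressed_normal, expressed_cancer, is_de)`.
#' @export
generate_expression <- function(config, interactome) {
  validate_synthetic_config(config)
  genes <- interactome$nodes
  n <- length(genes)
  m <- config$expression_modes
  with_rng(config$rng_seed + 1L, {
    silent_normal <- runif(n) < config$silent_fraction
    is_de <- runif(n) < config$frac_de_genes
    expressed_normal <- !silent_normal
    expressed_cancer <- ifelse(is_de, !expressed_normal, expressed_normal)
    draw <- function(expressed) {
      loc <- ifelse(expressed, m$expressed[1], m$silent[1])
      sc  <- ifelse(expressed, m$expressed[2], m$silent[2])
      k <- config$n_samples_per_group
      mat <- matrix(rnorm(n * k, mean = rep(loc, k), sd = rep(sc, k)),
                    nrow = n, ncol = k)
      rownames(mat) <- genes
      colnames(mat) <- NULL
      mat
    }
    nm <- draw(expressed_normal)
    cm <- draw(expressed_cancer)
    colnames(nm) <- sprintf("normal_%02d", seq_len(ncol(nm)))
    colnames(cm) <- sprintf("cancer_%02d", seq_len(ncol(cm)))
    prof <- expression_profile(nm, cm)
    attr(prof, "truth") <- data.frame(
      gene = genes,
      expressed_normal = expressed_normal,
      expressed_cancer = expressed_cancer,
      is_de = is_de, stringsAsFactors = FALSE)
    prof
  })
}

#' Generate a synthetic mutated-gene list
#'
#' Samples `n_seed_proteins` distinct nodes with weight proportional to
#' `degree^seed_centrality_bias` (bias 0 = uniform), emulating a cancer
#' gene census extract whose genes may preferentially be hubs.
#'
#' @inheritParams generate_expression
#' @return character vector of node identifiers.
#' @export
generate_mutations <- function(config, interactome) {
  validate_synthetic_config(config)
  if (config$n_seed_proteins > length(interactome$nodes))
    stop("invalid config: n_seed_proteins exceeds number of nodes")
  if (config$n_seed_proteins == 0) return(character(0))
  g <- as_igraph(interactome)
  deg <- igraph::degree(g)
  w <- deg ^ config$seed_centrality_bias
  w[!is.finite(w) | w <= 0] <- if (config$seed_centrality_bias == 0) 1 else 0
  if (all(w == 0)) w[] <- 1
  with_rng(config$rng_seed + 2L,
           sample(igraph::V(g)$name, config$n_seed_proteins, prob = w))
}

#' Generate synthetic GO biological-process annotations
#'
#' Assigns each protein between `go_terms_per_protein[1]` and
#' `go_terms_per_protein[2]` terms drawn from a pool of `n_go_terms`
#' syntactically valid GO identifiers (`GO:0000000` upward).
#'
#' @inheritParams generate_expression
#' @param term_offset first numeric term identifier of the pool; separate
#'   offsets give disjoint term pools (useful for overlap-controlled
#'   tests).
#' @return data.frame `(protein, term)`, one row per annotation.
#' @export
generate_go_annotations <- function(config, interactome, term_offset = 0L) {
  validate_synthetic_config(config)
  pool <- sprintf("GO:%07d", term_offset + seq_len(config$n_go_terms) - 1L)
  rng <- config$go_terms_per_protein
  with_rng(config$rng_seed + 3L, {
    ann <- lapply(interactome$nodes, function(p) {
      k <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      if (k == 0) return(NULL)
      data.frame(protein = p, term = sample(pool, k),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, ann)
    if (is.null(out))
      out <- data.frame(protein = character(), term = character())
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic bioactivity table
#'
#' Emulates a ChEMBL extract: each compound gets one or more target
#' records with an activity type in \{IC50, Ki, Kd\}, a potency drawn
#' log-uniformly from `potency_range_nM`, and a maximum clinical phase in
#' \{1,2,3,4\} with `P(phase 4) = frac_phase4`.
#'
#' @inheritParams generate_expression
#' @param max_targets_per_compound upper bound on targets per compound
#'   (uniform 1..max).
#' @return data.frame `(compound_id, target_id, activity_type, value_nM,
#'   max_phase, indication_class)`.
#' @export
generate_bioactivity <- function(config, interactome,
                                 max_targets_per_compound = 3L) {
  validate_synthetic_config(config)
  with_rng(config$rng_seed + 4L, {
    nc <- config$n_compounds
    ids <- sprintf("CPD%05d", seq_len(nc))
    phase <- ifelse(runif(nc) < config$frac_phase4, 4L,
                    sample(1:3, nc, replace = TRUE))
    nt <- sample(seq_len(max_targets_per_compound), nc, replace = TRUE)
    lo <- log10(config$potency_range_nM[1])
    hi <- log10(config$potency_range_nM[2])
    rows <- lapply(seq_len(nc), function(i) {
      data.frame(
        compound_id = ids[i],
        target_id = sample(interactome$nodes, nt[i]),
        activity_type = sample(c("IC50", "Ki", "Kd"), nt[i],
                               replace = TRUE),
        value_nM = 10 ^ runif(nt[i], lo, hi),
        max_phase = phase[i],
        indication_class = NA_character_,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper running every generator with one config; the
#' individual generators draw from independent sub-streams so each output
#' is reproducible on its own.
#'
#' @param config a [synthetic_config()].
#' @param resource resource label for the interactome.
#' @return list with elements `interactome`, `expression`, `mutated`,
#'   `go`, `bioactivity`, `truth` (the ground-truth data.frame with
#'   columns `gene`, `expressed_normal`, `expressed_cancer`, `is_de`,
#'   `is_mutated`).
#' @export
generate_dataset <- function(config, resource = "synthetic") {
  net <- generate_interactome(config, resource = resource)
  prof <- generate_expression(config, net)
  mut <- generate_mutations(config, net)
  truth <- attr(prof, "truth")
  truth$is_mutated <- truth$gene %in% mut
  list(interactome = net,
       expression = prof,
       mutated = mut,
       go = generate_go_annotations(config, net),
       bioactivity = generate_bioactivity(config, net),
       truth = truth)
}
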