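#' Pipeline configuration
#'
#' Bundles every stage parameter of an end-to-end run.  Inputs come
#' either from files (`resources` = named list of edge-list paths plus
#' `expression_path`/groups, `mutated_path`, `gaf_path`,
#' `bioactivity_path`) or from the synthetic generators (`synthetic` = a
#' [synthetic_config()]; one interactome per resource is grown from
#' derived seeds over a shared gene universe, expression and mutations
#' are generated once against the first resource).  Defaults mirror the
#' analysis conventions: 1000 giant-component perturbations, 100
#' randomization draws, 500 nM potency cutoff, clinical phase 4,
#' consensus over at least 3 resources.
#'
#' @param synthetic a [synthetic_config()], or `NULL` for file inputs.
#' @param n_resources number of synthetic resources to generate.
#' @param resources named list of edge-list TSV paths (file mode).
#' @param expression_path,normal_group,cancer_group expression TSV and
#'   its sample groups (file mode).
#' @param mutated_path mutated-gene list path (file mode).
#' @param gaf_path optional GAF path (file mode).
#' @param bioactivity_path optional bioactivity TSV path (file mode).
#' @param summary,sd_type,pooling discretization options, see
#'   [discretize()].
#' @param rule,unmeasured tissue-network options, see
#'   [build_tissue_network()].
#' @param restrict_to_de_fn influencer definition, see
#'   [find_influencers()].
#' @param n_perm giant-component perturbations.
#' @param n_random randomization draws.
#' @param potency_cutoff_nM,phase_cutoff drug filter parameters.
#' @param consensus_k minimum resources for consensus influencers.
#' @param rng_seed master seed; all stage seeds are derived from it.
#' @param out_dir optional output directory for TSV reports.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, n_resources = 1,
                            resources = NULL,
                            expression_path = NULL,
                            normal_group = NULL, cancer_group = NULL,
                            mutated_path = NULL, gaf_path = NULL,
                            bioactivity_path = NULL,
                            summary = "mean", sd_type = "sample",
                            pooling = "combined", rule = "union",
                            unmeasured = "absent",
                            restrict_to_de_fn = TRUE,
                            n_perm = 1000, n_random = 100,
                            potency_cutoff_nM = 500, phase_cutoff = 4,
                            consensus_k = 3, rng_seed = 1,
                            out_dir = NULL) {
  if (is.null(synthetic)) {
    paths <- c(unlist(resources), expression_path, mutated_path,
               gaf_path, bioactivity_path)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("config error: input path(s) do not exist: ",
           paste(missing, collapse = ", "))
    if (is.null(resources) || is.null(expression_path) ||
        is.null(mutated_path))
      stop("config error: file mode needs resources, expression_path and mutated_path")
  } else {
    stopifnot(inherits(synthetic, "synthetic_config"))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    base <- config$synthetic
    nets <- lapply(seq_len(config$n_resources), function(i) {
      cfg_i <- base
      cfg_i$rng_seed <- base$rng_seed + 1000L * (i - 1L)
      generate_interactome(cfg_i, resource = sprintf("resource_%d", i))
    })
    names(nets) <- vapply(nets, function(n) n$resource, "")
    prof <- generate_expression(base, nets[[1]])
    mut <- generate_mutations(base, nets[[1]])
    list(interactomes = nets, expression = prof, mutated = mut,
         go = generate_go_annotations(base, nets[[1]]),
         bioactivity = generate_bioactivity(base, nets[[1]]),
         truth = attr(prof, "truth"))
  } else {
    nets <- lapply(names(config$resources), function(nm)
      read_edge_list(config$resources[[nm]], resource_name = nm))
    names(nets) <- names(config$resources)
    list(interactomes = nets,
         expression = read_expression_matrix(config$expression_path,
                                             config$normal_group,
                                             config$cancer_group),
         mutated = read_gene_list(config$mutated_path),
         go = if (!is.null(config$gaf_path)) read_gaf(config$gaf_path),
         bioactivity = if (!is.null(config$bioactivity_path))
           read_bioactivity(config$bioactivity_path),
         truth = NULL)
  }
}

#' Analyse one network resource
#'
#' Runs the per-resource stages in order: discretization, binary DE
#' calling, tissue-network construction, classification, influencer
#' detection, topology with class comparisons, giant-component tests,
#' seed randomization, and (when annotations / bioactivity are supplied)
#' the added-BP test and the drug/compound counts.
#'
#' @param interactome an [interactome()].
#' @param expression an [expression_profile()].
#' @param mutated mutated gene identifiers.
#' @param go optional `(protein, term)` annotation data.frame.
#' @param bioactivity optional bioactivity data.frame.
#' @param config a [pipeline_config()].
#' @param stage_seed seed for this resource's permutation stages.
#' @return list with all stage results.
#' @export
analyse_resource <- function(interactome, expression, mutated,
                             go = NULL, bioactivity = NULL,
                             config = pipeline_config(
                               synthetic = synthetic_config()),
                             stage_seed = config$rng_seed) {
  disc <- discretize(expression, network_genes = interactome$nodes,
                     summary = config$summary, sd_type = config$sd_type,
                     pooling = config$pooling)
  de <- call_differential_expression(disc)
  tissue <- build_tissue_network(interactome, disc, rule = config$rule,
                                 unmeasured = config$unmeasured)
  classification <- classify(tissue, mutated = mutated, de = de)
  influencers <- suppressWarnings(
    find_influencers(tissue, classification,
                     restrict_to_de_fn = config$restrict_to_de_fn))
  topology <- compute_topology(tissue)
  comparisons <- suppressWarnings(
    compare_classes(topology, classification))
  gc_tests <- lapply(
    setNames(nm = c("cancer_related", "first_neighbour")),
    function(lbl) {
      if (length(class_nodes(classification, lbl)) == 0) return(NULL)
      giant_component_test(tissue, classification, lbl,
                           n_perm = config$n_perm,
                           rng_seed = stage_seed + 17L)
    })
  randomization <- if (config$n_random > 0)
    randomization_analysis(tissue, classification,
                           n_draws = config$n_random,
                           rng_seed = stage_seed + 29L)
  go_test <- NULL
  if (!is.null(go) && nrow(go) > 0) {
    bp <- suppressWarnings(added_bps(go, classification))
    go_test <- c(list(result = bp),
                 added_bp_binomial_test(bp, classification, tissue))
  }
  drug_counts <- NULL
  if (!is.null(bioactivity) && nrow(bioactivity) > 0) {
    filtered <- filter_drugs(bioactivity,
                             potency_cutoff_nM = config$potency_cutoff_nM,
                             phase_cutoff = config$phase_cutoff)
    n_cr <- length(class_nodes(classification, "cancer_related"))
    n_fn <- length(class_nodes(classification, "first_neighbour"))
    drug_counts <- count_by_class(
      filtered, classification,
      expected_fraction = n_cr / max(1, n_cr + n_fn))
  }
  list(resource = interactome$resource, discretization = disc,
       de_genes = de, tissue_network = tissue,
       classification = classification, influencers = influencers,
       topology = topology, comparisons = comparisons,
       gc_tests = gc_tests, randomization = randomization,
       go_test = go_test, drug_counts = drug_counts)
}

#' Run the full pipeline
#'
#' Loads or generates the inputs, analyses every resource, computes
#' consensus influencers when at least `consensus_k` resources are
#' available (otherwise the consensus section is omitted with a notice),
#' assembles a per-class summary table, and -- when `out_dir` is set --
#' writes every stage's TSV outputs plus a run log recording the seed
#' and discretization parameters.  Identical `(config, rng_seed)` yield
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`: list with `per_resource`
#'   (list of [analyse_resource()] results), `consensus_influencers`
#'   (or `NULL`), `summary` (per resource x class data.frame) and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  results <- lapply(seq_along(inputs$interactomes), function(i)
    analyse_resource(inputs$interactomes[[i]], inputs$expression,
                     inputs$mutated, go = inputs$go,
                     bioactivity = inputs$bioactivity, config = config,
                     stage_seed = config$rng_seed + 101L * i))
  names(results) <- names(inputs$interactomes)
  consensus <- NULL
  if (length(results) >= config$consensus_k) {
    consensus <- consensus_influencers(
      lapply(results, `[[`, "influencers"), k = config$consensus_k)
  } else {
    message("consensus section omitted: fewer than ", config$consensus_k,
            " resources")
  }
  summary_tab <- do.call(rbind, lapply(results, function(res) {
    cl <- res$classification
    sizes <- table(factor(cl$class,
                          levels = c("cancer_related", "first_neighbour",
                                     "unaffected")))
    med <- function(lbl, metric) {
      v <- res$topology[[metric]][res$topology$node %in%
                                    class_nodes(cl, lbl)]
      if (length(v)) median(v) else NA_real_
    }
    do.call(rbind, lapply(names(sizes), function(lbl) data.frame(
      resource = res$resource, class = lbl,
      size = as.integer(sizes[[lbl]]),
      median_degree = med(lbl, "degree"),
      median_betweenness = med(lbl, "betweenness"),
      gc_z = if (!is.null(res$gc_tests[[lbl]]))
        res$gc_tests[[lbl]]$z else NA_real_,
      gc_p_empirical = if (!is.null(res$gc_tests[[lbl]]))
        res$gc_tests[[lbl]]$p_empirical else NA_real_,
      n_influencers = length(res$influencers),
      stringsAsFactors = FALSE)))
  }))
  rownames(summary_tab) <- NULL
  report <- structure(list(per_resource = results,
                           consensus_influencers = consensus,
                           summary = summary_tab, config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d resource(s)\n",
              length(x$per_resource)))
  print(x$summary)
  if (!is.null(x$consensus_influencers))
    cat(sprintf("consensus influencers (k=%d): %d\n",
                x$config$consensus_k,
                length(x$consensus_influencers)))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (res in report$per_resource) {
    pre <- res$resource
    write_classification(res$classification,
                         file.path(out_dir,
                                   paste0(pre, "_classes.tsv")),
                         influencers = res$influencers)
    wt(res$topology, paste0(pre, "_topology.tsv"))
    wt(res$comparisons, paste0(pre, "_comparisons.tsv"))
    gc_tab <- do.call(rbind, lapply(
      Filter(Negate(is.null), res$gc_tests), function(t) data.frame(
        class = t$class_label, observed = t$ratio_observed,
        mean_null = t$mean_null, sd_null = t$sd_null, z = t$z,
        p_normal = t$p_normal, p_empirical = t$p_empirical)))
    if (!is.null(gc_tab)) wt(gc_tab, paste0(pre, "_giant_component.tsv"))
    if (!is.null(res$randomization))
      wt(res$randomization$occurrence,
         paste0(pre, "_randomization.tsv"))
  }
  wt(report$summary, "summary.tsv")
  if (!is.null(report$consensus_influencers))
    write_gene_list(report$consensus_influencers,
                    file.path(out_dir, "consensus_influencers.txt"))
  disc <- report$per_resource[[1]]$discretization
  writeLines(c(sprintf("rng_seed\t%d", report$config$rng_seed),
               sprintf("mu\t%s", paste(disc$mu, collapse = ",")),
               sprintf("sigma\t%s", paste(disc$sigma, collapse = ",")),
               sprintf("tau\t%s", paste(disc$tau, collapse = ","))),
             file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}
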