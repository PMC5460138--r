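#' Added GO biological processes of first neighbours
#'
#' Annotates the cancer-related proteins first, then gives the first
#' neighbours only those biological-process terms that were not already
#' annotated to a cancer-related protein.  The size of this added set
#' measures the functional reach that first neighbours contribute on top
#' of the cancer-related proteins themselves.
#'
#' @param annotations data.frame `(protein, term)` of biological-process
#'   annotations (e.g. from [read_gaf()] or
#'   [generate_go_annotations()]).
#' @param classification a [classify()] result.
#' @return object of class `added_bp`: list with `bp_cr` (terms of
#'   cancer-related proteins), `bp_added` (first-neighbour terms not in
#'   `bp_cr`; always disjoint from it) and the class sizes used
#'   downstream.
#' @export
added_bps <- function(annotations, classification) {
  stopifnot(all(c("protein", "term") %in% names(annotations)))
  cr <- class_nodes(classification, "cancer_related")
  fn <- class_nodes(classification, "first_neighbour")
  if (!any(annotations$protein %in% cr))
    warning("no annotated cancer-related protein; BP_cr is empty")
  bp_cr <- unique(annotations$term[annotations$protein %in% cr])
  bp_fn <- unique(annotations$term[annotations$protein %in% fn])
  bp_added <- setdiff(bp_fn, bp_cr)
  stopifnot(length(intersect(bp_added, bp_cr)) == 0)
  structure(list(bp_cr = bp_cr, bp_added = bp_added,
                 n_cr = length(cr), n_fn = length(fn)),
            class = "added_bp")
}

#' @export
print.added_bp <- function(x, ...) {
  cat(sprintf("<added_bp> %d CR terms; %d added first-neighbour terms\n",
              length(x$bp_cr), length(x$bp_added)))
  invisible(x)
}

#' Binomial test for the added-BP count
#'
#' Tests (one-sided, greater) whether first neighbours contribute more
#' added biological processes than expected from their share of the
#' network: `k = |BP_added|` successes in `n = |BP_cr union BP_added|`
#' trials with expected success probability `|FN| / |network nodes|`.
#'
#' @param result an [added_bps()] result.
#' @param classification a [classify()] result.
#' @param network the network the classification was computed on.
#' @return list with `k`, `n`, `p_expected` and the one-sided `p_value`.
#' @examples
#' # P(X >= 9 | n = 10, p = 0.5) = 11/1024
#' stats::binom.test(9, 10, 0.5, alternative = "greater")$p.value
#' @export
added_bp_binomial_test <- function(result, classification, network) {
  stopifnot(inherits(result, "added_bp"))
  k <- length(result$bp_added)
  n <- length(union(result$bp_cr, result$bp_added))
  if (n == 0) stop("no biological-process term over CR and FN proteins")
  n_net <- if (inherits(network, "tissue_network"))
    length(network$interactome$nodes) else length(network$nodes)
  fn <- class_nodes(classification, "first_neighbour")
  p_exp <- length(fn) / n_net
  p <- if (p_exp >= 1) 1
       else if (p_exp <= 0) as.numeric(k == 0)
       else binom.test(k, n, p_exp, alternative = "greater")$p.value
  list(k = k, n = n, p_expected = p_exp, p_value = p)
}

#' Filter bioactivity records into compounds and drugs
#'
#' A *compound* record has good potency: activity type IC50, Ki or Kd
#' with a value at or below the potency cutoff (500 nM by default).  A
#' *drug* record is a compound record whose compound additionally reached
#' the clinical-phase cutoff (phase 4, i.e. approved).  Records with an
#' unknown activity type are skipped with a message.
#'
#' @param bioactivity validated bioactivity data.frame (see
#'   [read_bioactivity()]).
#' @param potency_cutoff_nM potency threshold in nM (default 500).
#' @param phase_cutoff minimum clinical phase for drug status
#'   (default 4).
#' @return list with data.frames `compounds` and `drugs` (`drugs` is
#'   always a subset of `compounds`).
#' @export
filter_drugs <- function(bioactivity, potency_cutoff_nM = 500,
                         phase_cutoff = 4) {
  validate_bioactivity(bioactivity)
  known <- bioactivity$activity_type %in% c("IC50", "Ki", "Kd")
  if (any(!known))
    message(sum(!known), " record(s) with unknown activity type skipped")
  tab <- bioactivity[known, , drop = FALSE]
  compounds <- tab[tab$value_nM <= potency_cutoff_nM, , drop = FALSE]
  drugs <- compounds[compounds$max_phase >= phase_cutoff, , drop = FALSE]
  list(compounds = compounds, drugs = drugs)
}

#' Count drugs and compounds per node class
#'
#' A compound contributes to a class when at least one of its filtered
#' targets belongs to that class; within a class each compound is counted
#' once, but a compound hitting targets in several classes counts in each
#' of them.  The drug-vs-compound composition of the first two classes is
#' compared with a 2x2 chi-squared test without continuity correction
#' (Fisher's exact test is substituted when any expected cell is below
#' 5), and, when `expected_fraction` is given, the first class's share of
#' drugs and of compounds is each tested against it with a one-sided
#' binomial test.
#'
#' @param filtered a [filter_drugs()] result.
#' @param classification a [classify()] result.
#' @param classes classes to count (default cancer-related and
#'   first-neighbour).
#' @param expected_fraction optional expected share of the first class
#'   among the first two classes (e.g. the cancer-related / (CR + FN)
#'   protein ratio).
#' @return object of class `drug_count_result`: list with `counts`
#'   (data.frame `class`, `n_drugs`, `n_compounds`), `chisq` (list
#'   `statistic`, `p_value`, `method`) and optional `binomial`
#'   (data.frame per record type).
#' @export
count_by_class <- function(filtered, classification,
                           classes = c("cancer_related",
                                       "first_neighbour"),
                           expected_fraction = NULL) {
  count_one <- function(records, label) {
    members <- class_nodes(classification, label)
    length(unique(records$compound_id[records$target_id %in% members]))
  }
  counts <- data.frame(
    class = classes,
    n_drugs = vapply(classes, function(cl)
      count_one(filtered$drugs, cl), integer(1)),
    n_compounds = vapply(classes, function(cl)
      count_one(filtered$compounds, cl), integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  chisq <- NULL
  if (length(classes) >= 2) {
    tab <- rbind(drugs = counts$n_drugs[1:2],
                 compounds = counts$n_compounds[1:2])
    colnames(tab) <- classes[1:2]
    if (all(tab >= 0) && sum(tab) > 0 && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        chisq <- list(statistic = NA_real_, p_value = ft$p.value,
                      method = "Fisher exact")
      } else {
        ct <- chisq.test(tab, correct = FALSE)
        chisq <- list(statistic = unname(ct$statistic),
                      p_value = ct$p.value,
                      method = "chi-squared (no continuity correction)")
      }
    }
  }
  binomial <- NULL
  if (!is.null(expected_fraction) && length(classes) >= 2) {
    bt <- function(k, n) {
      if (n == 0) return(NA_real_)
      binom.test(k, n, expected_fraction,
                 alternative = "greater")$p.value
    }
    binomial <- data.frame(
      record_type = c("drugs", "compounds"),
      k = c(counts$n_drugs[1], counts$n_compounds[1]),
      n = c(sum(counts$n_drugs[1:2]), sum(counts$n_compounds[1:2])),
      expected_fraction = expected_fraction,
      p_value = c(bt(counts$n_drugs[1], sum(counts$n_drugs[1:2])),
                  bt(counts$n_compounds[1],
                     sum(counts$n_compounds[1:2]))),
      stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, chisq = chisq, binomial = binomial),
            class = "drug_count_result")
}

#' @export
print.drug_count_result <- function(x, ...) {
  cat("<drug_count_result>\n")
  print(x$counts)
  if (!is.null(x$chisq))
    cat(sprintf("  %s: p = %.4g\n", x$chisq$method, x$chisq$p_value))
  invisible(x)
}

#' Venn partition of per-cancer protein or compound sets
#'
#' Counts, for every non-empty subset of cancer types, the elements
#' found in exactly that combination (i.e. in all members of the subset and
#' in none of the others); the counts over all regions sum to the size
#' of the union.
#'
#' @param sets named list of character vectors, one per cancer type.
#' @return data.frame `(region, count)` with one row per non-empty
#'   subset; `region` joins the member names with `&`.
#' @export
multi_cancer_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  nm <- names(sets)
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(NULL, nm))
  keys <- apply(membership, 1, function(row)
    paste(nm[row], collapse = "&"))
  all_regions <- unlist(lapply(seq_along(nm), function(k)
    apply(combn(nm, k), 2, paste, collapse = "&")))
  counts <- table(factor(keys, levels = all_regions))
  data.frame(region = all_regions,
             count = as.integer(counts[all_regions]),
             stringsAsFactors = FALSE, row.names = NULL)
}
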