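#' Read an interactome edge list
#'
#' Reads a TSV with columns source, target and optionally a direction
#' flag.  Duplicate edges are collapsed and self-loops dropped (their
#' count is reported in a message and kept as attribute `n_self_loops` of
#' the result).
#'
#' @param path TSV file; a header line is expected.
#' @param resource_name label stored on the interactome.
#' @param directed_types for SIF-style files whose third column is an
#'   interaction type rather than a `directed`/`undirected` keyword: the
#'   set of type labels to treat as directed.
#' @return an [interactome()].
#' @export
read_edge_list <- function(path, resource_name = basename(path),
                           directed_types = character(0)) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = "character")
  if (nrow(tab) == 0) stop("empty interactome: no edge rows in ", path)
  if (ncol(tab) < 2)
    stop("malformed edge list: need at least 2 columns in ", path)
  bad <- which(!nzchar(tab[[1]]) | !nzchar(tab[[2]]))
  if (length(bad))
    stop(sprintf("malformed edge row at line %d of %s (empty endpoint)",
                 bad[1] + 1L, path))
  directed <- rep(FALSE, nrow(tab))
  if (ncol(tab) >= 3) {
    third <- tolower(trimws(tab[[3]]))
    directed <- third == "directed" |
      (nzchar(third) & third %in% tolower(directed_types))
  }
  net <- interactome(data.frame(from = tab[[1]], to = tab[[2]],
                                directed = directed,
                                stringsAsFactors = FALSE),
                     resource = resource_name)
  if (attr(net, "n_self_loops") > 0)
    message(attr(net, "n_self_loops"), " self-loop(s) removed from ",
            resource_name)
  net
}

#' Write an interactome edge list
#'
#' @param x an [interactome()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  out <- data.frame(source = x$edges$from, target = x$edges$to,
                    direction = ifelse(x$edges$directed, "directed",
                                       "undirected"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix
#'
#' First column holds gene identifiers, the remaining columns samples.
#' When several rows share a gene identifier, the row with the highest
#' mean value across all samples is kept (the standard probe-set
#' collapsing rule for array data).
#'
#' @param path TSV with header.
#' @param normal_group,cancer_group character vectors of column names
#'   forming the two disjoint sample groups.
#' @return an [expression_profile()].
#' @export
read_expression_matrix <- function(path, normal_group, cancer_group) {
  if (length(intersect(normal_group, cancer_group)) > 0)
    stop("config error: sample(s) listed in both groups: ",
         paste(intersect(normal_group, cancer_group), collapse = ", "))
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", check.names = FALSE)
  genes <- as.character(tab[[1]])
  miss <- setdiff(c(normal_group, cancer_group), names(tab))
  if (length(miss))
    stop("sample column(s) not found: ", paste(miss, collapse = ", "))
  vals <- tab[, c(normal_group, cancer_group), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error: non-numeric or missing cell at row %d, column '%s'",
                   bad[1], names(vals)[j]))
    vals[[j]] <- v
  }
  vals <- as.matrix(vals)
  # collapse duplicate gene IDs: keep the row with the highest overall mean
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(ix) ix[which.max(means[ix])]),
                   use.names = FALSE)
    vals <- vals[sort(keep), , drop = FALSE]
    genes <- genes[sort(keep)]
  }
  rownames(vals) <- genes
  expression_profile(vals[, normal_group, drop = FALSE],
                     vals[, cancer_group, drop = FALSE])
}

#' Write an expression profile as a TSV matrix
#'
#' @param x an [expression_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  mat <- cbind(x$normal, x$cancer)
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a plain gene list (one identifier per line)
#'
#' @param path text file, one identifier per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}

#' Read a GAF 2.x gene-association file (biological process only)
#'
#' Only rows whose aspect column is `P` (biological process) are kept;
#' molecular-function and cellular-component annotations are discarded.
#' Duplicated (protein, term) pairs are collapsed.
#'
#' @param path GAF file; comment lines start with `!`.
#' @param id_column which column identifies the protein: 2 (DB Object ID,
#'   default) or 3 (DB Object Symbol).
#' @return data.frame `(protein, term)`.
#' @export
read_gaf <- function(path, id_column = 2L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0)
    return(data.frame(protein = character(), term = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 0L) < 9)
  if (length(short))
    stop("malformed GAF row (fewer than 9 columns) at data line ", short[1])
  protein <- vapply(parts, `[[`, "", id_column)
  term <- vapply(parts, `[[`, "", 5L)
  aspect <- vapply(parts, `[[`, "", 9L)
  keep <- aspect == "P"
  unique(data.frame(protein = protein[keep], term = term[keep],
                    stringsAsFactors = FALSE))
}

#' Write GO annotations as a minimal GAF 2.1 file
#'
#' @param annotations data.frame `(protein, term)`.
#' @param path output path.
#' @param db database label for column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, db = "SYNTH") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  if (nrow(annotations)) {
    rows <- sprintf("%s\t%s\t%s\t\t%s\tREF:0\tIEA\t\tP\t\t\tprotein\ttaxon:9606\t20150602\t%s\t\t",
                    db, annotations$protein, annotations$protein,
                    annotations$term, db)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read / write a bioactivity table
#'
#' Expected TSV columns: `compound_id`, `target_id`, `activity_type`,
#' `value_nM`, `max_phase` and optionally `indication_class`.  Validates
#' that potency values are positive and clinical phases lie in 0..4;
#' duplicated records are collapsed.
#'
#' @param path TSV file with header.
#' @return validated data.frame.
#' @export
read_bioactivity <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
  need <- c("compound_id", "target_id", "activity_type", "value_nM",
            "max_phase")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("bioactivity table missing column(s): ",
         paste(miss, collapse = ", "))
  if (!("indication_class" %in% names(tab)))
    tab$indication_class <- NA_character_
  tab$value_nM <- as.numeric(tab$value_nM)
  tab$max_phase <- as.integer(tab$max_phase)
  validate_bioactivity(tab)
  unique(tab[, c(need, "indication_class")])
}

validate_bioactivity <- function(tab) {
  if (any(!is.finite(tab$value_nM)) || any(tab$value_nM <= 0))
    stop("validation error: value_nM must be positive and finite")
  if (any(is.na(tab$max_phase)) || any(tab$max_phase < 0 | tab$max_phase > 4))
    stop("validation error: max_phase must lie in 0..4")
  invisible(tab)
}

#' @rdname read_bioactivity
#' @param tab bioactivity data.frame to write.
#' @export
write_bioactivity <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a two-column identifier mapping table and apply it
#'
#' A namespace-agnostic substitute for an accession-mapping service: maps
#' the first-column identifiers to the second-column accessions.  A
#' source identifier may map to several accessions (one-to-many
#' expansion); identifiers absent from the table are dropped with a
#' message.
#'
#' @param path TSV with header and two columns (source id, mapped id).
#' @return data.frame `(id, mapped)`.
#' @export
read_id_mapping <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = "character")
  if (ncol(tab) < 2) stop("mapping table needs two columns")
  unique(data.frame(id = tab[[1]], mapped = tab[[2]],
                    stringsAsFactors = FALSE))
}

#' @rdname read_id_mapping
#' @param ids character vector of identifiers to map.
#' @param mapping data.frame returned by `read_id_mapping()`.
#' @export
map_ids <- function(ids, mapping) {
  hit <- mapping$id %in% ids
  dropped <- setdiff(ids, mapping$id)
  if (length(dropped))
    message(length(dropped), " identifier(s) without mapping dropped")
  unique(mapping$mapped[hit])
}

#' Write the synthetic ground truth table
#'
#' @param truth data.frame with columns `gene`, `is_mutated`,
#'   `is_de` (or `is_de_truth`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  de_col <- if ("is_de_truth" %in% names(truth)) "is_de_truth" else "is_de"
  out <- data.frame(node = truth$gene,
                    is_mutated = truth$is_mutated,
                    is_de_truth = truth[[de_col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
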