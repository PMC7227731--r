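# Domain types and delimited-text IO.
#
# A sample table holds one row per cortical tissue sample: an id, MNI
# coordinates in mm, an anatomical tissue label and a resting-state network
# label (0 = not in any network, 1..13 otherwise). An expression matrix is a
# plain numeric genes x samples matrix whose columns are aligned to a sample
# table. Both are deliberately lightweight: base data.frame / matrix with a
# class tag, in the style of vegan or ape.

SAMPLE_TABLE_COLUMNS <- c("sample_id", "x", "y", "z", "tissue_label", "network_label")

#' Construct and validate a sample table
#'
#' @param df a data.frame with columns `sample_id`, `x`, `y`, `z`,
#'   `tissue_label`, `network_label` (integer 0..13; 0 means the sample
#'   belongs to no resting-state network).
#' @return The validated data.frame with class `sample_table`.
#' @export
sample_table <- function(df) {
  missing_cols <- setdiff(SAMPLE_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    ssf_stop("ssf_format_error", "sample table is missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, SAMPLE_TABLE_COLUMNS]
  df$sample_id <- as.character(df$sample_id)
  df$tissue_label <- as.character(df$tissue_label)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    ssf_stop("ssf_validation_error", "duplicated sample_id(s): %s",
             paste(dup, collapse = ", "))
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    ssf_stop("ssf_validation_error", "coordinates must be finite numbers")
  }
  nl <- df$network_label
  if (any(is.na(nl)) || any(nl != as.integer(nl)) || any(nl < 0) || any(nl > 13)) {
    ssf_stop("ssf_validation_error", "network_label must be an integer in 0..13")
  }
  df$network_label <- as.integer(nl)
  if (length(setdiff(unique(df$network_label), 0L)) > 13) {
    ssf_stop("ssf_validation_error", "more than 13 distinct non-zero network labels")
  }
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

resolve_sep <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") return("\t")
  if (dialect == "comma") return(",")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample table from delimited text
#'
#' Expects a header row `sample_id, x, y, z, tissue_label, network_label`.
#' The dialect (TSV vs CSV) is auto-detected from the file extension and can
#' be overridden.
#'
#' @param path path to a TSV/CSV file.
#' @param dialect `"auto"` (default, from extension), `"tab"` or `"comma"`.
#' @return A [sample_table()] with row order preserved.
#' @export
read_sample_table <- function(path, dialect = "auto") {
  if (!file.exists(path)) ssf_stop("ssf_format_error", "file not found: %s", path)
  sep <- resolve_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  missing_cols <- setdiff(SAMPLE_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    ssf_stop("ssf_format_error", "sample table %s is missing column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  }
  for (col in c("x", "y", "z", "network_label")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      ssf_stop("ssf_parse_error", "non-numeric %s at data row(s) %s in %s",
               col, paste(bad, collapse = ", "), path)
    }
    df[[col]] <- vals
  }
  sample_table(df)
}

#' Write a sample table as delimited text
#'
#' @param table a [sample_table()].
#' @param path output path; dialect from extension unless overridden.
#' @param dialect `"auto"`, `"tab"` or `"comma"`.
#' @export
write_sample_table <- function(table, path, dialect = "auto") {
  sep <- resolve_sep(path, dialect)
  out <- as.data.frame(table)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' First column is the gene id; remaining column names are sample ids. When a
#' sample table is supplied the columns are reordered to the table's sample
#' order (the matrix may cover a subset of the table's samples, but every
#' matrix column must resolve to a table row). Missing values are an error
#' unless `impute_mean = TRUE`, which replaces them by the gene's row mean
#' and reports that it did so. Genes with zero variance are loaded but listed
#' in the `"zero_variance_genes"` attribute.
#'
#' @param path path to a TSV/CSV file.
#' @param table optional [sample_table()] to align against.
#' @param dialect `"auto"`, `"tab"` or `"comma"`.
#' @param impute_mean replace missing values by the gene's mean (logged).
#' @return A numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path, table = NULL, dialect = "auto",
                            impute_mean = FALSE) {
  if (!file.exists(path)) ssf_stop("ssf_format_error", "file not found: %s", path)
  sep <- resolve_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "", quote = "")
  if (nrow(df) == 0 || ncol(df) < 2) {
    ssf_stop("ssf_format_error", "expression matrix %s is empty", path)
  }
  genes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  expression_matrix(values, table = table, impute_mean = impute_mean)
}

#' Validate (and optionally align) an expression matrix
#'
#' @param values numeric genes x samples matrix with dimnames.
#' @param table optional [sample_table()] whose sample order the columns are
#'   aligned to.
#' @param impute_mean replace missing values by each gene's row mean.
#' @return The validated matrix (columns in table order when `table` given).
#' @export
expression_matrix <- function(values, table = NULL, impute_mean = FALSE) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ssf_stop("ssf_format_error", "expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    ssf_stop("ssf_validation_error", "duplicated gene ids in expression matrix")
  }
  if (!is.null(table)) {
    unknown <- setdiff(colnames(values), table$sample_id)
    if (length(unknown) > 0) {
      ssf_stop("ssf_alignment_error",
               "expression sample id(s) absent from sample table: %s",
               paste(unknown, collapse = ", "))
    }
    keep <- table$sample_id[table$sample_id %in% colnames(values)]
    values <- values[, keep, drop = FALSE]
  }
  if (anyNA(values)) {
    bad_genes <- rownames(values)[apply(is.na(values), 1, any)]
    if (impute_mean) {
      for (g in bad_genes) {
        row <- values[g, ]
        row[is.na(row)] <- mean(row, na.rm = TRUE)
        values[g, ] <- row
      }
      message(sprintf("imputed missing values by row mean for %d gene(s)",
                      length(bad_genes)))
    } else {
      ssf_stop("ssf_validation_error",
               "missing expression values for gene(s): %s (use impute_mean = TRUE to mean-impute)",
               paste(utils::head(bad_genes, 10), collapse = ", "))
    }
  }
  ss <- rowSums((values - rowMeans(values))^2)
  attr(values, "zero_variance_genes") <- rownames(values)[ss == 0]
  values
}

#' Genes flagged as zero-variance at load time
#'
#' @param expr matrix returned by [read_expression()] / [expression_matrix()].
#' @return Character vector of gene ids (possibly empty).
#' @export
zero_variance_genes <- function(expr) {
  zv <- attr(expr, "zero_variance_genes")
  if (is.null(zv)) character(0) else zv
}

#' Write an expression matrix as delimited text
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @param dialect `"auto"`, `"tab"` or `"comma"`.
#' @export
write_expression <- function(expr, path, dialect = "auto") {
  sep <- resolve_sep(path, dialect)
  out <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-set file
#'
#' Plain text, one gene id per line; `#` starts a comment.
#'
#' @param path file path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) ssf_stop("ssf_format_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Partition the genes of an expression matrix by a gene set
#'
#' Ids that do not resolve against the matrix are reported in the result, not
#' treated as fatal.
#'
#' @param gene_ids character vector of gene ids (e.g. from [read_gene_set()]).
#' @param expr genes x samples matrix.
#' @return List with `in_idx`, `out_idx` (row indices) and `unresolved`
#'   (character).
#' @export
resolve_gene_set <- function(gene_ids, expr) {
  all_ids <- rownames(expr)
  gene_ids <- unique(as.character(gene_ids))
  in_idx <- which(all_ids %in% gene_ids)
  list(
    in_idx = in_idx,
    out_idx = setdiff(seq_along(all_ids), in_idx),
    unresolved = setdiff(gene_ids, all_ids)
  )
}

#' Run configuration for the false-positive-rate experiment
#'
#' Bundles the simulation sweep parameters with the statistical conventions
#' of the strength-fraction test so one object fully determines a run.
#'
#' @param radii_mm spherical cluster radii to sweep (mm).
#' @param n_clusters number of contiguous clusters per simulated network set.
#' @param network_composition clusters per network; default nine networks of
#'   three clusters, three of two and one singleton (13 networks, 34 clusters).
#' @param n_networks simulated network sets per radius.
#' @param n_shuffles label shuffles per permutation test.
#' @param variant `"All"` (centers and members from all samples), `"Z-cn"`
#'   (members from all samples but centers restricted to non-network samples)
#'   or `"omit-RS"` (entire pool restricted to non-network samples).
#' @param seed master seed; every simulation derives its own stream from it.
#' @param weights_threshold_mm distance band for spatial weights (mm).
#' @param weights_scheme `"inverse_distance"` or `"binary"`.
#' @param edge_weights how correlations enter the strength sums
#'   (`"positive"`, `"absolute"`, `"raw"`).
#' @param within_tissue `"exclude"` same-tissue edges (default) or `"none"`.
#' @param denominator `"all"` eligible edges or `"incident"` to network samples.
#' @param max_proposals rejection-sampling budget for sphere packing.
#' @return A validated list with class `run_config`.
#' @export
run_config <- function(radii_mm,
                       n_clusters = 34,
                       network_composition = c(rep(3, 9), rep(2, 3), 1),
                       n_networks = 1000,
                       n_shuffles = 1000,
                       variant = c("All", "Z-cn", "omit-RS"),
                       seed = 1,
                       weights_threshold_mm = 16,
                       weights_scheme = c("inverse_distance", "binary"),
                       edge_weights = c("positive", "absolute", "raw"),
                       within_tissue = c("exclude", "none"),
                       denominator = c("all", "incident"),
                       max_proposals = 10000) {
  variant <- match.arg(variant)
  weights_scheme <- match.arg(weights_scheme)
  edge_weights <- match.arg(edge_weights)
  within_tissue <- match.arg(within_tissue)
  denominator <- match.arg(denominator)
  if (any(radii_mm < 0)) ssf_stop("ssf_config_error", "radii must be nonnegative")
  if (sum(network_composition) != n_clusters) {
    ssf_stop("ssf_config_error",
             "network_composition sums to %d but n_clusters is %d",
             sum(network_composition), n_clusters)
  }
  if (n_shuffles < 1) ssf_stop("ssf_config_error", "n_shuffles must be >= 1")
  if (weights_threshold_mm <= 0) {
    ssf_stop("ssf_config_error", "weights_threshold_mm must be positive")
  }
  structure(list(
    radii_mm = radii_mm, n_clusters = n_clusters,
    network_composition = network_composition,
    n_networks = n_networks, n_shuffles = n_shuffles,
    variant = variant, seed = as.integer(seed),
    weights_threshold_mm = weights_threshold_mm,
    weights_scheme = weights_scheme,
    edge_weights = edge_weights, within_tissue = within_tissue,
    denominator = denominator, max_proposals = max_proposals
  ), class = "run_config")
}

#' Write results (scalars, curves) as JSON
#'
#' Thin wrapper around jsonlite with scalar auto-unboxing and full numeric
#' precision, used for run summaries.
#'
#' @param x a list or data.frame of results.
#' @param path output path.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
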