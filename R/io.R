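#' Read an abundance table from TSV
#'
#' Reads a tab-delimited table (header row, first column ids) and returns a
#' validated taxa x samples abundance table.  Files written in the
#' samples-in-rows orientation (e.g. some QIIME2 exports) are transposed on
#' the way in.  Non-numeric cells, negative values and duplicated ids are
#' rejected with the offending coordinates named.
#'
#' @param path file path to a TSV with a header row; first column holds ids.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @param kind passed to [abundance_table()].
#' @return abundance table, taxa x samples.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("taxa_rows", "samples_rows"),
                                 kind = "counts") {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], names(num)[j], num[[j]][bad[1L]]))
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  abundance_table(m, kind = kind)
}

#' Write an abundance table to TSV
#'
#' @param table abundance table (taxa x samples).
#' @param path output path.
#' @param id_column header name for the id column.
#' @export
write_abundance_table <- function(table, path, id_column = "taxon_id") {
  df <- data.frame(id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' First column is the sample id; a `group` column is required; remaining
#' columns are numeric phenotypes with `NA` marking missing values.
#'
#' @param path TSV path.
#' @return data.frame with `sample_id`, `group`, and numeric phenotypes.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- "sample_id"
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!"group" %in% names(df)) stop("metadata requires a 'group' column")
  num_cols <- setdiff(names(df), c("sample_id", "group"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.infinite(v), na.rm = TRUE))
      stop("non-finite phenotype value in column '", cn, "'")
    df[[cn]] <- v
  }
  df
}

#' Write sample metadata to TSV
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample-by-sample distance matrix from TSV
#'
#' The file must be square with matching row/column ids, symmetric to
#' `1e-12` and with an exactly zero diagonal.
#'
#' @param path TSV path (header = sample ids, first column = sample ids).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  validate_distance_matrix(m)
}

validate_distance_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!is.null(colnames(m)) && !identical(rownames(m), colnames(m)))
    stop("distance matrix row and column ids differ")
  asym <- abs(m - t(m))
  if (any(asym > 1e-12)) {
    bad <- which(asym > 1e-12, arr.ind = TRUE)[1L, ]
    stop(sprintf("asymmetric distances at ('%s', '%s'): %g vs %g",
                 rownames(m)[bad[1L]], rownames(m)[bad[2L]],
                 m[bad[1L], bad[2L]], m[bad[2L], bad[1L]]))
  }
  if (any(diag(m) != 0))
    stop("nonzero diagonal at sample '",
         rownames(m)[which(diag(m) != 0)[1L]], "'")
  if (any(m < 0)) stop("negative distances are not allowed")
  m
}

#' Write a distance matrix to TSV
#' @param m symmetric distance matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(m, path) {
  validate_distance_matrix(m)
  df <- data.frame(sample_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-occurrence network to disk
#'
#' GraphML keeps all node attributes (abundance, module, Zi, Pi) and the
#' signed correlation edge attribute, suitable for Gephi/Cytoscape; the
#' edge-list TSV holds `source`, `target`, `correlation` columns.
#'
#' @param net an `igraph` network as built by [build_network()].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = TRUE)
    df <- data.frame(source = el[, 1L], target = el[, 2L],
                     correlation = igraph::E(net)$correlation,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network
#' @param path GraphML file path.
#' @return an `igraph` object.
#' @export
read_network <- function(path) igraph::read_graph(path, format = "graphml")

#' Write a JSON results envelope
#'
#' Standard envelope `{analysis, params, results}` used for machine-readable
#' stage outputs.
#'
#' @param analysis analysis name.
#' @param params named list of parameters.
#' @param results named list of results.
#' @param path output path.
#' @export
write_results_json <- function(analysis, params, results, path) {
  jsonlite::write_json(list(analysis = analysis, params = params,
                            results = results),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
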