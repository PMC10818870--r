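#' Construct and validate an abundance table
#'
#' An abundance table is a numeric matrix with taxa in rows and samples in
#' columns, row names holding taxon identifiers and column names holding
#' sample identifiers.  The `kind` attribute records whether entries are
#' raw counts (`"counts"`), relative abundances summing to one per sample
#' (`"relative"`), or log-transformed relative abundances (`"log"`).
#'
#' @param values numeric matrix, taxa x samples, with dimnames.
#' @param kind one of `"counts"`, `"relative"`, `"log"`.
#' @return the validated matrix with a `kind` attribute.
#' @examples
#' m <- matrix(c(4, 6, 1, 9), 2, 2,
#'             dimnames = list(c("ASV_1", "ASV_2"), c("S1", "S2")))
#' tab <- abundance_table(m, kind = "counts")
#' attr(tab, "kind")
#' @export
abundance_table <- function(values, kind = c("counts", "relative", "log")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("abundance table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance table must have taxon row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at taxon '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (kind != "log" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value %g at taxon '%s', sample '%s'",
                 values[bad[1L], bad[2L]],
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (kind == "relative") {
    cs <- colSums(values)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off))
      stop("relative-abundance columns must sum to 1; offending sample(s): ",
           paste(colnames(values)[off], collapse = ", "))
  }
  structure(values, kind = kind)
}

table_kind <- function(x) attr(x, "kind") %||% "counts"

stopifnot_counts <- function(x) {
  if (table_kind(x) == "relative")
    stop("a counts table is required, got relative abundances")
  invisible(x)
}

#' Convert counts to relative abundances
#'
#' @param table counts abundance table (taxa x samples).
#' @return abundance table of kind `"relative"`; each column sums to 1.
#' @export
relative_abundance <- function(table) {
  tot <- colSums(table)
  if (any(tot <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(table)[tot <= 0], collapse = ", "))
  abundance_table(sweep(table, 2L, tot, "/"), kind = "relative")
}
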