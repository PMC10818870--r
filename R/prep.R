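#' Prevalence filter
#'
#' Retains taxa detected (count > 0) in at least `fraction` of the samples,
#' inclusive at the boundary: with 24 samples and the default third, a
#' taxon present in exactly 8 samples is kept.
#'
#' @param table abundance table (taxa x samples).
#' @param fraction minimum fraction of samples, in `(0, 1]`.
#' @return filtered table; the sample set is unchanged.
#' @export
prevalence_filter <- function(table, fraction = 1 / 3) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  keep <- rowSums(table > 0) >= fraction * ncol(table)
  abundance_table(table[keep, , drop = FALSE], kind = table_kind(table))
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth`.  Samples
#' whose total is below `depth` are dropped with a warning rather than
#' padded, matching common amplicon practice.
#'
#' @param table counts table.
#' @param depth target depth (reads per sample).
#' @param seed integer seed; rarefaction is deterministic under it.
#' @return rarefied counts table; every column sums to `depth`.
#' @export
rarefy <- function(table, depth = 8509L, seed = NULL) {
  stopifnot_counts(table)
  if (depth <= 0) stop("depth must be positive")
  tot <- colSums(table)
  drop <- tot < depth
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[drop], collapse = ", "))
  kept <- table[, !drop, drop = FALSE]
  if (ncol(kept) == 0L) stop("no samples at or above the rarefaction depth")
  # vegan heuristically warns when counts lack singletons; the table is
  # already validated as counts, so that advisory is noise here
  out <- with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(kept), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  abundance_table(out, kind = "counts")
}

#' Shannon diversity of one sample
#'
#' `-sum(p_i * log(p_i))` over taxa with nonzero abundance, in natural-log
#' units by default (base configurable since amplicon pipelines differ).
#'
#' @param x non-negative abundance vector with positive total.
#' @param base logarithm base.
#' @return Shannon index (>= 0).
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0) || sum(x) <= 0) stop("need non-negative counts, total > 0")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Bias-corrected Chao1 richness of one sample
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1`/`F2` the singleton
#' and doubleton counts; equals observed richness when there are no
#' singletons.
#'
#' @param x integer count vector.
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(x) {
  if (any(x < 0) || any(x != round(x))) stop("chao1 needs integer counts")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Good's coverage of one sample
#'
#' `1 - F1 / N`: the probability that the next read belongs to a taxon
#' already observed; gauges sequencing-depth adequacy.
#'
#' @param x integer count vector with positive total.
#' @return coverage in `[0, 1]`.
#' @export
goods_coverage <- function(x) {
  if (any(x < 0) || any(x != round(x))) stop("integer counts required")
  n <- sum(x)
  if (n <= 0) stop("empty sample")
  1 - sum(x == 1) / n
}

#' Per-sample alpha diversity table
#'
#' @param table counts table (taxa x samples).
#' @param base Shannon log base.
#' @return data.frame with `sample_id`, `shannon`, `chao1`, `goods`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot_counts(table)
  data.frame(
    sample_id = colnames(table),
    shannon = apply(table, 2L, shannon, base = base),
    chao1 = apply(table, 2L, chao1),
    goods = apply(table, 2L, goods_coverage),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-transform relative abundances
#'
#' Natural log of abundance plus a pseudocount.  The default pseudocount is
#' half the smallest nonzero relative abundance in the whole table, a
#' table-scale-invariant rule that places zeros strictly below every
#' observed value; a fixed pseudocount can be supplied instead.
#'
#' @param table relative-abundance table.
#' @param rule `"half_min_nonzero"` or `"fixed"`.
#' @param pseudocount value used when `rule = "fixed"`.
#' @return log abundance table (kind `"log"`); the pseudocount used is
#'   stored in the `pseudocount` attribute.
#' @export
log_transform <- function(table, rule = c("half_min_nonzero", "fixed"),
                          pseudocount = NULL) {
  rule <- match.arg(rule)
  if (any(table < 0)) stop("negative abundances")
  pc <- switch(rule,
    half_min_nonzero = {
      nz <- table[table > 0]
      if (!length(nz)) stop("all-zero table")
      min(nz) / 2
    },
    fixed = {
      if (is.null(pseudocount) || pseudocount <= 0)
        stop("rule = 'fixed' needs a positive pseudocount")
      pseudocount
    })
  out <- abundance_table(log(table + pc), kind = "log")
  attr(out, "pseudocount") <- pc
  out
}
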