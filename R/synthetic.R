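#' Design of a synthetic two-group community experiment
#'
#' Describes a study-like 16S dataset: two groups of cows (low fecal score,
#' LFS, and high fecal score, HFS), compositional ASV counts with a
#' log-normal abundance spread, planted positively correlated taxon blocks
#' (co-occurring guilds), planted differential taxa with a group mean shift
#' on the log scale, and taxa structurally absent from one group.
#'
#' Defaults mirror the emulated study: 12 samples per group, sequencing
#' depths with mean 15623 and sd 2217 (log-normal, floored at 1000), and two
#' planted blocks at within-block correlation 0.95.
#'
#' @param n_per_group samples per group.
#' @param n_taxa number of taxa.
#' @param n_blocks number of planted positively-correlated taxon blocks.
#' @param block_size taxa per block.
#' @param block_rho target within-block correlation of latent log
#'   abundances, in `[0, 1]`.
#' @param n_diff_taxa number of taxa with a group mean shift.
#' @param effect_log2fc log2 fold change of the differential taxa
#'   (HFS relative to LFS; directions alternate + / -).
#' @param n_absent_taxa taxa forced to structural zero in the LFS group.
#' @param depth_mean,depth_sd mean and sd of the per-sample sequencing
#'   depth distribution (log-normal, truncated below at 1000).
#' @param abund_log_sd sd of per-taxon baseline log abundances; controls
#'   the community's abundance spread.
#' @param within_sd sd of the per-sample latent log-abundance noise.
#' @param seed integer seed; identical seeds give bit-identical data.
#' @return a validated `synthetic_design` list.
#' @export
synthetic_design <- function(n_per_group = 12L, n_taxa = 150L,
                             n_blocks = 2L, block_size = 15L,
                             block_rho = 0.95, n_diff_taxa = 10L,
                             effect_log2fc = 2, n_absent_taxa = 1L,
                             depth_mean = 15623, depth_sd = 2217,
                             abund_log_sd = 1.5, within_sd = 0.7,
                             seed = 1L) {
  d <- list(n_per_group = as.integer(n_per_group), n_taxa = as.integer(n_taxa),
            n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
            block_rho = block_rho, n_diff_taxa = as.integer(n_diff_taxa),
            effect_log2fc = effect_log2fc,
            n_absent_taxa = as.integer(n_absent_taxa),
            depth_mean = depth_mean, depth_sd = depth_sd,
            abund_log_sd = abund_log_sd, within_sd = within_sd,
            seed = as.integer(seed))
  if (d$n_per_group < 2L) stop("need at least 2 samples per group")
  if (d$block_rho < 0 || d$block_rho > 1) stop("block_rho must lie in [0, 1]")
  if (any(unlist(d[c("n_taxa", "n_blocks", "block_size", "n_diff_taxa",
                     "n_absent_taxa")]) < 0))
    stop("counts must be non-negative")
  n_structured <- d$n_blocks * d$block_size + d$n_diff_taxa + d$n_absent_taxa
  if (n_structured > d$n_taxa)
    stop(sprintf(paste("infeasible design: %d block + %d differential + %d",
                       "absent taxa exceed n_taxa = %d (blocks must not",
                       "overlap other planted structure)"),
                 d$n_blocks * d$block_size, d$n_diff_taxa, d$n_absent_taxa,
                 d$n_taxa))
  if (d$depth_mean <= 0 || d$depth_sd < 0) stop("invalid depth parameters")
  class(d) <- "synthetic_design"
  d
}

#' Generate a synthetic ASV count table with planted structure
#'
#' Latent log abundances are multivariate Gaussian: per-taxon baselines
#' drawn once from `N(0, abund_log_sd^2)`, per-sample noise with an
#' exchangeable within-block correlation `block_rho` (shared block factor
#' plus independent residual), and a mean shift of
#' `effect_log2fc * log(2)` applied to differential taxa in the HFS group.
#' The latent vector is mapped to a composition by softmax; absent taxa
#' have their composition entries zeroed for the LFS group *before*
#' multinomial sampling, so column sums always equal the sampled depths
#' while the planted taxa remain structurally zero.  Counts are multinomial
#' at a per-sample log-normal depth.
#'
#' @param design a [synthetic_design()].
#' @return list with `counts` (taxa x samples counts table), `metadata`
#'   (sample_id, group), and `truth` (block membership, differential taxa
#'   with direction, absent taxa, phenotype loadings).
#' @export
generate_counts <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  n <- 2L * d$n_per_group
  taxa <- sprintf("ASV_%04d", seq_len(d$n_taxa))
  samples <- c(sprintf("LFS_%02d", seq_len(d$n_per_group)),
               sprintf("HFS_%02d", seq_len(d$n_per_group)))
  groups <- rep(c("LFS", "HFS"), each = d$n_per_group)

  blk <- integer(d$n_taxa)                       # 0 = unstructured
  if (d$n_blocks > 0L && d$block_size > 0L)
    blk[seq_len(d$n_blocks * d$block_size)] <-
      rep(seq_len(d$n_blocks), each = d$block_size)
  off <- d$n_blocks * d$block_size
  diff_idx <- if (d$n_diff_taxa > 0L) off + seq_len(d$n_diff_taxa) else integer()
  absent_idx <- if (d$n_absent_taxa > 0L)
    off + d$n_diff_taxa + seq_len(d$n_absent_taxa) else integer()
  dir <- if (length(diff_idx)) rep_len(c(1, -1), length(diff_idx)) else numeric()

  counts <- with_seed(d$seed, {
    mu <- stats::rnorm(d$n_taxa, 0, d$abund_log_sd)
    # planted structure (blocks, differential, absent taxa) sits at the
    # detectable sub-percent relative-abundance scale, like the study's
    # differential genera and network members, so the planted signal is
    # identifiable rather than censored by sequencing depth; unstructured
    # taxa carry the full log-normal abundance spread
    planted <- c(which(blk > 0L), diff_idx, absent_idx)
    mu[planted] <- stats::rnorm(length(planted), 1, 0.5)
    shift <- numeric(d$n_taxa)
    shift[diff_idx] <- dir * d$effect_log2fc * log(2)
    m <- matrix(0L, d$n_taxa, n, dimnames = list(taxa, samples))
    depths <- pmax(1000, round(stats::rlnorm(
      n,
      meanlog = log(d$depth_mean^2 / sqrt(d$depth_mean^2 + d$depth_sd^2)),
      sdlog = sqrt(log(1 + d$depth_sd^2 / d$depth_mean^2)))))
    for (s in seq_len(n)) {
      eps <- stats::rnorm(d$n_taxa)
      g <- stats::rnorm(max(d$n_blocks, 1L))
      z <- mu + ifelse(blk > 0L,
                       d$within_sd * (sqrt(d$block_rho) * g[pmax(blk, 1L)] +
                                        sqrt(1 - d$block_rho) * eps),
                       d$within_sd * eps)
      if (groups[s] == "HFS") z <- z + shift
      p <- exp(z - max(z))
      if (groups[s] == "LFS") p[absent_idx] <- 0
      p <- p / sum(p)
      m[, s] <- stats::rmultinom(1L, depths[s], p)[, 1L]
    }
    m
  })

  loadings <- if (length(diff_idx)) stats::setNames(1, taxa[diff_idx[1L]])
              else stats::setNames(1, taxa[1L])
  truth <- list(
    block_membership = stats::setNames(blk, taxa),
    differential_taxa = data.frame(taxon = taxa[diff_idx],
                                   direction = dir,
                                   stringsAsFactors = FALSE),
    absent_taxa = taxa[absent_idx],
    absent_group = "LFS",
    phenotype_loadings = loadings)
  list(counts = abundance_table(counts, kind = "counts"),
       metadata = data.frame(sample_id = samples, group = groups,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate phenotypes correlated with chosen taxa
#'
#' Builds a numeric phenotype (named `fecal_water_content`) as a linear
#' combination of the relative abundances of the loaded taxa plus Gaussian
#' noise, and a group-informed `fecal_score` (LFS low, HFS high on the
#' 5-point scale).
#'
#' @param table counts or relative abundance table.
#' @param truth truth object from [generate_counts()] (uses
#'   `phenotype_loadings`); a plain named numeric vector of loadings is
#'   also accepted.
#' @param noise_sd sd of the additive Gaussian noise.
#' @param seed integer seed.
#' @param metadata optional metadata frame with `sample_id` and `group`;
#'   groups default to the `LFS_`/`HFS_` sample-id prefixes.
#' @return sample metadata data.frame with group and phenotypes.
#' @export
generate_phenotypes <- function(table, truth, noise_sd = 0.01, seed = 1L,
                                metadata = NULL) {
  loadings <- if (is.list(truth)) truth$phenotype_loadings else truth
  if (is.null(names(loadings)) || !all(names(loadings) %in% rownames(table)))
    stop("phenotype loadings must reference taxa present in the table")
  rel <- if (table_kind(table) == "relative") table else relative_abundance(table)
  base <- drop(crossprod(rel[names(loadings), , drop = FALSE], loadings))
  groups <- if (!is.null(metadata)) {
    metadata$group[match(colnames(table), metadata$sample_id)]
  } else {
    sub("_.*$", "", colnames(table))
  }
  with_seed(seed, {
    phen <- base + stats::rnorm(ncol(table), 0, noise_sd)
    score <- ifelse(groups == "HFS",
                    stats::rnorm(ncol(table), 3.5, 0.4),
                    stats::rnorm(ncol(table), 2.0, 0.3))
    data.frame(sample_id = colnames(table), group = groups,
               fecal_score = round(pmin(5, pmax(1, score)), 2),
               fecal_water_content = phen,
               stringsAsFactors = FALSE)
  })
}

#' Generate marker/nutrient concentration records for digestibility
#'
#' Simulates acid-insoluble-ash (AIA) marker and nutrient concentrations in
#' diet and feces for a set of animals, starting from a chosen true
#' apparent total-tract digestibility per nutrient, so the marker-ratio
#' formula recovers the simulated truth exactly.  Marker concentrates in
#' feces (`Af >= Ad`) because dry matter disappears along the tract.
#'
#' @param seed integer seed.
#' @param n_animals number of animals.
#' @param nutrients nutrient labels.
#' @return data.frame with columns `animal`, `nutrient`, `Ad`, `Af`, `Nd`,
#'   `Nf` (all g/kg) and the simulated `true_attd` (percent).
#' @export
generate_attd_inputs <- function(seed = 1L, n_animals = 24L,
                                 nutrients = c("OM", "NDF", "ADF", "EE", "CP")) {
  nd_typical <- c(OM = 920, NDF = 350, ADF = 220, EE = 40, CP = 170)
  attd_range <- list(OM = c(60, 75), NDF = c(40, 60), ADF = c(35, 55),
                     EE = c(60, 80), CP = c(55, 70))
  with_seed(seed, {
    Ad <- stats::runif(1L, 6, 10)               # one diet for all animals
    dmd <- stats::runif(n_animals, 0.55, 0.75)  # dry-matter disappearance
    rows <- lapply(nutrients, function(nu) {
      rng <- attd_range[[nu]] %||% c(40, 80)
      tr <- stats::runif(n_animals, rng[1L], rng[2L])
      Nd <- nd_typical[[nu]] %||% 200
      Af <- Ad / (1 - dmd)
      data.frame(animal = sprintf("cow_%02d", seq_len(n_animals)),
                 nutrient = nu, Ad = Ad, Af = Af, Nd = Nd,
                 Nf = (1 - tr / 100) * Af * Nd / Ad,
                 true_attd = tr, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
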