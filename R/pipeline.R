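#' Run the full co-occurrence analysis pipeline
#'
#' Orchestrates the end-to-end study replica from one configuration:
#' simulate (or load) a two-group count table, preprocess (rarefaction,
#' prevalence filter, alpha diversity), fit one co-occurrence network per
#' group, summarise topology and node roles, run the stability analyses
#' (random and targeted robustness, connectedness, cohesion, group
#' comparison), the two-group statistics (Wilcoxon + BH, Bray-Curtis
#' PERMANOVA, Spearman screen) and the digestibility calculation, writing
#' per-stage TSV/JSON artifacts plus a manifest with every parameter, seed
#' and file checksum.
#'
#' @param config named list, or path to a YAML/JSON file.  Recognised
#'   blocks (all optional, with defaults): `simulate` (arguments of
#'   [synthetic_design()]) or `input` (`counts`, `metadata`, optionally
#'   `attd` file paths), `prep` (`depth`, `prevalence`), `network`
#'   (`grid_min`, `grid_max`, `grid_step`, `min_eigs`, `alpha`),
#'   `robustness` (`fraction`, `replicates`, `n_hubs`, `cascade`,
#'   `theta`), `cohesion` (`null_reps`), `statistics` (`permutations`,
#'   `min_prevalence`, `phenotype`), and a global `seed`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stages <- character()
  put <- function(name) { files <<- c(files, file.path(out_dir, name)); files[length(files)] }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  ## 1. simulate or load ----
  dat <- stage("simulate", {
    if (!is.null(cfg$input)) {
      counts <- read_abundance_table(cfg$input$counts)
      meta <- read_sample_metadata(cfg$input$metadata)
      attd_in <- if (!is.null(cfg$input$attd))
        utils::read.delim(cfg$input$attd) else NULL
      list(counts = counts, metadata = meta, truth = NULL, attd = attd_in)
    } else {
      design <- do.call(synthetic_design,
                        utils::modifyList(cfg$simulate,
                                          list(seed = derive_seed(cfg$seed, 1L))))
      sim <- generate_counts(design)
      meta <- generate_phenotypes(sim$counts, sim$truth,
                                  seed = derive_seed(cfg$seed, 2L),
                                  metadata = sim$metadata)
      attd_in <- generate_attd_inputs(seed = derive_seed(cfg$seed, 3L))
      write_abundance_table(sim$counts, put("counts.tsv"))
      write_sample_metadata(meta, put("metadata.tsv"))
      jsonlite::write_json(sim$truth, put("truth.json"), auto_unbox = TRUE,
                           digits = NA)
      list(counts = sim$counts, metadata = meta, truth = sim$truth,
           attd = attd_in)
    }
  })
  groups <- dat$metadata$group[match(colnames(dat$counts),
                                     dat$metadata$sample_id)]
  glev <- unique(groups)
  if (length(glev) != 2L) stop("pipeline expects exactly two groups")

  ## 2. prep ----
  prep <- stage("prep", {
    rar <- rarefy(dat$counts, depth = cfg$prep$depth,
                  seed = derive_seed(cfg$seed, 4L))
    div <- alpha_diversity(rar)
    utils::write.table(div, put("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    filt <- prevalence_filter(rar, cfg$prep$prevalence)
    write_abundance_table(filt, put("filtered_counts.tsv"))
    list(rarefied = rar, filtered = filt, diversity = div)
  })
  g_of <- groups[match(colnames(prep$rarefied), colnames(dat$counts))]

  ## 3. per-group networks ----
  nets <- stage("network", {
    grid <- seq(cfg$network$grid_min, cfg$network$grid_max,
                by = cfg$network$grid_step)
    out <- lapply(glev, function(g) {
      fit <- conet(prep$rarefied[, g_of == g, drop = FALSE],
                   prevalence = cfg$prep$prevalence, grid = grid,
                   min_eigs = cfg$network$min_eigs, alpha = cfg$network$alpha,
                   seed = derive_seed(cfg$seed, 5L))
      write_network(fit$graph, put(paste0("network_", g, ".graphml")))
      utils::write.table(fit$scan$scan,
                         put(paste0("rmt_scan_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    })
    names(out) <- glev
    out
  })

  ## 4. topology ----
  stage("topology", {
    topo <- do.call(rbind, lapply(glev, function(g) {
      t <- nets[[g]]$topology
      data.frame(group = g, nodes = t$node_count, edges = t$edge_count,
                 average_degree = t$average_degree,
                 average_distance = t$average_distance,
                 components = t$n_components,
                 modularity = nets[[g]]$modules$modularity,
                 threshold = nets[[g]]$threshold)
    }))
    utils::write.table(topo, put("topology.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    zp <- do.call(rbind, lapply(glev, function(g)
      cbind(group = g, nets[[g]]$zipi)))
    utils::write.table(zp, put("zipi.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    topo
  })

  ## 5. stability ----
  stab <- stage("stability", {
    rp <- cfg$robustness
    rob <- lapply(glev, function(g) robustness_random(
      nets[[g]]$graph, fraction = rp$fraction, replicates = rp$replicates,
      cascade = rp$cascade, theta = rp$theta,
      seed = derive_seed(cfg$seed, 6L)))
    names(rob) <- glev
    tar <- lapply(glev, function(g) suppressWarnings(robustness_targeted(
      nets[[g]]$graph, nets[[g]]$zipi, n_hubs = rp$n_hubs,
      cascade = rp$cascade, theta = rp$theta)))
    names(tar) <- glev
    coh <- lapply(glev, function(g) {
      rel <- relative_abundance(
        prevalence_filter(prep$rarefied[, g_of == g, drop = FALSE],
                          cfg$prep$prevalence))
      conn <- connectedness(rel, null_reps = cfg$cohesion$null_reps,
                            seed = derive_seed(cfg$seed, 7L))
      cohesion(rel, conn)
    })
    names(coh) <- glev
    rob_tab <- do.call(rbind, lapply(glev, function(g)
      data.frame(group = g, replicate = seq_along(rob[[g]]$values),
                 robustness = rob[[g]]$values)))
    utils::write.table(rob_tab, put("robustness_random.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    coh_tab <- do.call(rbind, lapply(glev, function(g) cbind(group = g, coh[[g]])))
    utils::write.table(coh_tab, put("cohesion.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cmp <- list(
      robustness_random = compare_stability(rob[[1L]]$values, rob[[2L]]$values),
      cohesion_pos = compare_stability(coh[[1L]]$cohesion_pos,
                                       coh[[2L]]$cohesion_pos),
      cohesion_neg = compare_stability(coh[[1L]]$cohesion_neg,
                                       coh[[2L]]$cohesion_neg))
    write_results_json("network_stability", cfg$robustness, list(
      robustness_random_mean = lapply(rob, function(r) r$mean),
      robustness_targeted = lapply(tar, function(r) r$mean),
      comparisons = cmp), put("stability.json"))
    list(robustness = rob, targeted = tar, cohesion = coh, comparisons = cmp)
  })

  ## 6. statistics ----
  stage("statistics", {
    rel <- relative_abundance(prep$filtered)
    wt <- wilcoxon_fdr(rel, g_of)
    utils::write.table(wt, put("wilcoxon_fdr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bc <- bray_curtis(rel)
    write_distance_matrix(bc, put("bray_curtis.tsv"))
    pmv <- permanova(bc, g_of, permutations = cfg$statistics$permutations,
                     seed = derive_seed(cfg$seed, 8L))
    phen <- cfg$statistics$phenotype
    scr <- if (!is.null(phen) && phen %in% names(dat$metadata)) {
      ph <- dat$metadata[[phen]][match(colnames(rel), dat$metadata$sample_id)]
      s <- spearman_screen(rel, ph,
                           min_prevalence = cfg$statistics$min_prevalence)
      utils::write.table(s, put("spearman_screen.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      s
    } else NULL
    write_results_json("group_comparison",
                       cfg$statistics,
                       list(permanova_F = pmv$F, permanova_p = pmv$p,
                            n_features_tested = nrow(wt),
                            n_significant_padj05 = sum(wt$padj <= 0.05)),
                       put("statistics.json"))
    list(wilcoxon = wt, permanova = pmv, spearman = scr)
  })

  ## 7. digestibility ----
  stage("digestibility", {
    if (!is.null(dat$attd)) {
      res <- attd(dat$attd)
      utils::write.table(res, put("attd.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      res
    } else NULL
  })

  manifest <- list(
    stages_completed = stages,
    seed = cfg$seed,
    params = cfg[setdiff(names(cfg), "input")],
    files = lapply(stats::setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Fill defaults and validate every stage's parameters up front, so a bad
# config fails before any stage runs.
pipeline_config <- function(config) {
  cfg <- utils::modifyList(list(
    seed = 1L,
    simulate = list(),
    input = NULL,
    prep = list(depth = 8509L, prevalence = 1 / 3),
    network = list(grid_min = 0.30, grid_max = 0.95, grid_step = 0.01,
                   min_eigs = 50L, alpha = 0.05),
    robustness = list(fraction = 0.5, replicates = 100L, n_hubs = 3L,
                      cascade = "degree_zero", theta = 0.5),
    cohesion = list(null_reps = 200L),
    statistics = list(permutations = 1000L, min_prevalence = 0.5,
                      phenotype = "fecal_water_content")),
    config)
  if (is.null(cfg$input)) do.call(synthetic_design, cfg$simulate)
  stopifnot(cfg$prep$depth >= 1, cfg$prep$prevalence > 0,
            cfg$prep$prevalence <= 1,
            cfg$network$grid_min < cfg$network$grid_max,
            cfg$network$grid_step > 0, cfg$network$min_eigs >= 3,
            cfg$robustness$fraction > 0, cfg$robustness$fraction < 1,
            cfg$robustness$replicates >= 1,
            cfg$robustness$theta > 0, cfg$robustness$theta < 1,
            cfg$cohesion$null_reps >= 1,
            cfg$statistics$permutations >= 1)
  cfg
}
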