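#' Pipeline configuration
#'
#' Validates and assembles the thresholds and sizes used by
#' [run_pipeline()]. Unknown keys are rejected. Defaults are the package's
#' canonical parameters: statistic cutoffs 2 (strict) and 1.5 (relaxed),
#' breadth floor 3, overlap maxgap 100 bp, promoter half-width 2 kb, stitch
#' distance 12.5 kb, link window 500 kb, BFDR 0.02 and fold change 3, and
#' permutation counts 1,000 (enrichment), 100 (proximity curves) and
#' 10,000 (link enrichment).
#'
#' @param seed Integer seed driving the synthetic scenario and every
#'   permutation stream.
#' @param outdir Output directory.
#' @param scenario A [synthetic_scenario()]; defaults to
#'   `synthetic_scenario(seed)`.
#' @param ... Threshold overrides (see Details in the source; e.g.
#'   `stat_cutoff`, `relaxed_cutoff`, `breadth_min`, `max_gap`,
#'   `promoter_half_width`, `stitch_dist`, `link_max_dist`, `bfdr_max`,
#'   `fc_min`, `n_iter_enrich`, `n_perm_curve`, `n_iter_links`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("tfscape_run_"),
                            scenario = NULL, ...) {
  defaults <- list(
    stat_cutoff = 2, relaxed_cutoff = 1.5, breadth_min = 3, max_gap = 100,
    promoter_half_width = 2000, stitch_dist = 12500, link_max_dist = 5e5,
    link_fdr = 0.05, bfdr_max = 0.02, fc_min = 3,
    n_iter_enrich = 1000, n_perm_curve = 100, n_iter_links = 10000
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  params <- utils::modifyList(defaults, overrides)
  if (any(unlist(params) <= 0)) abort("all thresholds must be positive")
  structure(
    list(seed = as.integer(seed), outdir = outdir,
         scenario = scenario %||% synthetic_scenario(seed = as.integer(seed)),
         params = params),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `seed`, `outdir`, `scenario` (a mapping of
#' [synthetic_scenario()] arguments) and `params` (threshold overrides).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- if (!is.null(y$scenario)) {
    do.call(synthetic_scenario,
            utils::modifyList(list(seed = as.integer(y$seed %||% 1L)),
                              y$scenario))
  } else NULL
  do.call(pipeline_config,
          c(list(seed = y$seed %||% 1L, outdir = y$outdir %||% tempfile(),
                 scenario = scenario),
            y$params %||% list()))
}

stitched_constituent_sum <- function(stitched, peak_ids, values) {
  vapply(strsplit(stitched$constituents, ",", fixed = TRUE),
         function(ids) sum(values[match(ids, peak_ids)]), numeric(1))
}

#' Run the integrated synthetic-data pipeline
#'
#' Generates a full synthetic scenario, then executes every analysis stage
#' in dependency order: gene and peak contrast statistics and cluster
#' assignment (strict and relaxed), annotation-category and histone-mark
#' permutation enrichment per cluster, peak-breadth comparison, the
#' TSS-proximity enrichment curve, promoter-enhancer links and their
#' enrichment test, super-enhancer stitching and ranking, bait-prey
#' filtering and network construction, and signature survival
#' stratification. Per-stage tables are written under `config$outdir`
#' together with `results.json` (headline numbers) and `manifest.json`
#' (seed, parameters, package version). Re-running with the same config
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (default all):
#'   `"contrasts"`, `"clusters"`, `"enrichment"`, `"curves"`, `"links"`,
#'   `"superenh"`, `"bioid"`, `"survival"`. Dependencies of a requested
#'   stage run automatically.
#' @return Invisibly, a named list with every stage's in-memory results.
#' @export
run_pipeline <- function(config,
                         stages = c("contrasts", "clusters", "enrichment",
                                    "curves", "links", "superenh", "bioid",
                                    "survival")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c("clusters", "enrichment", "curves", "survival") %in% stages)) {
    stages <- union(stages, "contrasts")
  }
  if (any(c("enrichment", "curves", "survival") %in% stages)) {
    stages <- union(stages, "clusters")
  }
  pr <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, paste0(...))
  res <- list()
  results_json <- list()

  scenario <- config$scenario
  genome <- simulate_genome(scenario)
  gene_sim <- simulate_counts(scenario, genome)
  peak_sim <- simulate_peaks(scenario, genome)
  peaks <- annotate_peaks(peak_sim$peaks, genome,
                          promoter_half_width = pr$promoter_half_width)
  chip <- simulate_chip(scenario, genome, peak_sim$peaks, gene_sim$truth)

  if ("contrasts" %in% stages) {
    gene_counts <- filter_low_expression(gene_sim$counts)
    res$gene_contrasts <- contrast_stats(gene_counts, gene_sim$design)
    res$peak_contrasts <- contrast_stats(peak_sim$counts, peak_sim$design)
    readr::write_tsv(res$gene_contrasts, out("gene_contrasts.tsv"))
    readr::write_tsv(res$peak_contrasts, out("peak_contrasts.tsv"))
  }
  if ("clusters" %in% stages) {
    res$gene_clusters <- assign_gene_clusters(res$gene_contrasts,
                                              threshold = pr$stat_cutoff)
    res$peak_clusters <- assign_peak_clusters(res$peak_contrasts,
                                              threshold = pr$stat_cutoff)
    res$relaxed_clusters <- assign_relaxed_clusters(
      res$peak_contrasts, peaks,
      threshold = pr$relaxed_cutoff, breadth_min = pr$breadth_min)
    readr::write_tsv(res$gene_clusters, out("gene_clusters.tsv"))
    readr::write_tsv(res$peak_clusters, out("peak_clusters.tsv"))
    readr::write_tsv(res$relaxed_clusters, out("relaxed_clusters.tsv"))
    results_json$n_clustered_genes <-
      sum(res$gene_clusters$cluster != "none")
    results_json$n_clustered_peaks <-
      sum(res$peak_clusters$cluster != "none")
  }
  if ("enrichment" %in% stages) {
    assigned <- res$peak_clusters
    enrich <- list()
    for (cl in LETTERS[1:6]) {
      ids <- assigned$feature_id[assigned$cluster == cl]
      if (length(ids) < 2) next
      cl_peaks <- peaks[peaks$peak_id %in% ids, ]
      enrich[[cl]] <- list(
        promoter = tidy(category_enrichment_test(
          cl_peaks, peaks, "promoter-TSS",
          n_iter = pr$n_iter_enrich, seed = config$seed)),
        marks = tidy(mark_overlap_test(
          cl_peaks, peaks, chip$marks,
          n_iter = pr$n_iter_enrich, seed = config$seed,
          max_gap = pr$max_gap))
      )
    }
    res$enrichment <- enrich
    res$breadth <- breadth_compare(
      peaks[peaks$annotation == "promoter-TSS", ],
      peaks[peaks$annotation == "intergenic", ])
    jsonlite::write_json(list(enrichment = enrich, breadth = res$breadth),
                         out("enrichment.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("curves" %in% stages) {
    targets <- res$gene_clusters$feature_id[res$gene_clusters$cluster == "5"]
    pool <- res$gene_clusters$feature_id[res$gene_clusters$cluster == "none"]
    if (length(targets) >= 3) {
      res$curve <- tss_enrichment_curve(
        check_peaks(chip$er_MAFE2), targets, pool, genome,
        n_perm = pr$n_perm_curve, seed = config$seed)
      readr::write_tsv(tidy(res$curve), out("proximity_curve.tsv"))
    }
    res$meta_profile <- tss_meta_profile(
      peak_sim$counts, distance_to_tss(peak_sim$peaks, genome),
      peak_sim$design)
    readr::write_tsv(res$meta_profile, out("tss_meta_profile.tsv"))
  }
  if ("links" %in% stages) {
    link_sim <- simulate_link_data(scenario, genome)
    res$links <- build_links(link_sim$peak_signal, link_sim$expression,
                             link_sim$peaks, genome,
                             max_dist = pr$link_max_dist, fdr = pr$link_fdr)
    res$link_enrichment <- link_enrichment_test(
      candidate_peaks = link_sim$truth$peak_id,
      target_promoters = link_sim$truth$gene_id,
      links = res$links, all_peaks = link_sim$peaks$peak_id,
      n_iter = pr$n_iter_links, seed = config$seed)
    readr::write_tsv(res$links, out("links.tsv"))
    results_json$n_links <- nrow(res$links)
    results_json$link_enrichment_p <- res$link_enrichment$p_value
  }
  if ("superenh" %in% stages) {
    k27 <- check_peaks(chip$marks$H3K27ac)
    stitched <- stitch_enhancers(k27, genome,
                                 stitch_dist = pr$stitch_dist,
                                 promoter_exclusion = pr$promoter_half_width)
    signal <- stitched_constituent_sum(stitched, k27$peak_id, k27$signal)
    res$super_enhancers <- rank_super_enhancers(stitched, signal)
    readr::write_tsv(res$super_enhancers, out("super_enhancers.tsv"))
    results_json$n_super_enhancers <- sum(res$super_enhancers$is_super)
  }
  if ("bioid" %in% stages) {
    saint <- simulate_saint(scenario)
    reduced <- saint$table |> merge_engine_counts() |> select_top_replicates(k = 3)
    sets <- filter_high_confidence(reduced, bfdr_max = pr$bfdr_max,
                                   fc_min = pr$fc_min)
    res$bait_network <- build_bait_network(sets)
    jsonlite::write_json(res$bait_network[c("s_common", "l_common",
                                            "network", "fourway")],
                         out("bait_network.json"), pretty = TRUE)
    results_json$bioid_network_size <-
      unname(res$bait_network$sizes["network"])
  }
  if ("survival" %in% stages) {
    cohort <- simulate_cohort(scenario)
    cl1 <- res$gene_clusters$feature_id[res$gene_clusters$cluster == "1"]
    signature <- build_signature(cl1, chip$er_MAF, chip$er_MAFE2, genome)
    # the synthetic cohort carries its own signature gene ids
    signature_in_cohort <- if (any(signature %in% rownames(cohort$expression))) {
      signature
    } else cohort$truth$signature_genes
    scores <- score_samples(cohort$expression, signature_in_cohort)
    groups <- stratify_scores(scores)
    res$survival <- km_logrank(cohort$clinical, groups)
    res$signature <- signature
    readr::write_tsv(tidy(res$survival), out("km_curves.tsv"))
    results_json$logrank_p <- res$survival$p_value
    results_json$n_signature_genes <- length(signature)
  }

  jsonlite::write_json(results_json, out("results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "tfscape",
    version = as.character(utils::packageVersion("tfscape")),
    seed = config$seed,
    stages = stages,
    params = pr,
    param_hash = rlang::hash(pr),
    coordinates = "0-based half-open"
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
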