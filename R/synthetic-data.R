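#' Define a synthetic-data scenario
#'
#' A scenario bundles every parameter of the synthetic data generators:
#' genome size, the 2x2 perturbation design (factor overexpression crossed
#' with hormone stimulation: mock, mockE2, MAF, MAFE2), planted effect
#' sizes, enrichment fractions, link correlation, interactor structure and
#' the survival-cohort hazard effect. Each `simulate_*()` generator takes a
#' scenario and returns its data together with the ground truth used by
#' recovery tests. The same scenario (same seed) always reproduces identical
#' outputs.
#'
#' Defaults describe a deliberately recoverable instance: 2,000 genes and
#' 5,000 peaks on a 4 x 25 Mb genome, 3 replicates per condition,
#' negative-binomial counts with dispersion 0.1 and planted |log2 FC| = 2,
#' promoter fractions 0.8 (cluster peaks) vs 0.2 (background), link
#' correlation 0.7 over 50 samples, and a hazard ratio of 3 for the planted
#' survival signature in a cohort of 200.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_chrom,chrom_size,n_genes Genome layout.
#' @param n_rep Replicates per condition in the 2x2 design.
#' @param n_genes_per_cluster Genes planted per expression cluster (1-6).
#' @param lfc Planted absolute log2 fold change for cluster effects.
#' @param dispersion Negative-binomial dispersion alpha (Var = mu + alpha mu^2).
#' @param n_peaks,n_peaks_per_cluster Peak universe size and planted peaks
#'   per accessibility cluster (A-F).
#' @param promoter_frac_cluster,promoter_frac_bg Planted promoter-TSS
#'   fractions for cluster vs background peaks.
#' @param mark_frac_cluster,mark_frac_bg Planted histone-mark overlap
#'   fractions for cluster vs background peaks.
#' @param n_link_samples,link_rho,n_linked Link-data cohort size, planted
#'   peak-gene correlation, and number of planted linked pairs.
#' @param n_prey Preys in the simulated bait-prey table.
#' @param n_cohort,hazard_ratio,baseline_hazard,censor_max,n_signature_genes
#'   Survival cohort size, planted hazard ratio for the low-signature group,
#'   baseline exponential hazard (per month), uniform censoring horizon
#'   (months), and signature size.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_chrom = 4L,
                               chrom_size = 25e6,
                               n_genes = 2000L,
                               n_rep = 3L,
                               n_genes_per_cluster = 50L,
                               lfc = 2,
                               dispersion = 0.1,
                               n_peaks = 5000L,
                               n_peaks_per_cluster = 80L,
                               promoter_frac_cluster = 0.8,
                               promoter_frac_bg = 0.2,
                               mark_frac_cluster = 0.7,
                               mark_frac_bg = 0.2,
                               n_link_samples = 50L,
                               link_rho = 0.7,
                               n_linked = 100L,
                               n_prey = 300L,
                               n_cohort = 200L,
                               hazard_ratio = 3,
                               baseline_hazard = 0.015,
                               censor_max = 120,
                               n_signature_genes = 30L) {
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (n_rep < 2) abort("need >= 2 replicates per condition")
  if (any(chrom_size <= 0)) abort("chromosome sizes must be positive")
  sc <- as.list(environment())
  sc$conditions <- c("mock", "mockE2", "MAF", "MAFE2")
  structure(sc, class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> seed ", x$seed, ": ", x$n_genes, " genes, ",
      x$n_peaks, " peaks, ", x$n_rep, " reps/condition\n", sep = "")
  invisible(x)
}

# the 2x2 design table
scenario_design <- function(scenario) {
  tibble(
    sample = paste(rep(scenario$conditions, each = scenario$n_rep),
                   seq_len(scenario$n_rep), sep = "_"),
    condition = factor(rep(scenario$conditions, each = scenario$n_rep),
                       levels = scenario$conditions)
  )
}

#' Simulate a genome model
#'
#' Places `n_genes` genes with TSS positions uniform over the genome,
#' random strand, and log-normal gene lengths (median 20 kb), clipped to
#' chromosome bounds so the TSS distribution stays exactly uniform.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [genome_model()].
#' @export
simulate_genome <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sizes <- rep_len(scenario$chrom_size, scenario$n_chrom)
  names(sizes) <- paste0("chr", seq_len(scenario$n_chrom))
  min_len <- 200
  if (scenario$n_genes * min_len > 0.9 * sum(sizes)) {
    abort("gene density infeasible for the requested genome size")
  }
  withr::with_seed(scenario$seed + 1L, {
    n <- scenario$n_genes
    if (n == 0) {
      genes <- tibble(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character())
      return(genome_model(genes, sizes))
    }
    chrom <- sample(names(sizes), n, replace = TRUE, prob = sizes / sum(sizes))
    tss <- floor(runif(n, 0, sizes[chrom]))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- pmax(min_len, round(exp(rnorm(n, log(20000), 0.6))))
    start <- ifelse(strand == "+", tss, pmax(tss - len + 1, 0))
    end <- ifelse(strand == "+", pmin(tss + len, sizes[chrom]), tss + 1)
    genes <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      chrom = chrom, start = start, end = end, strand = strand
    )
    genome_model(genes, sizes)
  })
}

# planted log2 fold-change matrix (features x conditions) for cluster labels
# cluster semantics: 1/A factor-up, 2/B factor-down, 3/C hormone-up,
# 4/D hormone-down, 5/E both-up (only the doubly treated condition moves),
# 6/F both-down
cluster_lfc_matrix <- function(labels, lfc, conditions) {
  m <- matrix(0, nrow = length(labels), ncol = length(conditions),
              dimnames = list(NULL, conditions))
  m[labels %in% c(1, 2), c("MAF", "MAFE2")] <- lfc
  m[labels %in% c(3, 4), c("mockE2", "MAFE2")] <- lfc
  m[labels %in% c(5, 6), "MAFE2"] <- lfc
  m[labels %in% c(2, 4, 6), ] <- -m[labels %in% c(2, 4, 6), ]
  m
}

simulate_nb_matrix <- function(base_mean, lfc_mat, design, dispersion) {
  n <- length(base_mean)
  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(names(base_mean), design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- base_mean * 2^lfc_mat[, as.character(design$condition[j])]
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  counts
}

#' Simulate an RNA-seq-like count matrix with planted gene clusters
#'
#' Draws negative-binomial counts (Var = mu + alpha mu^2) under the 2x2
#' design. A subset of genes is planted into the six expression clusters:
#' (1) factor-upregulated, (2) factor-downregulated, (3) hormone-up,
#' (4) hormone-down, (5) up only under the combined treatment, (6) down only
#' under the combined treatment. Planted genes receive moderately high
#' baseline means so their effects are detectable at the scenario's
#' replicate count; null genes span a wide baseline range.
#'
#' @param scenario A [synthetic_scenario()].
#' @param genome Optional [genome_model()] supplying gene ids (its gene
#'   count must match `scenario$n_genes`).
#' @return List with `counts` (matrix genes x samples), `design` (tibble),
#'   and `truth` (tibble `gene_id`, `cluster` with `"none"` for null genes,
#'   `lfc`).
#' @export
simulate_counts <- function(scenario, genome = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  design <- scenario_design(scenario)
  n <- scenario$n_genes
  ids <- if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_model"), nrow(genome$genes) == n)
    genome$genes$gene_id
  } else sprintf("gene_%04d", seq_len(n))
  withr::with_seed(scenario$seed + 2L, {
    k <- scenario$n_genes_per_cluster
    if (6 * k > n) abort("too many planted genes for `n_genes`")
    planted <- if (k > 0) sample(n, 6 * k) else integer()
    cluster <- rep("none", n)
    cluster[planted] <- as.character(rep(1:6, each = k))
    base_mean <- exp(rnorm(n, log(150), 1))
    base_mean[planted] <- exp(rnorm(length(planted), log(200), 0.5))
    names(base_mean) <- ids
    lfc_mat <- cluster_lfc_matrix(cluster, scenario$lfc, scenario$conditions)
    counts <- simulate_nb_matrix(base_mean, lfc_mat, design, scenario$dispersion)
    truth <- tibble(gene_id = ids, cluster = cluster,
                    base_mean = unname(base_mean),
                    lfc = ifelse(cluster == "none", 0,
                                 ifelse(cluster %in% c("2", "4", "6"),
                                        -scenario$lfc, scenario$lfc)))
    list(counts = counts, design = design, truth = truth)
  })
}

place_peaks <- function(n, genome, widths, near_tss = rep(FALSE, n),
                        tss_jitter = 1500) {
  sizes <- genome$chrom_sizes
  chrom <- sample(names(sizes), n, replace = TRUE, prob = sizes / sum(sizes))
  mid <- floor(runif(n, 0, sizes[chrom]))
  if (any(near_tss) && nrow(genome$genes) > 0) {
    g <- genome$genes[sample(nrow(genome$genes), sum(near_tss), replace = TRUE), ]
    chrom[near_tss] <- g$chrom
    mid[near_tss] <- g$tss + round(runif(sum(near_tss), -tss_jitter, tss_jitter))
  }
  start <- pmax(0, mid - floor(widths / 2))
  end <- pmin(start + widths, sizes[chrom])
  start <- pmin(start, end - 1)
  tibble(chrom = chrom, start = start, end = end)
}

#' Simulate an accessibility peak set with planted clusters and enrichment
#'
#' Generates `n_peaks` consensus peaks with a per-sample count matrix under
#' the 2x2 design. Planted cluster peaks (A-F, same contrast semantics as
#' the gene clusters 1-6) are placed near TSSs with probability
#' `promoter_frac_cluster` (background peaks: `promoter_frac_bg`), and
#' cluster A/E peaks are drawn broad (width 1.5-6 kb) so that the
#' promoter+breadth filters of the relaxed cluster rules have planted
#' signal to find.
#'
#' @inheritParams simulate_counts
#' @param genome A [genome_model()] (required: peaks live on it).
#' @return List with `peaks` (tibble incl. `true_cluster`,
#'   `true_promoter`), `counts`, `design`, `truth`.
#' @export
simulate_peaks <- function(scenario, genome) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(genome, "genome_model"))
  design <- scenario_design(scenario)
  n <- scenario$n_peaks
  k <- scenario$n_peaks_per_cluster
  if (6 * k > n) abort("too many planted peaks for `n_peaks`")
  withr::with_seed(scenario$seed + 3L, {
    cluster <- rep("none", n)
    planted <- if (k > 0) sample(n, 6 * k) else integer()
    cluster[planted] <- rep(LETTERS[1:6], each = k)
    near_tss <- runif(n) < ifelse(cluster == "none",
                                  scenario$promoter_frac_bg,
                                  scenario$promoter_frac_cluster)
    widths <- round(exp(rnorm(n, log(450), 0.3)))
    broad <- cluster %in% c("A", "E")
    widths[broad] <- round(runif(sum(broad), 1500, 6000))
    peaks <- place_peaks(n, genome, widths, near_tss)
    peaks$peak_id <- sprintf("peak_%05d", seq_len(n))
    peaks$true_cluster <- cluster
    peaks$true_promoter <- near_tss
    base_mean <- exp(rnorm(n, log(120), 0.8))
    base_mean[planted] <- exp(rnorm(length(planted), log(200), 0.5))
    names(base_mean) <- peaks$peak_id
    num_cluster <- match(cluster, LETTERS[1:6])
    num_cluster[is.na(num_cluster)] <- 0
    lfc_mat <- cluster_lfc_matrix(ifelse(num_cluster == 0, "none", num_cluster),
                                  scenario$lfc, scenario$conditions)
    counts <- simulate_nb_matrix(base_mean, lfc_mat, design, scenario$dispersion)
    truth <- tibble(peak_id = peaks$peak_id, cluster = cluster,
                    promoter = near_tss)
    list(peaks = peaks, counts = counts, design = design, truth = truth)
  })
}

#' Simulate ChIP-like peak sets with planted overlap and binding structure
#'
#' Produces histone-mark peak sets (H3K27ac, H3K4me3) that overlap planted
#' cluster peaks at `mark_frac_cluster` and background peaks at
#' `mark_frac_bg`, plus two ER binding-site sets (factor-alone and
#' factor-plus-hormone conditions) placed at the TSSs of a planted subset of
#' cluster-1 genes: the true signature genes get an ER site in both
#' conditions, a further subset in only one.
#'
#' @inheritParams simulate_peaks
#' @param peaks Peak table from [simulate_peaks()] (its `$peaks` element).
#' @param gene_clusters Truth tibble from [simulate_counts()]; regenerated
#'   from the scenario when omitted.
#' @return List with `marks` (named list of H3K27ac/H3K4me3 peak tibbles),
#'   `er_MAF`, `er_MAFE2` (ER site tibbles), and `truth` (list with
#'   `signature_genes`, per-mark overlap fractions).
#' @export
simulate_chip <- function(scenario, genome, peaks, gene_clusters = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(genome, "genome_model"))
  peaks <- check_peaks(peaks)
  if (is.null(gene_clusters)) {
    gene_clusters <- simulate_counts(scenario, genome)$truth
  }
  withr::with_seed(scenario$seed + 4L, {
    is_cluster <- !is.null(peaks$true_cluster) & peaks$true_cluster != "none"
    mark <- function() {
      p_hit <- ifelse(is_cluster, scenario$mark_frac_cluster,
                      scenario$mark_frac_bg)
      hit <- runif(nrow(peaks)) < p_hit
      src <- peaks[hit, ]
      jitter <- round(runif(nrow(src), -80, 80))
      w <- round(exp(rnorm(nrow(src), log(600), 0.3)))
      mid <- peak_midpoint(src) + jitter
      tibble(chrom = src$chrom,
             start = pmax(0, mid - floor(w / 2)),
             end = pmax(0, mid - floor(w / 2)) + w,
             signal = exp(rnorm(nrow(src), log(10), 1)))
    }
    marks <- list(H3K27ac = mark(), H3K4me3 = mark())

    cl1 <- gene_clusters$gene_id[gene_clusters$cluster == "1"]
    n_both <- min(length(cl1), ceiling(length(cl1) / 2))
    both <- sample(cl1, n_both)
    remaining <- setdiff(cl1, both)
    only_one <- if (length(remaining) > 0) {
      sample(remaining, min(length(remaining), ceiling(length(cl1) / 4)))
    } else character()
    er_at <- function(gene_ids, n_random = 200) {
      g <- genome$genes[genome$genes$gene_id %in% gene_ids, ]
      w <- round(exp(rnorm(nrow(g) + n_random, log(400), 0.3)))
      at_tss <- tibble(chrom = g$chrom,
                       start = pmax(0, g$tss - floor(w[seq_len(nrow(g))] / 2)))
      at_tss$end <- at_tss$start + w[seq_len(nrow(g))]
      rnd <- place_peaks(n_random, genome, w[-seq_len(nrow(g))])
      bind_rows(at_tss, rnd)
    }
    er_MAF <- er_at(c(both, only_one))
    er_MAFE2 <- er_at(both)
    list(marks = marks, er_MAF = er_MAF, er_MAFE2 = er_MAFE2,
         truth = list(signature_genes = sort(both),
                      one_condition_genes = sort(only_one),
                      mark_frac_cluster = scenario$mark_frac_cluster,
                      mark_frac_bg = scenario$mark_frac_bg))
  })
}

#' Simulate paired peak-signal and expression matrices with planted links
#'
#' Emulates a tumour-cohort integration: `n_link_samples` samples with a
#' peak-signal matrix and a gene-expression matrix. `n_linked` planted
#' (peak, gene) pairs within 500 kb share a latent factor giving Pearson
#' (and approximately Spearman) correlation `link_rho`; an equal number of
#' decoy peaks sits within 500 kb of genes with independent signal.
#'
#' @inheritParams simulate_peaks
#' @return List with `peaks` (tibble), `peak_signal` (peaks x samples),
#'   `expression` (genes x samples), and `truth` (tibble of planted
#'   `peak_id`, `gene_id`).
#' @export
simulate_link_data <- function(scenario, genome) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(genome, "genome_model"))
  if (nrow(genome$genes) == 0) abort("genome model has no genes")
  withr::with_seed(scenario$seed + 5L, {
    ns <- scenario$n_link_samples
    nl <- scenario$n_linked
    rho <- scenario$link_rho
    genes <- genome$genes
    pick <- sample(nrow(genes), min(2 * nl, nrow(genes)))
    linked_genes <- genes[pick[seq_len(nl)], ]
    decoy_genes <- genes[pick[-seq_len(nl)], ]
    near_peak <- function(g) {
      offset <- round(runif(nrow(g), -4e5, 4e5))
      w <- round(exp(rnorm(nrow(g), log(450), 0.3)))
      mid <- pmax(1000, pmin(g$tss + offset, genome$chrom_sizes[g$chrom] - 1000))
      tibble(chrom = g$chrom, start = pmax(0, mid - floor(w / 2)),
             end = pmax(0, mid - floor(w / 2)) + w)
    }
    peaks <- bind_rows(near_peak(linked_genes), near_peak(decoy_genes))
    peaks$peak_id <- sprintf("lpeak_%04d", seq_len(nrow(peaks)))
    samples <- sprintf("tumour_%03d", seq_len(ns))
    z <- matrix(rnorm(nl * ns), nl, ns)
    sig_linked <- sqrt(rho) * z + sqrt(1 - rho) * matrix(rnorm(nl * ns), nl, ns)
    expr_linked <- sqrt(rho) * z + sqrt(1 - rho) * matrix(rnorm(nl * ns), nl, ns)
    nd <- nrow(decoy_genes)
    sig_decoy <- matrix(rnorm(nd * ns), nd, ns)
    peak_signal <- rbind(sig_linked, sig_decoy)
    dimnames(peak_signal) <- list(peaks$peak_id, samples)
    all_gene_ids <- c(linked_genes$gene_id, decoy_genes$gene_id)
    expression <- rbind(expr_linked, matrix(rnorm(nd * ns), nd, ns))
    dimnames(expression) <- list(all_gene_ids, samples)
    truth <- tibble(peak_id = peaks$peak_id[seq_len(nl)],
                    gene_id = linked_genes$gene_id)
    list(peaks = peaks, peak_signal = peak_signal, expression = expression,
         truth = truth)
  })
}

#' Simulate a SAINT-style bait-prey table with planted interactors
#'
#' Four baits (two isoforms, N- and C-terminal tags) plus a control are
#' profiled over `n_prey` preys, four replicates and two search engines.
#' Planted true interactors are structured with known commonalities (a
#' four-way core, isoform-common and bait-unique sets); they receive high
#' spectral counts, small BFDRs (Beta-like draw near 0) and large fold
#' changes; background preys get control-level counts, BFDR uniform on
#' (0.05, 1) and fold change near 1.
#'
#' @inheritParams simulate_counts
#' @return List with `table` (tibble: `bait`, `prey`, `replicate`, `engine`,
#'   `spectral_count`, `bfdr`, `fold_change`) and `truth` (list of per-bait
#'   true prey sets and the planted core sets).
#' @export
simulate_saint <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed + 6L, {
    baits <- c("MAF-S-N", "MAF-S-C", "MAF-L-N", "MAF-L-C")
    preys <- sprintf("prey_%03d", seq_len(scenario$n_prey))
    fourway <- preys[1:40]
    s_only <- preys[41:55]
    l_only <- preys[56:75]
    unique_sets <- list(
      `MAF-S-N` = preys[76:85], `MAF-S-C` = preys[86:95],
      `MAF-L-N` = preys[96:105], `MAF-L-C` = preys[106:115]
    )
    true_sets <- list(
      `MAF-S-N` = c(fourway, s_only, unique_sets$`MAF-S-N`),
      `MAF-S-C` = c(fourway, s_only, unique_sets$`MAF-S-C`),
      `MAF-L-N` = c(fourway, l_only, unique_sets$`MAF-L-N`),
      `MAF-L-C` = c(fourway, l_only, unique_sets$`MAF-L-C`)
    )
    grid <- tidyr::expand_grid(
      bait = c(baits, "control"), prey = preys,
      replicate = 1:4, engine = c("PD", "MQ")
    )
    is_true <- purrr::map2_lgl(grid$bait, grid$prey, function(b, p) {
      b != "control" && p %in% true_sets[[b]]
    })
    grid$spectral_count <- ifelse(
      is_true,
      rnbinom(nrow(grid), mu = 25, size = 5),
      rnbinom(nrow(grid), mu = 2, size = 2)
    )
    pair_true <- grid |>
      filter(.data$bait != "control") |>
      distinct(.data$bait, .data$prey) |>
      mutate(true = purrr::map2_lgl(.data$bait, .data$prey,
                                    ~ .y %in% true_sets[[.x]]))
    pair_true$bfdr <- ifelse(pair_true$true,
                             runif(nrow(pair_true), 0, 0.01),
                             runif(nrow(pair_true), 0.05, 1))
    ctrl_avg <- grid |>
      filter(.data$bait == "control") |>
      summarise(ctrl = mean(.data$spectral_count), .by = "prey")
    bait_avg <- grid |>
      filter(.data$bait != "control") |>
      summarise(avg = mean(.data$spectral_count), .by = c("bait", "prey"))
    pair_true <- pair_true |>
      left_join(bait_avg, by = c("bait", "prey")) |>
      left_join(ctrl_avg, by = "prey") |>
      mutate(fold_change = (.data$avg + 0.5) / (.data$ctrl + 0.5)) |>
      select("bait", "prey", "bfdr", "fold_change")
    table <- grid |>
      left_join(pair_true, by = c("bait", "prey"))
    list(table = table,
         truth = list(true_sets = lapply(true_sets, sort),
                      fourway = sort(fourway),
                      s_common = sort(c(fourway, s_only)),
                      l_common = sort(c(fourway, l_only))))
  })
}

#' Simulate a survival cohort with a planted signature hazard effect
#'
#' Samples carry a latent signature activity `u ~ N(0, 1)`; the
#' `n_signature_genes` signature genes express `u` plus noise (so the mean
#' z-score recovers `u`), and samples with `u < -1` (the population
#' mean-minus-one-SD group) have their exponential event hazard multiplied
#' by `hazard_ratio`. Censoring is independent uniform on
#' `(0, censor_max)` months. Binary HER2 status and tumour stage covariates
#' are included (independent of outcome by construction).
#'
#' @inheritParams simulate_counts
#' @return List with `expression` (genes x samples, log-ish scale),
#'   `clinical` (tibble `sample`, `time`, `event`, `her2`, `stage`), and
#'   `truth` (list: `signature_genes`, `hazard_ratio`, `true_low`).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed + 7L, {
    n <- scenario$n_cohort
    nsig <- scenario$n_signature_genes
    nnoise <- 170L
    samples <- sprintf("pt_%03d", seq_len(n))
    u <- rnorm(n)
    sig <- matrix(rep(u, each = nsig), nsig, n) +
      matrix(rnorm(nsig * n, sd = 0.4), nsig, n)
    noise <- matrix(rnorm(nnoise * n), nnoise, n)
    expression <- rbind(sig, noise)
    gene_ids <- c(sprintf("sig_gene_%03d", seq_len(nsig)),
                  sprintf("noise_gene_%03d", seq_len(nnoise)))
    dimnames(expression) <- list(gene_ids, samples)
    low <- u < -1
    hz <- scenario$baseline_hazard * ifelse(low, scenario$hazard_ratio, 1)
    t_event <- rexp(n, rate = hz)
    t_cens <- runif(n, 0, scenario$censor_max)
    clinical <- tibble(
      sample = samples,
      time = pmin(t_event, t_cens),
      event = t_event <= t_cens,
      her2 = sample(c(0L, 1L), n, replace = TRUE, prob = c(0.8, 0.2)),
      stage = sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    )
    list(expression = expression, clinical = clinical,
         truth = list(signature_genes = gene_ids[seq_len(nsig)],
                      hazard_ratio = scenario$hazard_ratio,
                      true_low = setNames(low, samples)))
  })
}
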