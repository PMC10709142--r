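#' Build promoter-enhancer links from paired signal matrices
#'
#' Correlates peak accessibility signal with gene expression across shared
#' samples for every (peak, gene) pair whose peak midpoint lies within
#' `max_dist` (default 500 kb) of the gene's TSS. Correlation is Spearman
#' (rank-based, hence invariant to monotone transforms of either signal);
#' p-values come from the t approximation on the rank correlation and are
#' BH-adjusted over all tested pairs. Pairs with adjusted p at most
#' `fdr` and positive correlation are retained as links.
#'
#' @param peak_signal Matrix peaks x samples.
#' @param expression Matrix genes x samples (sample names shared with
#'   `peak_signal`; at least 8 shared samples are recommended).
#' @param peaks Peak tibble locating the peak-signal rows (`peak_id`).
#' @param genome A [genome_model()] with the expression genes.
#' @param max_dist Maximum midpoint-to-TSS distance in bp.
#' @param fdr BH-adjusted significance cutoff.
#' @return Tibble of retained links: `peak_id`, `gene_id`, `distance`
#'   (signed midpoint - TSS), `rho`, `p_value`, `p_adj`; the number of
#'   tested pairs is stored in `attr(, "n_tested")`.
#' @export
build_links <- function(peak_signal, expression, peaks, genome,
                        max_dist = 5e5, fdr = 0.05) {
  stopifnot(inherits(genome, "genome_model"))
  peak_signal <- as.matrix(peak_signal)
  expression <- as.matrix(expression)
  peaks <- check_peaks(peaks)
  shared <- intersect(colnames(peak_signal), colnames(expression))
  if (length(shared) == 0) abort("no shared samples between the matrices")
  if (length(shared) < 8) {
    warn("fewer than 8 shared samples; correlations will be unstable")
  }
  idx <- match(rownames(peak_signal), peaks$peak_id)
  if (anyNA(idx)) abort("peak-signal rows missing from `peaks`")
  genes <- genome$genes[genome$genes$gene_id %in% rownames(expression), ]
  if (nrow(genes) == 0) abort("no expression genes found in the genome model")

  mid <- peak_midpoint(peaks)[idx]
  chrom <- peaks$chrom[idx]
  pairs <- purrr::map_dfr(unique(chrom), function(chr) {
    pk <- which(chrom == chr)
    g <- which(genes$chrom == chr)
    if (length(pk) == 0 || length(g) == 0) return(NULL)
    d <- outer(mid[pk], genes$tss[g], "-")
    hit <- which(abs(d) <= max_dist, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    tibble(peak_row = pk[hit[, 1]],
           gene_id = genes$gene_id[g[hit[, 2]]],
           distance = d[hit])
  })
  if (nrow(pairs) == 0) {
    out <- tibble(peak_id = character(), gene_id = character(),
                  distance = numeric(), rho = numeric(),
                  p_value = numeric(), p_adj = numeric())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  n <- length(shared)
  pr <- t(apply(peak_signal[, shared, drop = FALSE], 1, rank))
  er <- t(apply(expression[, shared, drop = FALSE], 1, rank))
  pr <- pr - rowMeans(pr)
  er <- er - rowMeans(er)
  pr_n <- pr / sqrt(rowSums(pr^2))
  er_n <- er / sqrt(rowSums(er^2))
  rho <- unname(rowSums(pr_n[pairs$peak_row, , drop = FALSE] *
                          er_n[match(pairs$gene_id, rownames(expression)), ,
                               drop = FALSE]))
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p_adj <- p.adjust(p, method = "BH")
  out <- tibble(peak_id = rownames(peak_signal)[pairs$peak_row],
                gene_id = pairs$gene_id, distance = pairs$distance,
                rho = rho, p_value = p, p_adj = p_adj) |>
    filter(.data$p_adj <= fdr, .data$rho > 0)
  attr(out, "n_tested") <- nrow(pairs)
  out
}

#' Link enrichment of a candidate peak set
#'
#' Tests, one-tailed, whether candidate peaks are linked to target gene
#' promoters more often than random peak selections: the observed
#' percentage of candidates with at least one link to a target gene is
#' compared with `n_iter` (default 10,000) equal-size draws from the full
#' peak universe, without replacement;
#' `p = (1 + #{null >= obs}) / (1 + n_iter)`.
#'
#' @param candidate_peaks Character vector of candidate peak ids (subset of
#'   `all_peaks`).
#' @param target_promoters Character vector of target gene ids.
#' @param links Link table from [build_links()].
#' @param all_peaks Character vector of all peak ids in the universe.
#' @param n_iter Permutation iterations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all subsets (small instances only).
#' @return A `perm_test` object.
#' @export
link_enrichment_test <- function(candidate_peaks, target_promoters, links,
                                 all_peaks, n_iter = 10000, seed = 1L,
                                 exhaustive = FALSE) {
  if (length(candidate_peaks) == 0) abort("`candidate_peaks` must be nonempty")
  if (!all(candidate_peaks %in% all_peaks)) {
    abort("candidate peaks must be a subset of `all_peaks`")
  }
  linked_ids <- unique(links$peak_id[links$gene_id %in% target_promoters])
  indicator <- all_peaks %in% linked_ids
  idx <- match(candidate_peaks, all_peaks)
  perm_percent_test(indicator, idx, n_iter, seed, exhaustive,
                    "% linked to target promoters")
}
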