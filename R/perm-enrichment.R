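#' @title Permutation enrichment tests against the consensus-peak background
#' @description One-tailed tests asking whether a peak cluster shows more of
#'   some property (annotation category, histone-mark overlap) than random
#'   subsets of the consensus peak universe of the same size.
#' @name perm_enrichment
NULL

new_perm_test <- function(observed, null_values, p_value, n_iter, seed,
                          statistic, method) {
  structure(
    list(observed = observed, null_values = null_values, p_value = p_value,
         n_iter = n_iter, seed = seed, statistic = statistic, method = method),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$statistic, "\n", sep = "")
  cat(sprintf("  observed %.3f vs null mean %.3f (%s, %d draws), p = %.4g\n",
              x$observed, mean(x$null_values), x$method,
              length(x$null_values), x$p_value))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         null_mean = mean(x$null_values), p_value = x$p_value,
         method = x$method, n_iter = x$n_iter, seed = x$seed)
}

#' @rdname tidiers
#' @export
glance.perm_test <- function(x, ...) tidy(x)

# shared engine: observed % with property among `k` cluster members vs
# random size-k subsets of the n-element universe
perm_percent_test <- function(indicator, cluster_idx, n_iter, seed,
                              exhaustive, statistic,
                              enum_limit = 2e5) {
  n <- length(indicator)
  k <- length(cluster_idx)
  observed <- 100 * mean(indicator[cluster_idx])
  if (exhaustive) {
    if (choose(n, k) > enum_limit) {
      abort("exhaustive enumeration infeasible for this instance size")
    }
    subsets <- combn(n, k)
    null_values <- 100 * colMeans(matrix(indicator[subsets], nrow = k))
    p <- mean(null_values >= observed)
    return(new_perm_test(observed, null_values, p, length(null_values),
                         NA_integer_, statistic, "exhaustive"))
  }
  null_values <- withr::with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) 100 * mean(indicator[sample.int(n, k)]),
           numeric(1))
  })
  p <- (1 + sum(null_values >= observed)) / (1 + n_iter)
  new_perm_test(observed, null_values, p, n_iter, seed, statistic,
                "sampled")
}

match_cluster <- function(cluster_peaks, consensus_peaks) {
  idx <- match(cluster_peaks$peak_id, consensus_peaks$peak_id)
  if (anyNA(idx)) {
    abort("every cluster peak must be part of the consensus set (by peak_id)")
  }
  if (nrow(cluster_peaks) > nrow(consensus_peaks)) {
    abort("cluster cannot be larger than the consensus set")
  }
  idx
}

#' Annotation-category enrichment of a peak cluster
#'
#' Compares the percentage of cluster peaks in an annotation category
#' (e.g. `promoter-TSS`) with the percentage in random same-size subsets of
#' the consensus peaks, one-tailed for enrichment. The sampled p-value uses
#' the add-one convention `p = (1 + #{null >= obs}) / (1 + n_iter)`, so it
#' is never zero; `exhaustive = TRUE` enumerates every subset on small
#' instances and returns the exact tail probability instead.
#'
#' @param cluster_peaks,consensus_peaks Annotated peak tibbles
#'   (see [annotate_peaks()]); cluster peaks must be a subset of the
#'   consensus by `peak_id`.
#' @param category Annotation category tested for enrichment.
#' @param n_iter Permutation iterations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all subsets instead of sampling.
#' @return A `perm_test` object ([tidy()]-able).
#' @export
category_enrichment_test <- function(cluster_peaks, consensus_peaks,
                                     category = "promoter-TSS",
                                     n_iter = 1000, seed = 1L,
                                     exhaustive = FALSE) {
  cluster_peaks <- check_peaks(cluster_peaks, "cluster_peaks")
  consensus_peaks <- check_peaks(consensus_peaks, "consensus_peaks")
  if (!"annotation" %in% names(consensus_peaks)) {
    abort("`consensus_peaks` must carry an `annotation` column")
  }
  idx <- match_cluster(cluster_peaks, consensus_peaks)
  indicator <- consensus_peaks$annotation == category
  perm_percent_test(indicator, idx, n_iter, seed, exhaustive,
                    paste0("% ", category))
}

#' Histone-mark overlap enrichment of a peak cluster
#'
#' As [category_enrichment_test()], with the tested property being overlap
#' (gap at most `max_gap` bp, default 100) with histone-mark peaks. Several
#' mark sets can be combined: `mode = "any"` counts a peak overlapping any
#' of the sets, `mode = "all"` requires overlap with every set (e.g. both
#' H3K27ac and H3K4me3).
#'
#' @inheritParams category_enrichment_test
#' @param mark_peaks A peak tibble, or a named list of peak tibbles.
#' @param max_gap Overlap gap tolerance in bp.
#' @param mode `"any"` or `"all"` across multiple mark sets.
#' @return A `perm_test` object.
#' @export
mark_overlap_test <- function(cluster_peaks, consensus_peaks, mark_peaks,
                              n_iter = 1000, seed = 1L, max_gap = 100,
                              mode = c("any", "all"), exhaustive = FALSE) {
  mode <- match.arg(mode)
  cluster_peaks <- check_peaks(cluster_peaks, "cluster_peaks")
  consensus_peaks <- check_peaks(consensus_peaks, "consensus_peaks")
  if (is.data.frame(mark_peaks)) mark_peaks <- list(mark = mark_peaks)
  if (length(mark_peaks) == 0 || any(vapply(mark_peaks, nrow, 1L) == 0)) {
    abort("mark peak set(s) must be nonempty")
  }
  idx <- match_cluster(cluster_peaks, consensus_peaks)
  hits <- vapply(mark_peaks,
                 function(m) overlaps_any(consensus_peaks, check_peaks(m), max_gap),
                 logical(nrow(consensus_peaks)))
  hits <- matrix(hits, nrow = nrow(consensus_peaks))
  indicator <- if (mode == "any") rowSums(hits) > 0 else rowSums(hits) == ncol(hits)
  perm_percent_test(indicator, idx, n_iter, seed, exhaustive,
                    paste0("% overlap (", mode, " of ",
                           paste(names(mark_peaks), collapse = "+"), ")"))
}

#' Compare peak breadth between two groups
#'
#' Two-sided Wilcoxon rank-sum test on breadth (`log10` width), the
#' standard comparison between promoter-TSS and intergenic peaks.
#'
#' @param peaks_group1,peaks_group2 Nonempty peak tibbles.
#' @return Tibble with the rank-sum statistic, `p_value`, group sizes and
#'   mean breadths.
#' @export
breadth_compare <- function(peaks_group1, peaks_group2) {
  peaks_group1 <- check_peaks(peaks_group1, "peaks_group1")
  peaks_group2 <- check_peaks(peaks_group2, "peaks_group2")
  if (nrow(peaks_group1) == 0 || nrow(peaks_group2) == 0) {
    abort("both peak groups must be nonempty")
  }
  b1 <- peak_breadth(peaks_group1)
  b2 <- peak_breadth(peaks_group2)
  ht <- suppressWarnings(wilcox.test(b1, b2, alternative = "two.sided"))
  # fully tied samples leave the normal approximation undefined; there is
  # then no evidence of a difference
  if (is.nan(ht$p.value)) ht$p.value <- 1
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n1 = length(b1), n2 = length(b2),
         mean_breadth1 = mean(b1), mean_breadth2 = mean(b2))
}

#' @describeIn perm_enrichment Null-distribution histogram with the observed
#'   value marked.
#' @param object A `perm_test`.
#' @param ... Unused.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble(null = object$null_values)
  ggplot(df, aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "firebrick",
               linewidth = 0.8) +
    labs(x = object$statistic, y = "permutations",
         title = sprintf("observed %.2f, p = %.3g",
                         object$observed, object$p_value)) +
    theme_minimal()
}
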