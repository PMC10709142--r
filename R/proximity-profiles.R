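#' Cumulative TSS-proximity enrichment curve with permutation envelope
#'
#' For a set of binding sites and a target gene set, computes the cumulative
#' percentage of sites whose midpoint lies within 10, 20, ..., 100 kb of any
#' target TSS, and compares it with curves for random gene sets of the same
#' size drawn from a comparison pool (typically constitutively expressed
#' genes). The envelope reported at each distance is the `envelope_rank`-th
#' largest permuted value (the 5th of 100 permutations gives an empirical
#' ~95% upper envelope).
#'
#' @param sites Peak tibble of binding sites.
#' @param target_genes Character vector of target gene ids.
#' @param comparison_pool Character vector of pool gene ids (at least as
#'   many as targets).
#' @param genome A [genome_model()] containing all involved genes.
#' @param n_perm Number of random gene-set draws (default 100).
#' @param seed Integer seed.
#' @param distances Evaluation grid in bp.
#' @param envelope_rank Which top-ranked permutation forms the envelope.
#' @param exhaustive Enumerate all pool subsets instead of sampling (small
#'   instances only).
#' @return A `proximity_curve` object: distances, observed and envelope
#'   percentages, the full permuted matrix, and the parameters used.
#' @export
tss_enrichment_curve <- function(sites, target_genes, comparison_pool,
                                 genome, n_perm = 100, seed = 1L,
                                 distances = seq(10000, 100000, by = 10000),
                                 envelope_rank = 5, exhaustive = FALSE) {
  stopifnot(inherits(genome, "genome_model"))
  sites <- check_peaks(sites, "sites")
  if (nrow(sites) == 0) abort("`sites` must be nonempty")
  if (length(target_genes) == 0) abort("`target_genes` must be nonempty")
  if (length(target_genes) > length(comparison_pool)) {
    abort("comparison pool must be at least as large as the target set")
  }
  genes <- genome$genes
  all_ids <- union(target_genes, comparison_pool)
  if (!all(all_ids %in% genes$gene_id)) {
    abort("all target/pool genes must exist in the genome model")
  }
  mid <- peak_midpoint(sites)
  dist_to <- function(ids) {
    g <- genes[match(ids, genes$gene_id), ]
    d <- abs(outer(mid, g$tss, "-"))
    d[outer(sites$chrom, g$chrom, "!=")] <- Inf
    d
  }
  curve_from <- function(dmin) {
    vapply(distances, function(d) 100 * mean(dmin <= d), numeric(1))
  }
  observed <- curve_from(apply(dist_to(target_genes), 1, min))

  D_pool <- dist_to(comparison_pool)
  k <- length(target_genes)
  perm_curve <- function(cols) {
    curve_from(apply(D_pool[, cols, drop = FALSE], 1, min))
  }
  if (exhaustive) {
    if (choose(length(comparison_pool), k) > 2e5) {
      abort("exhaustive enumeration infeasible for this pool size")
    }
    subsets <- combn(length(comparison_pool), k)
    permuted <- t(apply(subsets, 2, perm_curve))
    n_perm <- nrow(permuted)
  } else {
    permuted <- withr::with_seed(seed, {
      t(vapply(seq_len(n_perm),
               function(i) perm_curve(sample.int(length(comparison_pool), k)),
               numeric(length(distances))))
    })
  }
  if (envelope_rank > n_perm) abort("`envelope_rank` exceeds permutation count")
  envelope <- apply(permuted, 2,
                    function(v) sort(v, decreasing = TRUE)[envelope_rank])
  structure(
    list(distances = distances, observed = observed, envelope = envelope,
         permuted = permuted, n_perm = n_perm, seed = seed,
         envelope_rank = envelope_rank, n_sites = nrow(sites),
         n_targets = k),
    class = "proximity_curve"
  )
}

#' @export
print.proximity_curve <- function(x, ...) {
  cat("<proximity_curve> ", x$n_sites, " sites vs ", x$n_targets,
      " target genes, ", x$n_perm, " permutations\n", sep = "")
  print(tidy(x), n = length(x$distances))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.proximity_curve <- function(x, ...) {
  tibble(distance = x$distances, observed = x$observed,
         envelope = x$envelope)
}

#' @rdname tidiers
#' @export
glance.proximity_curve <- function(x, ...) {
  tibble(n_sites = x$n_sites, n_targets = x$n_targets, n_perm = x$n_perm,
         envelope_rank = x$envelope_rank,
         exceeds_envelope_at = sum(x$observed > x$envelope),
         n_distances = length(x$distances))
}

#' Autoplot a proximity curve
#'
#' Observed cumulative enrichment (red) against the permutation envelope
#' (grey).
#'
#' @param object A `proximity_curve`.
#' @param ... Unused.
#' @export
autoplot.proximity_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$distance / 1000)) +
    geom_line(aes(y = .data$envelope), colour = "grey55", linewidth = 0.7) +
    geom_line(aes(y = .data$observed), colour = "firebrick", linewidth = 0.9) +
    labs(x = "distance to TSS (kb)", y = "cumulative % of sites",
         title = sprintf("%d sites vs %d target genes (envelope: %d/%d)",
                         object$n_sites, object$n_targets,
                         object$envelope_rank, object$n_perm)) +
    theme_minimal()
}

#' Binned TSS meta-profile of normalised accessibility signal
#'
#' Size-factor-normalised log counts per peak are aggregated into
#' equally-spaced TSS-distance bins (default 25 bp, peaks within 25 kb of a
#' TSS only), averaged per condition, and differenced against the reference
#' condition. Bins use the signed midpoint-to-TSS distance. A cubic
#' smoothing spline (GCV-chosen smoothness) can be added for display; the
#' raw bin means are always returned.
#'
#' @param peak_counts Count matrix over consensus peaks (peaks x samples).
#' @param peaks Peak tibble carrying `tss_distance` (see
#'   [distance_to_tss()]); `peak_id` must match the matrix rows.
#' @param design Tibble with `sample`, `condition`.
#' @param bin_size Bin width in bp.
#' @param max_distance Maximum |TSS distance| in bp (boundary included).
#' @param reference Condition subtracted from every other condition.
#' @param sf Optional precomputed size factors.
#' @param smooth Add a `smoothed` column per condition.
#' @return Tibble: `bin` (bp, bin midpoint), `condition`, `diff` (mean log2
#'   signal minus reference), `n_peaks`, and optionally `smoothed`.
#' @export
tss_meta_profile <- function(peak_counts, peaks, design, bin_size = 25,
                             max_distance = 25000, reference = "mock",
                             sf = NULL, smooth = FALSE) {
  peak_counts <- as.matrix(peak_counts)
  peaks <- check_peaks(peaks)
  if (!"tss_distance" %in% names(peaks)) {
    abort("`peaks` must carry `tss_distance` (see `distance_to_tss()`)")
  }
  design <- validate_design(design, peak_counts)
  if (!reference %in% levels(design$condition)) {
    abort("`reference` condition absent from the design")
  }
  idx <- match(rownames(peak_counts), peaks$peak_id)
  if (anyNA(idx)) abort("count-matrix rows missing from `peaks`")
  d <- peaks$tss_distance[idx]
  keep <- !is.na(d) & abs(d) <= max_distance
  if (!any(keep)) abort("no peaks within `max_distance` of a TSS")
  if (is.null(sf)) sf <- size_factors(peak_counts)
  sig <- log2(1 + sweep(peak_counts[keep, , drop = FALSE], 2, sf, "/"))
  bin <- floor(d[keep] / bin_size) * bin_size + bin_size / 2

  long <- as_tibble(sig, rownames = "peak_id") |>
    mutate(bin = bin) |>
    tidyr::pivot_longer(cols = -c("peak_id", "bin"),
                        names_to = "sample", values_to = "signal") |>
    left_join(design, by = "sample") |>
    summarise(mean_signal = mean(.data$signal), n_peaks = n_distinct(.data$peak_id),
              .by = c("bin", "condition"))
  ref <- long |>
    filter(.data$condition == reference) |>
    select("bin", ref_signal = "mean_signal")
  out <- long |>
    filter(.data$condition != reference) |>
    left_join(ref, by = "bin") |>
    mutate(diff = .data$mean_signal - .data$ref_signal) |>
    select("bin", "condition", "diff", "n_peaks") |>
    arrange(.data$condition, .data$bin)
  if (smooth) {
    out <- out |>
      mutate(smoothed = if (n() >= 10) {
        predict(smooth.spline(.data$bin, .data$diff), .data$bin)$y
      } else .data$diff, .by = "condition")
  }
  out
}
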