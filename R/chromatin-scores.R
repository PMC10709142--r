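#' Expected motif matches in a region sample of the genome
#'
#' Under the model that the genome's motif matches are uniformly
#' distributed, the match count in regions totalling `region_total_bp` of a
#' `genome_total_bp` genome is binomial with
#' `p = region_total_bp / genome_total_bp` over `genome_match_count`
#' trials: `E = n p`, `S = sqrt(n p (1 - p))`.
#'
#' @param region_total_bp Total bp covered by the regions (> 0).
#' @param genome_total_bp Genome length in bp.
#' @param genome_match_count Total motif matches genome-wide.
#' @return Tibble with `expected` and `sd`.
#' @examples
#' expected_matches(1e6, 1e8, 1000)  # E = 10, S ~ 3.146
#' @export
expected_matches <- function(region_total_bp, genome_total_bp,
                             genome_match_count) {
  if (genome_total_bp <= 0) abort("`genome_total_bp` must be > 0")
  if (region_total_bp <= 0 || region_total_bp > genome_total_bp) {
    abort("need 0 < region_total_bp <= genome_total_bp")
  }
  if (genome_match_count < 0) abort("`genome_match_count` must be >= 0")
  p <- region_total_bp / genome_total_bp
  tibble(expected = genome_match_count * p,
         sd = sqrt(genome_match_count * p * (1 - p)))
}

#' Motif overrepresentation z-score and fold factor
#'
#' `motif_zscore()` applies the continuity-corrected formula
#' `z = (X - E - 0.5) / S`; `motif_fold()` is the overrepresentation factor
#' `X / E`. `X` is the observed match count in the regions, `E` and `S` the
#' expected count and its standard deviation under uniform genome-wide
#' placement (see [expected_matches()]).
#'
#' @param X Observed match count.
#' @param E Expected match count (> 0 for the fold factor).
#' @param S Standard deviation of the expected count (> 0).
#' @return Numeric scalar (vectorised over inputs).
#' @examples
#' motif_zscore(30, 20, 4)  # 2.375
#' motif_fold(30, 20)       # 1.5
#' @export
motif_zscore <- function(X, E, S) {
  if (any(S <= 0)) {
    abort("S must be > 0; for degenerate placements use an exact binomial test")
  }
  (X - E - 0.5) / S
}

#' @rdname motif_zscore
#' @export
motif_fold <- function(X, E) {
  if (any(E <= 0)) abort("E must be > 0")
  X / E
}

#' Count motif matches inside regions
#'
#' Given genome-wide match positions (base coordinates, 0-based), counts
#' the total number of matches falling inside the regions and the number of
#' regions (input sequences) with at least one match.
#'
#' @param regions Peak tibble.
#' @param matches Tibble with `chrom` and `pos` (0-based base positions),
#'   or a numeric vector of positions when all regions share one
#'   chromosome.
#' @return Tibble with `n_matches` (X) and `n_regions_with_match`.
#' @export
count_motif_matches <- function(regions, matches) {
  regions <- check_peaks(regions, "regions")
  if (is.numeric(matches)) {
    chroms <- unique(regions$chrom)
    if (length(chroms) != 1) {
      abort("positional vector input needs single-chromosome regions")
    }
    matches <- tibble(chrom = chroms, pos = matches)
  }
  matches <- as_tibble(matches)
  if (nrow(matches) == 0) {
    return(tibble(n_matches = 0L, n_regions_with_match = 0L))
  }
  mg <- GenomicRanges::GRanges(matches$chrom,
                               IRanges::IRanges(matches$pos + 1L, matches$pos + 1L))
  rg <- peaks_to_granges(regions)
  per_region <- GenomicRanges::countOverlaps(rg, mg)
  tibble(n_matches = sum(per_region),
         n_regions_with_match = sum(per_region > 0))
}

#' Stitch enhancer peaks into candidate (super-)enhancer domains
#'
#' Drops peaks fully contained within any promoter window (TSS +/-
#' `promoter_exclusion` bp), then single-linkage chains the remaining peaks
#' along each chromosome, merging neighbours whose gap is at most
#' `stitch_dist` bp (default 12.5 kb). Stitching is idempotent and
#' order-invariant.
#'
#' @param mark_peaks Peak tibble (e.g. H3K27ac peaks).
#' @param genome A [genome_model()] supplying TSSs.
#' @param stitch_dist Maximum gap merged into one domain, in bp.
#' @param promoter_exclusion Promoter half-width for the exclusion rule.
#' @return Tibble of stitched domains: `enhancer_id`, `chrom`, `start`,
#'   `end`, `n_constituents`, `constituents` (comma-separated peak ids).
#' @export
stitch_enhancers <- function(mark_peaks, genome, stitch_dist = 12500,
                             promoter_exclusion = 2000) {
  stopifnot(inherits(genome, "genome_model"))
  peaks <- check_peaks(mark_peaks, "mark_peaks")
  if (nrow(peaks) == 0) {
    return(tibble(enhancer_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  n_constituents = integer(), constituents = character()))
  }
  genes <- genome$genes
  if (nrow(genes) > 0) {
    # fully contained: every peak base within [tss - w, tss + w]
    win <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(genes$tss - promoter_exclusion, 0) + 1L,
                       genes$tss + promoter_exclusion + 1L)
    )
    contained <- IRanges::overlapsAny(peaks_to_granges(peaks), win,
                                      type = "within")
    peaks <- peaks[!contained, ]
  }
  if (nrow(peaks) == 0) {
    return(tibble(enhancer_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  n_constituents = integer(), constituents = character()))
  }
  peaks <- peaks |>
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end)) |>
    arrange(.data$chrom, .data$start, .data$end)
  out <- peaks |>
    mutate(.by = "chrom",
           run_end = cummax(.data$end),
           new_domain = .data$start - lag(.data$run_end, default = -Inf) > stitch_dist,
           domain = cumsum(.data$new_domain)) |>
    summarise(.by = c("chrom", "domain"),
              start = min(.data$start), end = max(.data$end),
              n_constituents = n(),
              constituents = paste(.data$peak_id, collapse = ",")) |>
    select(-"domain") |>
    arrange(.data$chrom, .data$start)
  out$enhancer_id <- sprintf("enh_%04d", seq_len(nrow(out)))
  out |> select("enhancer_id", "chrom", "start", "end", "n_constituents",
                "constituents")
}

#' Rank stitched enhancers and flag super-enhancers
#'
#' Scores each stitched domain as the target signal minus the input
#' (background) signal, floored at zero, ranks domains by score, and flags
#' super-enhancers with the classic rank-curve tangent rule: both axes are
#' scaled to \[0, 1\] and the cutoff is the score at the point where the
#' curve's slope reaches 1 (equivalently, where the vertical distance below
#' the diagonal is maximal); domains scoring above the cutoff are super.
#' The flags are invariant to uniform rescaling of the signals.
#'
#' @param stitched Tibble from [stitch_enhancers()].
#' @param target_signal,input_signal Numeric vectors aligned with
#'   `stitched` rows (input defaults to zero).
#' @return An `enhancer_ranking` tibble: the stitched table plus `score`,
#'   `rank` (1 = highest score) and `is_super`; the score cutoff is stored
#'   in `attr(, "cutoff")`.
#' @export
rank_super_enhancers <- function(stitched, target_signal,
                                 input_signal = 0) {
  stitched <- as_tibble(stitched)
  n <- nrow(stitched)
  if (n < 3) abort("need >= 3 stitched enhancers to place a cutoff")
  score <- pmax(target_signal - input_signal, 0)
  if (length(score) != n) abort("signal length must match `stitched` rows")
  ord <- order(score)  # ascending for the rank curve
  y <- score[ord]
  if (max(y) == min(y)) {
    out <- stitched |>
      mutate(score = score, rank = rank(-score, ties.method = "first"),
             is_super = FALSE)
    attr(out, "cutoff") <- Inf
    class(out) <- c("enhancer_ranking", class(out))
    return(out)
  }
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - min(y)) / (max(y) - min(y))
  cut_idx <- which.max(xs - ys)
  cutoff <- y[cut_idx]
  out <- stitched |>
    mutate(score = score, rank = rank(-score, ties.method = "first"),
           is_super = score > cutoff)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("enhancer_ranking", class(out))
  out
}

#' Autoplot an enhancer ranking
#'
#' The hockey-stick plot: domains ordered by score with super-enhancers
#' highlighted and the cutoff marked.
#'
#' @param object An `enhancer_ranking` from [rank_super_enhancers()].
#' @param ... Unused.
#' @export
autoplot.enhancer_ranking <- function(object, ...) {
  df <- object |> arrange(.data$score) |> mutate(i = dplyr::row_number())
  ggplot(df, aes(x = .data$i, y = .data$score, colour = .data$is_super)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = attr(object, "cutoff"), linetype = 2,
               colour = "grey40") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = "super-enhancer") +
    labs(x = "enhancers ranked by signal", y = "target - input signal") +
    theme_minimal()
}
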