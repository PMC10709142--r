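#' Merge dual-engine spectral counts
#'
#' Proximity-labeling runs searched with two engines (e.g. PD and MQ) are
#' merged by taking, per (bait, prey, replicate), the maximum spectral
#' count over engines; a count absent from one engine counts as 0.
#'
#' @param table Tibble with `bait`, `prey`, `replicate`, `engine`,
#'   `spectral_count` (extra per-pair columns such as `bfdr`/`fold_change`
#'   are carried through).
#' @return Tibble with one row per (bait, prey, replicate) and the merged
#'   `spectral_count`.
#' @export
merge_engine_counts <- function(table) {
  table <- as_tibble(table)
  req <- c("bait", "prey", "replicate", "spectral_count")
  if (!all(req %in% names(table))) {
    abort(paste0("`table` needs columns: ", paste(req, collapse = ", ")))
  }
  extra <- setdiff(names(table), c(req, "engine"))
  table |>
    summarise(spectral_count = max(.data$spectral_count, 0),
              across(all_of(extra), dplyr::first),
              .by = c("bait", "prey", "replicate"))
}

#' Keep the top-k replicates per bait-prey pair
#'
#' Mirrors the `-R3` style selection: per (bait, prey), only the `k`
#' replicates with the highest spectral counts are retained. Pairs with
#' fewer than `k` replicates pass through unchanged with a warning.
#'
#' @param table Tibble with `bait`, `prey`, `replicate`, `spectral_count`.
#' @param k Number of replicates to keep.
#' @return The reduced tibble.
#' @export
select_top_replicates <- function(table, k = 3) {
  table <- as_tibble(table)
  n_rep <- table |> summarise(n = n(), .by = c("bait", "prey"))
  if (any(n_rep$n < k)) {
    warn("some bait-prey pairs have fewer than `k` replicates; kept as is")
  }
  table |>
    arrange(desc(.data$spectral_count)) |>
    mutate(.by = c("bait", "prey"), .rank = dplyr::row_number()) |>
    filter(.data$.rank <= k) |>
    select(-".rank")
}

#' High-confidence interactor filter
#'
#' A prey is a high-confidence interactor of a bait when its BFDR is at
#' most `bfdr_max` (default 0.02) and its fold change over control at least
#' `fc_min` (default 3); both boundaries are inclusive. Relaxing either
#' threshold can only grow the prey sets.
#'
#' @param table Tibble with `bait`, `prey`, `bfdr`, `fold_change` (one or
#'   more rows per pair; pairs are deduplicated).
#' @param bfdr_max,fc_min Filter thresholds.
#' @return Named list of per-bait character vectors of retained prey ids.
#' @export
filter_high_confidence <- function(table, bfdr_max = 0.02, fc_min = 3) {
  table <- as_tibble(table)
  req <- c("bait", "prey", "bfdr", "fold_change")
  if (!all(req %in% names(table))) {
    abort(paste0("`table` needs columns: ", paste(req, collapse = ", ")))
  }
  pairs <- table |>
    filter(.data$bait != "control") |>
    distinct(.data$bait, .data$prey, .data$bfdr, .data$fold_change)
  if (anyNA(pairs$bfdr)) abort("missing BFDR values; score the table first")
  kept <- pairs |>
    filter(.data$bfdr <= bfdr_max, .data$fold_change >= fc_min)
  baits <- unique(pairs$bait)
  sets <- lapply(setNames(baits, baits),
                 function(b) sort(kept$prey[kept$bait == b]))
  sets
}

#' Bait-network set algebra over four bait conditions
#'
#' From per-bait high-confidence prey sets for the four baits (short and
#' long isoform, N- and C-terminal tags), derives: preys common to both
#' short-isoform baits, preys common to both long-isoform baits, their
#' union (the high-confidence network), and the four-way intersection.
#' Inclusion-exclusion holds exactly:
#' `|network| = |S_common| + |L_common| - |S_common intersect L_common|`.
#'
#' @param prey_sets Named list of four character vectors; names must
#'   contain the bait ids given in `baits`.
#' @param baits Character vector of length 4: the two short-isoform baits
#'   then the two long-isoform baits.
#' @return A `bait_network` list: `s_common`, `l_common`, `network`,
#'   `fourway`, and `sizes` (named integer vector).
#' @export
build_bait_network <- function(prey_sets,
                               baits = c("MAF-S-N", "MAF-S-C",
                                         "MAF-L-N", "MAF-L-C")) {
  if (length(baits) != 4) abort("`baits` must name exactly four baits")
  missing_baits <- setdiff(baits, names(prey_sets))
  if (length(missing_baits) > 0) {
    abort(paste0("missing bait set(s): ", paste(missing_baits, collapse = ", ")))
  }
  s_common <- intersect(prey_sets[[baits[1]]], prey_sets[[baits[2]]])
  l_common <- intersect(prey_sets[[baits[3]]], prey_sets[[baits[4]]])
  network <- union(s_common, l_common)
  fourway <- intersect(s_common, l_common)
  structure(
    list(s_common = sort(s_common), l_common = sort(l_common),
         network = sort(network), fourway = sort(fourway),
         sizes = c(s_common = length(s_common), l_common = length(l_common),
                   network = length(network), fourway = length(fourway))),
    class = "bait_network"
  )
}

#' @export
print.bait_network <- function(x, ...) {
  cat("<bait_network> S-common ", x$sizes["s_common"], ", L-common ",
      x$sizes["l_common"], ", network ", x$sizes["network"],
      " (four-way ", x$sizes["fourway"], ")\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.bait_network <- function(x, ...) {
  as_tibble(as.list(x$sizes))
}

#' Dot-plot summary for selected interactors
#'
#' For each (bait, prey) with the prey in `selected`, reports the average
#' spectral count over retained replicates, the relative abundance across
#' the four baits (max-normalised so the bait with the highest average gets
#' 1), and the pair's BFDR.
#'
#' @param table Bait-prey tibble (after engine merging / replicate
#'   selection) with `bait`, `prey`, `spectral_count` and optionally
#'   `bfdr`.
#' @param selected Character vector of prey ids to summarise.
#' @return Tibble: `bait`, `prey`, `avg_count`, `relative_abundance`,
#'   `bfdr`.
#' @export
dotplot_data <- function(table, selected) {
  table <- as_tibble(table)
  if (!all(selected %in% table$prey)) {
    abort("some selected preys are absent from the table")
  }
  has_bfdr <- "bfdr" %in% names(table)
  table |>
    filter(.data$bait != "control", .data$prey %in% selected) |>
    summarise(avg_count = mean(.data$spectral_count),
              bfdr = if (has_bfdr) dplyr::first(.data$bfdr) else NA_real_,
              .by = c("bait", "prey")) |>
    mutate(.by = "prey",
           relative_abundance = if (max(.data$avg_count) > 0) {
             .data$avg_count / max(.data$avg_count)
           } else 0) |>
    select("bait", "prey", "avg_count", "relative_abundance", "bfdr") |>
    arrange(.data$prey, .data$bait)
}
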