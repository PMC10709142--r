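#' Build a genome model from gene annotations
#'
#' A genome model bundles chromosome sizes with a gene table and is the
#' reference object used for peak annotation, TSS distances, link building
#' and signature construction. Coordinates are 0-based half-open throughout
#' the package; the TSS of a `+` gene is its span start, and of a `-` gene
#' its last base (`end - 1`).
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`). A `tss` column, if absent, is derived from
#'   the strand.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return An object of class `genome_model`: a list with `chrom_sizes` and
#'   a `genes` tibble (with `tss`).
#' @examples
#' gm <- genome_model(
#'   tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1000,
#'                  end = 5000, strand = "+"),
#'   c(chr1 = 1e6)
#' )
#' @export
genome_model <- function(genes, chrom_sizes) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("`genes` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("gene ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    abort("gene intervals must satisfy 0 <= start < end")
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("`chrom_sizes` must be a named vector")
  }
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    abort(paste0("gene chromosome(s) not in `chrom_sizes`: ",
                 paste(unknown, collapse = ", ")))
  }
  over <- genes$end > chrom_sizes[genes$chrom]
  if (any(over)) abort("gene span(s) exceed chromosome length")
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  }
  structure(
    list(chrom_sizes = chrom_sizes, genes = genes),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_sizes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

# validate a peak table and add peak ids when absent
check_peaks <- function(peaks, arg = "peaks") {
  peaks <- as_tibble(peaks)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(peaks))
  if (length(missing_cols) > 0) {
    abort(paste0("`", arg, "` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(peaks) > 0 && (any(peaks$start < 0) || any(peaks$start >= peaks$end))) {
    abort(paste0("`", arg, "` intervals must satisfy 0 <= start < end"))
  }
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  peaks
}

# 0-based half-open tibble -> GRanges (1-based closed)
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

peak_midpoint <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}

#' Annotate peaks by promoter/gene-body/intergenic category
#'
#' Each peak is annotated by its midpoint: `promoter-TSS` if the midpoint
#' lies within `promoter_half_width` bp (default 2 kb, both edges inclusive)
#' of any TSS; otherwise `gene-body` if the midpoint falls inside any gene
#' span; otherwise `intergenic`. The nearest gene is the gene minimising the
#' absolute midpoint-to-TSS distance, with ties broken by lexicographic gene
#' id. `tss_distance` is signed: positive downstream of the TSS in gene
#' orientation, negative upstream.
#'
#' @param peaks Data frame of peaks (`chrom`, `start`, `end`; 0-based
#'   half-open). A `peak_id` column is added when absent.
#' @param genome A [genome_model()].
#' @param promoter_half_width Promoter window half-width in bp.
#' @return The peak tibble with columns `annotation` (factor with levels
#'   `promoter-TSS`, `gene-body`, `intergenic`), `nearest_gene` and
#'   `tss_distance` added. Peaks on chromosomes without genes get
#'   `intergenic` with `NA` distance (with a warning).
#' @export
annotate_peaks <- function(peaks, genome, promoter_half_width = 2000) {
  stopifnot(inherits(genome, "genome_model"))
  peaks <- check_peaks(peaks)
  if (nrow(genome$genes) == 0) {
    abort("genome model has no genes; annotation is undefined")
  }
  if (nrow(peaks) == 0) {
    peaks$annotation <- factor(character(), levels = annotation_levels())
    peaks$nearest_gene <- character()
    peaks$tss_distance <- numeric()
    return(peaks)
  }
  mid <- peak_midpoint(peaks)
  nearest <- nearest_tss(peaks$chrom, mid, genome$genes)

  in_body <- midpoint_in_gene_body(peaks$chrom, mid, genome$genes)
  ann <- ifelse(!is.na(nearest$abs_distance) &
                  nearest$abs_distance <= promoter_half_width,
                "promoter-TSS",
                ifelse(in_body, "gene-body", "intergenic"))
  peaks$annotation <- factor(ann, levels = annotation_levels())
  peaks$nearest_gene <- nearest$gene_id
  peaks$tss_distance <- nearest$signed_distance
  peaks
}

annotation_levels <- function() c("promoter-TSS", "gene-body", "intergenic")

# nearest TSS per peak midpoint, within the peak's chromosome;
# ties at equal |distance| resolved by lexicographic gene id
nearest_tss <- function(chrom, mid, genes, block = 2000L) {
  n <- length(mid)
  gene_id <- rep(NA_character_, n)
  abs_d <- rep(NA_real_, n)
  signed_d <- rep(NA_real_, n)
  warned <- FALSE
  for (chr in unique(chrom)) {
    pk <- which(chrom == chr)
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) == 0) {
      warned <- TRUE
      next
    }
    g <- g[order(g$gene_id), ]
    for (i in seq(1, length(pk), by = block)) {
      idx <- pk[i:min(i + block - 1, length(pk))]
      dmat <- abs(outer(mid[idx], g$tss, "-"))
      best <- max.col(-dmat, ties.method = "first")
      gene_id[idx] <- g$gene_id[best]
      abs_d[idx] <- dmat[cbind(seq_along(idx), best)]
      signed_d[idx] <- ifelse(g$strand[best] == "+",
                              mid[idx] - g$tss[best],
                              g$tss[best] - mid[idx])
    }
  }
  if (warned) {
    warn("some peaks lie on chromosomes without genes; their nearest gene is NA")
  }
  list(gene_id = gene_id, abs_distance = abs_d, signed_distance = signed_d)
}

midpoint_in_gene_body <- function(chrom, mid, genes) {
  if (nrow(genes) == 0) return(rep(FALSE, length(mid)))
  mids <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  spans <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end)
  )
  GenomicRanges::countOverlaps(mids, spans) > 0
}

#' Signed distance from peak midpoints to the nearest TSS
#'
#' Convenience wrapper around the nearest-TSS scan used by
#' [annotate_peaks()]: adds `nearest_gene` and `tss_distance` (signed,
#' positive downstream in gene orientation) to the peak table.
#'
#' @inheritParams annotate_peaks
#' @return The peak tibble with `nearest_gene` and `tss_distance` added.
#' @export
distance_to_tss <- function(peaks, genome) {
  stopifnot(inherits(genome, "genome_model"))
  peaks <- check_peaks(peaks)
  if (nrow(genome$genes) == 0) {
    abort("genome model has no genes; TSS distance is undefined")
  }
  nearest <- nearest_tss(peaks$chrom, peak_midpoint(peaks), genome$genes)
  peaks$nearest_gene <- nearest$gene_id
  peaks$tss_distance <- nearest$signed_distance
  peaks
}

#' Gap-tolerant interval overlap
#'
#' Two intervals overlap at gap tolerance `max_gap` when they are on the same
#' chromosome and the gap between them is at most `max_gap` bp (overlapping
#' or adjacent intervals have gap 0). `a` and `b` are matched row-wise with
#' recycling of length-1 inputs.
#'
#' @param a,b Data frames of intervals (`chrom`, `start`, `end`).
#' @param max_gap Maximum tolerated gap in bp (>= 0).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, max_gap = 0) {
  if (max_gap < 0) abort("`max_gap` must be >= 0")
  a <- check_peaks(a, "a")
  b <- check_peaks(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1) b <- b[rep(1, n), ]
  if (nrow(a) != nrow(b)) abort("`a` and `b` must have matching (or length-1) row counts")
  gap <- pmax(a$start - b$end, b$start - a$end, 0)
  a$chrom == b$chrom & gap <= max_gap
}

# TRUE per row of `peaks` overlapping any interval of `others` at `max_gap`
overlaps_any <- function(peaks, others, max_gap = 0) {
  if (nrow(others) == 0) return(rep(FALSE, nrow(peaks)))
  suppressWarnings(GenomicRanges::countOverlaps(
    peaks_to_granges(peaks), peaks_to_granges(others),
    maxgap = max_gap
  )) > 0
}

#' Peak breadth
#'
#' Breadth is `log10` of the peak width in bp; peaks with breadth above 3
#' (width above 1 kb) are conventionally treated as broad.
#'
#' @param peaks Data frame of peaks, or a numeric vector of widths.
#' @return Numeric vector of breadth scores.
#' @examples
#' peak_breadth(data.frame(chrom = "chr1", start = 0, end = 1000))  # 3
#' @export
peak_breadth <- function(peaks) {
  width <- if (is.numeric(peaks)) peaks else {
    peaks <- check_peaks(peaks)
    peaks$end - peaks$start
  }
  if (any(width < 1)) abort("peak width must be >= 1 bp")
  log10(width)
}
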