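# shared in-code fixtures: a small deterministic genome and random-instance
# builders used by the brute-force oracles

tiny_genome <- function() {
  genome_model(
    tibble::tibble(
      gene_id = c("gA", "gB", "gC"),
      chrom   = c("chr1", "chr1", "chr2"),
      start   = c(10000, 50000, 5000),
      end     = c(20000, 60000, 9000),
      strand  = c("+", "-", "+")
    ),
    c(chr1 = 1e6, chr2 = 5e5)
  )
}

random_genome <- function(n_genes, seed, chrom_sizes = c(chr1 = 2e6, chr2 = 1e6)) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_sizes), n_genes, replace = TRUE)
    tss <- floor(runif(n_genes, 5000, chrom_sizes[chrom] - 5000))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    len <- sample(500:4000, n_genes, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = chrom,
      start = ifelse(strand == "+", tss, tss - len + 1),
      end = ifelse(strand == "+", tss + len, tss + 1),
      strand = strand
    )
    genome_model(genes, chrom_sizes)
  })
}

random_peaks <- function(n, seed, chrom_sizes = c(chr1 = 2e6, chr2 = 1e6)) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_sizes), n, replace = TRUE)
    start <- floor(runif(n, 0, chrom_sizes[chrom] - 2000))
    tibble::tibble(chrom = chrom, start = start,
                   end = start + sample(100:1500, n, replace = TRUE),
                   peak_id = sprintf("p%03d", seq_len(n)))
  })
}

# exhaustive nearest-TSS / categorisation oracle (O(peaks x genes))
annotate_oracle <- function(peaks, genome, half_width = 2000) {
  genes <- genome$genes
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) {
      return(list(annotation = "intergenic", nearest = NA, dist = NA))
    }
    d <- abs(mid[i] - g$tss)
    best <- which(d == min(d))
    best <- best[order(g$gene_id[best])][1]
    signed <- if (g$strand[best] == "+") mid[i] - g$tss[best] else g$tss[best] - mid[i]
    in_body <- any(mid[i] >= g$start & mid[i] < g$end)
    ann <- if (min(d) <= half_width) "promoter-TSS" else if (in_body) "gene-body" else "intergenic"
    list(annotation = ann, nearest = g$gene_id[best], dist = signed)
  })
  tibble::tibble(
    annotation = vapply(out, `[[`, "", "annotation"),
    nearest_gene = vapply(out, function(x) as.character(x$nearest), ""),
    tss_distance = vapply(out, function(x) as.numeric(x$dist), 0)
  )
}

# long contrast table from a named list of statistic vectors
make_contrast_table <- function(stats_by_contrast, ids = NULL) {
  n <- length(stats_by_contrast[[1]])
  ids <- ids %||% sprintf("f%03d", seq_len(n))
  purrr::imap_dfr(stats_by_contrast, function(s, ct) {
    tibble::tibble(feature_id = ids, contrast = ct, log2fc = s / 2,
                   stat = s, pvalue = 2 * stats::pnorm(-abs(s)))
  })
}

`%||%` <- rlang::`%||%`
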