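test_that("expected match count and spread follow the binomial closed form", {
  es <- expected_matches(1e6, 1e8, 1000)
  expect_equal(es$expected, 10)
  expect_equal(es$sd, sqrt(1000 * 0.01 * 0.99))
  whole <- expected_matches(1e8, 1e8, 1000)
  expect_equal(whole$expected, 1000)
  expect_equal(whole$sd, 0)
  expect_error(expected_matches(10, 0, 5), "genome_total_bp")
  expect_error(expected_matches(0, 10, 5), "region_total_bp")
  expect_error(motif_zscore(5, 1000, whole$sd), "binomial")
})

test_that("z-score and fold factor apply the stated formulas", {
  expect_equal(motif_zscore(30, 20, 4), 2.375)
  expect_equal(motif_fold(30, 20), 1.5)
  expect_equal(motif_zscore(20.5, 20, 4), 0)  # X = E + 0.5
  expect_error(motif_fold(10, 0), "E")
})

test_that("E and S match Monte-Carlo uniform placement of matches", {
  genome_bp <- 1e6
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0, 3e5, 7e5),
                            end = c(1e5, 3.5e5, 7.5e5))  # 200 kb total
  n_match <- 500
  es <- expected_matches(2e5, genome_bp, n_match)
  n_rep <- 10000
  withr::with_seed(55, {
    pos <- matrix(floor(runif(n_rep * n_match, 0, genome_bp)), n_rep)
  })
  in_region <- function(p) {
    (p >= 0 & p < 1e5) | (p >= 3e5 & p < 3.5e5) | (p >= 7e5 & p < 7.5e5)
  }
  X <- rowSums(matrix(in_region(pos), n_rep))
  expect_lt(abs(mean(X) - es$expected), 3 * es$sd / sqrt(n_rep))
  expect_lt(abs(sd(X) / es$sd - 1), 0.05)
})

test_that("match counting agrees with a quadratic membership oracle", {
  regions <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                            start = c(100, 500, 50), end = c(200, 700, 80),
                            peak_id = c("r1", "r2", "r3"))
  expect_equal(count_motif_matches(regions,
                                   tibble::tibble(chrom = character(),
                                                  pos = numeric()))$n_matches, 0)
  one_each <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                             pos = c(150, 600, 60))
  got <- count_motif_matches(regions, one_each)
  expect_equal(got$n_matches, 3)
  expect_equal(got$n_regions_with_match, 3)
  withr::with_seed(21, {
    mts <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                          pos = sample(0:1000, 200, TRUE))
  })
  inside <- vapply(seq_len(nrow(mts)), function(i) {
    any(mts$chrom[i] == regions$chrom & mts$pos[i] >= regions$start &
          mts$pos[i] < regions$end)
  }, logical(1))
  per_region <- vapply(seq_len(nrow(regions)), function(j) {
    sum(mts$chrom == regions$chrom[j] & mts$pos >= regions$start[j] &
          mts$pos < regions$end[j])
  }, numeric(1))
  got2 <- count_motif_matches(regions, mts)
  expect_equal(got2$n_matches, sum(per_region))
  expect_equal(got2$n_regions_with_match, sum(per_region > 0))
  expect_equal(got2$n_matches, sum(inside))
})

no_gene_genome <- function(size = 1e6) {
  genome_model(tibble::tibble(gene_id = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              strand = character()),
               c(chr1 = size))
}

test_that("stitching merges at 12,500 bp and splits at 12,501 bp", {
  gm <- no_gene_genome()
  close_pair <- tibble::tibble(chrom = "chr1", start = c(1000, 14500),
                               end = c(2000, 15000))  # gap 12,500
  far_pair <- tibble::tibble(chrom = "chr1", start = c(1000, 14501),
                             end = c(2000, 15000))    # gap 12,501
  expect_equal(nrow(stitch_enhancers(close_pair, gm)), 1)
  expect_equal(nrow(stitch_enhancers(far_pair, gm)), 2)
  merged <- stitch_enhancers(close_pair, gm)
  expect_equal(merged$start, 1000)
  expect_equal(merged$end, 15000)
  expect_equal(merged$n_constituents, 2L)
})

test_that("promoter-contained peaks are excluded, straddling peaks kept", {
  gm <- genome_model(
    tibble::tibble(gene_id = "g", chrom = "chr1", start = 50000, end = 60000,
                   strand = "+"),
    c(chr1 = 1e6)
  )
  inside <- tibble::tibble(chrom = "chr1", start = 49000, end = 51000)
  straddle <- tibble::tibble(chrom = "chr1", start = 47000, end = 49000)
  # window is [48000, 52000]; `inside` fully contained, `straddle` pokes out
  expect_equal(nrow(stitch_enhancers(inside, gm)), 0)
  expect_equal(nrow(stitch_enhancers(straddle, gm)), 1)
})

test_that("stitching matches a union-find oracle and is idempotent", {
  gm <- no_gene_genome(2e5)
  withr::with_seed(37, {
    start <- sort(sample(0:190000, 40))
    peaks <- tibble::tibble(chrom = "chr1", start = start,
                            end = start + sample(200:2000, 40, TRUE))
  })
  got <- stitch_enhancers(peaks, gm, stitch_dist = 3000)
  # union-find over all pairs with gap <= 3000
  parent <- seq_len(nrow(peaks))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(peaks))) {
    gap <- max(peaks$start[j] - peaks$end[i], peaks$start[i] - peaks$end[j], 0)
    if (gap <= 3000) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(nrow(peaks)), find, 1L)
  oracle <- tibble::tibble(comp = comp, start = peaks$start, end = peaks$end) |>
    dplyr::summarise(start = min(start), end = max(end), .by = comp) |>
    dplyr::arrange(start)
  expect_equal(got$start, oracle$start)
  expect_equal(got$end, oracle$end)
  # idempotence: stitching the stitched intervals changes nothing
  again <- stitch_enhancers(got, gm, stitch_dist = 3000)
  expect_equal(again[, c("chrom", "start", "end")],
               got[, c("chrom", "start", "end")])
  # order invariance
  shuffled <- stitch_enhancers(peaks[sample(nrow(peaks)), ], gm,
                               stitch_dist = 3000)
  expect_equal(shuffled$start, got$start)
})

test_that("super-enhancer flagging follows the tangent rule", {
  gm <- no_gene_genome()
  st <- tibble::tibble(enhancer_id = sprintf("e%02d", 1:20), chrom = "chr1",
                       start = (1:20) * 1e4, end = (1:20) * 1e4 + 5000,
                       n_constituents = 1L, constituents = "x")
  flat <- rank_super_enhancers(st, rep(5, 20))
  expect_false(any(flat$is_super))
  one_out <- rank_super_enhancers(st, c(rep(5, 19), 500))
  expect_equal(sum(one_out$is_super), 1)
  expect_true(one_out$is_super[20])
  # scale invariance of the flags
  scaled <- rank_super_enhancers(st, 10 * c(rep(5, 19), 500))
  expect_equal(scaled$is_super, one_out$is_super)
  # floor at zero when input exceeds target
  floored <- rank_super_enhancers(st, rep(1, 20), input_signal = rep(2, 20))
  expect_true(all(floored$score == 0))
  expect_error(rank_super_enhancers(st[1:2, ], c(1, 2)), ">= 3")
  expect_s3_class(autoplot(one_out), "ggplot")
})

test_that("z-scores are antisymmetric around E + 0.5 and fold is multiplicative", {
  E <- 40; S <- 5
  d <- 7
  expect_equal(motif_zscore(E + 0.5 + d, E, S),
               -motif_zscore(E + 0.5 - d, E, S))
  expect_equal(motif_fold(2 * 30, E), 2 * motif_fold(30, E))
})
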