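annotated_peaks <- function(categories, chrom = "chr1") {
  n <- length(categories)
  tibble::tibble(
    chrom = chrom, start = seq(0, by = 1000, length.out = n),
    end = seq(0, by = 1000, length.out = n) + 500,
    peak_id = sprintf("pk%03d", seq_len(n)),
    annotation = factor(categories,
                        levels = c("promoter-TSS", "gene-body", "intergenic"))
  )
}

test_that("a cluster equal to the consensus is never enriched", {
  cons <- annotated_peaks(rep(c("promoter-TSS", "intergenic"), each = 5))
  res <- category_enrichment_test(cons, cons, n_iter = 200, seed = 4)
  expect_equal(res$observed, 50)
  expect_equal(res$p_value, 1)  # every same-size draw is the full set
})

test_that("sampled and exhaustive category p-values agree with complete enumeration", {
  cons <- annotated_peaks(c("promoter-TSS", "promoter-TSS", "gene-body",
                            "gene-body", "intergenic", "intergenic"))
  clus <- cons[1:2, ]  # both promoter: the most extreme of the 15 subsets
  ex <- category_enrichment_test(clus, cons, exhaustive = TRUE)
  # oracle: complete enumeration over all C(6,2) subsets
  subsets <- combn(6, 2)
  ind <- cons$annotation == "promoter-TSS"
  null_pct <- 100 * colMeans(matrix(ind[subsets], nrow = 2))
  expect_equal(sort(ex$null_values), sort(null_pct))
  expect_equal(ex$p_value, mean(null_pct >= 100))
  expect_equal(ex$p_value, 1 / 15)
  mc <- category_enrichment_test(clus, cons, n_iter = 3000, seed = 9)
  expect_lt(abs(mc$p_value - ex$p_value), 0.02)
})

test_that("planted promoter enrichment is detected at the smallest attainable p", {
  withr::with_seed(31, {
    cons_cat <- c(sample(rep(c("promoter-TSS", "intergenic"), c(160, 40))),
                  sample(rep(c("promoter-TSS", "intergenic"), c(160, 640))))
  })
  cons <- annotated_peaks(cons_cat)
  clus <- cons[1:200, ]  # 80% promoter cluster over a 32% background
  res <- category_enrichment_test(clus, cons, n_iter = 1000, seed = 2)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, 1 / 1001)
  # bit-identical reruns under the same seed
  res2 <- category_enrichment_test(clus, cons, n_iter = 1000, seed = 2)
  expect_identical(res$null_values, res2$null_values)
})

test_that("mark overlap uses the maxgap rule and handles absent marks", {
  cons <- annotated_peaks(rep("intergenic", 6))
  # cons peak i spans [1000*(i-1), 1000*(i-1)+500)
  marks <- tibble::tibble(chrom = "chr1", start = c(600, 1601),
                          end = c(650, 1650))
  # gap to peak1 [0,500) is 100 -> hit; gap to peak2 [1000,1500) is 101 -> miss
  hits <- overlaps_any(cons, marks, max_gap = 100)
  expect_true(hits[1]); expect_false(hits[2])

  off_chrom <- tibble::tibble(chrom = "chr2", start = 0, end = 100)
  res <- mark_overlap_test(cons[1:3, ], cons, off_chrom, n_iter = 50, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  expect_error(mark_overlap_test(cons[1:3, ], cons, cons[0, ]), "nonempty")

  # exhaustive equality on a tiny instance
  clus <- cons[c(1, 3), ]
  ex <- mark_overlap_test(clus, cons, marks, exhaustive = TRUE)
  ind <- overlaps_any(cons, marks, max_gap = 100)
  subsets <- combn(6, 2)
  null_pct <- 100 * colMeans(matrix(ind[subsets], nrow = 2))
  obs <- 100 * mean(ind[c(1, 3)])
  expect_equal(ex$p_value, mean(null_pct >= obs))

  # "all" mode requires overlap with every mark set
  m2 <- list(k27 = marks, k4 = tibble::tibble(chrom = "chr1", start = 5,
                                              end = 20))
  both <- mark_overlap_test(cons[1, ], cons, m2, mode = "all",
                            n_iter = 50, seed = 1)
  expect_equal(both$observed, 100)  # peak 1 overlaps both sets
})

test_that("permutation p-values are valid under the uniform null", {
  cons <- annotated_peaks(rep(c("promoter-TSS", "intergenic"), c(15, 25)))
  n_rep <- 200; n_iter <- 199; alpha <- 0.1
  pvals <- withr::with_seed(99, {
    vapply(seq_len(n_rep), function(r) {
      clus <- cons[sample(40, 10), ]
      category_enrichment_test(clus, cons, n_iter = n_iter,
                               seed = 1000 + r)$p_value
    }, numeric(1))
  })
  bound <- alpha + 1 / (n_iter + 1) + 2 * sqrt(alpha * (1 - alpha) / n_rep)
  expect_lte(mean(pvals <= alpha), bound)
})

test_that("breadth comparison reproduces rank-sum boundary cases", {
  g1 <- tibble::tibble(chrom = "chr1", start = 0, end = c(10, 10, 10))
  g2 <- tibble::tibble(chrom = "chr1", start = 0, end = c(10000, 10000, 10000))
  res <- breadth_compare(g1, g2)
  # within-group ties force the tie-corrected normal approximation; the
  # result must match the reference rank-sum implementation and be the
  # smallest attainable for a complete separation at n = 3,3
  ref <- suppressWarnings(wilcox.test(rep(1, 3), rep(4, 3)))
  expect_equal(res$p_value, ref$p.value)
  expect_lt(res$p_value, 0.05)
  same <- breadth_compare(g1, g1)
  expect_equal(same$p_value, 1)
  expect_error(breadth_compare(g1[0, ], g2), "nonempty")
  # reference-implementation agreement on random data
  withr::with_seed(12, {
    a <- tibble::tibble(chrom = "chr1", start = 0,
                        end = sample(50:5000, 30))
    b <- tibble::tibble(chrom = "chr1", start = 0,
                        end = sample(50:5000, 25))
  })
  ref <- suppressWarnings(wilcox.test(log10(a$end), log10(b$end)))
  expect_equal(breadth_compare(a, b)$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("cluster subset membership is enforced", {
  cons <- annotated_peaks(rep("intergenic", 5))
  alien <- annotated_peaks(rep("intergenic", 2))
  alien$peak_id <- c("x1", "x2")
  expect_error(category_enrichment_test(alien, cons, n_iter = 10),
               "consensus")
})
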