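test_that("low-expression filter removes means at or below the threshold", {
  counts <- rbind(bnd = c(5, 5, 5, 5), keep = c(6, 6, 6, 6),
                  lo = c(0, 1, 0, 2))
  colnames(counts) <- paste0("s", 1:4)
  kept <- filter_low_expression(counts)
  expect_equal(rownames(kept), "keep")
  expect_error(filter_low_expression(matrix(nrow = 0, ncol = 0)), "empty")
  expect_error(filter_low_expression(-counts), "nonnegative")

  m <- matrix(rpois(600, 6), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  expect_equal(rownames(filter_low_expression(m)),
               rownames(m)[rowMeans(m) > 5])
})

test_that("size factors are median-of-ratios and scale proportionally", {
  withr::with_seed(11, {
    base <- matrix(rnbinom(400, mu = 100, size = 10), 100, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  })
  doubled <- base
  doubled[, 2] <- base[, 2] * 2
  sf <- size_factors(doubled)
  expect_equal(sf[["s2"]] / sf[["s1"]],
               2 * size_factors(base)[["s2"]] / size_factors(base)[["s1"]],
               tolerance = 1e-10)
  expect_equal(unname(size_factors(cbind(s1 = base[, 1], s2 = base[, 1]))),
               c(1, 1))
  # direct median-of-ratios oracle (median taken on the ratio scale; the
  # log-scale median used internally can differ only in even-count ties)
  pos <- base[rowSums(base <= 0) == 0, ]
  ref <- exp(rowMeans(log(pos)))
  oracle <- apply(pos, 2, function(x) median(x / ref))
  expect_equal(size_factors(base), oracle, tolerance = 1e-3)
  # independent implementation cross-check
  expect_equal(unname(size_factors(base)),
               unname(DESeq2::estimateSizeFactorsForMatrix(base)),
               tolerance = 1e-8)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "positive")
})

test_that("contrast statistics are calibrated under the null and powered for planted effects", {
  withr::with_seed(42, {
    n_null <- 450; n_fx <- 50
    mu <- rbind(matrix(100, n_null, 12),
                cbind(matrix(100, n_fx, 6), matrix(400, n_fx, 6)))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), nrow(mu))
  })
  rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", 1:12)
  design <- tibble::tibble(sample = colnames(counts),
                           condition = rep(c("ctl", "trt"), each = 6))
  ct <- contrast_stats(counts, design,
                       contrasts = list(trt_vs_ctl = c("trt", "ctl")))
  is_fx <- ct$feature_id %in% rownames(counts)[-(1:450)]
  # planted log2FC = 2 at mean 100: positive sign and |stat| > 2 almost always
  expect_gte(mean(ct$stat[is_fx] > 2), 0.9)
  expect_equal(mean(ct$log2fc[is_fx]), 2, tolerance = 0.15)
  # null features: tail no heavier than nominal (plus Monte-Carlo slack)
  expect_lte(mean(abs(ct$stat[!is_fx]) > 2), 2 * pnorm(-2) + 0.025)
  # sign coherence and p consistency
  expect_true(all(sign(ct$stat) == sign(ct$log2fc) | ct$stat == 0, na.rm = TRUE))
  expect_equal(ct$pvalue, 2 * pnorm(-abs(ct$stat)), tolerance = 1e-12)
})

test_that("a feature with identical counts in all samples has statistic zero", {
  withr::with_seed(3, {
    counts <- rbind(flat = rep(50, 8),
                    matrix(rnbinom(160, mu = 80, size = 10), 20, 8))
  })
  rownames(counts)[-1] <- sprintf("g%02d", 1:20)
  colnames(counts) <- paste0("s", 1:8)
  design <- tibble::tibble(sample = colnames(counts),
                           condition = rep(c("a", "b"), each = 4))
  ct <- contrast_stats(counts, design, contrasts = list(b_vs_a = c("b", "a")),
                       sf = setNames(rep(1, 8), colnames(counts)))
  expect_equal(ct$stat[ct$feature_id == "flat"], 0, tolerance = 1e-6)
})

test_that("statistics are invariant to sample-depth rescaling", {
  withr::with_seed(8, {
    counts <- matrix(rnbinom(240, mu = 200, size = 10), 20, 12,
                     dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:12)))
  })
  design <- tibble::tibble(sample = colnames(counts),
                           condition = rep(c("mock", "mockE2", "MAF", "MAFE2"),
                                           each = 3))
  ct1 <- contrast_stats(counts, design)
  scaled <- counts
  scaled[, 1] <- counts[, 1] * 2
  ct2 <- contrast_stats(scaled, design)
  # size factors absorb the rescaling; the NB working weights retain a
  # slight dependence on absolute depth, so invariance is near-exact
  expect_lt(max(abs(ct1$stat - ct2$stat)), 0.05)
  expect_gt(cor(ct1$stat, ct2$stat), 0.999)
  expect_error(
    contrast_stats(counts, dplyr::mutate(design, batch = condition)),
    "rank deficient")
})

test_that("cluster rules fire exactly as specified, with E/F priority", {
  zero <- rep(0, 4)
  tbl <- make_contrast_table(list(
    MAF_vs_mock     = c(3,  0, 0,  2.5),
    mockE2_vs_mock  = c(0,  0, 0,  0),
    MAFE2_vs_MAF    = c(0, -3, 4,  2.5),
    MAFE2_vs_mockE2 = c(2.5, -2.2, 4, 2.5),
    MAFE2_vs_mock   = zero
  ))
  pk <- assign_peak_clusters(tbl)
  expect_equal(as.character(pk$cluster), c("A", "F", "E", "E"))
  expect_equal(pk$rules_fired[4], "A,E")  # E outranks A
  gn <- assign_gene_clusters(tbl)
  expect_equal(as.character(gn$cluster), c("1", "6", "5", "5"))

  all0 <- make_contrast_table(purrr::map(default_contrasts(), ~ rep(0, 2)))
  expect_true(all(assign_gene_clusters(all0)$cluster == "none"))
  expect_error(assign_peak_clusters(tbl, threshold = 0), "threshold")
})

test_that("assignment is order-invariant and matches brute-force rule evaluation", {
  withr::with_seed(5, {
    stats <- purrr::map(default_contrasts(), ~ runif(120, -4, 4))
  })
  tbl <- make_contrast_table(stats)
  a1 <- assign_peak_clusters(tbl)
  a2 <- assign_peak_clusters(tbl[sample(nrow(tbl)), ])
  expect_equal(a1, a2[match(a1$feature_id, a2$feature_id), ],
               ignore_attr = TRUE)
  # brute-force evaluation of the three conjunctions with priority
  w <- as.data.frame(stats)
  oracle <- apply(w, 1, function(s) {
    if (s["MAFE2_vs_MAF"] > 2 && s["MAFE2_vs_mockE2"] > 2) "E"
    else if (s["MAFE2_vs_MAF"] < -2 && s["MAFE2_vs_mockE2"] < -2) "F"
    else if (s["MAF_vs_mock"] > 2 && s["MAFE2_vs_mockE2"] > 2) "A"
    else if (s["MAF_vs_mock"] < -2 && s["MAFE2_vs_mockE2"] < -2) "B"
    else if (s["MAFE2_vs_MAF"] > 2 && s["mockE2_vs_mock"] > 2) "C"
    else if (s["MAFE2_vs_MAF"] < -2 && s["mockE2_vs_mock"] < -2) "D"
    else "none"
  })
  expect_equal(as.character(a1$cluster), unname(oracle))
})

test_that("relaxed rules respect promoter restriction and the breadth floor", {
  qualifying <- list(
    MAF_vs_mock = c(1.6, 1.6, 1.6, 1.6), mockE2_vs_mock = rep(0, 4),
    MAFE2_vs_MAF = rep(0, 4), MAFE2_vs_mockE2 = c(1.6, 1.6, 1.6, 1.6),
    MAFE2_vs_mock = rep(0, 4)
  )
  tbl <- make_contrast_table(qualifying, ids = paste0("p", 1:4))
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(0, 0, 0, 0),
    end = c(1200, 900, 1200, 1200),          # breadths 3.08, 2.95, 3.08, 3.08
    peak_id = paste0("p", 1:4),
    annotation = factor(c("promoter-TSS", "promoter-TSS", "gene-body",
                          "promoter-TSS"),
                        levels = c("promoter-TSS", "gene-body", "intergenic"))
  )
  rel <- assign_relaxed_clusters(tbl, peaks)
  expect_equal(as.character(rel$cluster), c("A", "none", "none", "A"))
  expect_error(assign_relaxed_clusters(tbl, dplyr::select(peaks, -annotation)),
               "annotated")

  # strict promoter broad peaks remain assigned under the relaxed variant
  withr::with_seed(6, {
    stats <- purrr::map(default_contrasts(), ~ runif(80, -4, 4))
  })
  tbl2 <- make_contrast_table(stats)
  peaks2 <- tibble::tibble(
    chrom = "chr1", start = 0, end = 2000,
    peak_id = sprintf("f%03d", 1:80),
    annotation = factor(rep("promoter-TSS", 80),
                        levels = c("promoter-TSS", "gene-body", "intergenic"))
  )
  strict <- assign_peak_clusters(tbl2)
  relax <- assign_relaxed_clusters(tbl2, peaks2)
  strict_assigned <- strict$feature_id[strict$cluster != "none"]
  expect_true(all(relax$cluster[match(strict_assigned, relax$feature_id)] != "none"))
})
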