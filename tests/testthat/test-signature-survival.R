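test_that("signature construction requires binding in both conditions", {
  gm <- random_genome(30, seed = 301)
  cl1 <- gm$genes$gene_id[1:15]
  at_tss <- function(ids) {
    g <- gm$genes[match(ids, gm$genes$gene_id), ]
    tibble::tibble(chrom = g$chrom, start = pmax(g$tss - 100, 0),
                   end = g$tss + 100)
  }
  peaks_a <- at_tss(gm$genes$gene_id[c(1:6, 20:22)])
  peaks_b <- at_tss(gm$genes$gene_id[c(4:9, 23:25)])
  sig <- build_signature(cl1, peaks_a, peaks_b, gm)
  # brute-force double-membership oracle
  near_a <- annotate_oracle(peaks_a, gm)$nearest_gene
  near_b <- annotate_oracle(peaks_b, gm)$nearest_gene
  oracle <- sort(intersect(cl1, intersect(near_a, near_b)))
  expect_equal(sig, oracle)
  # a gene bound in one condition only is excluded
  expect_false(gm$genes$gene_id[1] %in% sig &&
                 !gm$genes$gene_id[1] %in% near_b)
  expect_error(build_signature(character(), peaks_a, peaks_b, gm), "nonempty")
})

test_that("sample scoring is the mean genewise z-score", {
  withr::with_seed(71, {
    expr <- matrix(rnorm(5 * 12, mean = 6), 5, 12,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  })
  one <- score_samples(expr, "g1")
  expect_equal(one, (expr["g1", ] - mean(expr["g1", ])) / sd(expr["g1", ]))
  multi <- score_samples(expr, c("g1", "g2", "g3"))
  z <- t(scale(t(expr[c("g1", "g2", "g3"), ])))
  expect_equal(multi, colMeans(z))
  expr["g2", ] <- 4
  expect_warning(s2 <- score_samples(expr, c("g1", "g2")), "constant")
  expect_equal(s2, score_samples(expr, "g1"))
  expect_error(score_samples(expr, "absent"), "present")
})

test_that("stratification splits strictly below mean minus one SD", {
  scores <- c(-3, rep(0, 8), 3)
  grp <- stratify_scores(scores)
  expect_equal(sum(grp == "low"), 1)
  expect_equal(which(grp == "low"), 1L)
  # affine invariance
  expect_equal(stratify_scores(10 + 2 * scores), grp)
  expect_warning(flat <- stratify_scores(rep(1, 5)), "variance")
  expect_true(all(flat == "mid-high"))
  expect_error(stratify_scores(c(1, 2)), ">= 3")
})

test_that("log-rank matches a hand-computed oracle and degenerate cases behave", {
  clinical <- tibble::tibble(
    sample = paste0("s", 1:6),
    time = c(1, 3, 5, 2, 4, 6),
    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  groups <- factor(rep(c("low", "mid-high"), each = 3),
                   levels = c("low", "mid-high"))
  names(groups) <- clinical$sample
  res <- km_logrank(clinical, groups)
  # independent log-rank computation from the risk tables
  ev_times <- sort(clinical$time[clinical$event])
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- clinical$time >= t
    n1 <- sum(at_risk & groups == "low"); n <- sum(at_risk)
    d <- sum(clinical$time == t & clinical$event)
    d1 <- sum(clinical$time == t & clinical$event & groups == "low")
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chisq, (O1 - E1)^2 / V, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq((O1 - E1)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # identical event patterns in both groups: chi-square ~ 0, p ~ 1
  clin2 <- tibble::tibble(sample = paste0("s", 1:8),
                          time = rep(c(2, 4, 6, 8), 2),
                          event = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  g2 <- factor(rep(c("low", "mid-high"), each = 4)); names(g2) <- clin2$sample
  same <- km_logrank(clin2, g2)
  expect_lt(same$chisq, 1e-9)
  expect_gt(same$p_value, 0.999)

  # zero events in one group still yields a defined statistic, with a note
  clin3 <- tibble::tibble(sample = paste0("s", 1:8),
                          time = c(1, 2, 3, 4, 5, 6, 7, 8),
                          event = c(rep(TRUE, 4), rep(FALSE, 4)))
  g3 <- factor(rep(c("low", "mid-high"), each = 4)); names(g3) <- clin3$sample
  noev <- km_logrank(clin3, g3)
  expect_true(is.finite(noev$chisq))
  expect_false(is.na(noev$note))
  expect_error(km_logrank(clin3, factor(rep("low", 8))), "two nonempty")
})

test_that("KM estimate equals the empirical survival function without censoring", {
  withr::with_seed(81, {
    times <- sample(1:50, 20, replace = TRUE)
  })
  clinical <- tibble::tibble(sample = paste0("s", 1:20), time = times,
                             event = TRUE)
  groups <- factor(rep(c("low", "mid-high"), each = 10))
  names(groups) <- clinical$sample
  res <- km_logrank(clinical, groups)
  km_low <- res$km[res$km$group == "low", ]
  t_low <- times[1:10]
  for (i in seq_len(nrow(km_low))) {
    expect_equal(km_low$surv[i], mean(t_low > km_low$time[i]))
  }
  expect_true(all(diff(km_low$surv) <= 0))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(glance(res), "tbl_df")
})

test_that("a planted hazard effect in the synthetic cohort is detected", {
  sc <- synthetic_scenario(seed = 29)
  co <- simulate_cohort(sc)
  scores <- score_samples(co$expression, co$truth$signature_genes)
  grp <- stratify_scores(scores)
  res <- km_logrank(co$clinical, grp)
  expect_lt(res$p_value, 0.05)
  # the score-derived low group closely matches the planted one
  agreement <- mean((grp == "low") == co$truth$true_low)
  expect_gt(agreement, 0.85)
})

test_that("gene correlation equals the rank-correlation oracle", {
  withr::with_seed(91, {
    x <- rnorm(40)
    expr <- rbind(a = x, b = exp(x), c = rnorm(40), d = rep(1, 40))
  })
  colnames(expr) <- paste0("s", 1:40)
  mono <- gene_correlation(expr, "a", "b")
  expect_equal(mono$rho, 1)
  rnd <- gene_correlation(expr, "a", "c")
  oracle_rho <- cor(rank(expr["a", ]), rank(expr["c", ]))
  expect_equal(rnd$rho, oracle_rho, tolerance = 1e-9)
  expect_error(gene_correlation(expr, "a", "d"), "constant")
  expect_error(gene_correlation(expr[, 1:5], "a", "c"), ">= 10")
})

test_that("covariate adjustment residualises exactly", {
  cov <- tibble::tibble(sample = paste0("s", 1:10),
                        x = rep(c(0, 1), each = 5))
  # orthogonal: equal group means -> unchanged
  e1 <- matrix(rep(c(1, 2, 3, 4, 5), 2), 1, 10,
               dimnames = list("g1", cov$sample))
  expect_equal(adjust_expression(e1, cov), e1)
  # exact linear function of the covariate -> constant at the gene mean
  e2 <- matrix(2 * cov$x + 3, 1, 10, dimnames = list("g2", cov$sample))
  adj2 <- adjust_expression(e2, cov)
  expect_true(all(abs(adj2 - mean(e2)) < 1e-12))
  # normal-equations oracle on random data
  withr::with_seed(101, {
    E <- matrix(rnorm(5 * 10), 5, 10,
                dimnames = list(paste0("g", 1:5), cov$sample))
    cov$z <- rnorm(10)
  })
  adj <- adjust_expression(E, cov)
  X <- model.matrix(~ x + z, data = cov)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  oracle <- E - E %*% t(H) + rowMeans(E)
  expect_equal(adj, oracle, tolerance = 1e-10)
  expect_error(adjust_expression(E, dplyr::mutate(cov, w = x)),
               "rank deficient")
})
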