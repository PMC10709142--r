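#' The five condition contrasts of the 2x2 design
#'
#' Named list of (numerator, denominator) condition pairs: factor vs mock,
#' hormone vs mock, combined vs factor, combined vs hormone, combined vs
#' mock. Cluster rules are conjunctions over these contrasts.
#'
#' @return Named list of length-2 character vectors.
#' @export
default_contrasts <- function() {
  list(
    MAF_vs_mock     = c("MAF", "mock"),
    mockE2_vs_mock  = c("mockE2", "mock"),
    MAFE2_vs_MAF    = c("MAFE2", "MAF"),
    MAFE2_vs_mockE2 = c("MAFE2", "mockE2"),
    MAFE2_vs_mock   = c("MAFE2", "mock")
  )
}

#' Filter lowly covered features
#'
#' Removes features whose mean raw count across all samples is at or below
#' `min_mean` (default 5, the boundary itself is removed).
#'
#' @param counts Nonnegative count matrix, features x samples.
#' @param min_mean Mean-count threshold.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_mean = 5) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) abort("`counts` is empty")
  if (any(counts < 0)) abort("`counts` must be nonnegative")
  counts[rowMeans(counts) > min_mean, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: each sample's factor is the median of
#' its ratios to the genewise geometric-mean reference, computed over
#' features positive in every sample.
#'
#' @param counts Count matrix, features x samples.
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    abort(paste("no feature has positive counts in every sample;",
                "size factors are undefined (filter or pool samples first)"))
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lc)
  apply(lc, 2, function(x) exp(median(x - ref)))
}

validate_design <- function(design, counts) {
  design <- as_tibble(design)
  if (!all(c("sample", "condition") %in% names(design))) {
    abort("`design` needs `sample` and `condition` columns")
  }
  if (!setequal(design$sample, colnames(counts))) {
    abort("`design$sample` must match the count matrix columns")
  }
  design <- design[match(colnames(counts), design$sample), ]
  design$condition <- factor(design$condition)
  if (any(table(design$condition) < 2)) {
    abort("need >= 2 replicates per condition")
  }
  design
}

# raw (unclamped) method-of-moments NB dispersion per feature from
# normalised counts, pooled over condition groups
mom_dispersion_raw <- function(q, group, inv_sf) {
  levs <- levels(group)
  num <- 0; den <- 0
  for (lev in levs) {
    j <- which(group == lev)
    if (length(j) < 2) next
    mu <- mean(q[j])
    if (mu <= 0) next
    s2 <- var(q[j])
    num <- num + (length(j) - 1) * (s2 - mu * mean(inv_sf[j])) / mu^2
    den <- den + (length(j) - 1)
  }
  if (den == 0) return(NA_real_)
  num / den
}

clamp_alpha <- function(a) pmin(pmax(a, 1e-8), 10)

# mean-dispersion trend: lowess of the raw per-feature estimates against
# log mean, evaluated at every feature; stabilises the estimate so the
# five contrast statistics of a feature do not share estimation noise
trend_dispersion <- function(alpha_raw, mu) {
  ok <- is.finite(alpha_raw) & is.finite(mu) & mu > 0
  if (sum(ok) < 50) {
    return(rep(clamp_alpha(stats::weighted.mean(alpha_raw[ok], mu[ok])),
               length(alpha_raw)))
  }
  lo <- stats::lowess(log(mu[ok]), alpha_raw[ok], f = 2 / 3)
  fitted <- stats::approx(lo$x, lo$y, xout = log(pmax(mu, min(mu[ok]))),
                          rule = 2)$y
  clamp_alpha(fitted)
}

#' Negative-binomial Wald contrast statistics
#'
#' Fits, per feature, a negative-binomial log-linear model over the
#' condition means (plus an optional additive batch term), with
#' median-of-ratios size factors as offsets and a method-of-moments
#' dispersion (Var = mu + alpha mu^2). By default the per-feature raw
#' dispersion estimates are pooled through a mean-dispersion lowess trend
#' (`dispersion = "trended"`); `dispersion = "per-feature"` uses each
#' feature's own (clamped) estimate, which is substantially noisier at few
#' replicates and makes a feature's contrasts share estimation noise.
#' Each requested contrast is reported as a signed Wald statistic: the raw
#' log-fold-change/SE ratio is calibrated through a t reference with the
#' model's residual degrees of freedom and mapped back to the
#' standard-normal scale, so that `|stat| > 2` keeps its nominal normal
#' tail meaning at small replicate numbers and
#' `p = 2 * pnorm(-|stat|)` stays consistent with the statistic. The
#' statistic's sign always agrees with the fold-change sign. Absolute
#' values differ from shrinkage-based differential-expression tools; a
#' table produced by such a tool can be substituted anywhere a contrast
#' table is consumed, as long as it carries the same columns.
#'
#' @param counts Count matrix, features x samples.
#' @param design Tibble with `sample`, `condition` (mock/mockE2/MAF/MAFE2 or
#'   any factor covering the requested contrasts) and optionally `batch`.
#' @param contrasts Named list of (numerator, denominator) condition pairs;
#'   defaults to [default_contrasts()].
#' @param sf Optional precomputed size factors; computed when `NULL`.
#' @param dispersion `"trended"` (default) or `"per-feature"`.
#' @return A tibble of class `contrast_tbl` in long form: `feature_id`,
#'   `contrast`, `log2fc`, `stat`, `pvalue`, with size factors stored in
#'   `attr(, "size_factors")`.
#' @export
contrast_stats <- function(counts, design, contrasts = default_contrasts(),
                           sf = NULL,
                           dispersion = c("trended", "per-feature")) {
  dispersion <- match.arg(dispersion)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  }
  design <- validate_design(design, counts)
  conds <- levels(design$condition)
  for (ct in contrasts) {
    if (!all(ct %in% conds)) {
      abort(paste0("contrast level(s) absent from design: ",
                   paste(setdiff(ct, conds), collapse = ", ")))
    }
  }
  has_batch <- "batch" %in% names(design)
  X <- if (has_batch) {
    stats::model.matrix(~ 0 + condition + factor(batch), data = design)
  } else {
    stats::model.matrix(~ 0 + condition, data = design)
  }
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")
  cond_cols <- match(paste0("condition", conds), colnames(X))
  L <- vapply(contrasts, function(ct) {
    l <- numeric(ncol(X))
    l[cond_cols[match(ct[1], conds)]] <- 1
    l[cond_cols[match(ct[2], conds)]] <- -1
    l
  }, numeric(ncol(X)))

  if (is.null(sf)) sf <- size_factors(counts)
  inv_sf <- 1 / sf
  off <- log(sf)
  n_feat <- nrow(counts)
  n_ct <- length(contrasts)

  q <- sweep(counts, 2, sf, "/")
  alpha_raw <- vapply(seq_len(n_feat), function(i) {
    mom_dispersion_raw(q[i, ], design$condition, inv_sf)
  }, numeric(1))
  alpha <- if (dispersion == "trended") {
    trend_dispersion(alpha_raw, rowMeans(q))
  } else {
    clamp_alpha(ifelse(is.finite(alpha_raw), alpha_raw, 1e-8))
  }

  df_resid <- nrow(design) - qr(X)$rank
  est <- matrix(NA_real_, n_feat, n_ct)
  se <- matrix(NA_real_, n_feat, n_ct)
  for (i in seq_len(n_feat)) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, counts[i, ], offset = off,
        family = MASS::negative.binomial(theta = 1 / alpha[i], link = "log")
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || any(!is.finite(fit$coefficients))) next
    R <- qr.R(fit$qr)
    piv <- fit$qr$pivot
    V <- matrix(NA_real_, ncol(X), ncol(X))
    V[piv, piv] <- chol2inv(R)
    b <- fit$coefficients
    est[i, ] <- drop(b %*% L)
    se[i, ] <- sqrt(colSums(L * (V %*% L)))
  }
  tt <- est / se
  # t-reference calibration with residual df, back to the z scale
  zz <- if (df_resid > 0) {
    sign(tt) * qnorm(stats::pt(abs(tt), df_resid, lower.tail = FALSE),
                     lower.tail = FALSE)
  } else tt
  out <- tibble(
    feature_id = rep(rownames(counts), times = n_ct),
    contrast = rep(names(contrasts), each = n_feat),
    log2fc = as.vector(est) / log(2),
    stat = as.vector(zz),
    pvalue = 2 * pnorm(-abs(as.vector(zz)))
  )
  attr(out, "size_factors") <- sf
  class(out) <- c("contrast_tbl", class(out))
  out
}

# cluster conjunction rules over the five contrasts; returns a logical
# matrix features x rules (A..F)
cluster_rule_matrix <- function(wide, threshold) {
  up <- function(ct) !is.na(wide[[ct]]) & wide[[ct]] > threshold
  dn <- function(ct) !is.na(wide[[ct]]) & wide[[ct]] < -threshold
  cbind(
    A = up("MAF_vs_mock") & up("MAFE2_vs_mockE2"),
    B = dn("MAF_vs_mock") & dn("MAFE2_vs_mockE2"),
    C = up("MAFE2_vs_MAF") & up("mockE2_vs_mock"),
    D = dn("MAFE2_vs_MAF") & dn("mockE2_vs_mock"),
    E = up("MAFE2_vs_MAF") & up("MAFE2_vs_mockE2"),
    F = dn("MAFE2_vs_MAF") & dn("MAFE2_vs_mockE2")
  )
}

contrast_wide <- function(table) {
  needed <- c("MAF_vs_mock", "mockE2_vs_mock", "MAFE2_vs_MAF",
              "MAFE2_vs_mockE2")
  missing_ct <- setdiff(needed, unique(table$contrast))
  if (length(missing_ct) > 0) {
    abort(paste0("contrast table lacks contrast(s): ",
                 paste(missing_ct, collapse = ", ")))
  }
  table |>
    select("feature_id", "contrast", "stat") |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "stat")
}

assign_from_rules <- function(fired, labels) {
  # priority: interaction clusters (E/F), then factor (A/B), then hormone (C/D)
  priority <- c("E", "F", "A", "B", "C", "D")
  lab <- rep("none", nrow(fired))
  for (r in rev(priority)) lab[fired[, r]] <- r
  lab <- labels[match(lab, c(LETTERS[1:6], "none"))]
  lab
}

#' Assign accessibility-peak clusters A-F from contrast statistics
#'
#' Applies the three conjunction rules at `|stat| > threshold` (default 2):
#' clusters A/B require the statistic beyond the cutoff (positive for A,
#' negative for B) in both factor-vs-mock and combined-vs-hormone contrasts;
#' C/D in both combined-vs-factor and hormone-vs-mock; E/F in both
#' combined-vs-factor and combined-vs-hormone. When several rules fire, the
#' interaction clusters E/F take priority over A/B, then C/D; all fired
#' rules are also reported.
#'
#' @param table A `contrast_tbl` from [contrast_stats()] (or any long tibble
#'   with `feature_id`, `contrast`, `stat`).
#' @param threshold Positive statistic cutoff.
#' @return Tibble: `feature_id`, `cluster` (factor, levels A-F and `none`),
#'   `rules_fired` (comma-separated), `rule_variant`.
#' @export
assign_peak_clusters <- function(table, threshold = 2) {
  if (threshold <= 0) abort("`threshold` must be > 0")
  wide <- contrast_wide(table)
  fired <- cluster_rule_matrix(wide, threshold)
  labels <- c(LETTERS[1:6], "none")
  tibble(
    feature_id = wide$feature_id,
    cluster = factor(assign_from_rules(fired, labels), levels = labels),
    rules_fired = apply(fired, 1, function(z) paste(colnames(fired)[z], collapse = ",")),
    rule_variant = paste0("strict", format(threshold))
  )
}

#' Assign gene expression clusters 1-6
#'
#' Same rule machinery as [assign_peak_clusters()] with labels mapped
#' 1<->A ... 6<->F: (1) factor-up, (2) factor-down, (3) hormone-up,
#' (4) hormone-down, (5) up and (6) down only under the combined treatment.
#'
#' @inheritParams assign_peak_clusters
#' @return Tibble as in [assign_peak_clusters()] with labels `1`-`6`/`none`.
#' @export
assign_gene_clusters <- function(table, threshold = 2) {
  if (threshold <= 0) abort("`threshold` must be > 0")
  wide <- contrast_wide(table)
  fired <- cluster_rule_matrix(wide, threshold)
  labels <- c(as.character(1:6), "none")
  tibble(
    feature_id = wide$feature_id,
    cluster = factor(assign_from_rules(fired, labels), levels = labels),
    rules_fired = apply(fired, 1, function(z) paste(colnames(fired)[z], collapse = ",")),
    rule_variant = paste0("strict", format(threshold))
  )
}

#' Relaxed cluster assignment for promoter peaks
#'
#' The integration variant of the A-F rules: cutoff `|stat| > 1.5`,
#' restricted to peaks annotated `promoter-TSS`, and additionally requiring
#' breadth (`log10` width) above `breadth_min` for the opening clusters A
#' and E.
#'
#' @inheritParams assign_peak_clusters
#' @param peaks Annotated peak tibble (from [annotate_peaks()]) whose
#'   `peak_id` matches `feature_id` in `table`.
#' @param threshold Relaxed statistic cutoff (default 1.5).
#' @param breadth_min Breadth floor for clusters A and E (default 3).
#' @return Tibble as in [assign_peak_clusters()] (`rule_variant`
#'   `"relaxed1.5"` by default); peaks failing the promoter or breadth
#'   restriction get cluster `none`.
#' @export
assign_relaxed_clusters <- function(table, peaks, threshold = 1.5,
                                    breadth_min = 3) {
  if (threshold <= 0) abort("`threshold` must be > 0")
  peaks <- check_peaks(peaks)
  if (!"annotation" %in% names(peaks)) {
    abort("`peaks` must be annotated (see `annotate_peaks()`)")
  }
  wide <- contrast_wide(table)
  idx <- match(wide$feature_id, peaks$peak_id)
  if (anyNA(idx)) abort("contrast features missing from `peaks`")
  fired <- cluster_rule_matrix(wide, threshold)
  promoter <- peaks$annotation[idx] == "promoter-TSS"
  breadth <- peak_breadth(peaks$end[idx] - peaks$start[idx])
  fired[!promoter, ] <- FALSE
  fired[breadth <= breadth_min, c("A", "E")] <- FALSE
  labels <- c(LETTERS[1:6], "none")
  tibble(
    feature_id = wide$feature_id,
    cluster = factor(assign_from_rules(fired, labels), levels = labels),
    rules_fired = apply(fired, 1, function(z) paste(colnames(fired)[z], collapse = ",")),
    rule_variant = paste0("relaxed", format(threshold))
  )
}
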