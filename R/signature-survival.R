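#' Build a factor-tested gene signature from cluster genes and binding sites
#'
#' The signature is the set of cluster-1 (factor-upregulated) genes that are
#' the nearest-TSS annotation target of at least one binding site in BOTH
#' binding conditions (factor alone, and factor plus hormone). Optionally a
#' maximum |midpoint - TSS| distance restricts which sites count as
#' associated.
#'
#' @param cluster1_genes Character vector of cluster-1 gene ids (nonempty).
#' @param er_peaks_a,er_peaks_b Peak tibbles for the two binding conditions.
#' @param genome A [genome_model()].
#' @param max_distance Maximum |TSS distance| in bp for a site-gene
#'   association (default `Inf`: nearest gene at any distance).
#' @return Sorted character vector of signature gene ids.
#' @export
build_signature <- function(cluster1_genes, er_peaks_a, er_peaks_b, genome,
                            max_distance = Inf) {
  if (length(cluster1_genes) == 0) abort("`cluster1_genes` must be nonempty")
  stopifnot(inherits(genome, "genome_model"))
  bound_genes <- function(peaks) {
    ann <- distance_to_tss(check_peaks(peaks), genome)
    keep <- !is.na(ann$tss_distance) & abs(ann$tss_distance) <= max_distance
    unique(ann$nearest_gene[keep])
  }
  in_both <- intersect(bound_genes(er_peaks_a), bound_genes(er_peaks_b))
  sort(intersect(cluster1_genes, in_both))
}

#' Score cohort samples on a gene signature
#'
#' The per-sample signature score is the mean of genewise z-scored (log)
#' expression over the signature genes present in the matrix. Genes with
#' zero variance are excluded with a warning.
#'
#' @param expression Matrix genes x samples on a log scale.
#' @param signature Character vector of signature gene ids.
#' @return Named numeric vector of scores (one per sample).
#' @export
score_samples <- function(expression, signature) {
  expression <- as.matrix(expression)
  present <- intersect(signature, rownames(expression))
  if (length(present) == 0) {
    abort("no signature gene is present in the expression matrix")
  }
  sub <- expression[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0), " constant signature gene(s) excluded from scoring"))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(sub) == 0) abort("all signature genes are constant")
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Stratify samples at mean minus one standard deviation
#'
#' Samples whose score is strictly below `mean(scores) - sd(scores)` form
#' the `low` group; all others are `mid-high`. The split is invariant to
#' affine transformations of the scores. With zero score variance all
#' samples are `mid-high` (with a warning).
#'
#' @param scores Numeric vector of per-sample scores (length >= 3).
#' @return Factor with levels `low`, `mid-high`, named like `scores`.
#' @export
stratify_scores <- function(scores) {
  if (length(scores) < 3) abort("need >= 3 samples to stratify")
  s <- sd(scores)
  if (s == 0) {
    warn("zero score variance; no `low` group")
    grp <- rep("mid-high", length(scores))
  } else {
    grp <- ifelse(scores < mean(scores) - s, "low", "mid-high")
  }
  factor(setNames(grp, names(scores)), levels = c("low", "mid-high"))
}

#' Kaplan-Meier curves and log-rank comparison between score groups
#'
#' Product-limit survival estimates per group and the two-sided log-rank
#' chi-square test (1 df) comparing them, via the `survival` package.
#'
#' @param clinical Tibble with `sample`, `time` (> 0) and `event` (logical
#'   or 0/1).
#' @param groups Factor from [stratify_scores()] (or any two-level factor),
#'   aligned with `clinical$sample` by name or by position.
#' @return A `signature_survival` object: `km` (tibble `group`, `time`,
#'   `surv`, `n_risk`, `n_event`), `chisq`, `df`, `p_value`, `group_sizes`,
#'   and `note` (non-`NA` when a group has zero events).
#' @export
km_logrank <- function(clinical, groups) {
  clinical <- as_tibble(clinical)
  if (!all(c("sample", "time", "event") %in% names(clinical))) {
    abort("`clinical` needs `sample`, `time`, `event` columns")
  }
  if (any(clinical$time <= 0)) abort("follow-up times must be > 0")
  if (!is.null(names(groups))) {
    groups <- groups[match(clinical$sample, names(groups))]
  }
  if (length(groups) != nrow(clinical) || anyNA(groups)) {
    abort("`groups` must cover every clinical sample")
  }
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) abort("need two nonempty groups")
  event <- as.integer(clinical$event)
  surv <- survival::Surv(clinical$time, event)
  fit <- survival::survfit(surv ~ groups)
  sdf <- survival::survdiff(surv ~ groups)
  df <- length(sdf$n) - 1
  p <- pchisq(sdf$chisq, df = df, lower.tail = FALSE)
  strata_group <- sub("^groups=", "", rep(names(fit$strata), fit$strata))
  km <- tibble(group = strata_group, time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, n_event = fit$n.event)
  events_per_group <- tapply(event, groups, sum)
  note <- if (any(events_per_group == 0)) {
    "a group has zero events; the log-rank statistic is still defined"
  } else NA_character_
  structure(
    list(km = km, chisq = unname(sdf$chisq), df = df, p_value = p,
         group_sizes = table(groups), note = note),
    class = "signature_survival"
  )
}

#' @export
print.signature_survival <- function(x, ...) {
  cat("<signature_survival> log-rank chi-square ",
      format(x$chisq, digits = 4), " (", x$df, " df), p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.signature_survival <- function(x, ...) x$km

#' @rdname tidiers
#' @export
glance.signature_survival <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p_value = x$p_value,
         n = sum(x$group_sizes), n_low = unname(x$group_sizes["low"]))
}

#' Autoplot Kaplan-Meier curves
#'
#' @param object A `signature_survival` from [km_logrank()].
#' @param ... Unused.
#' @export
autoplot.signature_survival <- function(object, ...) {
  km <- object$km |>
    group_by(.data$group) |>
    group_modify(~ bind_rows(tibble(time = 0, surv = 1, n_risk = max(.x$n_risk),
                                    n_event = 0L), .x)) |>
    ungroup()
  ggplot(km, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step(linewidth = 0.9) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "event-free probability",
         title = sprintf("log-rank p = %.3g", object$p_value)) +
    theme_minimal()
}

#' Spearman correlation between two genes
#'
#' Rank correlation between two rows of an expression matrix, with the
#' two-sided p-value from `stats::cor.test`.
#'
#' @param expression Matrix genes x samples.
#' @param gene_a,gene_b Gene ids (rows of `expression`).
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
gene_correlation <- function(expression, gene_a, gene_b) {
  expression <- as.matrix(expression)
  if (!all(c(gene_a, gene_b) %in% rownames(expression))) {
    abort("both genes must be rows of `expression`")
  }
  x <- expression[gene_a, ]
  y <- expression[gene_b, ]
  ok <- complete.cases(x, y)
  if (sum(ok) < 10) abort("need >= 10 paired observations")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("constant expression vector; correlation undefined")
  }
  ht <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value, n = sum(ok))
}

#' Residualise expression genewise against clinical covariates
#'
#' Per gene, fits ordinary least squares of (log) expression on the
#' covariate design and replaces values by residuals recentred at the gene
#' mean. Samples with missing covariates are dropped (listwise).
#'
#' @param expression Matrix genes x samples on a log scale.
#' @param covariates Tibble with `sample` plus covariate columns.
#' @return The adjusted matrix (possibly fewer columns after listwise
#'   deletion).
#' @export
adjust_expression <- function(expression, covariates) {
  expression <- as.matrix(expression)
  covariates <- as_tibble(covariates)
  if (!"sample" %in% names(covariates)) abort("`covariates` needs `sample`")
  covariates <- covariates[match(colnames(expression), covariates$sample), ]
  keep <- complete.cases(covariates)
  covariates <- covariates[keep, ]
  expression <- expression[, keep, drop = FALSE]
  X <- stats::model.matrix(~ ., data = covariates[, setdiff(names(covariates), "sample"),
                                                  drop = FALSE])
  if (qr(X)$rank < ncol(X)) abort("covariate design is rank deficient")
  fit <- lm.fit(X, t(expression))
  res <- t(fit$residuals) + rowMeans(expression)
  dimnames(res) <- dimnames(expression)
  res
}
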