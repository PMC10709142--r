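#' Read and write BED peak files
#'
#' BED3/BED6, tab-separated, 0-based half-open, no header; CRLF line ends
#' are accepted. Malformed coordinate lines raise an error naming the line.
#'
#' @param path File path.
#' @return `read_bed()`: a peak tibble (`chrom`, `start`, `end`, and for
#'   BED6 `peak_id`, `score`, `strand`).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", which(nf < 3)[1], " has fewer than 3 fields"))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("BED line ", bad[1], ": invalid coordinates"))
  }
  out <- tibble(chrom = vapply(fields, `[[`, "", 1), start = start, end = end)
  if (all(nf >= 6)) {
    out$peak_id <- vapply(fields, `[[`, "", 4)
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
    out$strand <- vapply(fields, `[[`, "", 6)
  }
  out
}

#' @rdname read_bed
#' @param peaks Peak tibble; with `peak_id` a BED6 is written (score 0,
#'   strand `.` unless present).
#' @export
write_bed <- function(peaks, path) {
  peaks <- check_peaks(peaks)
  df <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   peaks$peak_id,
                   if ("score" %in% names(peaks)) peaks$score else 0,
                   if ("strand" %in% names(peaks)) peaks$strand else ".")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read and write gene model tables
#'
#' Plain TSV with header `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open).
#'
#' @param path File path.
#' @return `read_gene_models()`: a gene tibble usable with
#'   [genome_model()].
#' @export
read_gene_models <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = "c", chrom = "c", start = "d", end = "d",
                    strand = "c"))
}

#' @rdname read_gene_models
#' @param genes Gene tibble (e.g. `genome$genes`).
#' @export
write_gene_models <- function(genes, path) {
  readr::write_tsv(genes[, c("gene_id", "chrom", "start", "end", "strand")],
                   path)
  invisible(path)
}

#' Read gene models from a minimal GTF
#'
#' Parses `gene` feature lines only, taking `gene_id` from the attribute
#' column and converting GTF's 1-based closed coordinates to the package's
#' 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return Gene tibble usable with [genome_model()].
#' @export
read_gtf_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", TRUE)
  fields <- fields[keep]
  if (length(fields) == 0) abort("no `gene` feature lines found")
  attr_field <- vapply(fields, `[[`, "", 9)
  gene_id <- stringr::str_match(attr_field, 'gene_id[ =]+"?([^";]+)"?')[, 2]
  if (anyNA(gene_id)) abort("gene line(s) without a gene_id attribute")
  tibble(
    gene_id = gene_id,
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 4)) - 1,
    end = as.numeric(vapply(fields, `[[`, "", 5)),
    strand = vapply(fields, `[[`, "", 7)
  )
}

#' Read and write count matrices
#'
#' TSV with a leading feature-id column and one column per sample.
#'
#' @param path File path.
#' @return `read_count_matrix()`: numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_count_matrix
#' @param counts Matrix features x samples.
#' @export
write_count_matrix <- function(counts, path) {
  df <- as_tibble(as.data.frame(counts), rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a SAINT-style interactor table
#'
#' Tab-separated with header columns `Bait`, `Prey`, `Spec`
#' (pipe-separated per-replicate spectral counts), `AvgSpec`, `FoldChange`,
#' `BFDR` (a `ctrlCounts` column, when present, is ignored for analysis).
#' Returns the long per-replicate form consumed by the interactome
#' functions.
#'
#' @param path File path.
#' @return Tibble: `bait`, `prey`, `replicate`, `spectral_count`, `bfdr`,
#'   `fold_change`.
#' @export
read_saint_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("Bait", "Prey", "Spec", "FoldChange", "BFDR")
  if (!all(req %in% names(df))) {
    abort(paste0("SAINT table lacks column(s): ",
                 paste(setdiff(req, names(df)), collapse = ", ")))
  }
  counts <- strsplit(as.character(df$Spec), "|", fixed = TRUE)
  tibble(
    bait = rep(df$Bait, lengths(counts)),
    prey = rep(df$Prey, lengths(counts)),
    replicate = unlist(lapply(lengths(counts), seq_len)),
    spectral_count = as.numeric(unlist(counts)),
    bfdr = rep(df$BFDR, lengths(counts)),
    fold_change = rep(df$FoldChange, lengths(counts))
  )
}

#' @rdname read_saint_table
#' @param table Long bait-prey tibble (engines already merged).
#' @export
write_saint_table <- function(table, path) {
  wide <- table |>
    filter(.data$bait != "control") |>
    arrange(.data$bait, .data$prey, .data$replicate) |>
    summarise(Spec = paste(.data$spectral_count, collapse = "|"),
              AvgSpec = mean(.data$spectral_count),
              FoldChange = dplyr::first(.data$fold_change),
              BFDR = dplyr::first(.data$bfdr),
              .by = c("bait", "prey")) |>
    rename(Bait = "bait", Prey = "prey")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read and write survival cohort tables
#'
#' TSV with `sample`, `time`, `event` plus any covariate columns.
#'
#' @param path File path.
#' @return `read_survival_table()`: a clinical tibble with logical `event`.
#' @export
read_survival_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df))) {
    abort("survival table needs `sample`, `time`, `event`")
  }
  df$event <- as.logical(df$event)
  df
}

#' @rdname read_survival_table
#' @param clinical Clinical tibble.
#' @export
write_survival_table <- function(clinical, path) {
  clinical$event <- as.integer(clinical$event)
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Write a full synthetic scenario to disk
#'
#' Generates every pipeline input from the scenario and writes it in the
#' same plain-text formats the readers consume (BED peaks, TSV gene models
#' and matrices, SAINT-style TSV, survival TSV), each alongside a
#' ground-truth JSON sidecar (`*.truth.json`) recording the planted
#' structure.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  truth_json <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  genome <- simulate_genome(scenario)
  write_gene_models(genome$genes, p("genes.tsv"))
  counts <- simulate_counts(scenario, genome)
  write_count_matrix(counts$counts, p("gene_counts.tsv"))
  readr::write_tsv(counts$design, p("design.tsv"))
  truth_json(counts$truth, p("gene_counts.truth.json"))
  pk <- simulate_peaks(scenario, genome)
  write_bed(pk$peaks, p("peaks.bed"))
  write_count_matrix(pk$counts, p("peak_counts.tsv"))
  truth_json(pk$truth, p("peaks.truth.json"))
  chip <- simulate_chip(scenario, genome, pk$peaks, counts$truth)
  write_bed(check_peaks(chip$marks$H3K27ac), p("h3k27ac.bed"))
  write_bed(check_peaks(chip$marks$H3K4me3), p("h3k4me3.bed"))
  write_bed(check_peaks(chip$er_MAF), p("er_maf.bed"))
  write_bed(check_peaks(chip$er_MAFE2), p("er_mafe2.bed"))
  truth_json(chip$truth, p("chip.truth.json"))
  links <- simulate_link_data(scenario, genome)
  write_bed(links$peaks, p("link_peaks.bed"))
  write_count_matrix(round(links$peak_signal, 6), p("link_peak_signal.tsv"))
  write_count_matrix(round(links$expression, 6), p("link_expression.tsv"))
  truth_json(links$truth, p("links.truth.json"))
  saint <- simulate_saint(scenario)
  write_saint_table(merge_engine_counts(saint$table), p("saint.tsv"))
  truth_json(saint$truth, p("saint.truth.json"))
  cohort <- simulate_cohort(scenario)
  write_count_matrix(round(cohort$expression, 6), p("cohort_expression.tsv"))
  write_survival_table(cohort$clinical, p("cohort_clinical.tsv"))
  truth_json(list(signature_genes = cohort$truth$signature_genes,
                  hazard_ratio = cohort$truth$hazard_ratio),
             p("cohort.truth.json"))
  invisible(list(dir = dir))
}
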