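#' Rank genes by cross-mutant convergence
#'
#' Counts, for every gene, how many distinct resistant lines carry at least
#' one candidate mutation in it -- the recurrence signal that nominates a
#' causal gene when several independently derived mutants hit it. Two
#' different variants in the same gene in one line count once: recurrence
#' is a line-level statement.
#'
#' @param candidates Annotated candidate tibble with `line_id` and
#'   `gene_id` columns (e.g. from [retain_amino_acid_changing()]).
#' @param genes Optional gene-model tibble; when given, each report row
#'   carries the gene's CDS length for manual context.
#' @return A tibble of class `convergence_report`, sorted by `n_lines`
#'   descending with ties broken by total candidate count then gene id:
#'   `gene_id`, `n_lines`, `line_ids` (comma-separated), `n_variants`,
#'   `shared_identical` (TRUE if an identical variant recurs across lines).
#' @export
build_convergence_report <- function(candidates, genes = NULL) {
  if (nrow(candidates) > 0L &&
      (!"gene_id" %in% names(candidates) || anyNA(candidates$gene_id))) {
    abort("Candidates must carry non-missing `gene_id` annotations.")
  }
  shared <- flag_shared_identical_variants(candidates)
  report <- candidates %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_lines = dplyr::n_distinct(.data$line_id),
      line_ids = paste(sort(unique(.data$line_id)), collapse = ","),
      n_variants = n(),
      .groups = "drop"
    ) %>%
    mutate(shared_identical = .data$gene_id %in% shared$gene_id) %>%
    arrange(desc(.data$n_lines), desc(.data$n_variants), .data$gene_id)
  if (!is.null(genes) && nrow(report) > 0L) {
    lens <- genes %>%
      group_by(.data$gene_id) %>%
      summarise(cds_length = sum(.data$end - .data$start + 1L),
                .groups = "drop")
    report <- report %>% left_join(lens, by = "gene_id")
  }
  class(report) <- c("convergence_report", class(report))
  report
}

#' Flag identical variants shared across lines
#'
#' Emits one warning row per (chrom, pos, alt) present identically in two
#' or more lines -- possible clonal or artifactual sharing that would
#' violate the independence assumption behind convergence. Candidates are
#' flagged, never removed.
#'
#' @param candidates Candidate tibble with `line_id`, `chrom`, `pos`, `alt`
#'   (and `gene_id` if available).
#' @return A tibble of flagged variants (`chrom`, `pos`, `alt`, `gene_id`
#'   if present, `n_lines`, `line_ids`); zero rows when all candidates are
#'   unique. A warning summarises any flags.
#' @export
flag_shared_identical_variants <- function(candidates) {
  grouping <- intersect(c("chrom", "pos", "alt", "gene_id"),
                        names(candidates))
  flags <- candidates %>%
    group_by(across(dplyr::all_of(grouping))) %>%
    summarise(
      n_lines = dplyr::n_distinct(.data$line_id),
      line_ids = paste(sort(unique(.data$line_id)), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_lines >= 2L)
  if (nrow(flags) > 0L) {
    warn(sprintf(
      "%d identical variant(s) shared across lines (e.g. %s:%d %s in %s).",
      nrow(flags), flags$chrom[1], flags$pos[1], flags$alt[1],
      flags$line_ids[1]
    ))
  }
  flags
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %d gene(s)\n", nrow(x)))
  NextMethod()
}

#' Plot a convergence report
#'
#' Bar chart of the top genes by number of independent lines hit.
#'
#' @param object A `convergence_report`.
#' @param top_n Number of genes to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.convergence_report <- function(object, top_n = 15L, ...) {
  df <- head(as_tibble(object), top_n) %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_lines, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Independent resistant lines with a candidate",
                  y = NULL, title = "Cross-mutant convergence") +
    ggplot2::theme_minimal()
}
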