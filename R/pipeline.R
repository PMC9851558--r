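#' Read and write growth-measurement tables
#'
#' CSV with header `line_id, compound, dose, dose_units, replicate, area`.
#'
#' @param path CSV path.
#' @return [read_growth_csv()] returns the growth tibble.
#' @export
read_growth_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    line_id = readr::col_character(),
    compound = readr::col_character(),
    dose = readr::col_double(),
    dose_units = readr::col_character(),
    replicate = readr::col_integer(),
    area = readr::col_double()
  ))
}

#' @rdname read_growth_csv
#' @param measurements Growth tibble.
#' @export
write_growth_csv <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read and write precursor-scan peak tables
#'
#' Long CSV with header `peak_id, sample_id, rt, precursor_mz, ion_count,
#' fragment_mz, fragment_intensity` (one row per fragment ion); the reader
#' nests fragments back into the list-column layout of
#' [sim_precursor_scan()].
#'
#' @param path CSV path.
#' @return [read_peaks_csv()] returns the nested peak tibble.
#' @export
read_peaks_csv <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    peak_id = readr::col_character(),
    sample_id = readr::col_character(),
    rt = readr::col_double(),
    precursor_mz = readr::col_double(),
    ion_count = readr::col_double(),
    fragment_mz = readr::col_double(),
    fragment_intensity = readr::col_double()
  ))
  long %>%
    group_by(.data$peak_id, .data$sample_id, .data$rt, .data$precursor_mz,
             .data$ion_count) %>%
    summarise(fragments = {
      mzv <- .data$fragment_mz
      intv <- .data$fragment_intensity
      list(tibble(mz = mzv, intensity = intv))
    }, .groups = "drop")
}

#' @rdname read_peaks_csv
#' @param peaks Nested peak tibble.
#' @export
write_peaks_csv <- function(peaks, path) {
  long <- peaks %>%
    tidyr::unnest("fragments") %>%
    rename(fragment_mz = "mz", fragment_intensity = "intensity") %>%
    select("peak_id", "sample_id", "rt", "precursor_mz", "ion_count",
           "fragment_mz", "fragment_intensity")
  readr::write_csv(long, path)
  invisible(path)
}

#' Configuration for an end-to-end screen analysis
#'
#' Validates paths and options for [run_full_screen()]. All stages read
#' standard formats: FASTA genome, GFF3 gene models, one VCF per line,
#' optional growth and peak CSVs.
#'
#' @param genome_fasta,genes_gff3 Reference paths.
#' @param vcf_paths Named character vector, `line_id = path`.
#' @param phenotypes Named character vector, `line_id = phenotype`, with
#'   phenotypes in `resistant`, `sensitive`, `wild_type`.
#' @param growth_csv,peaks_csv Optional stage inputs.
#' @param filter A [filter_config()].
#' @param alpha Significance level for resistance classification.
#' @param direction `"resistance"` or `"sensitivity"` (reference-line rule
#'   for RIs).
#' @param zero_epsilon Dead-replicate threshold for LD100.
#' @param min_lines Convergence threshold reported in the summary.
#' @param out_dir Optional report directory.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(genome_fasta, genes_gff3, vcf_paths, phenotypes,
                          growth_csv = NULL, peaks_csv = NULL,
                          filter = filter_config(), alpha = 0.05,
                          direction = "resistance", zero_epsilon = 0,
                          min_lines = 3L, out_dir = NULL) {
  paths <- c(genome_fasta, genes_gff3, vcf_paths, growth_csv, peaks_csv)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0("Input path(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(names(vcf_paths)) || is.null(names(phenotypes))) {
    abort("`vcf_paths` and `phenotypes` must be named by line_id.")
  }
  bad <- setdiff(phenotypes, c("resistant", "sensitive", "wild_type"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown phenotype label(s): ", paste(bad, collapse = ", ")))
  }
  if (!setequal(names(vcf_paths), names(phenotypes))) {
    abort("`vcf_paths` and `phenotypes` must cover the same line ids.")
  }
  if (!any(phenotypes == "resistant")) {
    abort("No resistant lines configured; nothing to screen.")
  }
  structure(
    list(genome_fasta = genome_fasta, genes_gff3 = genes_gff3,
         vcf_paths = vcf_paths, phenotypes = phenotypes,
         growth_csv = growth_csv, peaks_csv = peaks_csv,
         filter = filter, alpha = alpha, direction = direction,
         zero_epsilon = zero_epsilon, min_lines = as.integer(min_lines),
         out_dir = out_dir),
    class = "screen_config"
  )
}

#' Run the screen analysis end to end
#'
#' Executes filter cascade, coding-effect annotation and triage, and
#' convergence ranking; fits dose-response curves when a growth table is
#' configured. Deterministic given the configuration and inputs. When
#' `out_dir` is set, [write_screen_report()] is called on the result.
#'
#' @param config A [screen_config()].
#' @return A list of class `screen_result`: `cascade` (candidate_sets),
#'   `annotated`, `candidates` (amino-acid-changing), `convergence`,
#'   `dose_fits` (or NULL), `top_gene`, `config`.
#' @export
run_full_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  genome <- read_reference_fasta(config$genome_fasta)
  genes <- read_genes_gff3(config$genes_gff3)
  variants <- purrr::map_dfr(names(config$vcf_paths), function(lid) {
    read_variants_vcf(config$vcf_paths[[lid]], line_id = lid)
  })
  lines <- tibble(
    line_id = names(config$phenotypes),
    phenotype = ifelse(unname(config$phenotypes) == "resistant",
                       "resistant", "sensitive")
  )
  cascade <- run_candidate_cascade(variants, lines, config$filter)
  annotated <- annotate_candidates(cascade$candidates, genes, genome)
  candidates <- retain_amino_acid_changing(annotated)
  convergence <- build_convergence_report(candidates, genes)
  dose_fits <- if (!is.null(config$growth_csv)) {
    fit_dose_response_curves(read_growth_csv(config$growth_csv))
  }
  result <- structure(
    list(cascade = cascade, annotated = annotated, candidates = candidates,
         convergence = convergence, dose_fits = dose_fits,
         top_gene = if (nrow(convergence) > 0L) convergence$gene_id[1]
                    else NA_character_,
         config = config),
    class = "screen_result"
  )
  if (!is.null(config$out_dir)) write_screen_report(result, config$out_dir)
  result
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  %d candidate(s) after full triage across %d line(s)\n",
              nrow(x$candidates), dplyr::n_distinct(x$candidates$line_id)))
  if (!is.na(x$top_gene)) {
    cat(sprintf("  top convergent gene: %s (%d line(s))\n",
                x$top_gene, x$convergence$n_lines[1]))
  }
  invisible(x)
}

#' Write the report bundle for a screen result
#'
#' Emits `candidates.tsv`, `convergence.tsv`, `audit.json`, a
#' machine-readable `report.json` (schema version 1, with every threshold
#' actually applied echoed back), and a human-readable `summary.txt`.
#'
#' @param result A `screen_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_report <- function(result, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", out_dir))
  }
  write_candidates_tsv(result$candidates, file.path(out_dir, "candidates.tsv"))
  readr::write_tsv(as_tibble(result$convergence),
                   file.path(out_dir, "convergence.tsv"))
  jsonlite::write_json(result$cascade$audit,
                       file.path(out_dir, "audit.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  report <- list(
    schema_version = 1L,
    thresholds = list(
      min_support = cfg$filter$min_support,
      max_support = cfg$filter$max_support,
      alt_fraction_threshold = cfg$filter$alt_fraction_threshold,
      canonical_changes = cfg$filter$canonical_changes,
      support_basis = cfg$filter$support_basis,
      alpha = cfg$alpha, direction = cfg$direction,
      zero_epsilon = cfg$zero_epsilon, min_lines = cfg$min_lines
    ),
    n_candidates = nrow(result$candidates),
    candidates_per_line = result$candidates %>% count(.data$line_id),
    top_gene = result$top_gene,
    convergence = as_tibble(result$convergence),
    min_lines_reached = nrow(result$convergence) > 0L &&
      result$convergence$n_lines[1] >= cfg$min_lines
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  summary_lines <- c(
    "herbiscreen screen summary",
    sprintf("lines: %d (%d resistant)", length(cfg$phenotypes),
            sum(cfg$phenotypes == "resistant")),
    sprintf("candidates after triage: %d", nrow(result$candidates)),
    sprintf("top convergent gene: %s (%s lines; threshold %d %s)",
            result$top_gene,
            if (nrow(result$convergence) > 0L) result$convergence$n_lines[1]
            else "0",
            cfg$min_lines,
            if (isTRUE(report$min_lines_reached)) "reached" else "not reached"),
    sprintf("filters: support %d-%d (%s), alt fraction > %g, spectrum %s",
            cfg$filter$min_support, cfg$filter$max_support,
            cfg$filter$support_basis, cfg$filter$alt_fraction_threshold,
            paste(cfg$filter$canonical_changes, collapse = ","))
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
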