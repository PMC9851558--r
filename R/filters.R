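#' Filter-cascade configuration
#'
#' Thresholds for the candidate-mutation filter cascade. Defaults follow
#' the screen's published rules: mismatches supported by 7-100 reads, an
#' alternative-allele fraction strictly above 0.5, and the canonical UV-B
#' spectrum C>T / G>A on the reference strand.
#'
#' `support_basis` selects what "supported by" counts: reads supporting the
#' alternative allele (`"alt_reads"`, the default -- "supported" modifies
#' the mismatch) or total site depth (`"total_reads"`).
#'
#' @param min_support,max_support Inclusive read-support window.
#' @param alt_fraction_threshold Strict lower bound on
#'   (alt-fwd + alt-rev) / sum(DP4); exact ties are removed.
#' @param canonical_changes Character vector of `"REF>ALT"` single-base
#'   changes retained by the spectrum filter.
#' @param support_basis `"alt_reads"` or `"total_reads"`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_support = 7L,
                          max_support = 100L,
                          alt_fraction_threshold = 0.5,
                          canonical_changes = c("C>T", "G>A"),
                          support_basis = c("alt_reads", "total_reads")) {
  support_basis <- match.arg(support_basis)
  if (min_support > max_support) {
    abort("`min_support` must not exceed `max_support`.")
  }
  if (alt_fraction_threshold <= 0 || alt_fraction_threshold >= 1) {
    abort("`alt_fraction_threshold` must lie strictly in (0, 1).")
  }
  structure(
    list(min_support = as.integer(min_support),
         max_support = as.integer(max_support),
         alt_fraction_threshold = alt_fraction_threshold,
         canonical_changes = canonical_changes,
         support_basis = support_basis),
    class = "filter_config"
  )
}

dp4_cols <- c("dp4_rf", "dp4_rr", "dp4_af", "dp4_ar")

variant_support <- function(records, cfg) {
  if (cfg$support_basis == "alt_reads") {
    records$dp4_af + records$dp4_ar
  } else {
    records$dp4_rf + records$dp4_rr + records$dp4_af + records$dp4_ar
  }
}

has_depth <- function(records) {
  total <- records$dp4_rf + records$dp4_rr + records$dp4_af + records$dp4_ar
  !is.na(total) & total > 0L
}

#' Read-support filter
#'
#' Retains records whose support (per `support_basis`) lies in the
#' inclusive window `[min_support, max_support]`. Records with missing or
#' zero depth are removed with audit reason `"no_depth"`.
#'
#' @param records Variant tibble with `DP4` columns.
#' @param cfg A [filter_config()].
#' @return The retained records.
#' @export
filter_by_support <- function(records, cfg = filter_config()) {
  ok <- has_depth(records)
  s <- variant_support(records, cfg)
  records[ok & s >= cfg$min_support & s <= cfg$max_support, , drop = FALSE]
}

#' Alternative-allele-fraction filter
#'
#' Retains records with (alt-fwd + alt-rev) / sum(DP4) strictly greater
#' than `alt_fraction_threshold`; exact ties are removed. Records without
#' depth are removed with reason `"no_depth"`.
#'
#' @inheritParams filter_by_support
#' @return The retained records.
#' @export
filter_by_allele_fraction <- function(records, cfg = filter_config()) {
  ok <- has_depth(records)
  total <- records$dp4_rf + records$dp4_rr + records$dp4_af + records$dp4_ar
  frac <- (records$dp4_af + records$dp4_ar) / total
  records[ok & frac > cfg$alt_fraction_threshold, , drop = FALSE]
}

is_snv <- function(records) {
  records$ref %in% c("A", "C", "G", "T") & records$alt %in% c("A", "C", "G", "T")
}

#' UV-B mutation-spectrum filter
#'
#' Retains single-nucleotide records whose reference-strand change is in
#' the canonical UV-B set (default C>T and G>A, the reverse-complement
#' images of one pyrimidine-dimer lesion class). Non-SNV records are
#' removed.
#'
#' @inheritParams filter_by_support
#' @return The retained records.
#' @export
filter_by_uv_spectrum <- function(records, cfg = filter_config()) {
  change <- paste0(records$ref, ">", records$alt)
  records[is_snv(records) & change %in% cfg$canonical_changes, , drop = FALSE]
}

#' Subtract variants seen in non-allelic comparator lines
#'
#' Removes any record whose (chrom, pos, alt) is present in at least one
#' comparator line's raw call set -- the non-allelism assumption that
#' causal mutations are private to the phenotype-positive line.
#'
#' @param records Variant tibble for one focal line.
#' @param comparators Variant tibble pooling the comparator lines' raw
#'   (pre-filter) calls.
#' @return The retained records. An empty comparator set passes everything
#'   through with a warning.
#' @export
subtract_nonallelic_lines <- function(records, comparators) {
  if (is.null(comparators) || nrow(comparators) == 0L) {
    warn("No comparator lines supplied; non-allelism subtraction is a no-op.")
    return(records)
  }
  anti_join(records, comparators %>% distinct(.data$chrom, .data$pos, .data$alt),
            by = c("chrom", "pos", "alt"))
}

filter_reasons <- function(records, comparators, cfg) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  depth_ok <- has_depth(records)
  reason[!depth_ok] <- "no_depth"
  s <- variant_support(records, cfg)
  fail_support <- depth_ok & !(s >= cfg$min_support & s <= cfg$max_support)
  reason[is.na(reason) & fail_support] <- "support_window"
  total <- records$dp4_rf + records$dp4_rr + records$dp4_af + records$dp4_ar
  frac <- (records$dp4_af + records$dp4_ar) / total
  fail_frac <- depth_ok & !(frac > cfg$alt_fraction_threshold)
  reason[is.na(reason) & fail_frac] <- "alt_fraction"
  change <- paste0(records$ref, ">", records$alt)
  fail_spec <- !(is_snv(records) & change %in% cfg$canonical_changes)
  reason[is.na(reason) & fail_spec] <- "uv_spectrum"
  if (!is.null(comparators) && nrow(comparators) > 0L) {
    key <- paste(records$chrom, records$pos, records$alt)
    comp_key <- unique(paste(comparators$chrom, comparators$pos,
                             comparators$alt))
    reason[is.na(reason) & key %in% comp_key] <- "nonallelic_subtraction"
  }
  reason
}

#' Run the candidate-mutation filter cascade over a cohort
#'
#' Applies the four per-record filters in the published order -- read
#' support, alternative-allele fraction, UV-B spectrum, subtraction against
#' non-allelic comparator lines -- to every resistant line's variant set.
#' Because every filter is a pure per-record predicate (given fixed
#' comparator call sets), the surviving set is order-invariant; the order
#' only affects which filter an audit entry blames.
#'
#' Comparator sets are the *raw* (pre-filter) calls of all lines without
#' the resistant phenotype, the more conservative removal rule.
#'
#' @param variants Variant tibble for all lines (column `line_id`).
#' @param lines Tibble (`line_id`, `phenotype`); phenotype `resistant`
#'   marks focal lines, all other lines are comparators.
#' @param cfg A [filter_config()].
#' @return A list of class `candidate_sets`:
#'   * `candidates`: surviving records with `support` and `alt_fraction`,
#'   * `audit`: every input record with `removed_by` (`NA` if it survived),
#'   * `cfg`: the configuration applied.
#' @export
run_candidate_cascade <- function(variants, lines, cfg = filter_config()) {
  res_ids <- lines$line_id[lines$phenotype == "resistant"]
  comparators <- variants %>% filter(!.data$line_id %in% res_ids)
  focal <- variants %>% filter(.data$line_id %in% res_ids)
  empty_lines <- setdiff(res_ids, unique(focal$line_id))
  if (length(empty_lines) > 0L) {
    warn(sprintf("Resistant line(s) with zero input records: %s",
                 paste(empty_lines, collapse = ", ")))
  }
  reason <- if (nrow(focal) > 0L) {
    filter_reasons(focal, comparators, cfg)
  } else {
    character()
  }
  audit <- focal %>% mutate(removed_by = reason)
  survivors <- audit %>%
    filter(is.na(.data$removed_by)) %>%
    select(-"removed_by") %>%
    mutate(
      support = variant_support(., cfg),
      alt_fraction = (.data$dp4_af + .data$dp4_ar) /
        (.data$dp4_rf + .data$dp4_rr + .data$dp4_af + .data$dp4_ar)
    )
  structure(
    list(candidates = survivors, audit = audit, cfg = cfg),
    class = "candidate_sets"
  )
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("<candidate_sets>\n")
  tab <- x$candidates %>% count(.data$line_id)
  cat(sprintf("  %d surviving records across %d lines (of %d input records)\n",
              nrow(x$candidates), nrow(tab), nrow(x$audit)))
  if (nrow(x$audit) > 0L) {
    removed <- x$audit %>%
      filter(!is.na(.data$removed_by)) %>%
      count(.data$removed_by)
    for (i in seq_len(nrow(removed))) {
      cat(sprintf("  removed by %s: %d\n",
                  removed$removed_by[i], removed$n[i]))
    }
  }
  invisible(x)
}

#' Write a candidate table as TSV
#'
#' @param candidates The `candidates` tibble of a `candidate_sets` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  readr::write_tsv(
    candidates %>% select(dplyr::any_of(c(
      "line_id", "chrom", "pos", "ref", "alt", "support", "alt_fraction",
      "gene_id", "aa_change", "effect_class"
    ))),
    path
  )
  invisible(path)
}
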