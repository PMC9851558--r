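#' Configuration for a synthetic UV-mutagenesis screen cohort
#'
#' Bundles every knob of the synthetic-data generator: the reference genome
#' and gene-model geometry, the cohort composition (resistant / sensitive
#' lines, causal-gene spike-in), the UV-B mutation spectrum, and the
#' read-support model used to simulate strand-split `DP4` counts.
#'
#' The defaults emulate a screen of 13 independent resistant haploid lines
#' compared against 4 sensitive lines, with one causal gene carrying a
#' non-synonymous canonical (C>T / G>A) mutation in 3 of the resistant
#' lines, on a scaled-down single-chromosome genome. The scale is chosen so
#' that, after the full filter cascade plus coding-effect triage, each line
#' retains roughly 6-27 candidate mutations while gene-level collisions
#' between lines remain rare enough for the causal gene to top the
#' convergence ranking.
#'
#' @param genome_length Genome length in bases (single chromosome `chr1`).
#' @param n_genes Number of non-overlapping protein-coding genes.
#' @param cds_length_range Length-2 integer vector, min/max CDS length in
#'   bases; both must be multiples of 3.
#' @param n_resistant_lines,n_sensitive_lines Cohort composition.
#' @param mutations_per_line_mean Poisson mean of private SNVs per line.
#' @param canonical_fraction Probability that a simulated SNV is C>T or
#'   G>A on the reference strand (the UV-B pyrimidine-dimer signature).
#' @param causal_gene_id Gene receiving the spiked causal mutations.
#' @param n_causal_lines Number of resistant lines given one non-synonymous
#'   causal-gene variant each; must not exceed `n_resistant_lines`.
#' @param shared_background_count Variants present in every line (clonal
#'   background shared with the sensitive comparators).
#' @param depth_range Length-2 integer vector, min/max total read depth for
#'   simulated `DP4` counts.
#' @param alt_fraction_shape1,alt_fraction_shape2 Beta parameters for the
#'   simulated alternative-allele fraction (haploid calls sit near 1).
#' @param seed Master integer seed; each artifact (reference, cohort, dose
#'   tables, peak tables) draws from its own labelled stream derived from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(genome_length = 3e4, n_genes = 10, seed = 1)
#' @export
sim_config <- function(genome_length = 8e6L,
                       n_genes = 4000L,
                       cds_length_range = c(300L, 900L),
                       n_resistant_lines = 13L,
                       n_sensitive_lines = 4L,
                       mutations_per_line_mean = 75,
                       canonical_fraction = 0.75,
                       causal_gene_id = NULL,
                       n_causal_lines = 3L,
                       shared_background_count = 50L,
                       depth_range = c(20L, 80L),
                       alt_fraction_shape1 = 18,
                       alt_fraction_shape2 = 2,
                       seed = 1L) {
  if (length(cds_length_range) != 2L || any(cds_length_range %% 3L != 0L)) {
    abort("`cds_length_range` must be two CDS lengths, each a multiple of 3.")
  }
  if (cds_length_range[1] > cds_length_range[2] || cds_length_range[1] < 9L) {
    abort("`cds_length_range` must be increasing and allow at least 3 codons.")
  }
  if (canonical_fraction < 0 || canonical_fraction > 1) {
    abort("`canonical_fraction` must lie in [0, 1].")
  }
  if (n_causal_lines > n_resistant_lines) {
    abort("`n_causal_lines` cannot exceed `n_resistant_lines`.")
  }
  if (length(depth_range) != 2L || depth_range[1] < 1L ||
      depth_range[1] > depth_range[2]) {
    abort("`depth_range` must be an increasing pair of positive depths.")
  }
  if (mutations_per_line_mean < 0 || shared_background_count < 0) {
    abort("Mutation counts must be non-negative.")
  }
  if (is.null(causal_gene_id) && n_genes > 0L) {
    causal_gene_id <- gene_id_label(max(1L, n_genes %/% 2L))
  }
  structure(
    list(
      genome_length = as.integer(genome_length),
      n_genes = as.integer(n_genes),
      cds_length_range = as.integer(cds_length_range),
      n_resistant_lines = as.integer(n_resistant_lines),
      n_sensitive_lines = as.integer(n_sensitive_lines),
      mutations_per_line_mean = mutations_per_line_mean,
      canonical_fraction = canonical_fraction,
      causal_gene_id = causal_gene_id,
      n_causal_lines = as.integer(n_causal_lines),
      shared_background_count = as.integer(shared_background_count),
      depth_range = as.integer(depth_range),
      alt_fraction_shape1 = alt_fraction_shape1,
      alt_fraction_shape2 = alt_fraction_shape2,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

gene_id_label <- function(i) sprintf("gene%05d", i)

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %s bp, %d genes (CDS %d-%d bp)\n",
              format(x$genome_length, big.mark = ","), x$n_genes,
              x$cds_length_range[1], x$cds_length_range[2]))
  cat(sprintf("  cohort: %d resistant + %d sensitive lines, causal gene %s in %d lines\n",
              x$n_resistant_lines, x$n_sensitive_lines,
              x$causal_gene_id %||% "<none>", x$n_causal_lines))
  cat(sprintf("  mutations/line ~ Poisson(%g), canonical fraction %g, %d shared background\n",
              x$mutations_per_line_mean, x$canonical_fraction,
              x$shared_background_count))
  cat(sprintf("  depth %d-%d, alt fraction ~ Beta(%g, %g), seed %d\n",
              x$depth_range[1], x$depth_range[2],
              x$alt_fraction_shape1, x$alt_fraction_shape2, x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
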