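AMINO_3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Chromosome sequences as a named character vector; converting a
# DNAStringSet once up front keeps per-variant lookups cheap.
genome_strings <- function(genome) {
  if (is.character(genome)) return(genome)
  setNames(as.character(genome), names(genome))
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Transcription-ordered segments with cumulative CDS length before each.
tx_segments <- function(segs) {
  segs <- segs[order(segs$exon_rank), , drop = FALSE]
  len <- segs$end - segs$start + 1L
  segs$cum_before <- c(0L, cumsum(len))[seq_len(nrow(segs))]
  segs$len <- len
  segs
}

# Genomic position of 1-based spliced-CDS offsets for one gene.
cds_offset_to_genomic <- function(segs_tx, offsets) {
  idx <- findInterval(offsets - 1L, segs_tx$cum_before)
  s <- segs_tx[idx, , drop = FALSE]
  within <- offsets - s$cum_before
  ifelse(s$strand == "+", s$start + within - 1L, s$end - within + 1L)
}

#' Map variants onto spliced coding sequences
#'
#' For every variant, returns each gene whose CDS contains the position,
#' together with the 1-based offset in the spliced coding sequence
#' (strand-aware). Positions outside any CDS simply yield no rows.
#'
#' @param variants Tibble with at least `chrom` and `pos`.
#' @param genes Gene-model tibble (see [sim_reference()]).
#' @return Tibble with `chrom`, `pos`, `gene_id`, `strand`, `cds_offset`.
#' @export
map_to_cds <- function(variants, genes) {
  empty <- tibble(chrom = character(), pos = integer(), gene_id = character(),
                  strand = character(), cds_offset = integer())
  if (nrow(variants) == 0L || nrow(genes) == 0L) return(empty)
  hits_list <- lapply(unique(variants$chrom), function(ch) {
    v <- variants %>% filter(.data$chrom == ch) %>% distinct(.data$pos)
    g <- genes %>% filter(.data$chrom == ch)
    if (nrow(v) == 0L || nrow(g) == 0L) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(v$pos, v$pos),
      IRanges::IRanges(g$start, g$end)
    )
    if (length(ov) == 0L) return(NULL)
    tibble(chrom = ch,
           pos = v$pos[S4Vectors::queryHits(ov)],
           gene_id = g$gene_id[S4Vectors::subjectHits(ov)])
  })
  hits <- bind_rows(hits_list)
  if (nrow(hits) == 0L) return(empty)
  # strand-aware offset within the spliced CDS
  gene_rows <- split(seq_len(nrow(genes)), genes$gene_id)
  idx <- split(seq_len(nrow(hits)), hits$gene_id)
  strand_out <- character(nrow(hits))
  off_out <- integer(nrow(hits))
  for (g in names(idx)) {
    rows <- idx[[g]]
    segs <- tx_segments(genes[gene_rows[[g]], , drop = FALSE])
    p <- hits$pos[rows]
    seg_i <- vapply(p, function(pp) {
      which(pp >= segs$start & pp <= segs$end)[1]
    }, integer(1))
    within <- ifelse(segs$strand[seg_i] == "+",
                     p - segs$start[seg_i] + 1L,
                     segs$end[seg_i] - p + 1L)
    off_out[rows] <- segs$cum_before[seg_i] + as.integer(within)
    strand_out[rows] <- segs$strand[1]
  }
  tibble(chrom = hits$chrom, pos = hits$pos, gene_id = hits$gene_id,
         strand = strand_out, cds_offset = off_out)
}

#' Annotate the codon-level effect of one variant in one gene
#'
#' Builds the affected codon of the spliced coding sequence (reverse
#' complemented for minus-strand genes), substitutes the alternative base,
#' translates under the standard genetic code, and classifies the change.
#'
#' @param variant One-row tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_segments CDS segments of a single gene (rows of the
#'   gene-model tibble).
#' @param genome The reference, either a [Biostrings::DNAStringSet] or a
#'   named character vector of chromosome sequences.
#' @return One-row tibble: `gene_id`, `codon_index`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `aa_change` (e.g. `"Pro197Ser"`),
#'   `effect_class` in `synonymous` / `missense` / `nonsense` / `stop_loss`.
#' @export
annotate_coding_effect <- function(variant, gene_segments, genome) {
  segs <- tx_segments(gene_segments)
  seq_chr <- genome_strings(genome)[[variant$chrom[1]]]
  ref_genomic <- substring(seq_chr, variant$pos[1], variant$pos[1])
  if (ref_genomic != variant$ref[1]) {
    abort(sprintf(
      "Reference mismatch at %s:%d: VCF says %s, FASTA says %s.",
      variant$chrom[1], variant$pos[1], variant$ref[1], ref_genomic
    ))
  }
  i <- which(variant$pos[1] >= segs$start & variant$pos[1] <= segs$end)[1]
  if (is.na(i)) {
    abort(sprintf("Position %s:%d is not inside the gene's CDS.",
                  variant$chrom[1], variant$pos[1]))
  }
  minus <- segs$strand[1] == "-"
  within <- if (minus) segs$end[i] - variant$pos[1] + 1L
            else variant$pos[1] - segs$start[i] + 1L
  offset <- segs$cum_before[i] + within
  codon_index <- (offset - 1L) %/% 3L + 1L
  codon_pos <- (offset - 1L) %% 3L + 1L

  codon_offsets <- (codon_index - 1L) * 3L + 1:3
  gpos <- cds_offset_to_genomic(segs, codon_offsets)
  bases <- substring(seq_chr, gpos, gpos)
  if (minus) bases <- unname(COMPLEMENT[bases])
  ref_codon <- paste(bases, collapse = "")

  alt_tx <- if (minus) unname(COMPLEMENT[variant$alt[1]]) else variant$alt[1]
  bases[codon_pos] <- alt_tx
  alt_codon <- paste(bases, collapse = "")

  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect_class <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
  tibble(
    gene_id = segs$gene_id[1],
    codon_index = codon_index,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    aa_change = sprintf("%s%d%s", AMINO_3[[ref_aa]], codon_index,
                        AMINO_3[[alt_aa]]),
    effect_class = effect_class
  )
}

# Vectorised effect annotation for many variants in one gene. `df` needs
# chrom, pos, ref, alt; returns plain vectors in a list (no per-row tibble
# overhead). Shares its arithmetic with annotate_coding_effect by
# construction; the single-variant function remains the documented surface.
coding_effects_one_gene <- function(df, segs_raw, seq_chr) {
  segs <- tx_segments(segs_raw)
  minus <- segs$strand[1] == "-"
  ref_genomic <- substring(seq_chr, df$pos, df$pos)
  bad <- ref_genomic != df$ref
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Reference mismatch at %s:%d: VCF says %s, FASTA says %s.",
                  df$chrom[i], df$pos[i], df$ref[i], ref_genomic[i]))
  }
  seg_idx <- vapply(df$pos, function(p) {
    which(p >= segs$start & p <= segs$end)[1]
  }, integer(1))
  within <- if (minus) segs$end[seg_idx] - df$pos + 1L
            else df$pos - segs$start[seg_idx] + 1L
  offset <- segs$cum_before[seg_idx] + within
  codon_index <- (offset - 1L) %/% 3L + 1L
  codon_pos <- (offset - 1L) %% 3L + 1L
  n <- nrow(df)
  codon_offsets <- rep((codon_index - 1L) * 3L, each = 3L) + rep(1:3, n)
  gpos <- cds_offset_to_genomic(segs, codon_offsets)
  bases <- substring(seq_chr, gpos, gpos)
  if (minus) bases <- unname(COMPLEMENT[bases])
  mat <- matrix(bases, nrow = 3L)
  ref_codon <- paste0(mat[1, ], mat[2, ], mat[3, ])
  alt_tx <- if (minus) unname(COMPLEMENT[df$alt]) else df$alt
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_tx
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  effect_class <- ifelse(ref_aa == alt_aa, "synonymous",
                  ifelse(alt_aa == "*", "nonsense",
                  ifelse(ref_aa == "*", "stop_loss", "missense")))
  list(
    cds_offset = offset,
    codon_index = codon_index,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    aa_change = sprintf("%s%d%s", AMINO_3[ref_aa], codon_index,
                        AMINO_3[alt_aa]),
    effect_class = effect_class
  )
}

#' Annotate candidate variants against all overlapping gene models
#'
#' Joins [map_to_cds()] with [annotate_coding_effect()]: one output row per
#' (variant, overlapping gene). Variants outside any CDS produce no rows.
#'
#' @param candidates Variant tibble (with `line_id`, `chrom`, `pos`, `ref`,
#'   `alt`, ...).
#' @param genes Gene-model tibble.
#' @param genome Reference [Biostrings::DNAStringSet].
#' @return `candidates` joined with effect columns and `gene_id`.
#' @export
annotate_candidates <- function(candidates, genes, genome) {
  genome <- genome_strings(genome)
  mapping <- map_to_cds(candidates, genes)
  joined <- candidates %>%
    inner_join(mapping, by = c("chrom", "pos"), relationship = "many-to-many")
  if (nrow(joined) == 0L) {
    return(bind_cols(
      candidates[0, ],
      tibble(gene_id = character(), strand = character(),
             cds_offset = integer(), codon_index = integer(),
             ref_codon = character(), alt_codon = character(),
             ref_aa = character(), alt_aa = character(),
             aa_change = character(), effect_class = character())
    ))
  }
  joined <- joined %>% select(-"cds_offset") %>% arrange(.data$gene_id)
  n <- nrow(joined)
  gene_rows <- split(seq_len(nrow(genes)), genes$gene_id)
  idx <- split(seq_len(n), joined$gene_id)
  out <- list(
    cds_offset = integer(n), codon_index = integer(n),
    ref_codon = character(n), alt_codon = character(n),
    ref_aa = character(n), alt_aa = character(n),
    aa_change = character(n), effect_class = character(n)
  )
  for (g in names(idx)) {
    rows <- idx[[g]]
    segs <- genes[gene_rows[[g]], , drop = FALSE]
    eff <- coding_effects_one_gene(joined[rows, ], segs,
                                   genome[[joined$chrom[rows[1]]]])
    for (nm in names(out)) out[[nm]][rows] <- eff[[nm]]
  }
  bind_cols(joined, as_tibble(out))
}

#' Keep candidates that change an amino acid in at least one gene model
#'
#' A variant overlapping several gene models is retained if it is
#' non-synonymous in any of them; the reported annotation is the most
#' severe one (nonsense, then stop-loss, then missense).
#'
#' @param annotated Output of [annotate_candidates()].
#' @return One row per retained variant (per line), with its chosen
#'   annotation.
#' @export
retain_amino_acid_changing <- function(annotated) {
  severity <- c(nonsense = 1L, stop_loss = 2L, missense = 3L, synonymous = 4L)
  annotated %>%
    filter(.data$effect_class != "synonymous") %>%
    mutate(.sev = severity[.data$effect_class]) %>%
    group_by(.data$line_id, .data$chrom, .data$pos, .data$alt) %>%
    arrange(.data$.sev, .data$gene_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-".sev") %>%
    arrange(.data$line_id, .data$chrom, .data$pos)
}

#' Spliced coding sequence of a gene (transcription orientation)
#'
#' @param gene_segments CDS segments of one gene.
#' @param genome Reference [Biostrings::DNAStringSet].
#' @return Character scalar, the CDS 5' to 3'.
#' @export
spliced_cds <- function(gene_segments, genome) {
  segs <- gene_segments[order(gene_segments$start), , drop = FALSE]
  seq_chr <- genome_strings(genome)[[segs$chrom[1]]]
  genomic <- paste(substring(seq_chr, segs$start, segs$end), collapse = "")
  if (segs$strand[1] == "-") revcomp(genomic) else genomic
}
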