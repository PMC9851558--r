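# Small shared fixtures, built in code once per test run.

tiny_cfg <- sim_config(
  genome_length = 3e4, n_genes = 10, cds_length_range = c(150L, 450L),
  n_resistant_lines = 3, n_sensitive_lines = 2, n_causal_lines = 2,
  mutations_per_line_mean = 25, shared_background_count = 6,
  causal_gene_id = "gene00005", seed = 42
)
tiny_ref <- sim_reference(tiny_cfg)
tiny_cohort <- sim_uv_cohort(tiny_cfg, tiny_ref$genome, tiny_ref$genes)

# A hand-built reference for codon-arithmetic checks: one plus-strand and
# one minus-strand single-exon gene with known codons.
#   plus gene "gp" at 11..19:  ATG GAA TAA
#   minus gene "gm" at 31..39: genomic revcomp of ATG CAA TAA = TTATTGCAT
hand_genome_chr <- paste0(
  strrep("A", 10), "ATGGAATAA",          # 11..19
  strrep("C", 11),                        # 20..30
  "TTATTGCAT",                            # 31..39
  strrep("G", 11)                         # 40..50
)
hand_genome <- Biostrings::DNAStringSet(stats::setNames(hand_genome_chr, "chr1"))
hand_genes <- tibble::tibble(
  gene_id = c("gp", "gm"),
  chrom = "chr1",
  strand = c("+", "-"),
  start = c(11L, 31L),
  end = c(19L, 39L),
  exon_rank = 1L,
  phase = 0L
)

# Independent full-CDS translation oracle built on seqinr (different
# package and path from the implementation's single-codon arithmetic).
oracle_translate <- function(seq) {
  paste(seqinr::translate(seqinr::s2c(seq)), collapse = "")
}

# `chr_string` may be the chromosome string or an already-split character
# vector of single bases (cheaper when called in a loop).
oracle_spliced_cds <- function(chr_string, segs, mutate_pos = NULL,
                               mutate_base = NULL) {
  chars <- if (length(chr_string) > 1L) chr_string
           else strsplit(chr_string, "", fixed = TRUE)[[1]]
  if (!is.null(mutate_pos)) chars[mutate_pos] <- mutate_base
  segs <- segs[order(segs$start), , drop = FALSE]
  genomic <- paste(unlist(lapply(seq_len(nrow(segs)), function(i) {
    chars[segs$start[i]:segs$end[i]]
  })), collapse = "")
  if (segs$strand[1] == "-") {
    paste(rev(seqinr::comp(strsplit(genomic, "")[[1]], forceToLower = FALSE)),
          collapse = "")
  } else {
    genomic
  }
}

# Classify a single-base substitution by re-translating the whole mutated
# spliced CDS and diffing amino acids.
oracle_effect <- function(chr_string, segs, pos, alt) {
  ref_aa <- oracle_translate(oracle_spliced_cds(chr_string, segs))
  alt_aa <- oracle_translate(oracle_spliced_cds(chr_string, segs, pos, alt))
  ref_v <- strsplit(ref_aa, "")[[1]]
  alt_v <- strsplit(alt_aa, "")[[1]]
  diff <- which(ref_v != alt_v)
  if (length(diff) == 0L) return(list(class = "synonymous", codon = NA))
  i <- diff[1]
  cls <- if (alt_v[i] == "*") "nonsense"
    else if (ref_v[i] == "*") "stop_loss"
    else "missense"
  list(class = cls, codon = i)
}

# One-pass brute-force re-implementation of the cascade predicate,
# independent of the package's filter functions.
oracle_cascade_keep <- function(records, comparator_keys, cfg) {
  total <- records$dp4_rf + records$dp4_rr + records$dp4_af + records$dp4_ar
  alt_reads <- records$dp4_af + records$dp4_ar
  support <- if (cfg$support_basis == "alt_reads") alt_reads else total
  frac <- alt_reads / total
  snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% c("A", "C", "G", "T") &
    records$alt %in% c("A", "C", "G", "T")
  canon <- paste0(records$ref, ">", records$alt) %in% cfg$canonical_changes
  key <- paste(records$chrom, records$pos, records$alt)
  total > 0 &
    support >= cfg$min_support & support <= cfg$max_support &
    frac > cfg$alt_fraction_threshold &
    snv & canon &
    !(key %in% comparator_keys)
}

variant_key <- function(df) paste(df$line_id, df$chrom, df$pos, df$alt)
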