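STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

SENSE_CODONS <- setdiff(all_codons(), STOP_CODONS)

base_code <- c(A = 65L, C = 67L, G = 71L, T = 84L)

#' Generate a synthetic reference genome and gene models
#'
#' Builds a single-chromosome random genome and places `n_genes`
#' non-overlapping protein-coding genes on it, roughly half per strand.
#' Each gene carries a valid CDS (start codon, no internal stop, one
#' terminal stop) split over 1-3 exons separated by short introns, so the
#' gene models exercise spliced, strand-aware coordinate arithmetic.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet] named `chr1`)
#'   and `genes`, a tibble of CDS segments with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive), `exon_rank` (5' to 3' in
#'   transcription direction) and `phase` (GFF3 convention).
#' @examples
#' ref <- sim_reference(sim_config(genome_length = 3e4, n_genes = 5, seed = 1))
#' ref$genes
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "reference", {
    n <- config$genome_length
    codes <- unname(base_code)[as.integer(runif(n) * 4) + 1L]
    if (config$n_genes == 0L) {
      genome <- Biostrings::DNAStringSet(setNames(intToUtf8(codes), "chr1"))
      return(list(genome = genome, genes = empty_gene_tibble()))
    }

    cds_len <- 3L * sample.int(
      config$cds_length_range[2] %/% 3L - config$cds_length_range[1] %/% 3L + 1L,
      config$n_genes, replace = TRUE
    ) + config$cds_length_range[1] - 3L
    n_exons <- sample(1:3, config$n_genes, replace = TRUE, prob = c(.5, .3, .2))
    intron_pool <- sample(50:200, sum(n_exons - 1L), replace = TRUE)
    intron_len <- split(
      intron_pool,
      factor(rep.int(seq_len(config$n_genes), n_exons - 1L),
             levels = seq_len(config$n_genes))
    )
    span <- cds_len + vapply(intron_len, sum, integer(1))

    min_gap <- 10L
    required <- sum(span) + min_gap * (config$n_genes + 1L)
    if (n < required) {
      abort(sprintf(
        "%d genes do not fit in a %d bp genome; need at least %d bp.",
        config$n_genes, n, required
      ))
    }
    extra <- n - required + min_gap  # slack to distribute over n_genes + 1 gaps
    gaps <- min_gap + as.vector(stats::rmultinom(
      1, extra - min_gap, rep(1, config$n_genes + 1L)
    ))
    strand <- sample(rep_len(c("+", "-"), config$n_genes))

    # draw all coding sequence in bulk, then stitch per gene
    n_mid <- cds_len %/% 3L - 2L
    mid_pool <- sample(SENSE_CODONS, sum(n_mid), replace = TRUE)
    mid_by_gene <- split(mid_pool, factor(rep.int(seq_len(config$n_genes), n_mid),
                                          levels = seq_len(config$n_genes)))
    stop_by_gene <- sample(STOP_CODONS, config$n_genes, replace = TRUE)

    # preallocated accumulators; one tibble at the end
    n_seg <- sum(n_exons)
    acc_gene <- character(n_seg); acc_strand <- character(n_seg)
    acc_start <- integer(n_seg); acc_end <- integer(n_seg)
    acc_rank <- integer(n_seg); acc_phase <- integer(n_seg)
    seg_at <- 0L
    cursor <- 0L
    for (i in seq_len(config$n_genes)) {
      cursor <- cursor + gaps[i]
      gstart <- cursor + 1L
      # exon lengths: split the CDS at random internal points
      L <- cds_len[i]
      k <- n_exons[i]
      if (k == 1L) {
        exon_len <- L
      } else {
        cuts <- sort(sample.int(L - 1L, k - 1L))
        exon_len <- diff(c(0L, cuts, L))
      }
      # genomic intervals, ascending
      starts <- integer(k)
      ends <- integer(k)
      pos <- gstart
      for (j in seq_len(k)) {
        starts[j] <- pos
        ends[j] <- pos + exon_len[j] - 1L
        pos <- ends[j] + 1L + if (j < k) intron_len[[i]][j] else 0L
      }
      cursor <- ends[k]

      cds_seq <- paste0(
        "ATG", paste(mid_by_gene[[i]], collapse = ""), stop_by_gene[i]
      )
      genomic_seq <- if (strand[i] == "+") cds_seq else revcomp_chr(cds_seq)
      seq_codes <- utf8ToInt(genomic_seq)
      offset <- 0L
      for (j in seq_len(k)) {
        len_j <- ends[j] - starts[j] + 1L
        codes[starts[j]:ends[j]] <- seq_codes[(offset + 1L):(offset + len_j)]
        offset <- offset + len_j
      }

      # exon_rank in transcription direction; phase per GFF3
      rank <- if (strand[i] == "+") seq_len(k) else rev(seq_len(k))
      len_in_tx <- if (strand[i] == "+") exon_len else rev(exon_len)
      cum_before <- c(0L, cumsum(len_in_tx))[seq_len(k)]
      phase_tx <- (3L - cum_before %% 3L) %% 3L
      phase <- if (strand[i] == "+") phase_tx else rev(phase_tx)

      at <- seg_at + seq_len(k)
      acc_gene[at] <- gene_id_label(i)
      acc_strand[at] <- strand[i]
      acc_start[at] <- starts
      acc_end[at] <- ends
      acc_rank[at] <- rank
      acc_phase[at] <- phase
      seg_at <- seg_at + k
    }

    genome <- Biostrings::DNAStringSet(setNames(intToUtf8(codes), "chr1"))
    genes <- tibble(
      gene_id = acc_gene, chrom = "chr1", strand = acc_strand,
      start = acc_start, end = acc_end, exon_rank = acc_rank,
      phase = acc_phase
    )
    list(genome = genome, genes = genes)
  })
}

empty_gene_tibble <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), exon_rank = integer(),
    phase = integer()
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# character-level reverse complement, cheap enough for tight loops
revcomp_chr <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", x))))
}

#' Write a reference genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reference_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per gene plus its `CDS` segments with `strand`
#' and `phase`, 1-based inclusive coordinates.
#'
#' @param genes A gene-model tibble as returned by [sim_reference()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gene_rows <- genes %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    arrange(.data$start)
  gr_gene <- GenomicRanges::GRanges(
    gene_rows$chrom,
    IRanges::IRanges(gene_rows$start, gene_rows$end),
    strand = gene_rows$strand,
    type = "gene", ID = gene_rows$gene_id
  )
  cds <- genes %>% arrange(.data$start)
  gr_cds <- GenomicRanges::GRanges(
    cds$chrom,
    IRanges::IRanges(cds$start, cds$end),
    strand = cds$strand,
    type = "CDS",
    ID = sprintf("%s.cds%d", cds$gene_id, cds$exon_rank),
    Parent = cds$gene_id,
    phase = as.integer(cds$phase)
  )
  gr <- c(gr_gene, gr_cds)
  gr <- gr[order(GenomicRanges::start(gr),
                 S4Vectors::mcols(gr)$type != "gene")]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models (CDS features) from GFF3
#'
#' Respects `strand` and `phase`; segments are ordered 5' to 3' in
#' transcription direction and assigned `exon_rank` accordingly. Genes whose
#' concatenated CDS length is not divisible by 3 are dropped with a warning
#' rather than silently used.
#'
#' @param path GFF3 path.
#' @return A gene-model tibble (see [sim_reference()]).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0L) return(empty_gene_tibble())
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  out <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    phase = as.integer(S4Vectors::mcols(gr)$phase)
  ) %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(exon_rank = if (.data$strand[1] == "+") row_number()
           else rev(row_number())) %>%
    ungroup() %>%
    select("gene_id", "chrom", "strand", "start", "end", "exon_rank",
           "phase") %>%
    arrange(.data$gene_id, .data$exon_rank)
  bad <- out %>%
    group_by(.data$gene_id) %>%
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop") %>%
    filter(.data$len %% 3L != 0L)
  if (nrow(bad) > 0L) {
    warn(sprintf(
      "Dropping %d gene model(s) whose CDS length is not a multiple of 3: %s",
      nrow(bad), paste(head(bad$gene_id, 5L), collapse = ", ")
    ))
    out <- out %>% filter(!.data$gene_id %in% bad$gene_id)
  }
  out
}
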