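test_that("known codon substitutions classify correctly on the plus strand", {
  # gp CDS is ATG GAA TAA; genomic offset 4 is the G of GAA at pos 14
  v <- tibble::tibble(chrom = "chr1", pos = 14L, ref = "G", alt = "A")
  eff <- annotate_coding_effect(v, hand_genes[hand_genes$gene_id == "gp", ],
                                hand_genome)
  expect_equal(eff$ref_codon, "GAA")
  expect_equal(eff$alt_codon, "AAA")
  expect_equal(eff$ref_aa, "E")
  expect_equal(eff$alt_aa, "K")
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$aa_change, "Glu2Lys")
})

test_that("minus-strand codons are read in transcription orientation", {
  # gm CDS is ATG CAA TAA; its CAA codon occupies genomic 34..36 (TTG)
  # CDS base C (codon 2 pos 1) sits at genomic pos 36 on the minus strand
  v <- tibble::tibble(chrom = "chr1", pos = 36L, ref = "G", alt = "A")
  eff <- annotate_coding_effect(v, hand_genes[hand_genes$gene_id == "gm", ],
                                hand_genome)
  expect_equal(eff$ref_codon, "CAA")
  expect_equal(eff$alt_codon, "TAA")
  expect_equal(eff$effect_class, "nonsense")
  expect_equal(eff$aa_change, "Gln2Ter")
})

test_that("a reference mismatch between VCF and FASTA is a data-integrity error", {
  v <- tibble::tibble(chrom = "chr1", pos = 14L, ref = "T", alt = "A")
  expect_error(
    annotate_coding_effect(v, hand_genes[hand_genes$gene_id == "gp", ],
                           hand_genome),
    "chr1:14"
  )
})

test_that("intergenic positions map to no gene; CDS positions map with correct offsets", {
  v <- tibble::tibble(chrom = "chr1", pos = c(5L, 14L, 25L, 36L))
  m <- map_to_cds(v, hand_genes)
  expect_equal(nrow(m), 2L)
  expect_equal(m$gene_id[m$pos == 14], "gp")
  expect_equal(m$cds_offset[m$pos == 14], 4L)
  expect_equal(m$gene_id[m$pos == 36], "gm")
  expect_equal(m$cds_offset[m$pos == 36], 4L)
  none <- map_to_cds(tibble::tibble(chrom = "chrX", pos = 14L), hand_genes)
  expect_equal(nrow(none), 0L)
})

test_that("random positions map identically to a brute-force interval scan", {
  set.seed(5)
  pos <- sample.int(tiny_cfg$genome_length, 3000L)
  v <- tibble::tibble(chrom = "chr1", pos = pos)
  m <- map_to_cds(v, tiny_ref$genes)
  # brute force over all segments
  brute <- do.call(rbind, lapply(pos, function(p) {
    hit <- tiny_ref$genes[p >= tiny_ref$genes$start & p <= tiny_ref$genes$end, ]
    if (nrow(hit) == 0L) NULL else data.frame(pos = p, gene_id = hit$gene_id)
  }))
  expect_setequal(paste(m$pos, m$gene_id), paste(brute$pos, brute$gene_id))
})

test_that("effects agree with full re-translation across strands (sampled)", {
  chr <- as.character(tiny_ref$genome[[1]])
  set.seed(6)
  cds_pos <- unlist(lapply(seq_len(nrow(tiny_ref$genes)), function(i) {
    tiny_ref$genes$start[i]:tiny_ref$genes$end[i]
  }))
  pos <- sample(cds_pos, 300L)
  ref <- substring(chr, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  cand <- tibble::tibble(line_id = "L", chrom = "chr1", pos = pos,
                         ref = ref, alt = alt)
  ann <- annotate_candidates(cand, tiny_ref$genes, tiny_ref$genome)
  expect_equal(nrow(ann), 300L)
  for (i in seq_len(nrow(ann))) {
    segs <- tiny_ref$genes[tiny_ref$genes$gene_id == ann$gene_id[i], ]
    oracle <- oracle_effect(chr, segs, ann$pos[i], ann$alt[i])
    expect_equal(ann$effect_class[i], oracle$class)
    if (!is.na(oracle$codon)) expect_equal(ann$codon_index[i], oracle$codon)
  }
})

test_that("a variant synonymous in one overlapping gene but missense in another is retained", {
  # two genes sharing the interval; CDS of g2 shifted one base so the same
  # genomic substitution lands in different codon positions
  chr <- paste0("AA", "ATGCTGTAA", "CTAA", strrep("G", 10))
  genome <- Biostrings::DNAStringSet(stats::setNames(chr, "chr1"))
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(3L, 4L), end = c(11L, 12L), exon_rank = 1L, phase = 0L
  )
  # pos 8 is the G of CTG in g1 (CTG->CTA, Leu->Leu, synonymous); in g2
  # (CDS TGC TGT AAC starting at 4) it is base 2 of TGT (Cys->Tyr)
  v <- tibble::tibble(line_id = "L", chrom = "chr1", pos = 8L,
                      ref = "G", alt = "A")
  ann <- annotate_candidates(v, genes, genome)
  expect_setequal(ann$effect_class[ann$gene_id == "g1"], "synonymous")
  expect_true(all(ann$effect_class[ann$gene_id == "g2"] != "synonymous"))
  kept <- retain_amino_acid_changing(ann)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$gene_id, "g2")
})

test_that("synonymous-only candidates are removed, amino-acid-changing retained", {
  chr <- as.character(tiny_ref$genome[[1]])
  set.seed(7)
  cds_pos <- unlist(lapply(seq_len(nrow(tiny_ref$genes)), function(i) {
    tiny_ref$genes$start[i]:tiny_ref$genes$end[i]
  }))
  pos <- sample(cds_pos, 200L)
  ref <- substring(chr, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  cand <- tibble::tibble(line_id = "L", chrom = "chr1", pos = pos,
                         ref = ref, alt = alt)
  ann <- annotate_candidates(cand, tiny_ref$genes, tiny_ref$genome)
  kept <- retain_amino_acid_changing(ann)
  expect_true(all(kept$effect_class %in% c("missense", "nonsense", "stop_loss")))
  syn_only <- setdiff(ann$pos[ann$effect_class == "synonymous"],
                      ann$pos[ann$effect_class != "synonymous"])
  expect_length(intersect(kept$pos, syn_only), 0L)
})
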