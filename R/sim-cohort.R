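CANONICAL_ALT <- c(C = "T", G = "A")

#' Simulate a UV-mutagenized screen cohort with ground truth
#'
#' Draws per-line private SNVs enriched for the canonical UV-B spectrum
#' (C>T / G>A on the reference strand), injects clonal background variants
#' shared by every line, spikes one non-synonymous canonical variant in the
#' causal gene into `n_causal_lines` resistant lines, and simulates
#' strand-split `DP4` read support for every record.
#'
#' @param config A [sim_config()]; must be the one used for [sim_reference()].
#' @param genome,genes The reference pair from [sim_reference()].
#' @return A list with:
#'   * `variants`: tibble of all records (`line_id`, `chrom`, `pos`, `ref`,
#'     `alt`, `dp4_rf`, `dp4_rr`, `dp4_af`, `dp4_ar`),
#'   * `lines`: tibble (`line_id`, `phenotype` in `resistant`/`sensitive`),
#'   * `truth`: list of `causal` (line_id, chrom, pos, ref, alt, gene_id),
#'     `background` (chrom, pos, ref, alt; present in every line) and
#'     `per_line_counts`.
#' @examples
#' cfg <- sim_config(genome_length = 3e4, n_genes = 5,
#'                   mutations_per_line_mean = 10,
#'                   n_resistant_lines = 3, n_sensitive_lines = 2,
#'                   n_causal_lines = 2, shared_background_count = 4,
#'                   causal_gene_id = "gene00001", seed = 7)
#' ref <- sim_reference(cfg)
#' cohort <- sim_uv_cohort(cfg, ref$genome, ref$genes)
#' @export
sim_uv_cohort <- function(config, genome, genes) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_causal_lines > 0L &&
      !config$causal_gene_id %in% genes$gene_id) {
    abort(sprintf("causal_gene_id '%s' is absent from the gene set.",
                  config$causal_gene_id))
  }
  seq_chr <- as.character(genome[[1]])
  chrom_name <- names(genome)[1]
  glen <- nchar(seq_chr)

  with_stream(config$seed, "cohort", {
    res_ids <- sprintf("res%02d", seq_len(config$n_resistant_lines))
    sen_ids <- sprintf("sen%02d", seq_len(config$n_sensitive_lines))
    lines <- tibble(
      line_id = c(res_ids, sen_ids),
      phenotype = rep(c("resistant", "sensitive"),
                      c(length(res_ids), length(sen_ids)))
    )

    background <- draw_snvs(config$shared_background_count, seq_chr, glen,
                            config$canonical_fraction, chrom_name)

    causal <- tibble(line_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     gene_id = character())
    if (config$n_causal_lines > 0L) {
      sites <- nonsyn_canonical_sites(genome, genes, config$causal_gene_id)
      if (nrow(sites) < config$n_causal_lines) {
        abort(sprintf(
          "Causal gene %s offers only %d non-synonymous canonical sites (< %d).",
          config$causal_gene_id, nrow(sites), config$n_causal_lines
        ))
      }
      causal_lines <- sort(sample(res_ids, config$n_causal_lines))
      picked <- sites[sample.int(nrow(sites), config$n_causal_lines), ]
      causal <- tibble(
        line_id = causal_lines, chrom = picked$chrom, pos = picked$pos,
        ref = picked$ref, alt = picked$alt,
        gene_id = config$causal_gene_id
      )
    }

    per_line <- vector("list", nrow(lines))
    for (i in seq_len(nrow(lines))) {
      lid <- lines$line_id[i]
      n_priv <- rpois(1, config$mutations_per_line_mean)
      priv <- draw_snvs(n_priv, seq_chr, glen, config$canonical_fraction,
                        chrom_name)
      recs <- bind_rows(
        priv,
        background,
        causal %>% filter(.data$line_id == lid) %>%
          select("chrom", "pos", "ref", "alt")
      ) %>%
        distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
        mutate(line_id = lid, .before = 1)
      per_line[[i]] <- recs
    }
    variants <- bind_rows(per_line)
    variants <- bind_cols(variants, sim_dp4(nrow(variants), config)) %>%
      arrange(.data$line_id, .data$chrom, .data$pos)

    per_line_counts <- variants %>%
      count(.data$line_id, name = "n_total") %>%
      left_join(lines, by = "line_id") %>%
      select("line_id", "phenotype", "n_total")

    list(
      variants = variants,
      lines = lines,
      truth = list(causal = causal, background = background,
                   per_line_counts = per_line_counts)
    )
  })
}

# SNVs with the stated canonical fraction; canonical draws are placed on
# C/G reference positions by rejection sampling (~2 tries expected).
draw_snvs <- function(n, seq_chr, glen, canonical_fraction, chrom_name) {
  empty <- tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character())
  if (n == 0L) return(empty)
  is_canon <- runif(n) < canonical_fraction
  out_pos <- integer(n)
  out_ref <- character(n)
  out_alt <- character(n)

  n_c <- sum(is_canon)
  if (n_c > 0L) {
    pos <- integer(0); ref <- character(0)
    while (length(pos) < n_c) {
      cand <- sample.int(glen, 2L * (n_c - length(pos)) + 8L, replace = TRUE)
      b <- substring(seq_chr, cand, cand)
      keep <- b %in% c("C", "G")
      pos <- c(pos, cand[keep]); ref <- c(ref, b[keep])
    }
    pos <- pos[seq_len(n_c)]; ref <- ref[seq_len(n_c)]
    out_pos[is_canon] <- pos
    out_ref[is_canon] <- ref
    out_alt[is_canon] <- unname(CANONICAL_ALT[ref])
  }

  n_nc <- n - n_c
  if (n_nc > 0L) {
    pos <- sample.int(glen, n_nc, replace = TRUE)
    ref <- substring(seq_chr, pos, pos)
    alt <- vapply(ref, function(b) {
      choices <- setdiff(c("A", "C", "G", "T"), b)
      if (b %in% names(CANONICAL_ALT)) {
        choices <- setdiff(choices, CANONICAL_ALT[[b]])
      }
      sample(choices, 1L)
    }, character(1), USE.NAMES = FALSE)
    out_pos[!is_canon] <- pos
    out_ref[!is_canon] <- ref
    out_alt[!is_canon] <- alt
  }
  tibble(chrom = chrom_name, pos = out_pos, ref = out_ref, alt = out_alt) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

sim_dp4 <- function(n, config) {
  if (n == 0L) {
    return(tibble(dp4_rf = integer(), dp4_rr = integer(),
                  dp4_af = integer(), dp4_ar = integer()))
  }
  depth <- sample(config$depth_range[1]:config$depth_range[2], n, replace = TRUE)
  frac <- stats::rbeta(n, config$alt_fraction_shape1, config$alt_fraction_shape2)
  alt <- pmax(1L, rbinom(n, depth, frac))
  ref <- depth - alt
  af <- rbinom(n, alt, 0.5)
  rf <- rbinom(n, ref, 0.5)
  tibble(dp4_rf = rf, dp4_rr = ref - rf, dp4_af = af, dp4_ar = alt - af)
}

# CDS positions in `gene_id` where the canonical substitution (C>T or G>A
# on the reference strand) changes the encoded amino acid.
nonsyn_canonical_sites <- function(genome, genes, gene_id) {
  genome <- genome_strings(genome)
  segs <- genes %>% filter(.data$gene_id == .env$gene_id)
  pos_all <- unlist(lapply(seq_len(nrow(segs)),
                           function(i) segs$start[i]:segs$end[i]))
  seq_chr <- genome[[segs$chrom[1]]]
  ref <- substring(seq_chr, pos_all, pos_all)
  keep <- ref %in% c("C", "G")
  pos <- pos_all[keep]
  ref <- ref[keep]
  alt <- unname(CANONICAL_ALT[ref])
  if (length(pos) == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  v <- tibble(chrom = segs$chrom[1], pos = pos, ref = ref, alt = alt)
  eff <- coding_effects_one_gene(v, segs, seq_chr)
  v[eff$effect_class != "synonymous", ]
}

#' Write variant records to a VCF v4.2 file
#'
#' One file per line, `DP4` (ref-forward, ref-reverse, alt-forward,
#' alt-reverse) carried in INFO.
#'
#' @param records Variant tibble for a single line (see [sim_uv_cohort()]).
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(records, path, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=herbiscreen",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs)
    },
    paste0("##INFO=<ID=DP4,Number=4,Type=Integer,Description=",
           "\"Strand-split read counts: ref-fwd,ref-rev,alt-fwd,alt-rev\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(records) == 0L) character() else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP4=%d,%d,%d,%d",
    records$chrom, records$pos, records$ref, records$alt,
    records$dp4_rf, records$dp4_rr, records$dp4_af, records$dp4_ar
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant records from a VCF file
#'
#' Accepts `DP4` either in INFO or as a per-sample FORMAT field (first
#' sample used). Multi-allelic records are split into biallelic records,
#' each inheriting the site's `DP4`.
#'
#' @param path VCF path.
#' @param line_id Line identifier attached to every record (default: file
#'   name without extension).
#' @return A variant tibble (see [sim_uv_cohort()]).
#' @export
read_variants_vcf <- function(path, line_id = NULL) {
  if (is.null(line_id)) {
    line_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(line_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), dp4_rf = integer(),
                  dp4_rr = integer(), dp4_af = integer(), dp4_ar = integer()))
  }
  dp4 <- vcfR::extract.info(v, "DP4")
  if (all(is.na(dp4)) && ncol(v@gt) >= 2L) {
    dp4 <- vcfR::extract.gt(v, "DP4")[, 1]
  }
  counts <- t(vapply(strsplit(ifelse(is.na(dp4), "NA,NA,NA,NA", dp4), ","),
                     function(x) suppressWarnings(as.integer(x[1:4])),
                     integer(4)))
  out <- tibble(
    line_id = line_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    dp4_rf = counts[, 1], dp4_rr = counts[, 2],
    dp4_af = counts[, 3], dp4_ar = counts[, 4]
  )
  # split multi-allelic records into biallelic ones
  out %>%
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) %>%
    tidyr::unnest("alt")
}

#' Write cohort ground truth to JSON
#'
#' @param truth The `truth` element of [sim_uv_cohort()]'s result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
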