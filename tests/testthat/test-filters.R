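mk_rec <- function(dp4, ref = "C", alt = "T", pos = 100L, line = "L1") {
  tibble::tibble(line_id = line, chrom = "chr1", pos = pos, ref = ref,
                 alt = alt, dp4_rf = dp4[1], dp4_rr = dp4[2],
                 dp4_af = dp4[3], dp4_ar = dp4[4])
}

test_that("read-support window is inclusive at both published bounds", {
  cfg <- filter_config()
  expect_equal(nrow(filter_by_support(mk_rec(c(2, 1, 4, 3)), cfg)), 1L)  # 7 alt
  expect_equal(nrow(filter_by_support(mk_rec(c(0, 0, 60, 50)), cfg)), 0L) # 110
  expect_equal(nrow(filter_by_support(mk_rec(c(0, 0, 50, 50)), cfg)), 1L) # 100
  expect_equal(nrow(filter_by_support(mk_rec(c(5, 5, 3, 3)), cfg)), 0L)  # 6
  total <- filter_config(support_basis = "total_reads")
  expect_equal(nrow(filter_by_support(mk_rec(c(2, 1, 2, 2)), total)), 1L) # 7
  expect_equal(nrow(filter_by_support(mk_rec(c(60, 41, 5, 5)), total)), 0L)
})

test_that("allele-fraction filter is strictly greater than one half", {
  cfg <- filter_config()
  expect_equal(nrow(filter_by_allele_fraction(mk_rec(c(0, 0, 5, 5)), cfg)), 1L)
  expect_equal(nrow(filter_by_allele_fraction(mk_rec(c(5, 5, 5, 5)), cfg)), 0L)
  expect_equal(nrow(filter_by_allele_fraction(mk_rec(c(6, 6, 4, 4)), cfg)), 0L)
})

test_that("spectrum filter keeps only canonical SNVs and drops non-SNVs", {
  cfg <- filter_config()
  expect_equal(nrow(filter_by_uv_spectrum(mk_rec(c(0, 0, 5, 5), "C", "T"), cfg)), 1L)
  expect_equal(nrow(filter_by_uv_spectrum(mk_rec(c(0, 0, 5, 5), "G", "A"), cfg)), 1L)
  expect_equal(nrow(filter_by_uv_spectrum(mk_rec(c(0, 0, 5, 5), "A", "C"), cfg)), 0L)
  expect_equal(nrow(filter_by_uv_spectrum(mk_rec(c(0, 0, 5, 5), "T", "C"), cfg)), 0L)
  insertion <- mk_rec(c(0, 0, 5, 5), "C", "CAT")
  expect_equal(nrow(filter_by_uv_spectrum(insertion, cfg)), 0L)
})

test_that("non-allelism subtraction removes shared calls and warns on empty comparators", {
  focal <- dplyr::bind_rows(
    mk_rec(c(0, 0, 5, 5), pos = 100L),
    mk_rec(c(0, 0, 5, 5), pos = 200L)
  )
  comp <- mk_rec(c(1, 1, 3, 3), pos = 100L, line = "S1")
  kept <- subtract_nonallelic_lines(focal, comp)
  expect_equal(kept$pos, 200L)
  expect_warning(subtract_nonallelic_lines(focal, comp[0, ]), "no-op")
})

test_that("cascade survivors match an independent one-pass predicate, both support bases", {
  casc <- suppressWarnings(
    run_candidate_cascade(tiny_cohort$variants, tiny_cohort$lines)
  )
  for (basis in c("alt_reads", "total_reads")) {
    cfg <- filter_config(support_basis = basis)
    got <- run_candidate_cascade(tiny_cohort$variants, tiny_cohort$lines, cfg)
    res_ids <- tiny_cohort$lines$line_id[tiny_cohort$lines$phenotype == "resistant"]
    focal <- dplyr::filter(tiny_cohort$variants, line_id %in% res_ids)
    comp <- dplyr::filter(tiny_cohort$variants, !line_id %in% res_ids)
    keep <- oracle_cascade_keep(focal, paste(comp$chrom, comp$pos, comp$alt), cfg)
    expect_setequal(variant_key(got$candidates), variant_key(focal[keep, ]))
  }
})

test_that("the audit trail covers every focal record exactly once", {
  casc <- run_candidate_cascade(tiny_cohort$variants, tiny_cohort$lines)
  res_ids <- tiny_cohort$lines$line_id[tiny_cohort$lines$phenotype == "resistant"]
  focal <- dplyr::filter(tiny_cohort$variants, line_id %in% res_ids)
  expect_equal(nrow(casc$audit), nrow(focal))
  expect_setequal(variant_key(casc$audit), variant_key(focal))
  expect_equal(sum(is.na(casc$audit$removed_by)), nrow(casc$candidates))
  expect_true(all(stats::na.omit(casc$audit$removed_by) %in%
    c("no_depth", "support_window", "alt_fraction", "uv_spectrum",
      "nonallelic_subtraction")))
})

test_that("the cascade equals the conjunction of its predicates in any order", {
  cfg <- filter_config()
  res_ids <- tiny_cohort$lines$line_id[tiny_cohort$lines$phenotype == "resistant"]
  focal <- dplyr::filter(tiny_cohort$variants, line_id %in% res_ids)
  comp <- dplyr::filter(tiny_cohort$variants, !line_id %in% res_ids)
  steps <- list(
    support = function(x) filter_by_support(x, cfg),
    fraction = function(x) filter_by_allele_fraction(x, cfg),
    spectrum = function(x) filter_by_uv_spectrum(x, cfg),
    subtract = function(x) suppressWarnings(subtract_nonallelic_lines(x, comp))
  )
  reference <- run_candidate_cascade(tiny_cohort$variants, tiny_cohort$lines,
                                     cfg)$candidates
  set.seed(1)
  for (i in 1:6) {
    out <- focal
    for (f in sample(steps)) out <- f(out)
    expect_setequal(variant_key(out), variant_key(reference))
  }
})

test_that("the cascade is idempotent and survivors are a subset of the input", {
  first <- run_candidate_cascade(tiny_cohort$variants, tiny_cohort$lines)
  again_input <- dplyr::bind_rows(
    first$candidates %>% dplyr::select(-support, -alt_fraction),
    dplyr::filter(tiny_cohort$variants,
                  !line_id %in% unique(first$candidates$line_id) |
                    !(line_id %in% tiny_cohort$lines$line_id[
                      tiny_cohort$lines$phenotype == "resistant"]))
  )
  second <- suppressWarnings(
    run_candidate_cascade(again_input, tiny_cohort$lines)
  )
  expect_setequal(variant_key(second$candidates), variant_key(first$candidates))
  expect_true(all(variant_key(first$candidates) %in%
                  variant_key(tiny_cohort$variants)))
})

test_that("spiked causal variants survive the cascade; shared background does not", {
  casc <- run_candidate_cascade(tiny_cohort$variants, tiny_cohort$lines)
  truth <- tiny_cohort$truth
  causal_key <- paste(truth$causal$line_id, truth$causal$chrom,
                      truth$causal$pos, truth$causal$alt)
  expect_true(all(causal_key %in% variant_key(casc$candidates)))
  bg_key <- paste(truth$background$chrom, truth$background$pos,
                  truth$background$alt)
  surv_key <- paste(casc$candidates$chrom, casc$candidates$pos,
                    casc$candidates$alt)
  expect_length(intersect(bg_key, surv_key), 0L)
})

test_that("an empty cohort yields an empty candidate set with a complete audit", {
  empty <- tiny_cohort$variants[0, ]
  out <- suppressWarnings(run_candidate_cascade(empty, tiny_cohort$lines))
  expect_equal(nrow(out$candidates), 0L)
  expect_equal(nrow(out$audit), 0L)
})
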