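#' Simulate an MS/MS precursor-ion-scan peak table
#'
#' Emits a parent compound peak, exactly one true derivative at
#' `parent_mz - loss_da` carrying *all* of the parent's required fragment
#' ions, and `n_decoys` decoy peaks that share at most one required
#' fragment (or none), so the derivative is the unique peak a
#' fragment-sharing search should return.
#'
#' @param parent_mz Parent precursor m/z (singly charged assumed).
#' @param fragments Numeric vector of the parent's dominant fragment m/z
#'   values; non-empty.
#' @param loss_da Neutral-loss delta in Da; positive.
#' @param n_decoys Number of decoy peaks.
#' @param seed Integer seed (own labelled stream).
#' @param rt_parent,rt_derivative Retention times (minutes).
#' @return A peak tibble: `peak_id`, `sample_id`, `rt`, `precursor_mz`,
#'   `ion_count`, and a `fragments` list-column of tibbles (`mz`,
#'   `intensity`).
#' @examples
#' peaks <- sim_precursor_scan(439.1, c(247.1, 219.1), 45, n_decoys = 5,
#'                             seed = 1)
#' @export
sim_precursor_scan <- function(parent_mz, fragments, loss_da, n_decoys = 20L,
                               seed = 1L, rt_parent = 8.99,
                               rt_derivative = 9.25) {
  if (length(fragments) == 0L) abort("`fragments` must be non-empty.")
  if (loss_da <= 0) abort("`loss_da` must be positive.")
  if (any(fragments >= parent_mz)) {
    abort("Fragment m/z must be below the precursor m/z.")
  }
  with_stream(seed, "peaks", {
    frag_tbl <- function(mz) {
      tibble(mz = mz, intensity = round(runif(length(mz), 1e3, 1e5)))
    }
    deriv_mz <- parent_mz - loss_da
    rows <- list(
      tibble(peak_id = "parent", rt = rt_parent, precursor_mz = parent_mz,
             ion_count = round(runif(1, 1e5, 1e6)),
             fragments = list(frag_tbl(fragments))),
      tibble(peak_id = "derivative", rt = rt_derivative,
             precursor_mz = deriv_mz,
             ion_count = round(runif(1, 1e4, 1e5)),
             fragments = list(frag_tbl(fragments)))
    )
    if (n_decoys > 0L) {
      # decoy precursors kept >= 2 Da away from parent and derivative
      decoy_mz <- numeric(0)
      while (length(decoy_mz) < n_decoys) {
        cand <- round(runif(2L * n_decoys, min = 150, max = parent_mz + 150), 1)
        cand <- cand[abs(cand - parent_mz) > 2 & abs(cand - deriv_mz) > 2]
        decoy_mz <- c(decoy_mz, cand)
      }
      decoy_mz <- decoy_mz[seq_len(n_decoys)]
      shares_one <- runif(n_decoys) < 0.5
      decoy_frag <- lapply(seq_len(n_decoys), function(i) {
        n_extra <- sample(2:4, 1)
        # random fragments kept away from every required fragment
        extra <- numeric(0)
        while (length(extra) < n_extra) {
          cand <- round(runif(2L * n_extra, 50, decoy_mz[i] - 5), 1)
          cand <- cand[vapply(cand,
                              function(m) all(abs(m - fragments) > 2),
                              logical(1))]
          extra <- c(extra, cand)
        }
        mz <- extra[seq_len(n_extra)]
        if (shares_one[i] && decoy_mz[i] > max(fragments) + 5) {
          mz <- c(sample(fragments, 1L), mz[-1])
        }
        frag_tbl(sort(mz))
      })
      rows <- c(rows, list(tibble(
        peak_id = sprintf("decoy%03d", seq_len(n_decoys)),
        rt = round(runif(n_decoys, 1, 14), 2),
        precursor_mz = decoy_mz,
        ion_count = round(runif(n_decoys, 1e3, 1e5)),
        fragments = decoy_frag
      )))
    }
    bind_rows(rows) %>% mutate(sample_id = "sim", .before = 1)
  })
}

#' Find precursors sharing a parent's fragment ions
#'
#' Scans a precursor-ion peak table for every non-parent precursor whose
#' fragment list contains *all* of the required fragment ions within
#' `mz_tol` -- the signature of a structurally related derivative.
#' Retention time is reported but not used for matching. Precursor m/z
#' differences are read directly as mass deltas (singly charged, [M+H]+).
#'
#' @param peaks Peak tibble (see [sim_precursor_scan()]; the `fragments`
#'   list-column holds tibbles with an `mz` column).
#' @param parent_mz Parent precursor m/z; a peak within `mz_tol` of it must
#'   be present in the table.
#' @param required_fragments Fragment m/z values that must all be matched.
#' @param mz_tol Match tolerance in Da (default 0.5, unit resolution).
#' @return Tibble of candidates: `peak_id`, `rt`, `precursor_mz`,
#'   `delta_mass` (parent minus candidate), `matched_fragments`,
#'   `ion_count`.
#' @export
find_fragment_sharing_precursors <- function(peaks, parent_mz,
                                             required_fragments,
                                             mz_tol = 0.5) {
  if (length(required_fragments) == 0L) {
    abort("`required_fragments` must be non-empty.")
  }
  if (mz_tol <= 0) abort("`mz_tol` must be positive.")
  is_parent <- abs(peaks$precursor_mz - parent_mz) <= mz_tol
  if (!any(is_parent)) {
    abort(sprintf("No parent peak at m/z %.4g found in the table.", parent_mz))
  }
  candidates <- peaks[!is_parent, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    return(tibble(peak_id = character(), rt = numeric(),
                  precursor_mz = numeric(), delta_mass = numeric(),
                  matched_fragments = character(), ion_count = numeric()))
  }
  hit <- vapply(candidates$fragments, function(ft) {
    all(vapply(required_fragments,
               function(f) any(abs(ft$mz - f) <= mz_tol), logical(1)))
  }, logical(1))
  out <- candidates[hit, , drop = FALSE]
  tibble(
    peak_id = out$peak_id,
    rt = out$rt,
    precursor_mz = out$precursor_mz,
    delta_mass = parent_mz - out$precursor_mz,
    matched_fragments = paste(required_fragments, collapse = ","),
    ion_count = out$ion_count
  )
}

#' Default neutral-loss annotation table
#'
#' Small editable table of common neutral losses plus the nitro-replacement
#' delta relevant to nitro-group-bearing phytotoxins. The 45 Da entry is
#' labelled putative: a 45 Da delta is *consistent with* replacing NO2 by
#' H, not proof of it.
#'
#' @return Tibble with `mass` (Da) and `label`.
#' @export
default_neutral_losses <- function() {
  tibble(
    mass = c(45.0, 18.011, 17.027, 27.995, 43.990),
    label = c(
      "nitro group replaced by hydrogen (-NO2 +H; putative)",
      "water loss (-H2O)",
      "ammonia loss (-NH3)",
      "carbon monoxide loss (-CO)",
      "carbon dioxide loss (-CO2)"
    )
  )
}

#' Annotate a neutral-loss delta mass
#'
#' Returns the label of the closest loss-table entry within `mass_tol`,
#' else `"unassigned"`.
#'
#' @param delta_mass Numeric vector of deltas (Da).
#' @param loss_table Tibble with `mass` and `label` columns.
#' @param mass_tol Tolerance in Da (default 0.3).
#' @return Character vector of annotations.
#' @export
annotate_neutral_loss <- function(delta_mass,
                                  loss_table = default_neutral_losses(),
                                  mass_tol = 0.3) {
  if (mass_tol <= 0) abort("`mass_tol` must be positive.")
  vapply(delta_mass, function(dm) {
    dist <- abs(loss_table$mass - dm)
    i <- which.min(dist)
    if (length(i) == 1L && dist[i] <= mass_tol) loss_table$label[i]
    else "unassigned"
  }, character(1))
}

#' Compare derivative ion counts between two genotypes
#'
#' Two-sided two-sample Student's t-test (pooled variance) on ion counts,
#' optionally weight-normalised upstream. Reports the direction of the
#' non-reference genotype relative to the reference.
#'
#' @param counts Tibble with `genotype` and `ion_count` columns; exactly
#'   two genotypes, at least 2 samples each.
#' @param reference The wild-type/reference genotype name.
#' @param welch Use the Welch test instead of pooled variance.
#' @return One-row tibble: `genotype`, `reference`, `mean`, `reference_mean`,
#'   `direction` (`"lower"`, `"higher"`, `"none"`), `p_value`.
#' @export
compare_ion_counts <- function(counts, reference, welch = FALSE) {
  gts <- unique(counts$genotype)
  if (length(gts) != 2L || !reference %in% gts) {
    abort("`counts` must contain exactly two genotypes including `reference`.")
  }
  other <- setdiff(gts, reference)
  x <- counts$ion_count[counts$genotype == other]
  y <- counts$ion_count[counts$genotype == reference]
  if (length(x) < 2L || length(y) < 2L) {
    abort("Each genotype needs at least 2 samples; add replicates.")
  }
  p <- pooled_t_p(x, y, welch = welch)
  direction <- if (isTRUE(all.equal(mean(x), mean(y)))) "none"
    else if (mean(x) < mean(y)) "lower" else "higher"
  tibble(genotype = other, reference = reference,
         mean = mean(x), reference_mean = mean(y),
         direction = direction, p_value = p)
}
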