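---
title: "Methods: mutation triage and resistance quantification in UV screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation triage and resistance quantification in UV screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbiscreen)
library(dplyr)
```

herbiscreen implements the computational side of a forward-genetic
herbicide-resistance screen in a haploid plant: UV-mutagenized clonal lines
are selected on a lethal herbicide dose, survivors are whole-genome
sequenced, and the candidate causal mutation is triaged by a filter cascade
plus recurrence across independent mutants. Around that core sit the
quantitative phenotyping tools the same study design needs: log-logistic
dose-response fits with resistance metrics, and MS/MS precursor-scan
annotation of herbicide metabolites.

## The candidate-mutation filter cascade

Each sequenced line contributes a set of single-nucleotide mismatch calls
with strand-split read support (`DP4` = ref-forward, ref-reverse,
alt-forward, alt-reverse). Four per-record predicates are applied in order:

1. **Read support.** Keep records supported by 7--100 reads, both bounds
   inclusive. "Supported" is read as reads carrying the alternative allele
   (`DP4[3]+DP4[4]`); whether the original rule meant alternative-allele or
   total depth is not decidable from its wording, so
   `filter_config(support_basis = "total_reads")` switches the basis and
   both are exercised in the tests.
2. **Allele fraction.** Keep records with
   `(DP4[3]+DP4[4])/sum(DP4) > 0.5`, strictly: a haploid clone should be
   near-fixed for a real mutation, and an exact 50/50 tie is removed. The
   source rule is stated both as a weak inequality in prose and as a strict
   expression; the strict expression governs here.
3. **UV-B spectrum.** Keep canonical UV-B changes only -- C>T and G>A on
   the reference strand, the two reverse-complement images of the
   pyrimidine-dimer lesion class. Non-SNV records are removed.
4. **Non-allelism subtraction.** Remove any variant whose (chrom, pos, alt)
   appears in the *raw* call set of any line without the phenotype.
   Comparing against raw rather than filtered comparator calls is the more
   conservative choice: a variant weakly called in a sensitive line is
   still evidence it does not confer resistance.

Each predicate is pure and per-record given fixed comparator sets, so the
surviving set is invariant to filter order (a property the tests assert by
permuting the order); the order above only decides which filter the audit
trail blames for a removal. Candidates are then restricted to coding
sequence and to changes that alter the encoded amino acid, using
strand-aware spliced-CDS arithmetic under the standard genetic code. A
variant overlapping several gene models is kept if it changes the protein
in any of them. Intronic, UTR and splice-site positions count as non-CDS;
no splice-disruption logic is attempted.

Manual inspection of alignments (used in the original workflow to discard
misaligned or low-quality calls) is not reproducible and is not emulated;
the audit trail and the `shared_identical` flag are the automated
substitutes for human judgement calls.

## Convergence across independent mutants

`build_convergence_report()` ranks genes by the number of distinct
resistant lines carrying at least one surviving candidate in them. Two
variants in one gene in one line count once: recurrence is a line-level
statement about independent mutational events. Ties break by total
candidate count, then gene id. No enrichment statistic is computed -- with
a handful of lines and genes the raw recurrence count is the evidence, and
the report carries CDS length per gene so a reader can judge whether a
long gene's recurrence is surprising. Identical variants shared by two or
more lines are flagged (possible clonal sharing or artifact) but never
removed, since removal would silently break the independence accounting.

## Dose-response model and resistance metrics

Growth is summarised as the living-tissue area of plantlets after growth
on a dose series. The model is the four-parameter log-logistic with the
lower asymptote fixed at 0:

$$f(x) = \frac{d}{1 + \exp\!\big(b(\log x - \log e)\big)}, \qquad f(0) := d$$

where `d` is the untreated response, `b` the slope, and `e` the dose at
half-maximal response (the IC50). Vehicle controls (dose 0) enter at the
upper asymptote, the model's limit for positive slope. Fitting is
Levenberg-Marquardt least squares (`minpack.lm`), started at `d0` = largest
mean area, `e0` = tested dose nearest half of `d0`, `b0 = 1`, with three
perturbed restarts; a fit that still fails is returned flagged rather than
silently replaced. Standard errors come from the local curvature of the
objective.

Three metrics follow the screen's conventions:

- **IC50** is the fitted `e`.
- **LD100** is the smallest *tested* dose at which every replicate's area
  is at or below `zero_epsilon` (default exactly 0, matching an imaging
  pipeline that reports 0 when no autofluorescing tissue remains);
  right-censored at the maximum tested dose otherwise.
- **RI** (resistance index) is the mutant IC50 over a conservatively chosen
  wild-type reference: the *most resistant* wild type for resistance
  claims, the *most sensitive* for sensitivity claims, so the claim is
  always made against the least favourable baseline. The study prints RI
  uncertainties as unqualified "±" values; here the RI standard error is
  first-order (delta-method) propagation of the two IC50 standard errors,
  and that choice is documented rather than hidden.

Resistance *classification* at a single screening dose uses two two-sided
two-sample Student's t-tests (pooled variance, matching the name; Welch
behind a flag): a line is resistant only if it is significantly larger
than *each* wild-type line and its mean exceeds both. Groups with zero
variance and equal means get p = 1 by convention. Under the null this
dual test with the mean-ordering constraint calls resistance at roughly
(α/2)² times a correlation inflation (the mutant sample is shared between
the two tests); the acceptance suite checks the empirical rate against the
exact bivariate-normal orthant value computed by quadrature.

## Metabolite annotation from precursor-ion scans

A precursor-ion scan finds all precursors that yield a given fragment ion.
A derivative of the parent compound is expected to share the parent's
dominant fragment ions while its precursor mass shifts by the modification.
`find_fragment_sharing_precursors()` returns every non-parent precursor
whose fragment list contains *all* required fragments within a unit-scale
tolerance (0.5 Da default, appropriate for triple-quadrupole data), and
reports the precursor mass difference directly as a neutral-loss delta --
a singly-charged [M+H]+ reading, which is how the 439.1 − 394.1 = 45 Da
arithmetic works. Retention time is reported but never used for matching.
The default loss table labels 45.0 Da as replacement of a nitro group by
hydrogen and marks it putative: a mass delta is consistent with a
structure, not proof of it. Genotype comparisons of derivative ion counts
use the same pooled t-test as the growth classification.

## What the synthetic cohort emulates

`sim_config()` + `sim_reference()` + `sim_uv_cohort()` generate every input
the pipeline consumes, with ground truth. The defaults emulate the screen's
design: 13 resistant lines against 4 sensitive comparators, one causal gene
carrying a non-synonymous canonical variant in 3 independent resistant
lines, 50 shared clonal background variants, private mutations at
Poisson(75) per line with 75% canonical (C>T/G>A) spectrum, and DP4 depths
of 20--80 reads with Beta(18, 2) alternative-allele fractions (haploid
calls sit near fixation).

The genome is scaled down -- 8 Mb, one chromosome, 4000 genes of 300--900 bp
CDS in 1--3 exons on both strands -- chosen so that two things hold at
once: the post-triage candidate count per line lands in the screen's
reported 6--27 window (expected ≈ 75 × 0.30 coding fraction × 0.75
canonical × ≈0.75 non-synonymous × ≈0.97 depth-pass ≈ 12), and gene-level
collisions between lines stay rare enough that the spiked gene uniquely
tops the convergence ranking in ≥95% of seeds (expected background genes
hit by ≥3 of 13 lines ≈ C(13,3)·c³/G² ≈ 0.03 at c = 12 candidates and
G = 4000 genes). These sizes are the package's choice of a tractable
stand-in for a ~220 Mb genome with ~19k genes; on the real genome
collisions are rarer still, so the scaled-down recovery rate is the harder
test. Per-line mutation load after UV mutagenesis is not reported anywhere
we can check, so Poisson(75) is calibration to the post-filter window, not
a measured rate.

What the generator does *not* emulate: read-level errors (inputs start at
variant calls, as the pipeline's contract says), alignment artifacts and
mapping bias (the very things the original workflow removed by manual
inspection), indels and structural variants (the spectrum filter would
discard them anyway), linked selection or any population structure, and
isoform complexity beyond multi-exon single-transcript genes. Passing
tests on synthetic cohorts therefore demonstrate the *logic* of the triage
is correct under the stated noise model -- they say nothing about
upstream calling quality on real data.

Determinism: every generator draws from its own RNG stream derived from
the master seed by a fixed labelled offset, so the genome, cohort, growth
tables and peak tables can be regenerated independently and byte-identical
(FASTA/GFF3/VCF writers are covered by byte-level tests).

## The synthetic benchmark assays

The study's quantitative growth measurements live in a supplementary
workbook that is not redistributable with this package, so
`sim_benchmark_assays()` generates *synthetic* stand-in tables whose
generating parameters are set to the published values: wild-type thaxtomin
A IC50s of 56 and 135 nM (n = 18) with LD100 at 5 µM, mutant thaxtomin A
RIs of 9.1 and 4.1 against the more resistant wild type (n = 3), an H2O2
RI of 0.64 against the more sensitive wild type, a paraquat LD100 of
3.3 µM, isoxaben RIs of 4.22/3.94, a 2,4-D RI of 0.33, and a UV-B
half-lethal exposure of 110 s (dose = seconds of irradiation; the same
curve machinery applies unchanged). Replicate noise is additive Gaussian
with SD 5 on a response scale of d = 100, sampled from the conditional
distribution on [0, ∞) so live doses never report exactly zero; means
below a detection floor of 0.2 area units are recorded as 0 -- complete
kill is a qualitative event in the imaging, and this makes the simulated
LD100 exact. Curve slopes (b = 2--4 by compound) are chosen so the
designed LD100s fall at the published tested doses.

Refitting these tables through `fit_log_logistic_4p()`,
`estimate_ld100()` and `compute_resistance_index()` checks that the
package's conventions (reference-line choice, f(0) = d handling of
controls, the all-replicates-dead LD100 rule, delta-method RI errors)
recover the designed values within the published uncertainty bands. It is
a round-trip of the machinery at the study's conditions, not a reanalysis
of the original measurements.

## Numerical choices and degenerate inputs

- Records with zero or missing total depth are removed with audit reason
  `no_depth`, never silently dropped.
- Multi-allelic VCF records are split into biallelic records before
  filtering, each inheriting the site's DP4.
- Gene models whose concatenated CDS length is not divisible by 3 are
  dropped with a warning at GFF3 read time, not silently used.
- An all-dead dose-response table is a fit error ("no surviving tissue"),
  and fewer than 4 distinct doses refuses to fit.
- A reference VCF/FASTA base mismatch aborts with the offending
  coordinate: it means the inputs do not belong together.
- Mass-tolerance defaults (0.5 Da precursor/fragment match, 0.3 Da loss
  annotation) reflect unit-resolution triple-quadrupole data and are
  configurable.

## Problem sizes used in the checks

The shipped verification suite runs the filter-cascade oracle on 50
seeded cohorts of ≥1000 records, codon-effect agreement on 10^4 random
variants re-translated in full by an independent route, causal-gene
recovery on 100 default cohorts, 4PL recovery on 100 noisy refits, and
the null calibration on 10^4 simulated screens of 30 replicates per
group. These sizes make the Monte-Carlo error small against every margin
tested while the whole suite stays comfortably runnable on a laptop.

## Known limitations

- The support-basis ambiguity (alternative vs total reads) is resolved by
  a documented default, not by evidence.
- Candidate counts per line depend on calibration (mutation load is not
  reported in the source material); the 6--27 window is matched by
  design, not discovered.
- The dual-t-test classification applies no multiple-testing correction
  across lines, faithfully mirroring the original analysis.
- LD100 is a tested-dose statistic: it is only as fine as the dose grid.
- The nitro-loss annotation is putative by construction; confirming a
  metabolite structure needs authentic standards, not mass deltas.
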