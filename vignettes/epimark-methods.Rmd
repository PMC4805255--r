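---
title: "Methods: MS-AFLP scoring, epigenetic differentiation, and CpG depletion signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MS-AFLP scoring, epigenetic differentiation, and CpG depletion signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimark)
```

epimark implements three complementary ways of reading DNA methylation in a
non-model organism without a reference genome: methylation-sensitive AFLP
(MS-AFLP) profiles scored into population-level epigenetic statistics,
per-cytosine calls from bisulfite conversion of a single amplicon, and the
evolutionary footprint of germline methylation in transcriptome dinucleotide
composition. This vignette explains the models behind each, the parameters
that matter, and the design decisions taken where conventions in the field
genuinely diverge.

## MS-AFLP scoring

Each DNA sample is digested in two parallel reactions with the isoschizomers
MspI and HpaII, which share the CCGG recognition site but differ in
methylation sensitivity: HpaII is blocked when the internal cytosine is
methylated, MspI is not. Scoring fragment presence/absence in both reactions
gives one of four patterns per individual and locus (written MspI/HpaII):

* `1/1` — both bands: unmethylated site;
* `1/0` — MspI only: internal cytosine methylated;
* `0/1` — HpaII only: treated as an *unspecific product*, not as
  hemimethylation, because both enzymes fail to cut when the external
  cytosine is methylated and external-cytosine methylation is not CpG
  methylation anyway;
* `0/0` — no band: uninformative (hypermethylation or restriction-site
  absence are indistinguishable).

`combine_digests()` performs this pairing losslessly; `split_digests()`
inverts it.

**MSL classification.** A locus is *methylation-susceptible* (MSL) when the
proportion of individuals showing a methylated pattern (`1/0` or `0/1`)
*exceeds* an error-rate threshold, 5% by default, mirroring the default of
AFLP scoring-error models. Two conventions exist for the denominator; the
package defaults to individuals with informative data (non-`0/0`) at the
locus and exposes `denominator = "all"` for the alternative, since published
scoring tools do not document their choice unambiguously. The inequality is
strict: exactly 5% methylated stays nonmethylated (NML).

**Marker encodings.** Two binary encodings are produced. The *MSL binary*
scheme scores each MSL locus 1 (methylated pattern) / 0 (unmethylated), with
`0/0` missing by default — the package deliberately does not read no-digestion
as hypermethylation, though `uninformative = "methylated"` reproduces that
convention. The *Mixed Scoring 2* scheme expands each locus into up to three
epiloci (`u` = `1/1`, `m` = `1/0`, `h` = `0/1`), creating an epilocus only for
conditions observed in at least one individual anywhere (not per group — the
only reading that gives fixed marker totals across groups). Uninformative
individuals score 0, not missing, at all epiloci of the locus, keeping rows
complete for downstream diversity calculations; per individual and locus at
most one of the three epiloci carries a 1.

## Diversity and differentiation

Within groups, `diversity_report()` tabulates per marker type: the number and
percentage of polymorphic markers (both alleles present among non-missing
entries), the percentage of private markers, and the mean Shannon information
index $I = -(p\ln p + (1-p)\ln(1-p))$ over markers, with $0\ln 0 = 0$ and
natural logarithms (the base used by the classic dominant-marker scripts is
undocumented; natural log is the default here, bounding $I$ by $\ln 2$).
"Private" defaults to the per-group reading — presence observed in exactly one
group — with the stricter per-individual reading behind `per = "individual"`,
because the phrase "pattern seen in just one sample" is ambiguous in the
literature this follows.

Among groups, `amova_phi()` estimates the fixation-index analogue
$\Phi = \sigma^2_{among} / (\sigma^2_{among} + \sigma^2_{within})$ from an
analysis of molecular variance on pairwise squared Euclidean distances
between binary rows — the distance convention shared by the msap-style
$\Phi_{ST}$ and the GenAlEx-style PhiPT, which makes the two labels one
estimator applied to different encodings (the package labels results by input
scheme). Variance components use the standard unbalanced two-level
estimators with $n_0 = (N - \sum n_g^2/N)/(k-1)$. Design choices:

* Missing entries are handled pairwise-complete, rescaling each distance by
  $L/L_{complete}$, which keeps distances comparable across pairs with
  different missingness.
* Significance is by permutation of individuals among groups with group
  sizes fixed, default 10,000 permutations, with the add-one rule
  $p = (1 + \#\{\Phi_\pi \ge \Phi\})/(B+1)$, so $p \ge 1/(B+1)$ and never 0.
* Exceedances are counted with a $10^{-12}$ tolerance: with binary markers
  and small samples, distinct relabelings frequently yield mathematically
  identical $\Phi$, and bitwise comparison would drop ties that differ only
  by floating-point summation order. The tolerance is orders of magnitude
  below any real difference between partitions.
* Negative $\Phi$ estimates, expected under no differentiation, are reported
  as computed and never truncated at zero.
* Global mode is a one-level AMOVA over all groups; only the two-level
  (among/within) partition is implemented — no hierarchical nesting.

`pairwise_differentiation()` applies the same test to every pair of groups;
`render_pairwise_table()` produces the conventional square table with
statistics below and p-values above the diagonal, rounded (3 decimals) only
at render time.

## Bisulfite methylation calling

Bisulfite treatment converts unmethylated cytosines to uracil, read as
thymine after sequencing, while 5-methylcytosine is protected.
`align_converted()` places the converted fragment on the untreated reference
by exhaustive offset scan under bisulfite-aware equality (reference C pairs
with read C or T; everything else exact; N wild): conversion is
substitution-only, so gap-free placement is sufficient and indel-tolerant
alignment is deliberately excluded. Zero or multiple qualifying offsets are
errors — a reverse-strand read fails placement and is rejected rather than
silently reverse-complemented; only the forward (bisulfite top) strand is
modelled. `call_methylation()` then calls each reference cytosine in the
span: read C → methylated, T → unmethylated, N → uncallable, anything else a
data-integrity error. CpG context is taken from the untreated reference
(conversion destroys context in the read), a cytosine at the reference's last
position counting as non-CpG. Coordinates are 1-based on the reference.
Percentages are reported both at full precision and rounded to the nearest
integer. `conversion_rate()` — the fraction of non-CpG cytosines called
unmethylated — is the usual conversion-efficiency proxy, since animal
methylation outside CpG context is rare. Disagreements between multiple
reads of one amplicon are not adjudicated; each read is called separately.

## CpG observed/expected ratios

Persistent germline methylation depletes CpG over evolutionary time because
5-methylcytosine deaminates to thymine, converting CpG to TpG. For a
sequence of effective length $l$ (ambiguous N bases are excluded from all
counts and subtracted from $l$):

$$\mathrm{CpG~o/e} = \frac{n_{CpG}}{n_C \times n_G} \cdot \frac{l^2}{l-1}$$

with overlapping dinucleotide counts. The $l^2/(l-1)$ factor — the sequence
has $l-1$ dinucleotide windows — is the default; `length_correction =
"simple"` gives the plain factor $l$ common elsewhere in the literature. The
same formula applied to GpC (same composition, no methylation target) is the
negative control expected near 1, and TpG o/e is the positive control:
`depletion_correlation()` reports the Pearson correlation between TpG and
CpG o/e across contigs, negative when deamination drives the depletion,
plus means and kernel-density tables for all three ratios. Undefined ratios
(a zero mononucleotide count) are flagged NA, never dropped silently.

Contig filtering (`filter_contigs()`) keeps ORF-containing contigs with at
least one biological-process GO term and a mean FPKM of at least 10 in at
least one condition — unweighted contig-level values; expression is consumed
as an input table, never computed. `assign_goslim()` maps GO terms through a
user-supplied GO→GO Slim table: a contig joins every bin its terms map to but
each bin at most once; unmapped terms are logged and term-less contigs are
excluded from category statistics. The bundled
`extdata/demo_goslim_map.tsv` is a small synthetic demonstration mapping,
not an authoritative GO Slim. `category_stats()` reports per-bin mean and
SEM (sample SD/$\sqrt{n}$), one-way ANOVA across bins, and all pairwise
t-tests with the pooled SD; `group_contrasts()` compares the two
expression-defined contig sets bin by bin and reports which group's mean is
higher. P-values are raw by default — a Holm option exists but is off —
matching the way such category scans are conventionally reported.

## The simulators: what they emulate, and what they do not

`simulate_msap()` draws each individual × locus state from its group's
4-vector over the band patterns and decomposes it into the two digests,
flipping each band call independently with `scoring_error_rate` (the digests
are separate reactions). The default design (`msap_sim_defaults()`) is four
groups of 18/12/12/12 individuals at 165 loci with roughly a quarter of
informative cells methylated and half of cells uninformative — a realistic
shape for an invertebrate MS-AFLP survey. No published error-rate estimate
exists for this kind of scoring, so the default 5% mirrors the error-rate
rationale behind the MSL threshold; it is a free parameter. The simulator
does not model electropherograms, peak heights, fragment-size binning, or
locus linkage — states are independent across loci, so simulated data lack
the correlation structure real restriction profiles may carry.

`simulate_cpg_depletion()` draws iid sequences at a given GC content, flags
each CpG once as germline-methylated (`methylation_level`) — methylation is
per-site and stable, the regime the o/e statistic assumes — and then lets
each methylated, still-intact CpG mutate to TpG with `deamination_rate` per
round. Length is conserved. Real coding sequence is not iid (codon
structure, isochores, selection), so passing baselines on these sequences
shows the statistic behaves correctly, not that real transcriptomes are iid.

`simulate_bisulfite()` retains masked cytosines and converts the rest with
probability `conversion_efficiency`; at efficiency 1 the caller recovers the
mask exactly (a round-trip property the tests enforce). All generators
thread a single seeded RNG through every draw, so outputs are bit-reproducible
given (configuration, seed), and emit uppercase A/C/G/T only.

## Numerical choices and check sizes

Strict inequality at the MSL threshold; $0\ln 0 = 0$ in the Shannon index;
state-probability vectors validated to sum to 1 within $10^{-12}$; the
permutation tie tolerance above; rounding only at render time (3 decimals
for statistics, 1 for percentages, matching how such tables are printed).
The statistical checks in the test suite use sizes chosen to make sampling
error small relative to the asserted effects: 500 iid sequences of 2 kb for
the o/e ≈ 1 baseline, 200 contigs of 1 kb per methylation level for the
depletion monotonicity, 50 null replicates at 1,000 permutations for
p-value calibration, and exhaustive 20-way enumeration against 10,000
permutations on 6-individual data for the AMOVA oracle.

## Limitations

MS-AFLP reads methylation only at CCGG sites and cannot separate
hypermethylation from site absence (`0/0`); the per-locus states are
anonymous, so nothing links an epilocus to a genomic feature. The AMOVA is
two-level only. The bisulfite caller handles one strand, no indels, and no
mixed (partially methylated) peaks. CpG o/e is an evolutionary signal of
*germline* methylation, not a measurement of current methylation in any
tissue. Small-sample bias of $\Phi$ is documented behaviour, not corrected.

```{r example, eval = FALSE}
sim <- do.call(simulate_msap, c(msap_sim_defaults(), list(seed = 7)))
res <- run_msap_pipeline(sim$mspI, sim$hpaII, n_permutations = 10000, seed = 1)
res
render_pairwise_table(res$pairwise_msl, res$pairwise_m)
```
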