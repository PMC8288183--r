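---
title: "Methods: models, filters and design choices in m5Ctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, filters and design choices in m5Ctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical model behind each step, the defaults and why they are set where
they are, what the synthetic-data generator does and does not emulate, and
the numerical choices a maintainer would want written down.

## 1. The bisulfite observation model and site calling

Bisulfite treatment deaminates unmethylated cytosines to uracil; methylated
cytosines resist. At a cytosine with true methylation level $m$ and
per-sample conversion rate $c$, a read reports C with probability

$$p_{\mathrm{obs}} = m + (1 - m)(1 - c),$$

so the observed C fraction estimates $m$ with an additive floor of
$(1-m)(1-c)$ — the *non-conversion floor*. The methylation level is defined
as unconverted/coverage exactly, with no back-correction for $c$: levels
stay interpretable as raw fractions, and published threshold comparisons
(≥ 0.1, < 0.05) apply to the same quantity they were stated for.

`count_conversions()` counts, per reference cytosine, reads showing C
(unconverted) and reads showing C or T (coverage); reads with any other
base at the position are treated as sequencing/alignment noise and excluded
from both counts. Counting is strand-aware; in genome mode reference Gs are
additionally counted as minus-strand cytosines via G/A.

`estimate_conversion_rate()` is a one-iteration trimmed estimator: a first
pass discards cytosines with apparent level ≥ 0.1 (putative genuine sites),
and the rate is $1 - \sum \text{unconverted} / \sum \text{coverage}$ over
the rest. With a site fraction of a few percent this recovers $c$ to within
±0.002 at ordinary depths; the trim level is exposed because heavily
methylated transcriptomes would need a stricter cut.

`call_sites()` calls a cytosine iff

* coverage ≥ 20 reads (10 in tRNA mode) — the published coverage filter;
* level ≥ 0.1 — the published level filter;
* unconverted reads ≥ 3, and
* Benjamini–Hochberg adjusted one-sided binomial
  $P[X \ge \text{unconverted}]$, $X \sim \mathrm{Bin}(\text{coverage},
  1-c)$, at FDR ≤ 0.05.

The first two filters follow the published analysis; the last two are this
package's statistical-soundness additions (the upstream discovery
framework's full signal filters are not publicly specified) and are exposed as
configuration, not claimed as fidelity. The BH universe is all cytosines
passing the coverage filter. p-values use `stats::pbinom` and agree with an
exact tail summation to 10⁻¹², which the test suite asserts.

Dependency calling (`classify_dependency`) compares a wild-type call set
against knockout (and optionally rescue) levels: a site called in wild type
and covered (≥ 20) in the knockout is *dependent* when its knockout level
is < 0.05, *independent* otherwise, *rescued* when additionally the rescue
level is ≥ 0.05, and *unresolved* when coverage fails. Comparisons use the
printed thresholds with exact ≥/< semantics; levels are kept as exact
fractions and never rounded before comparison.

## 2. Motif typing

Type II: the four bases at +1..+4 equal UCCA, an exact string match — no
mismatches, because the UCCA motif is the robust signature of the class and
fuzzy matching would manufacture false Type II assignments. Type I is
operationalized as a GGG triplet anywhere within +2..+6; the G-rich motif
is described only loosely in the literature, so both the pattern and the
window are configuration with these defaults. On the rare double match,
Type II wins. All classification happens on RNA-alphabet, strand-corrected
context strings whose centre base must be C; a non-C centre is a hard error
because it always indicates stale coordinates.

## 3. Secondary structure: folding, geometry, metaprofiles

`fold_window()` implements Nussinov-style base-pair maximization over
Watson–Crick plus G–U wobble pairs with a minimum hairpin loop of 3 nt.
Among co-optimal structures the engine maximizes the number of stacked
pairs (pairs whose inner neighbour is also paired) as a secondary
objective, then breaks remaining ties with a deterministic traceback
(outer pair first, then smallest partner index), so identical input always
gives an identical dot-bracket. The stacking objective stands in for the
thermodynamic preference for contiguous helices in a free-energy folder;
an adapter accepts externally computed dot-bracket strings (e.g. RNAfold
output) wherever a FoldResult is consumed, for fidelity runs against a
thermodynamic model. The engine's pair counts are verified against
exhaustive enumeration for sequences up to 14 nt.

`hairpin_geometry()` reads loop and stem length off the structure: the
innermost pair enclosing the site with no pairs between defines the hairpin
loop; the stem is counted walking outward through the enclosing helix,
tolerating bulges/internal loops up to 2 nt per side (the tolerance is
configuration; the source analysis does not state one).

`pairing_metaprofile()` folds the ±50 nt window around each site and
reports, per offset in −25..+25, the fraction of sites paired there;
windows truncated by transcript ends are dropped and counted. The profile
of a set equals the mean of single-site profiles by construction, which the
suite asserts as a linearity property.

`sample_background()` draws the null: the pool is every cytosine followed
by UCCA on m⁵C-containing transcripts (transcripts carrying at least one
queried site), excluding called sites; 100 resamples of |sites| pool
members without replacement each yield a metaprofile, summarized as
pointwise median and quartiles. A pool smaller than the site count is a
hard error reporting the pool size; a pool exactly equal to the site count
degenerates to a fixed profile with a zero-width band, which is the
documented limiting behaviour.

Methylation stratification of binding sites uses the bins
[0, 1%), [1%, 10%), [10%, 100%] with the 10% boundary inclusive in the
high group.

## 4. Writer inference

`rank_writers()` correlates each candidate enzyme's expression across
samples with the per-sample Type II site count and sorts by descending
coefficient. Spearman is the default: expression units (TPM/FPKM, log or
linear) are unknown in general, and rank correlation is invariant to any
monotone transform of each row, which the suite asserts as scale
invariance. Pearson is available. Enzymes with zero expression variance
have no defined coefficient and rank last; remaining ties break by enzyme
id so ranking is a deterministic permutation. Fewer than three shared
samples is an error rather than a coefficient.

## 5. Reporter mutagenesis

`design_variant_library()` enumerates the four published perturbation
schemes around a Type II site insert: all $4^4 = 256$ core-motif
substitutions at +1..+4; flank substitutions (singles at −3 plus the full
4 × 4 grid at −2/+5); loop truncation (deleting the −2 and +5 loop bases)
and A₁–A₄ extensions (n adenosines added at both ends of the loop); and
stem disruptions replacing the C/G base of designated pairs with A on one
side. Which pairs each disruption variant breaks is a parameter (the
published design table is not machine-readable); perturbations that would
delete the target cytosine are rejected.

Barcodes are 10-mers over {A, G, T} with pairwise Hamming distance ≥ 3:
a C-free barcode cannot be altered by bisulfite conversion, so
demultiplexing is conversion-proof, and the distance margin leaves headroom
for an optional 1-mismatch rescue (`max_mismatch`). Quantification reports
unconverted/covered at the variant's target cytosine among assigned reads,
suppresses variants under 20 reads (the published reporting rule), and
flags variants whose reads disagree with the design at > 20 % of
non-cytosine positions as contaminated (cross-variant bleed-through or
synthesis errors). `position_max_profile()` reports, per motif position and
base, the maximum level over reported variants carrying that base — the
position-wise summary used to read off base preferences.

The generator's default effect rules encode the qualitative findings as
ground truth: the intact motif methylates at 0.8; +3 tolerates pyrimidines
at reduced level while purines abolish methylation; +5 A→G/C and −3 A→C/U
are strongly deleterious while −2 substitutions are tolerated; loop
truncation, progressive loop extension and increasing stem disruption tune
methylation down. These are generator truths for recovery testing, not
measurements.

## 6. RT-stall scoring

miCLIP-style reverse-transcription truncation concentrates read 5′ ends
adjacent to the crosslinked/modified base. `truncation_profile()` counts 5′
ends per offset in ±10 nt and scores stalling as the 5′-end count at
offset +1 divided by the mean per-base coverage of the window. The +1
convention (RT stops one nucleotide 3′ of the modified base on the cDNA
sense) is configuration, since the convention differs between protocols.
Sites with zero window coverage are flagged undefined rather than scored 0.
Profiles are translation-equivariant (shifting all reads shifts the
profile), which the suite asserts.

## 7. Translation analysis

Polysome-fraction methylation matrices are min–max normalized per site,
$L_{\mathrm{norm}} = (L - L_{\min})/(L_{\max} - L_{\min})$; rows without
dynamic range are set to 0 and flagged (the convention is arbitrary; the
flag lets downstream displays drop them). The support filter keeps sites
with ≥ 20 reads in ≥ 5 fractions. TE is RPF RPKM over mRNA RPKM with
RPKM $= 10^9 \cdot \text{count}/(\text{library size} \times \text{length})$;
the comparison set keeps genes with both RPKMs > 2 in every condition. TE
group comparisons use a one-sided two-sample Kolmogorov–Smirnov test on
log TE with the default direction "m⁵C genes lower", configurable; the KS
p-value is checked against a permutation oracle on small fixtures.
Localization enrichment uses a two-sided Mann–Whitney U test per
compartment on log₂ fold-change enrichments, with `stats::wilcox.test`'s
tie-corrected normal approximation on tie-heavy data.

## 8. The synthetic-data generator: what it emulates, and what it does not

The generator exists to plant *known, exactly recoverable* ground truth in
every input format the pipeline reads. Its defaults are the study
conditions exercised by the tests:

* conversion rate 0.995 (non-conversion floor 0.005, a typical RNA BS-seq
  residual), planted levels uniform on [0.1, 0.9];
* Type II hairpins with an 11-bp stem and a 7-nt loop (`CCC U CCA` around
  the site, UCCA at +1..+4), matching the mode of the observed stem/loop
  geometry; Type I sites with a downstream GGGG run at the 5′ side of a
  hairpin; motif-less methylated sites; and unmethylated background C-UCCA
  motifs for null resampling;
* per-sample Type II counts uniform on 5..169, the observed cross-sample
  range, with one planted writer whose sample Spearman correlation is
  constructed on the rank lattice to match the requested strength;
* a 0.7× TE multiplier on m⁵C genes with log-normal (σ = 0.5) biological
  TE variation and Poisson count noise; polysome trends strictly monotone
  per site, most decreasing toward heavy fractions.

Transcript *sequence* is engineered, not realistic. Transcripts are
concatenations of designed cassettes separated by A-only spacers: hairpin
stems are mixed G/C, loops are A-only (plus the motif), and every G in a
transcript is consumed by a designed stem. Under base-pair maximization,
re-pairing any stem base elsewhere is never a net gain and always loses
stacking, so the maximum-pair, maximum-stack fold provably recovers the
planted structures — Type II windows fold to exactly the planted stem and
loop, and the generator contract (folding a planted window recovers at
least stem − 2 pairs with the site in the loop) holds deterministically.
Type II hairpins are additionally insulated by A spacers wider than the
fold window flank, so their ±50 nt windows contain nothing but the designed
hairpin and inert adenosines. Background motifs are embedded in hairpin
tilings whose geometry (arm length, motif depth, arm choice, occasional
stem–loop boundary placement, a bulged-site variant) is randomized per
cassette, so the pairing probability around background cytosines is high
and approximately offset-independent — a flat bootstrap null. Terminal
spacers exceed the read length so planted sites sit in the
uniform-coverage plateau rather than the transcript-end ramp-down.

Consequences for interpretation: passing tests demonstrates that the
*computations* are correct and that planted effects of realistic size are
recovered at realistic depths. They do not demonstrate performance on real
transcriptomes, where base composition is mixed, structure is
thermodynamic rather than combinatorial, coverage is non-uniform,
alignment errors and PCR duplicates exist (both outside scope — reads are
emitted pre-aligned by design), and the null pairing landscape is far less
flat. The generator also emits DNA-alphabet FASTA (T, not U); RNA logic is
applied after T→U mapping in the analysis layer.

## 9. Numerical choices and degenerate inputs

* Coordinates are 0-based internally; 1-based only where a format requires
  it (SAM POS, GTF). BED I/O is 0-based half-open on disk.
* Levels are exact ratios of integer counts; threshold comparisons use the
  printed ≥/< semantics directly.
* The folding engine is exact for its objective; it is O(n³) in C++ and
  folds a 101-nt window in milliseconds, so 100-resample nulls over dozens
  of sites complete in seconds.
* Empty call sets, empty matrices and samples without sites are valid and
  return empty results (proportion NA for zero-site samples); zero
  coverage, unbalanced dot-brackets, duplicate barcodes, missing
  compartments, and reference/alignment id mismatches are hard errors.
* Constant expression rows get NA coefficients ranked last; constant
  fraction rows normalize to 0 with a flag.
* Reporter recovery checks use the exact binomial central region at the
  3σ confidence level around the *expected observed* level
  $m + (1-m)(1-c)$: expected unconverted counts at null variants are of
  order 1, where normal-approximation bands are meaningless and the raw
  level would be compared against a zero-width interval.

## 10. Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run, per invocation: 200 planted
sites across 20 transcripts at depth 50 over 5 replicate samples for
level-recovery; 120 sites at depth 100 for dependency calling; 60-site
metaprofiles against a 120-cytosine background pool with 100 resamples;
100 replicate 125-enzyme screens; a 285-variant reporter library at depth
200; and 100 + 100 replicate TE simulations with 500 genes per group.
These sizes were chosen to hold Monte-Carlo error well below each check's
tolerance while keeping a full run in tens of seconds on one core.

## 11. Known limitations

* The Nussinov objective ignores thermodynamics; real hairpin calls should
  use the RNAfold adapter where fidelity matters.
* Metagene densities use fixed 20/40/20 compartment bins; the published
  density calculation is in inaccessible methods, so bin widths are
  configuration.
* The Type I motif window, the stall offset, the stem bulge tolerance and
  the reporter oligo architecture are all documented configuration, since
  the corresponding upstream specifications are unavailable.
* Genome-mode UTR refinement resolves compartments against per-chromosome
  CDS bounds and is intended for the simple single-gene fixtures used
  here; transcript-mode annotation is the primary path.
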