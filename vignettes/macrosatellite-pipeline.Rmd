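---
title: "Detecting and characterizing macrosatellite tandem repeats with macrosat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing macrosatellite tandem repeats with macrosat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrosat)
```

# Scope and model

macrosat re-implements, as a tested pipeline, the computational analysis
used to identify and characterize a macrosatellite tandem repeat — a repeat
with very large (multi-kilobase) units spanning tens of kilobases, of which
the mouse Dxz4 array is the motivating example. The pipeline covers five
analyses around such a locus:

1. **Self-alignment and repeat calling.** A sequence is compared with
   itself on both strands. Parallel off-diagonal match bands indicate a
   tandem array; anti-diagonal bands indicate an inverted repeat.
2. **Monomer decomposition.** A called array is cut into its repeat units
   (monomers), inter-monomer divergence is quantified by global alignment,
   and an internal variable number tandem repeat (VNTR) is detected with a
   per-monomer copy number.
3. **CpG composition.** GC fraction, CpG counts, observed/expected CpG and
   CpG-island (CGI) calls describe the locus's regulatory potential.
4. **Bisulfite clone methylation.** Per-CpG methylation states are called
   from cloned bisulfite PCR products and per-clone percent methylation is
   compared between groups (e.g. males vs females) with the unequal-variance
   two-sample t-test.
5. **Allele-specific read assignment.** Strain-discriminating SNPs called
   from clone sets assign ChIP-Seq-style reads to their parental haplotype
   under a 100%-identity / minimum-30-bp rule, yielding allelic fractions.
6. **Cross-species conservation.** From equal-length homologous monomer
   sequences, the minimal window spanning all invariant alignment columns
   is extracted and summarized as a position weight matrix (PWM) with
   per-column information content, then compared against IUPAC consensus
   motifs (the conserved core of this repeat family is a CTCF binding
   site).

Every stage consumes synthetic inputs from the package's own generators,
which plant known structure and return it as ground truth, so the whole
pipeline is testable without genome downloads.

# The self-aligner

`self_matches()` finds every maximal exact match of length at least
`min_segment` between distinct positions of a sequence (forward strand) and
between the sequence and its reverse complement (reverse strand). Exact
k-mer seeds are grouped by hash; because a maximal exact match of length L
contains exactly L − k + 1 seeds at consecutive positions on one diagonal,
runs of consecutive seeds reconstruct the maximal matches with no per-base
extension step. This requires `min_segment >= k`.

Defaults are `k = 13`, `min_segment = 25`: at ~5% pairwise divergence
between repeat units, roughly half of all positions still share an exact
13-mer with a sister unit, while a 200-kb i.i.d. random background is
expected to contain no spurious 25-bp exact repeat at all (the chance of
even a duplicated 13-mer seed pair is ≈ n²/2·4⁻¹³ ≈ 0.3, and a seed only
becomes a reported segment at 25 bp). These two facts make the caller's
false-positive behaviour attributable entirely to the caller, which the
background-only negative controls verify.

## Tandem calling and the local-period profile

`call_tandem_arrays()` clusters forward segments by overlapping footprints
(single linkage, gaps up to `max_gap = 2000` bp — wide enough to bridge
segment breaks caused by VNTR copy-number differences between adjacent
units). Periodicity is then read from diagonal offsets rather than segment
counts, with one refinement over taking the raw smallest recurring offset:
for every base of the footprint we record the **smallest offset of any
segment covering it** — the local distance to the next aligned copy. An
internal VNTR contributes a short local period (its own unit length,
~900 bp) but only over the VNTR's footprint, a minority of the array;
monomer-scale offsets dominate everywhere else. The dominant local-period
cluster therefore identifies the repeat-unit scale, offsets commensurate
with one unit (0.6–1.67× the dominant value) give the period statistics,
and `copy_estimate = round(span / median unit offset)`. For uniform-length
units this reduces to footprint/period exactly; for variable-length units
(VNTR) the median unit offset is the median monomer length, which is the
right denominator for a copy count.

Inverted repeats are called from reverse-strand segments whose left
interval precedes their right interval, clustered by band center; arms are
the union footprints per side. Calls with overlapping arms, arms below
`min_arm`, spacers beyond `max_spacer`, or arm lengths differing by more
than 20% are discarded as inconsistent with a genuine two-armed palindrome.

`survey_chromosome()` applies the caller in sliding windows (default 500-kb
windows, 250-kb step) and reports the largest call per window, emulating a
chromosome-scale scan for macrosatellite-sized repeats.

The dotplot (`dotplot()`) is a diagnostic artifact only — a binned count
matrix writable as TSV — and is never an input to calling.

# Monomer decomposition

Because the VNTR makes monomer length variable (3.8–5.7 kb at the
motivating locus), the array cannot be cut at a fixed period. Instead:

* **Anchor phasing** (`find_anchor()`, `k = 16`). Among all k-mers with at
  least two occurrences, each candidate is scored by (number of
  occurrences whose successive spacings lie within 40% of their own
  median) × (median spacing), capped at the array length — the span of the
  array that the periodic recurrence explains. A k-mer of the VNTR unit
  recurs more often but with ~900-bp spacing and explains far less span
  than a once-per-monomer k-mer, so the monomer-level anchor wins; scoring
  by raw occurrence counts would instead select the VNTR. Near-maximal
  scores (within 5%) are treated as ties, broken toward the candidate with
  the most regularly spaced occurrences, then the fewest off-period extra
  occurrences (an anchor inside a VNTR copy accumulates such extras when
  the k-mer survives in a second copy), then lexicographically — making
  the choice deterministic.
* **Register refinement** (`segment_monomers()`). An anchor sits at an
  arbitrary offset inside the unit, so raw anchor cuts would tile the
  array in an arbitrary register. The first 200 bp of the array are the
  leading edge of unit 1; their approximate recurrences (matched at up to
  20% mismatches, a comfortable margin over the ~10% expected at 5%
  pairwise divergence) mark every unit start directly. When exactly one
  recurrence is found per anchor, cuts snap to those positions and the
  segmentation matches the true unit boundaries to within a few bases;
  otherwise the raw anchor cuts are used and the leading partial flank is
  reported separately.
* **Divergence** (`divergence_matrix()`). Pairs are globally aligned
  (Needleman–Wunsch, affine gaps: open 12, extend 0.5, so that the
  kilobase-scale VNTR length differences become single contiguous gap
  runs). Percent divergence counts substituted columns over alignment
  columns, excluding columns inside gap runs of ≥ 50 bp: divergence is
  meant to describe substitution-level sequence difference, not VNTR
  copy-number difference. On indel-free equal-length pairs this reduces to
  Hamming distance, which the tests verify to 0.1 percentage points.
* **VNTR detection** (`detect_vntr()`). The self-aligner runs within each
  monomer; the smallest recurring internal offset family (coverage-weighted)
  defines the unit length, and a monomer whose largest internal offset is m
  units carries m + 1 copies. The max-offset rule is deliberately used
  instead of footprint/unit: at ~5% divergence between copies the exact
  segments covering a copy pair are fragmented, so footprints under-count,
  while the existence of *any* ≥ 25-bp exact match at offset m·unit is
  near-certain for every true copy pair. The unit's coordinates are
  reported on the shortest monomer (the natural single-copy reference),
  located by approximate matching at up to 15% mismatches.

# The synthetic generators

`generate_array()` builds each monomer from one shared template that
carries exactly one copy of the VNTR unit; per monomer the unit is expanded
to its stated copy number and the whole monomer is mutated independently.
Ground truth records the exact monomer tiling, copy numbers and mutated
positions. `dxz4_like_spec()` packages the reference conditions: a 3.8-kb
template, 900-bp unit, seven monomers at copies (2,1,3,2,1,2,3) and ~5%
inter-monomer divergence, matching the structure of the motivating locus.

One calibration deserves emphasis: **`substitution_rate` is the target
pairwise divergence between units**, because that is the quantity the field
reports ("units differ by >5%") and the quantity `divergence_matrix()`
estimates. Two copies independently mutated from a template at per-base
rate r differ at 2r(1−r) + (2/3)r² (replacements uniform over the three
other bases), so the generator applies the per-copy rate r solving that
equation (r ≈ 0.0254 for a 5% target). Specifying the per-copy rate as 5%
directly would produce ~9.7% pairwise divergence, which is not what "5%
diverged monomers" means to a reader of repeat literature.

Backgrounds (`plant_features()`) are i.i.d. uniform over the four bases —
deliberately free of repeat structure so that any false tandem call
indicts the caller, not the simulator. Indels are off by default
(`indel_rate = 0`), keeping the planted length arithmetic exact; when
enabled, lengths are geometric with a cap. Each generator takes one
explicit seed, sets the RNG once and draws sub-streams sequentially per
monomer/clone/read, so identical spec + seed gives byte-identical output.

The bisulfite generator plants three-state truth per CpG: with
`variant_prob` the site's C is replaced by A or G — never T, so a destroyed
CpG is unambiguously distinguishable from an unmethylated one after
conversion; otherwise the site is methylated with its site/group
probability (C retained) or unmethylated (C→T). All non-CpG cytosines
convert with `conversion_efficiency`. `cpg_scaffold()` builds reference
regions with an exact CpG count by drawing spacers from an alphabet
without G, so the only CG dinucleotides are the planted ones while
cytosines remain available for conversion QC.

The allelic generator draws uniform-start reads from two haplotypes at a
chosen ratio with independent substitution errors. The species generator
mutates an ancestral region independently per lineage except inside a
protected core. `dxz4_species_spec()` fixes the reference conditions: 25
species, a 143-bp region (the cross-species alignable interval at the
motivating locus) with a 34-bp protected core at offset 59 (mirroring
bases 978–1011 of a 919–1061 alignment region).

**Choice of the default lineage divergence (0.35).** The conserved window
is defined as the minimal interval containing *all* invariant columns, so a
single column that stays invariant by chance outside the core widens the
window. With s star-shaped lineages the chance a flanking column is
invariant is ≈ (1−d)²⁵, which at d = 0.15 is ~1.7% per column — across a
~110-bp flank that is 2–3 expected chance columns, and the window would
routinely overshoot the core. A deep-mammal alignment of weakly constrained
repeat flanks is, however, near saturation (the motivating comparison shows
74% identity between the two *closest* well-studied lineages alone, and the
full 25-taxon set spans far deeper splits), so per-lineage divergence 0.35
(pairwise identity ≈ 46% outside the core) is the realistic default; at
that depth chance invariance is ~2×10⁻⁵ per column and the recovered window
matches the planted core edge-to-edge in ≥95% of simulations. The
generator exposes the rate, and the property tests additionally verify the
pairwise-identity expectation at 0.15.

What the generators deliberately do **not** emulate: read-quality profiles,
PCR duplicates, paired-end geometry, repeat-bearing backgrounds,
tree-correlated (non-star) evolution, and bottom-strand bisulfite PCR.
Passing tests therefore demonstrate correctness of the algorithms under
clean, independence-assuming conditions — not robustness to the full
messiness of real libraries.

# CpG metrics

CGI calling follows the classical Gardiner-Garden & Frommer criteria —
200-bp windows stepped by 1 bp with GC ≥ 0.5 and observed/expected CpG
≥ 0.6 — since no alternative algorithm is mandated by the analyses this
package reproduces; all three thresholds are parameters. An island is the
union of overlapping qualifying windows (the maximal extent still covered
by qualifying windows), with island-level metrics recomputed on the merged
interval. Ambiguous bases are excluded from numerators and denominators,
and a CpG spanning an ambiguous base is not counted. Island calls are
verified against brute-force window enumeration.

# Bisulfite methylation calling and comparison

Clone calling assumes top-strand bisulfite PCR. Clones are compared to the
reference in a C→T-collapsed frame (equal-length clones in place; others
after global alignment), rejecting clones below 80% collapsed-frame
identity. At each reference CpG, clone base C = methylated, T =
unmethylated, anything else or a deletion = absent. Conversion QC is the
fraction of non-CpG reference cytosines reading T; clones under 0.95 are
flagged, not dropped.

The unit of analysis is the per-clone percent methylation with absent
sites excluded from the denominator; clones with no informative site are
dropped with a warning. Group comparison is the Welch unequal-variance
two-sample t-test on those per-clone percentages — implemented directly
(statistic, Welch–Satterthwaite degrees of freedom, two-tailed p) and
cross-checked against `stats::t.test` to 10⁻⁹ in the tests. Zero-variance
edge cases are defined explicitly: equal constant groups give t = 0,
p = 1; unequal constant groups report the limit p = 0 with a
"zero-variance" flag. Groups below nine clones warn (profiles are
conventionally built from at least nine independent clones). No
multiple-testing correction is applied across regions, matching the
original analysis design.

Simulation-based calibration (run in the acceptance tests): under a null
model (both groups at site probability 0.5, 30 CpGs, 10 clones/group) the
type-I error at nominal 0.05 sits within [0.03, 0.07] over 1,000
simulations; under the sex-difference design — one group uniformly at 0.85,
the other an equal mixture of 0.85 (Xa-like) and 0.15 (Xi-like) clones —
power exceeds 90% over 200 simulations. The mixture uses an exactly equal
Xa/Xi split, which is the biology being mimicked (each female clone derives
from one of the two X chromosomes at random conversion, but profiles pool
cells with one active X each).

# Allele-specific assignment

SNP discovery takes the per-position modal base of each strain's clone set
and calls positions where the consensuses differ and both modal fractions
reach `min_support = 0.9` (with >100 clones per strain, high support is
available; the threshold tolerates 0.5% clone error comfortably).

Read assignment realizes "100% identity over ≥ 30 bp" as exact substring
search: any perfect overlap of length ≥ L contains an exact L-mer, so a
read is screened against the SNP-covering 30-mers of each haplotype. A
read labels A when it shares such a 30-mer with haplotype A and none with
haplotype B (symmetrically for B); reads matching both haplotypes (no
discriminating site covered, or conflicting sites), reads matching
neither, and reads shorter than 30 bp are uninformative. Consequently a
sequencing error well away from a SNP does not silence a read — the
SNP-covering stretch is still perfect — while an error at the SNP either
abstains (third base) or, if it exactly converts one allele into the
other with clean flanks, misassigns; that mechanism bounds misassignment
by ≈ error_rate/3 per covered SNP, verified empirically (<1% at 1% error).
Paired-end mates are treated as independent reads.

# Cross-species window and PWM

`conserved_window()` takes pre-aligned, equal-length sequences (alignment
construction is out of scope) and returns the minimal interval containing
all invariant columns — columns inside the window need not be invariant,
mirroring the "window encompassing all invariable nucleotides" idea.
`build_pwm()` reports per-column counts, frequencies with optional
pseudocount (default 0, reproducing sequence-logo information content) and
IC = 2 + Σ f·log₂f bits. `consensus_match()` scores an IUPAC consensus at
every offset on both strands, so motif orientation never matters; known
binding-site consensus strings (CTCF, C/EBPα, ELK4 and similar) are
supplied by the user, as matrix versions vary between databases.

# Problem sizes and determinism

The test suite and acceptance script use: 200-kb backgrounds with one
planted 7-monomer array (5 seeds), 5 background-only negatives, 2-kb/5-kb
oracle-equivalence fixtures (20 each), 1,000 null and 200 alternative
methylation simulations, 10,000-read assignment experiments, and 100
conserved-window seeds — sizes chosen so each stage's statistical claims
are testable at useful precision on a single CPU in minutes. All
randomness flows through explicit integer seeds; generators restore the
caller's RNG state.

# Known limitations

* The self-aligner reports exact segments only; highly diverged (>15%)
  repeat families fragment into short segments and may fall below
  `min_segment` coverage. Gapped/affine extension is out of scope.
* `copy_estimate` is a footprint/period ratio; for arrays of fewer than
  ~4 units or units of strongly varying length it can be off by one.
  Monomer counts from anchor phasing are the authoritative unit count.
* Monomer boundary *register* is inherently arbitrary for circularly
  permutable repeats; the leading-edge refinement fixes it to the array's
  own start, which matches planted truth but need not match any published
  annotation's register for a real locus.
* The divergence estimate depends mildly on alignment gap parameters near
  VNTR boundaries; the long-indel exclusion absorbs most, not all, of it.
* Welch-test calibration is verified for per-clone percentages from ≥ 30
  sites; with very few CpGs the percentage scale is coarse and the t
  approximation degrades.
* `call_strain_snps()` requires clones co-linear with the reference
  (full-length, equal-length copies); indel-bearing clones are skipped
  rather than aligned.
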