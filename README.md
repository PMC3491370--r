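# macrosat

Macrosatellites are tandem repeats with unusually large units — several
kilobases each, arranged head to tail over tens of kilobases. The mouse
Dxz4 array, the motivating locus for this package, is a ~33-kb array of
roughly seven 3.8–5.7-kb monomers whose size variation comes from an
internal ~900-bp variable number tandem repeat (VNTR) at one to three
copies per monomer, with >5% sequence divergence between monomers, a
CpG-island-bearing flank, sex-differential CpG methylation, CTCF bound on
both parental X chromosomes, and a 34-bp core conserved across mammals.

`macrosat` implements the computational side of characterizing such a
locus as a reusable, fully tested R pipeline:

* **Self-alignment & calling** — exact-seed self-alignment on both strands
  (`self_matches`), tandem-array calls from the dominant local period of
  diagonal offsets (`call_tandem_arrays`), inverted-repeat calls from
  anti-diagonal bands (`call_inverted_repeats`), windowed chromosome
  surveys (`survey_chromosome`), diagnostic dotplots (`dotplot`).
* **Monomer decomposition** — periodic-anchor phasing (`find_anchor`),
  register-refined segmentation (`segment_monomers`), pairwise percent
  divergence with long-indel exclusion (`divergence_matrix`), VNTR unit
  and per-monomer copy numbers (`detect_vntr`); `decompose_array` runs all
  four.
* **CpG metrics** — `gc_fraction`, `cpg_count`, `cpg_obs_exp` and
  Gardiner-Garden & Frommer-style island calling (`find_cgis`).
* **Bisulfite methylation** — three-state per-CpG clone calling
  (`call_clone_methylation`), per-clone percent methylation
  (`percent_methylation`), and the Welch unequal-variance two-sample
  t-test on clone percentages (`compare_groups`):
  t = (m₁−m₂)/√(s₁²/n₁ + s₂²/n₂) with Welch–Satterthwaite degrees of
  freedom and a two-tailed p.
* **Allele-specific assignment** — strain-SNP discovery from clone sets
  (`call_strain_snps`) and read-to-haplotype assignment under the
  100%-identity / ≥30-bp rule (`assign_reads`, `summarize_assignments`).
* **Conservation** — invariant-column window extraction
  (`conserved_window`), position weight matrices with per-column
  information content IC = 2 + Σ f·log₂f bits (`build_pwm`), and IUPAC
  consensus matching on both strands (`consensus_match`).
* **Synthetic data with ground truth** — generators for diverged arrays
  (`generate_array`, `dxz4_like_spec`), planted genomes
  (`plant_features`), bisulfite clone sets (`simulate_bisulfite_clones`),
  haplotype read mixtures (`simulate_allelic_reads`,
  `simulate_strain_clones`) and species-labelled monomers with a
  protected core (`simulate_species_monomers`, `dxz4_species_spec`).

See the vignette (`vignettes/macrosatellite-pipeline.Rmd`) for the methods
and the reasoning behind defaults.

## Worked example

```r
library(macrosat)

# 1. simulate a Dxz4-like locus: 7 monomers, 900-bp VNTR, ~5% divergence
spec  <- dxz4_like_spec(seed = 42)
arr   <- generate_array(spec)
locus <- plant_features(200000,
                        list(list(sequence = arr$sequence, position = 80000)),
                        seed = 43)

# 2. self-align and call the array
calls <- call_tandem_arrays(self_matches(locus$sequence))
calls
#>   start    end  span copy_estimate period_min period_median period_max support
#> 1 79998 112900 32902             7       3800          4700       5600    1984

# 3. decompose the called interval
dec <- decompose_array(substr(locus$sequence, calls$start + 1, calls$end))
dec$monomer_set
#> monomer_set: 7 monomers, lengths 3800-5602 bp (register: refined)
dec$vntr
#> vntr_call: unit 900 bp, copies per monomer [2,1,3,2,1,2,3], reference monomer 2
round(range(dec$divergence$divergence[upper.tri(dec$divergence$divergence)]), 2)
#> [1] 4.85 5.79
```

The call sits within 2 bp of the planted interval (truth: 80000–112900),
the seven monomers tile it exactly, the VNTR copy vector matches the
planted (2,1,3,2,1,2,3), and all pairwise monomer divergences center on
the 5% the generator was asked for.

```r
# 4. methylation: males uniform at 0.85 vs females mixing Xa/Xi clones
ref    <- cpg_scaffold(30, seed = 7)
male   <- simulate_bisulfite_clones(bisulfite_spec(ref, 0.85,
            clones_per_group = 10, groups = "male", seed = 11))
female <- simulate_bisulfite_clones(bisulfite_spec(ref,
            matrix(c(rep(0.85, 30), rep(0.15, 30)), ncol = 2),
            clones_per_group = 5, groups = c("xa", "xi"), seed = 12))
pct <- function(sim) vapply(seq_len(nrow(sim$clones)), function(i)
  percent_methylation(call_clone_methylation(ref, sim$clones$sequence[i])),
  numeric(1))
compare_groups(pct(male), pct(female))
#> Welch two-sample comparison of percent methylation
#>   group 1: mean 83.67 (sd 10.59, n 10)
#>   group 2: mean 50.67 (sd 37.54, n 10)
#>   t = 2.6752, df = 10.42, two-tailed p = 0.02252
```

The female group's bimodal clone percentages (hypermethylated Xa-derived,
hypomethylated Xi-derived clones) inflate its variance — exactly the
situation the unequal-variance test is for.

```r
# 5. allele-specific read assignment at 1% sequencing error
region <- random_dna(500, seed = 3)
snps   <- data.frame(position = c(60, 160, 260, 360, 460),
                     allele_A = c("A","T","C","G","T"),   # reference bases
                     allele_B = c("G","C","G","T","A"))
reads  <- simulate_allelic_reads(allelic_spec(region, snps,
            allelic_ratio = 0.5, n_reads = 2000, error_rate = 0.01, seed = 5))
summarize_assignments(assign_reads(reads$reads, reads$haplotypes$A,
                                   reads$haplotypes$B))
#> assignment_summary: 2000 reads, 1795 informative
#>   A: 902 (50.3% of informative)
#>   B: 893 (49.7% of informative)
#>   uninformative: 205

# 6. conserved core across 25 simulated mammals
sim <- simulate_species_monomers(dxz4_species_spec(seed = 9))
cw  <- conserved_window(sim$sequences)
cw
#> conserved_window: [59, 93) (34 bp), 34 invariant columns across 25 sequences
build_pwm(window_sequences(sim$sequences, cw))
#> pwm: width 34, 25 sequences, mean IC 2.00 bits/column
```

The recovered window is exactly the planted 34-bp protected core; reads
split ~50:50 between haplotypes as simulated, with misassignment well
under 1%.

## Command line

A thin wrapper over the same functions ships in
`inst/scripts/macrosat-cli.R` with subcommands `simulate`, `scan`,
`survey`, `monomers`, `cgi`, `bisulfite`, `assign-alleles` and `motif`:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts","macrosat-cli.R",package="macrosat"))')
Rscript "$CLI" scan --fasta locus.fa --out-prefix out/locus
Rscript "$CLI" monomers --fasta array.fa --out-prefix out/array
```

Outputs are FASTA, BED (0-based half-open) and TSV.

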