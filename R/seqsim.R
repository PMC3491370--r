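## Synthetic-data generators. Every generator returns its planted ground
## truth alongside the sequence so downstream callers can be scored without
## any external data. All coordinates are 0-based, half-open.

## ---- array simulation ------------------------------------------------------

#' Specification of a synthetic macrosatellite array
#'
#' The array is built from a shared monomer template that carries exactly one
#' copy of an internal VNTR unit; each monomer expands the unit to its own
#' copy number and is then mutated independently.
#'
#' `substitution_rate` is the target expected pairwise divergence between two
#' monomer copies. Each copy is mutated from the template at the per-base
#' rate r solving 2r(1-r) + (2/3)r^2 = substitution_rate (two independently
#' mutated copies of one template differ at that rate when replacements are
#' uniform over the three other bases), so that the realized inter-monomer
#' divergence matches the stated rate.
#'
#' @param monomer_template DNA string containing one copy of `vntr_unit` at
#'   `vntr_insert_position`.
#' @param copy_count Number of monomers (positive integer).
#' @param vntr_unit DNA string, the internal repeat unit (~900 bp in the
#'   motivating locus).
#' @param vntr_insert_position 0-based offset of the unit within the
#'   template.
#' @param vntr_copies Integer vector, one VNTR copy number (>= 1) per
#'   monomer.
#' @param substitution_rate Target pairwise divergence in [0, 1].
#' @param indel_rate Per-base indel probability (default 0, which keeps the
#'   length arithmetic of the planted truth exact).
#' @param max_indel_len Cap on geometric indel lengths, bp.
#' @param seed Integer RNG seed.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(monomer_template, copy_count, vntr_unit,
                       vntr_insert_position, vntr_copies,
                       substitution_rate = 0.05, indel_rate = 0,
                       max_indel_len = 10, seed = 1L) {
  monomer_template <- check_dna(monomer_template, "monomer_template")
  vntr_unit <- check_dna(vntr_unit, "vntr_unit")
  if (!is.numeric(copy_count) || copy_count < 1 || copy_count %% 1 != 0)
    stopf("field 'copy_count' must be a positive integer")
  if (length(vntr_copies) != copy_count)
    stopf("field 'vntr_copies' must have length copy_count (%d)", copy_count)
  if (any(vntr_copies < 1) || any(vntr_copies %% 1 != 0))
    stopf("field 'vntr_copies' entries must be integers >= 1")
  check_prob(substitution_rate, "substitution_rate")
  check_prob(indel_rate, "indel_rate")
  if (vntr_insert_position < 0 ||
      vntr_insert_position + nchar(vntr_unit) > nchar(monomer_template))
    stopf("field 'vntr_insert_position' places the unit outside the template")
  structure(list(monomer_template = monomer_template,
                 copy_count = as.integer(copy_count),
                 vntr_unit = vntr_unit,
                 vntr_insert_position = as.integer(vntr_insert_position),
                 vntr_copies = as.integer(vntr_copies),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 max_indel_len = as.integer(max_indel_len),
                 seed = as.integer(seed)),
            class = "array_spec")
}

## Per-copy mutation rate realizing a target pairwise divergence p:
## solve 2r(1-r) + (2/3) r^2 = p for r.
per_copy_rate <- function(pairwise) {
  if (pairwise == 0) return(0)
  (6 - 3 * sqrt(4 - 16 * pairwise / 3)) / 8
}

#' Array spec emulating the mouse Dxz4 locus structure
#'
#' Seven monomers built on a 3.8-kb template (one embedded copy of a 900-bp
#' VNTR unit), VNTR copy numbers between one and three, ~5% inter-monomer
#' divergence. The template and unit are drawn from the seed.
#'
#' @param seed Integer RNG seed.
#' @param vntr_copies Per-monomer VNTR copy numbers.
#' @param substitution_rate Target pairwise divergence.
#' @return An `array_spec`.
#' @export
dxz4_like_spec <- function(seed = 1L, vntr_copies = c(2, 1, 3, 2, 1, 2, 3),
                           substitution_rate = 0.05) {
  with_seed(seed, {
    vpos <- sample(500:2300, 1L)
    unit <- random_dna(900)
    template <- paste0(random_dna(vpos), unit, random_dna(3800 - vpos - 900))
  })
  array_spec(template, length(vntr_copies), unit, vpos, vntr_copies,
             substitution_rate = substitution_rate, seed = seed)
}

apply_indels <- function(chars, rate, max_len) {
  hits <- which(runif(length(chars)) < rate)
  for (i in rev(hits)) {
    len <- min(1L + rgeom(1L, 0.5), max_len)
    if (runif(1) < 0.5) {  # insertion after i
      chars <- append(chars, sample(DNA_BASES, len, replace = TRUE), after = i)
    } else {               # deletion starting at i
      chars <- chars[-(i:min(i + len - 1L, length(chars)))]
    }
  }
  chars
}

#' Generate a synthetic tandem array with planted truth
#'
#' Each monomer is the template with its VNTR expanded to the specified copy
#' number, then mutated; monomers are concatenated head to tail. Identical
#' spec and seed give byte-identical output.
#'
#' @param spec An [array_spec()].
#' @return A list with `sequence` (the array), and `truth`: `array_interval`,
#'   `monomer_intervals` (data frame, 0-based half-open, tiling the array),
#'   `vntr_copy_counts`, `variant_positions` (list of 0-based mutated sites
#'   per monomer, in pre-indel coordinates), and `per_copy_rate`.
#' @export
generate_array <- function(spec) {
  stopifnot(inherits(spec, "array_spec"))
  r <- per_copy_rate(spec$substitution_rate)
  tmpl <- seq_chars(spec$monomer_template)
  unit <- seq_chars(spec$vntr_unit)
  vpos <- spec$vntr_insert_position
  pre <- tmpl[seq_len(vpos)]
  post <- tmpl[seq(vpos + length(unit) + 1L, length(tmpl))]
  with_seed(spec$seed, {
    monomers <- vector("list", spec$copy_count)
    variants <- vector("list", spec$copy_count)
    for (i in seq_len(spec$copy_count)) {
      chars <- c(pre, rep(unit, spec$vntr_copies[i]), post)
      mut <- mutate_chars(chars, r)
      chars <- mut$chars
      if (spec$indel_rate > 0)
        chars <- apply_indels(chars, spec$indel_rate, spec$max_indel_len)
      monomers[[i]] <- chars
      variants[[i]] <- mut$positions
    }
  })
  lens <- lengths(monomers)
  ends <- cumsum(lens)
  starts <- c(0L, head(ends, -1L))
  list(sequence = chars_seq(unlist(monomers)),
       truth = list(
         array_interval = c(0L, ends[length(ends)]),
         monomer_intervals = data.frame(start = starts, end = ends,
                                        length = lens),
         vntr_copy_counts = spec$vntr_copies,
         variant_positions = variants,
         per_copy_rate = r))
}

#' Plant feature sequences in a uniform random background
#'
#' The background is i.i.d. uniform over the four bases; each feature
#' replaces the background at its stated position, so every planted feature
#' is recoverable verbatim at its truth coordinates.
#'
#' @param background_length Genome length in bp.
#' @param features List of `list(sequence=, position=)` entries (positions
#'   0-based) or a data frame with columns `sequence`, `position`.
#' @param seed Integer RNG seed for the background.
#' @param chrom Name used in the truth BED records.
#' @return List with `sequence` and `truth`, a BED-like data frame
#'   (`chrom`, `start`, `end`, `name`) sorted by start.
#' @export
plant_features <- function(background_length, features, seed = 1L,
                           chrom = "synthetic") {
  if (is.data.frame(features))
    features <- lapply(seq_len(nrow(features)), function(i)
      list(sequence = features$sequence[i], position = features$position[i]))
  starts <- vapply(features, function(f) as.integer(f$position), integer(1))
  lens <- vapply(features, function(f) nchar(f$sequence), integer(1))
  ends <- starts + lens
  bad <- which(starts < 0 | ends > background_length)
  if (length(bad))
    stopf("features out of range: %s", paste(bad, collapse = ", "))
  ord <- order(starts)
  so <- starts[ord]; eo <- ends[ord]
  ovl <- which(so[-1] < eo[-length(eo)])
  if (length(ovl))
    stopf("overlapping features: %s",
          paste(ord[c(ovl, ovl + 1L)], collapse = ", "))
  chars <- with_seed(seed, sample(DNA_BASES, background_length,
                                  replace = TRUE))
  for (f in features) {
    idx <- seq(f$position + 1L, f$position + nchar(f$sequence))
    chars[idx] <- seq_chars(f$sequence)
  }
  truth <- data.frame(chrom = chrom, start = so, end = eo,
                      name = paste0("feature_", seq_along(so)))
  list(sequence = chars_seq(chars), truth = truth)
}

## ---- bisulfite simulation --------------------------------------------------

#' 0-based start positions of CpG dinucleotides
#' @param sequence DNA string.
#' @return Integer vector of 0-based positions where "CG" starts.
#' @export
cpg_positions <- function(sequence) {
  ch <- seq_chars(toupper(sequence))
  n <- length(ch)
  if (n < 2L) return(integer(0))
  which(ch[-n] == "C" & ch[-1L] == "G") - 1L
}

#' Specification for simulated bisulfite clone sets
#'
#' @param reference_region Untreated reference DNA string.
#' @param methylation_prob Per-site-per-group methylation probabilities:
#'   a matrix (sites x groups), one value per group, or a single value.
#' @param variant_prob Probability that a clone carries a CpG-destroying
#'   substitution at a site (the C is replaced by A or G, so the site is
#'   unambiguously non-CpG after conversion).
#' @param conversion_efficiency Probability that an unmethylated C reads as T.
#' @param clones_per_group Integer (recycled over groups) or vector.
#' @param groups Character vector of group labels.
#' @param seed Integer RNG seed.
#' @return An object of class `bisulfite_spec`.
#' @export
bisulfite_spec <- function(reference_region, methylation_prob,
                           variant_prob = 0, conversion_efficiency = 1,
                           clones_per_group = 10L,
                           groups = c("group1", "group2"), seed = 1L) {
  reference_region <- check_dna(reference_region, "reference_region")
  sites <- cpg_positions(reference_region)
  ng <- length(groups)
  if (is.matrix(methylation_prob)) {
    if (nrow(methylation_prob) != length(sites) ||
        ncol(methylation_prob) != ng)
      stopf("field 'methylation_prob' matrix must be %d sites x %d groups",
            length(sites), ng)
    pm <- methylation_prob
  } else {
    pm <- matrix(rep(rep_len(methylation_prob, ng), each = length(sites)),
                 ncol = ng)
  }
  check_prob(pm, "methylation_prob")
  check_prob(variant_prob, "variant_prob")
  check_prob(conversion_efficiency, "conversion_efficiency")
  npc <- rep_len(as.integer(clones_per_group), ng)
  if (any(npc < 1)) stopf("field 'clones_per_group' must be >= 1")
  structure(list(reference_region = reference_region, cpg_sites = sites,
                 methylation_prob = pm, variant_prob = variant_prob,
                 conversion_efficiency = conversion_efficiency,
                 clones_per_group = npc, groups = groups,
                 seed = as.integer(seed)),
            class = "bisulfite_spec")
}

#' Simulate bisulfite-converted clone sequences
#'
#' Per clone and CpG site: with `variant_prob` the C is replaced by A or G
#' (truth state "absent"); otherwise the site is methylated with its
#' site/group probability (C retained) or unmethylated (C read as T). Every
#' non-CpG cytosine converts to T with probability `conversion_efficiency`.
#'
#' @param spec A [bisulfite_spec()].
#' @return List with `clones` (data frame: `group`, `clone_id`, `sequence`),
#'   `truth` (long data frame of per-clone per-site states), `cpg_sites`
#'   and `reference`.
#' @export
simulate_bisulfite_clones <- function(spec) {
  stopifnot(inherits(spec, "bisulfite_spec"))
  ref <- seq_chars(spec$reference_region)
  sites <- spec$cpg_sites
  if (length(sites) == 0L) stopf("reference region contains no CpG site")
  noncpg_c <- setdiff(which(ref == "C"), sites + 1L)
  rows <- list(); truth <- list(); k <- 0L
  with_seed(spec$seed, {
    for (g in seq_along(spec$groups)) {
      for (j in seq_len(spec$clones_per_group[g])) {
        k <- k + 1L
        chars <- ref
        state <- character(length(sites))
        is_var <- runif(length(sites)) < spec$variant_prob
        is_meth <- runif(length(sites)) < spec$methylation_prob[, g]
        state[is_var] <- "absent"
        state[!is_var & is_meth] <- "methylated"
        state[!is_var & !is_meth] <- "unmethylated"
        chars[sites[is_var] + 1L] <-
          sample(c("A", "G"), sum(is_var), replace = TRUE)
        chars[sites[!is_var & !is_meth] + 1L] <- "T"
        conv <- noncpg_c[runif(length(noncpg_c)) <
                           spec$conversion_efficiency]
        chars[conv] <- "T"
        id <- sprintf("%s_clone%02d", spec$groups[g], j)
        rows[[k]] <- data.frame(group = spec$groups[g], clone_id = id,
                                sequence = chars_seq(chars))
        truth[[k]] <- data.frame(group = spec$groups[g], clone_id = id,
                                 site = sites, state = state)
      }
    }
  })
  list(clones = do.call(rbind, rows), truth = do.call(rbind, truth),
       cpg_sites = sites, reference = spec$reference_region)
}

#' Build a reference region carrying an exact number of CpG sites
#'
#' Spacers are drawn from an alphabet without G, so the only CG dinucleotides
#' are the planted ones; spacers still contain cytosines for conversion QC.
#'
#' @param n_cpg Number of CpG sites.
#' @param spacer_len Spacer length between consecutive CpGs, bp.
#' @param seed Integer RNG seed.
#' @return DNA string with exactly `n_cpg` CpGs.
#' @export
cpg_scaffold <- function(n_cpg, spacer_len = 12L, seed = 1L) {
  with_seed(seed, {
    spacers <- replicate(n_cpg + 1L,
      paste(sample(c("A", "C", "T"), spacer_len, replace = TRUE),
            collapse = ""))
  })
  paste0(paste0(spacers[seq_len(n_cpg)], "CG", collapse = ""),
         spacers[n_cpg + 1L])
}

## ---- allelic simulation ----------------------------------------------------

#' Specification for allele-specific read simulation
#'
#' @param reference Reference DNA string.
#' @param snp_table Data frame with columns `position` (0-based),
#'   `allele_A`, `allele_B`; alleles must differ at every row.
#' @param allelic_ratio Fraction of reads drawn from haplotype A.
#' @param read_length Read length in bp.
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer RNG seed.
#' @return An object of class `allelic_spec`.
#' @export
allelic_spec <- function(reference, snp_table, allelic_ratio = 0.5,
                         read_length = 100L, n_reads = 1000L,
                         error_rate = 0, seed = 1L) {
  reference <- check_dna(reference, "reference")
  stopifnot(is.data.frame(snp_table),
            all(c("position", "allele_A", "allele_B") %in% names(snp_table)))
  if (any(duplicated(snp_table$position)))
    stopf("field 'snp_table' has duplicated positions")
  if (any(snp_table$position < 0 |
          snp_table$position >= nchar(reference)))
    stopf("field 'snp_table' has positions outside the reference")
  if (any(snp_table$allele_A == snp_table$allele_B))
    stopf("field 'snp_table' has rows where the alleles do not differ")
  check_prob(allelic_ratio, "allelic_ratio")
  check_prob(error_rate, "error_rate")
  if (read_length > nchar(reference))
    stopf("field 'read_length' exceeds the reference length")
  structure(list(reference = reference, snp_table = snp_table,
                 allelic_ratio = allelic_ratio,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "allelic_spec")
}

#' Apply SNP alleles to a reference to obtain a haplotype
#' @param reference DNA string.
#' @param positions 0-based positions.
#' @param alleles Replacement bases.
#' @return DNA string.
#' @export
apply_alleles <- function(reference, positions, alleles) {
  chars <- seq_chars(reference)
  chars[positions + 1L] <- alleles
  chars_seq(chars)
}

#' Simulate reads from two haplotypes at a chosen allelic ratio
#'
#' Reads are uniform-start substrings of haplotype A (reference with
#' `allele_A` applied) or haplotype B, chosen with `allelic_ratio`, with
#' independent per-base substitution errors.
#'
#' @param spec An [allelic_spec()].
#' @return List with `reads` (data frame: `read_id`, `sequence`, `hap`
#'   (truth label), `start` 0-based), `haplotypes` (list A/B) and
#'   `snp_table`.
#' @export
simulate_allelic_reads <- function(spec) {
  stopifnot(inherits(spec, "allelic_spec"))
  hapA <- apply_alleles(spec$reference, spec$snp_table$position,
                        spec$snp_table$allele_A)
  hapB <- apply_alleles(spec$reference, spec$snp_table$position,
                        spec$snp_table$allele_B)
  n <- spec$n_reads; L <- spec$read_length
  with_seed(spec$seed, {
    from_a <- runif(n) < spec$allelic_ratio
    starts <- sample.int(nchar(spec$reference) - L + 1L, n, replace = TRUE)
    reads <- ifelse(from_a,
                    substring(hapA, starts, starts + L - 1L),
                    substring(hapB, starts, starts + L - 1L))
    if (spec$error_rate > 0) {
      hits <- which(runif(n * L) < spec$error_rate)
      for (h in hits) {
        r <- (h - 1L) %/% L + 1L
        p <- (h - 1L) %% L + 1L
        base <- substr(reads[r], p, p)
        substr(reads[r], p, p) <- sample(setdiff(DNA_BASES, base), 1L)
      }
    }
  })
  list(reads = data.frame(read_id = sprintf("read_%05d", seq_len(n)),
                          sequence = reads,
                          hap = ifelse(from_a, "A", "B"),
                          start = starts - 1L),
       haplotypes = list(A = hapA, B = hapB),
       snp_table = spec$snp_table)
}

#' Simulate strain clone sets for SNP discovery
#'
#' Each clone is a full-length copy of the reference region for its strain's
#' haplotype with independent per-base errors, emulating cloned and Sanger-
#' sequenced PCR products.
#'
#' @param reference Reference DNA string (strain A's sequence).
#' @param snp_table As in [allelic_spec()]; strain A carries `allele_A`,
#'   strain B `allele_B`.
#' @param clones_per_strain Number of clones per strain.
#' @param error_rate Per-base clone error probability.
#' @param seed Integer RNG seed.
#' @return List with `clones_A`, `clones_B` (character vectors) and the
#'   haplotypes.
#' @export
simulate_strain_clones <- function(reference, snp_table,
                                   clones_per_strain = 100L,
                                   error_rate = 0.005, seed = 1L) {
  hapA <- apply_alleles(reference, snp_table$position, snp_table$allele_A)
  hapB <- apply_alleles(reference, snp_table$position, snp_table$allele_B)
  noisy <- function(hap, m) {
    vapply(seq_len(m), function(i)
      chars_seq(mutate_chars(seq_chars(hap), error_rate)$chars),
      character(1))
  }
  with_seed(seed, {
    ca <- noisy(hapA, clones_per_strain)
    cb <- noisy(hapB, clones_per_strain)
  })
  list(clones_A = ca, clones_B = cb, haplotypes = list(A = hapA, B = hapB))
}

## ---- cross-species simulation ----------------------------------------------

#' Specification for species-labelled monomer simulation
#'
#' Emulates homologous repeat-monomer sequence from many species: each
#' species is the ancestral sequence mutated independently per base, except
#' inside a conserved interval that is copied verbatim (a constrained core,
#' e.g. a protein binding site, within otherwise diverged DNA).
#'
#' @param ancestral_monomer Ancestral DNA string.
#' @param n_species Number of species.
#' @param per_species_divergence Per-base substitution probability applied to
#'   each species lineage (scalar or vector of length `n_species`).
#' @param conserved_interval 0-based half-open `c(start, end)` protected from
#'   mutation.
#' @param seed Integer RNG seed.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(ancestral_monomer, n_species = 25L,
                         per_species_divergence = 0.35,
                         conserved_interval, seed = 1L) {
  ancestral_monomer <- check_dna(ancestral_monomer, "ancestral_monomer")
  check_prob(per_species_divergence, "per_species_divergence")
  ci <- as.integer(conserved_interval)
  if (length(ci) != 2L || ci[1] < 0 || ci[2] > nchar(ancestral_monomer) ||
      ci[1] >= ci[2])
    stopf("field 'conserved_interval' lies outside the ancestral monomer")
  structure(list(ancestral_monomer = ancestral_monomer,
                 n_species = as.integer(n_species),
                 per_species_divergence =
                   rep_len(per_species_divergence, n_species),
                 conserved_interval = ci, seed = as.integer(seed)),
            class = "species_spec")
}

#' Species spec emulating the 25-mammal conserved-core alignment
#'
#' A 143-bp ancestral region (the size of the cross-species alignable
#' interval at the motivating locus) with a 34-bp protected core at offset
#' 59, diverged at the default deep-mammal rate.
#'
#' @param seed Integer RNG seed.
#' @param per_species_divergence Per-lineage substitution probability.
#' @return A `species_spec`.
#' @export
dxz4_species_spec <- function(seed = 1L, per_species_divergence = 0.35) {
  species_spec(random_dna(143, seed = seed), n_species = 25L,
               per_species_divergence = per_species_divergence,
               conserved_interval = c(59L, 93L), seed = seed)
}

#' Simulate species-labelled monomer sequences with a protected core
#'
#' @param spec A [species_spec()].
#' @return List with `sequences` (named character vector, equal lengths) and
#'   `conserved_interval` (0-based half-open truth).
#' @export
simulate_species_monomers <- function(spec) {
  stopifnot(inherits(spec, "species_spec"))
  anc <- seq_chars(spec$ancestral_monomer)
  protect <- seq(spec$conserved_interval[1], spec$conserved_interval[2] - 1L)
  with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n_species), function(i)
      chars_seq(mutate_chars(anc, spec$per_species_divergence[i],
                             protect = protect)$chars),
      character(1))
  })
  names(seqs) <- sprintf("species_%02d", seq_len(spec$n_species))
  list(sequences = seqs, conserved_interval = spec$conserved_interval)
}
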