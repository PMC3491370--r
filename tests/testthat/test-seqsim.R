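test_that("zero-rate arrays are exact template concatenations", {
  tmpl <- paste0(random_dna(1000, seed = 1), random_dna(300, seed = 2),
                 random_dna(700, seed = 3))
  unit <- substr(tmpl, 1001, 1300)
  spec <- array_spec(tmpl, 3, unit, 1000, c(1, 1, 1),
                     substitution_rate = 0, seed = 5)
  arr <- generate_array(spec)
  expect_identical(nchar(arr$sequence), 3L * nchar(tmpl))
  iv <- arr$truth$monomer_intervals
  expect_equal(iv$start, c(0, 2000, 4000))
  expect_equal(iv$end, c(2000, 4000, 6000))
  for (i in 1:3)
    expect_identical(substr(arr$sequence, iv$start[i] + 1, iv$end[i]), tmpl)
})

test_that("array length follows the VNTR copy arithmetic", {
  copies <- c(2, 1, 3, 2, 1, 2, 3)
  spec <- dxz4_like_spec(seed = 11, vntr_copies = copies)
  arr <- generate_array(spec)
  expected <- sum(3800 + (copies - 1) * 900)
  expect_equal(nchar(arr$sequence), expected)
  iv <- arr$truth$monomer_intervals
  # tiling without gaps or overlaps
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_equal(iv$start[1], 0)
  expect_equal(iv$end[nrow(iv)], expected)
  expect_equal(iv$length, 3800 + (copies - 1) * 900)
})

test_that("per-monomer mutation counts match the binomial model", {
  spec <- dxz4_like_spec(seed = 21)
  arr <- generate_array(spec)
  r <- arr$truth$per_copy_rate
  # the generator calibrates the per-copy rate so that two copies diverge
  # pairwise at the stated rate; 2r(1-r) + (2/3)r^2 = substitution_rate
  expect_equal(2 * r * (1 - r) + (2 / 3) * r^2, spec$substitution_rate,
               tolerance = 1e-12)
  iv <- arr$truth$monomer_intervals
  for (i in seq_len(nrow(iv))) {
    L <- iv$length[i]
    n_mut <- length(arr$truth$variant_positions[[i]])
    expect_lt(abs(n_mut - L * r), 3 * sqrt(L * r * (1 - r)) + 1)
  }
})

test_that("identical spec and seed give byte-identical arrays", {
  a1 <- generate_array(dxz4_like_spec(seed = 33))
  a2 <- generate_array(dxz4_like_spec(seed = 33))
  expect_identical(a1$sequence, a2$sequence)
  expect_identical(a1$truth, a2$truth)
  a3 <- generate_array(dxz4_like_spec(seed = 34))
  expect_false(identical(a1$sequence, a3$sequence))
})

test_that("array_spec validates its fields by name", {
  tmpl <- random_dna(2000, seed = 1)
  unit <- substr(tmpl, 501, 800)
  expect_error(array_spec(tmpl, 3, unit, 500, c(1, 1)), "vntr_copies")
  expect_error(array_spec(tmpl, 3, unit, 500, c(1, 0, 1)), "vntr_copies")
  expect_error(array_spec(tmpl, 3, unit, 1900, c(1, 1, 1)),
               "vntr_insert_position")
  expect_error(array_spec(tmpl, 3, unit, 500, c(1, 1, 1),
                          substitution_rate = 1.2), "substitution_rate")
})

test_that("planted features are recoverable verbatim at truth coordinates", {
  feat <- random_dna(1000, seed = 7)
  g <- plant_features(20000, list(list(sequence = feat, position = 5000)),
                      seed = 8)
  expect_identical(substr(g$sequence, 5001, 6000), feat)
  expect_identical(nchar(g$sequence), 20000L)
  # two features, sorted truth
  f2 <- random_dna(500, seed = 9)
  g2 <- plant_features(20000, list(list(sequence = f2, position = 9000),
                                   list(sequence = feat, position = 2000)),
                       seed = 8)
  expect_equal(g2$truth$start, c(2000, 9000))
  expect_equal(nrow(g2$truth), 2L)
  expect_error(plant_features(20000,
                              list(list(sequence = feat, position = 1000),
                                   list(sequence = feat, position = 1500))),
               "overlap")
  expect_error(plant_features(2000,
                              list(list(sequence = feat, position = 1500))),
               "range")
})

test_that("bisulfite simulation respects the methylation model", {
  ref <- cpg_scaffold(30, seed = 41)
  # fully methylated, perfect conversion: CpG Cs retained, others read T
  sim1 <- simulate_bisulfite_clones(
    bisulfite_spec(ref, 1, conversion_efficiency = 1, clones_per_group = 2,
                   seed = 42))
  sites <- sim1$cpg_sites
  for (s in sim1$clones$sequence) {
    expect_identical(substring(s, sites + 1, sites + 1),
                     rep("C", length(sites)))
    non_cpg_c <- setdiff(which(strsplit(ref, "")[[1]] == "C") - 1, sites)
    expect_identical(unique(substring(s, non_cpg_c + 1, non_cpg_c + 1)), "T")
  }
  # fully unmethylated: every CpG reads T
  sim0 <- simulate_bisulfite_clones(
    bisulfite_spec(ref, 0, clones_per_group = 2, seed = 43))
  for (s in sim0$clones$sequence)
    expect_identical(unique(substring(s, sites + 1, sites + 1)), "T")
  # half-methylation: overall methylated fraction is binomial
  simh <- simulate_bisulfite_clones(
    bisulfite_spec(ref, 0.5, clones_per_group = 10, seed = 44))
  n_tot <- nrow(simh$truth)
  frac <- mean(simh$truth$state == "methylated")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("allelic read simulation honours ratio, starts and error model", {
  ref <- random_dna(500, seed = 51)
  snps <- make_snp_table(ref, c(50, 150, 250, 350, 450))
  spec0 <- allelic_spec(ref, snps, allelic_ratio = 1, read_length = 100,
                        n_reads = 50, error_rate = 0, seed = 52)
  sim0 <- simulate_allelic_reads(spec0)
  expect_true(all(sim0$reads$hap == "A"))
  for (i in seq_len(nrow(sim0$reads)))
    expect_identical(sim0$reads$sequence[i],
                     substr(sim0$haplotypes$A, sim0$reads$start[i] + 1,
                            sim0$reads$start[i] + 100))
  spec1 <- allelic_spec(ref, snps, allelic_ratio = 0.5, read_length = 100,
                        n_reads = 1000, error_rate = 0.01, seed = 53)
  sim1 <- simulate_allelic_reads(spec1)
  mism <- vapply(seq_len(nrow(sim1$reads)), function(i) {
    src <- sim1$haplotypes[[sim1$reads$hap[i]]]
    a <- strsplit(sim1$reads$sequence[i], "")[[1]]
    b <- strsplit(substr(src, sim1$reads$start[i] + 1,
                         sim1$reads$start[i] + 100), "")[[1]]
    sum(a != b)
  }, numeric(1))
  expect_lt(abs(mean(mism) - 1), 3 * sqrt(100 * 0.01 * 0.99 / 1000))
  expect_error(allelic_spec(ref, snps, read_length = 600), "read_length")
})

test_that("species simulation protects the conserved core", {
  anc <- random_dna(143, seed = 61)
  sp0 <- species_spec(anc, n_species = 5, per_species_divergence = 0,
                      conserved_interval = c(59, 93), seed = 62)
  s0 <- simulate_species_monomers(sp0)
  expect_true(all(s0$sequences == anc))
  sp <- species_spec(anc, n_species = 25, per_species_divergence = 0.15,
                     conserved_interval = c(59, 93), seed = 63)
  s <- simulate_species_monomers(sp)
  core <- substring(s$sequences, 60, 93)
  expect_identical(unique(core), substr(anc, 60, 93))
  # mean pairwise identity outside the core matches the independent-
  # mutation expectation (1-d)^2 + d^2/3
  out_idx <- c(1:59, 94:143)
  m <- matrix(unlist(strsplit(s$sequences, "")), nrow = 25, byrow = TRUE)
  m <- m[, out_idx]
  pr <- combn(25, 2)
  ident <- vapply(seq_len(ncol(pr)), function(j)
    mean(m[pr[1, j], ] == m[pr[2, j], ]), numeric(1))
  q <- 0.85^2 + 0.15^2 / 3
  expect_lt(abs(mean(ident) - q), 3 * sqrt(q * (1 - q) / length(out_idx)))
  expect_error(species_spec(anc, conserved_interval = c(100, 200)),
               "conserved_interval")
})
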