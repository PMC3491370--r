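test_that("strain-specific consensus differences are called as SNPs", {
  ref <- random_dna(232, seed = 401)
  # strain A clones identical to reference; strain B all carry G at 117
  alt <- strsplit(ref, "")[[1]]
  alt[118] <- if (alt[118] == "G") "C" else "G"
  hapB <- paste(alt, collapse = "")
  snps <- call_strain_snps(rep(ref, 5), rep(hapB, 5), ref)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$position, 117L)
  expect_equal(snps$allele_B, alt[118])
})

test_that("within-strain polymorphism below support is not called", {
  ref <- random_dna(232, seed = 402)
  alt <- strsplit(ref, "")[[1]]
  alt[51] <- if (alt[51] == "A") "T" else "A"
  mixed_b <- c(rep(paste(alt, collapse = ""), 7), rep(ref, 3))  # 70/30
  snps <- call_strain_snps(rep(ref, 10), mixed_b, ref, min_support = 0.9)
  expect_equal(nrow(snps), 0L)
})

test_that("planted SNPs are recovered from noisy clone sets", {
  for (seed in c(411, 412)) {
    ref <- random_dna(232, seed = seed)
    truth <- make_snp_table(ref, c(30, 75, 117, 160, 205))
    sim <- simulate_strain_clones(ref, truth, clones_per_strain = 100,
                                  error_rate = 0.005, seed = seed + 1)
    snps <- call_strain_snps(sim$clones_A, sim$clones_B, ref)
    expect_equal(snps$position, truth$position)
    expect_equal(snps$allele_A, truth$allele_A)
    expect_equal(snps$allele_B, truth$allele_B)
  }
})

test_that("the perfect-identity rule assigns and abstains correctly", {
  ref <- random_dna(400, seed = 421)
  truth <- make_snp_table(ref, 200)
  hapA <- apply_alleles(ref, truth$position, truth$allele_A)
  hapB <- apply_alleles(ref, truth$position, truth$allele_B)
  # 100-bp read identical to A spanning the SNP
  read <- substr(hapA, 151, 250)
  a <- assign_reads(read, hapA, hapB)
  expect_equal(a$label, "A")
  expect_gte(a$matched_overlap, 30)
  expect_gte(a$sites_covered, 1L)
  # error at the SNP converting to B's allele: assigned B (the known
  # misassignment mechanism at nonzero error rate)
  snp_in_read <- truth$position + 1L - 150L  # 1-based offset within read
  flip <- read
  substr(flip, snp_in_read, snp_in_read) <- truth$allele_B
  expect_equal(assign_reads(flip, hapA, hapB)$label, "B")
  # error at the SNP to a third base matches neither haplotype
  third <- read
  substr(third, snp_in_read, snp_in_read) <-
    setdiff(c("A", "C", "G", "T"), c(truth$allele_A, truth$allele_B))[1]
  expect_equal(assign_reads(third, hapA, hapB)$label, "uninformative")
  # a read that covers no discriminating site matches both haplotypes
  expect_equal(assign_reads(substr(hapA, 1, 100), hapA, hapB)$label,
               "uninformative")
  # perfect 25-bp match spanning the SNP is below the minimum overlap
  expect_equal(assign_reads(substr(hapA, 190, 214), hapA, hapB)$label,
               "uninformative")
})

test_that("error-free reads are never misassigned", {
  ref <- random_dna(500, seed = 431)
  truth <- make_snp_table(ref, c(60, 160, 260, 360, 460))
  sim <- simulate_allelic_reads(
    allelic_spec(ref, truth, allelic_ratio = 0.5, read_length = 100,
                 n_reads = 1000, error_rate = 0, seed = 432))
  asg <- assign_reads(sim$reads, sim$haplotypes$A, sim$haplotypes$B)
  inf <- asg$label != "uninformative"
  expect_gt(sum(inf), 900)
  expect_equal(sum(asg$label[inf] != sim$reads$hap[inf]), 0L)
})

test_that("allelic fraction estimates track the simulated ratio", {
  ref <- random_dna(500, seed = 441)
  truth <- make_snp_table(ref, c(60, 160, 260, 360, 460))
  for (ratio in c(0.3, 0.7)) {
    est <- vapply(1:5, function(s) {
      sim <- simulate_allelic_reads(
        allelic_spec(ref, truth, allelic_ratio = ratio, read_length = 100,
                     n_reads = 400, error_rate = 0,
                     seed = 450 + s + round(1000 * ratio)))
      asg <- assign_reads(sim$reads, sim$haplotypes$A, sim$haplotypes$B)
      summarize_assignments(asg)$fractions[["A"]]
    }, numeric(1))
    expect_lt(abs(mean(est) - ratio), 0.05)
  }
})

test_that("assignment summaries keep counts and fractions consistent", {
  df <- data.frame(read_id = sprintf("r%d", 1:6),
                   label = c("A", "A", "A", "B", "uninformative", "A"),
                   matched_overlap = c(40, 35, 60, 31, 0, 99),
                   sites_covered = c(1, 1, 2, 1, 0, 3))
  s <- summarize_assignments(df)
  expect_equal(s$counts[["A"]], 4L)
  expect_equal(s$informative, 5L)
  expect_equal(sum(s$fractions), 1)
  expect_equal(s$fractions[["A"]], 0.8)
  all_a <- summarize_assignments(df[df$label == "A", ])
  expect_equal(all_a$fractions[["A"]], 1)
})
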