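ref_fixture <- cpg_scaffold(12, seed = 301)

test_that("clone state calling follows the C/T/other convention", {
  sites <- cpg_positions(ref_fixture)
  # untreated clone: every CpG reads methylated, conversion QC 0, flagged
  p0 <- call_clone_methylation(ref_fixture, ref_fixture)
  expect_true(all(p0$states == "methylated"))
  expect_equal(p0$conversion_qc, 0)
  expect_true(p0$qc_flag)
  # fully converted, unmethylated clone
  conv <- chartr("C", "T", ref_fixture)
  p1 <- call_clone_methylation(ref_fixture, conv)
  expect_true(all(p1$states == "unmethylated"))
  expect_equal(p1$conversion_qc, 1)
  expect_false(p1$qc_flag)
  # CpG-destroying variant: A at one CpG's C reads absent, others intact
  ch <- strsplit(conv, "")[[1]]
  ch[sites[3] + 1] <- "A"
  p2 <- call_clone_methylation(ref_fixture, paste(ch, collapse = ""))
  expect_equal(as.character(p2$states[3]), "absent")
  expect_true(all(p2$states[-3] == "unmethylated"))
})

test_that("clones of different length are aligned before calling", {
  conv <- chartr("C", "T", ref_fixture)
  # 4-base insertion in the middle must not shift downstream site calls
  mid <- nchar(conv) %/% 2
  ins <- paste0(substr(conv, 1, mid), "TTAA",
                substr(conv, mid + 1, nchar(conv)))
  p <- call_clone_methylation(ref_fixture, ins)
  expect_true(all(p$states == "unmethylated"))
})

test_that("unrelated sequence is rejected", {
  expect_error(call_clone_methylation(ref_fixture,
                                      random_dna(nchar(ref_fixture) + 37,
                                                 seed = 9)),
               "does not match")
})

test_that("percent methylation excludes absent sites", {
  st <- function(x) factor(x, levels = c("methylated", "unmethylated",
                                         "absent"))
  expect_equal(percent_methylation(st(rep("methylated", 5))), 100)
  expect_equal(percent_methylation(st(c(rep("methylated", 3),
                                        rep("unmethylated", 3)))), 50)
  expect_equal(percent_methylation(st(c("methylated", "methylated",
                                        "unmethylated", "unmethylated",
                                        rep("absent", 4)))), 50)
  expect_warning(p <- percent_methylation(st(rep("absent", 4))), "absent")
  expect_true(is.na(p))
})

test_that("Welch comparison matches stats::t.test to high precision", {
  set.seed(311)
  for (i in 1:20) {
    x <- runif(sample(3:15, 1), 0, 100)
    y <- runif(sample(3:15, 1), 0, 100)
    got <- suppressWarnings(compare_groups(x, y))
    want <- t.test(x, y, var.equal = FALSE)
    expect_lt(abs(got$t - unname(want$statistic)), 1e-9)
    expect_lt(abs(got$df - unname(want$parameter)), 1e-9)
    expect_lt(abs(got$p - want$p.value), 1e-9)
  }
})

test_that("Welch comparison handles degenerate and symmetric cases", {
  x <- c(50, 50, 50)
  expect_warning(r0 <- compare_groups(x, x), "clones")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  suppressWarnings({
    rz <- compare_groups(c(10, 10, 10), c(20, 20, 20))
    expect_equal(rz$p, 0)
    expect_equal(rz$flag, "zero-variance")
    a <- runif(10, 0, 100); b <- runif(10, 0, 100)
    r1 <- compare_groups(a, b); r2 <- compare_groups(b, a)
    expect_equal(r1$p, r2$p)
    expect_equal(r1$t, -r2$t)
  })
})

test_that("null simulations give nominal type-I error rates", {
  ref <- cpg_scaffold(30, seed = 321)
  pvals <- vapply(1:200, function(s)
    run_welch_sim(ref, 0.5, 10, seed = 10000 + s)$p, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.015)
  expect_lte(rate, 0.10)
})

test_that("the sex-difference design is detected with high power", {
  ref <- cpg_scaffold(30, seed = 331)
  n_sites <- 30
  hits <- vapply(1:50, function(s) {
    # males: all clones at 0.85; females: half 0.85 (Xa), half 0.15 (Xi)
    spec_m <- bisulfite_spec(ref, 0.85, clones_per_group = 10,
                             groups = "male", seed = 20000 + s)
    male <- simulate_bisulfite_clones(spec_m)
    male_pct <- vapply(seq_len(nrow(male$clones)), function(i)
      percent_methylation(call_clone_methylation(
        ref, male$clones$sequence[i])), numeric(1))
    pf <- matrix(c(rep(0.85, n_sites), rep(0.15, n_sites)), ncol = 2)
    spec_f <- bisulfite_spec(ref, pf, clones_per_group = 5,
                             groups = c("xa", "xi"), seed = 30000 + s)
    fem <- simulate_bisulfite_clones(spec_f)
    fem_pct <- vapply(seq_len(nrow(fem$clones)), function(i)
      percent_methylation(call_clone_methylation(
        ref, fem$clones$sequence[i])), numeric(1))
    suppressWarnings(compare_groups(male_pct, fem_pct)$p) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("state matrix renders the lollipop layout", {
  conv <- chartr("C", "T", ref_fixture)
  profs <- list(call_clone_methylation(ref_fixture, ref_fixture, "c1"),
                call_clone_methylation(ref_fixture, conv, "c2"))
  m <- state_matrix(profs)
  expect_equal(dim(m), c(2L, 12L))
  expect_true(all(m["c1", ] == "M"))
  expect_true(all(m["c2", ] == "U"))
})
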