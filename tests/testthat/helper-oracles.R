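## Independent oracles and fixture builders shared across test files.
## Oracles deliberately use a different algorithmic route than the package
## (diagonal run-length scans instead of k-mer hashing; direct per-window
## counting instead of cumulative sums).

## All maximal exact matches of length >= min_segment between distinct
## positions (forward) and against the reverse complement (reverse), by
## scanning every diagonal with run-length encoding.
brute_self_matches <- function(sequence, min_segment) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  rows <- list(); ri <- 0L
  for (d in seq_len(n - 1L)) {
    i <- seq_len(n - d)
    eq <- ch[i] == ch[i + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_segment)
    for (h in hit) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        q_start = starts[h] - 1L, q_end = starts[h] - 1L + r$lengths[h],
        t_start = starts[h] - 1L + d, t_end = starts[h] - 1L + d + r$lengths[h],
        strand = "forward")
    }
  }
  rc <- strsplit(macrosat::revcomp(sequence), "")[[1]]
  for (d in (1L - n):(n - 1L)) {
    i <- seq(max(1L, 1L - d), min(n, n - d))
    eq <- ch[i] == rc[i + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- i[1L] + ends - r$lengths
    hit <- which(r$values & r$lengths >= min_segment)
    for (h in hit) {
      q0 <- starts[h] - 1L; len <- r$lengths[h]
      j0 <- q0 + d
      t0 <- n - (j0 + len); t1 <- n - j0
      if (q0 > t0) { tmp <- q0; q0 <- t0; t0 <- tmp }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(q_start = q0, q_end = q0 + len,
                               t_start = t0, t_end = t0 + len,
                               strand = "reverse")
    }
  }
  if (ri == 0L)
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0)))
  out <- unique(do.call(rbind, rows))
  out[order(out$strand, out$q_start, out$t_start), , drop = FALSE]
}

## Direct per-window CpG-island criteria check and merge.
brute_find_cgis <- function(sequence, min_length = 200L, min_gc = 0.5,
                            min_obs_exp = 0.6) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  w <- min_length
  qual <- logical(n - w + 1L)
  for (s in seq_len(n - w + 1L)) {
    win <- ch[s:(s + w - 1L)]
    nc <- sum(win == "C"); ng <- sum(win == "G")
    ncpg <- sum(win[-w] == "C" & win[-1L] == "G")
    gc <- (nc + ng) / w
    oe <- if (nc > 0 && ng > 0) ncpg / (nc * ng / w) else 0
    qual[s] <- gc >= min_gc && oe >= min_obs_exp
  }
  hits <- which(qual)
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(TRUE, diff(hits) > w)   # windows overlap when starts differ < w
  cl <- cumsum(brk)
  do.call(rbind, lapply(split(hits, cl), function(q)
    data.frame(start = min(q) - 1L, end = max(q) + w - 1L)))
}

## Shannon-entropy information content computed directly from a character
## matrix, independent of build_pwm.
brute_column_ic <- function(seqs) {
  m <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
              byrow = TRUE)
  apply(m, 2L, function(col) {
    f <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    f <- f[f > 0]
    2 - sum(-f * log2(f))
  })
}

## sequence with embedded direct/inverted structure for oracle comparisons
structured_seq <- function(seed, len = 2000L) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  block <- substr(base, 101L, 400L)
  # duplicate a block and insert its reverse complement elsewhere
  paste0(substr(base, 1L, 900L), block,
         substr(base, 901L, 1500L), macrosat::revcomp(block),
         substr(base, 1501L, len))
}

run_welch_sim <- function(ref, prob_matrix, n_clones, seed,
                          groups = c("g1", "g2")) {
  spec <- bisulfite_spec(ref, methylation_prob = prob_matrix,
                         clones_per_group = n_clones, groups = groups,
                         seed = seed)
  sim <- simulate_bisulfite_clones(spec)
  pct <- vapply(seq_len(nrow(sim$clones)), function(i) {
    prof <- call_clone_methylation(ref, sim$clones$sequence[i],
                                   sim$clones$clone_id[i])
    percent_methylation(prof)
  }, numeric(1))
  suppressWarnings(
    compare_groups(pct[sim$clones$group == groups[1]],
                   pct[sim$clones$group == groups[2]]))
}

revcomp_iupac_test <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(motif), "")[[1]]]), collapse = "")
}

make_snp_table <- function(reference, positions) {
  ref_a <- substring(reference, positions + 1L, positions + 1L)
  alt <- vapply(ref_a, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1L], character(1))
  data.frame(position = positions, allele_A = unname(ref_a),
             allele_B = unname(alt))
}
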