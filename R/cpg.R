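## Base-composition statistics and CpG-island calling. Island criteria
## follow the classical Gardiner-Garden & Frommer thresholds (length >= 200,
## GC >= 50%, observed/expected CpG >= 0.6); all three are exposed as
## parameters.

comp_counts <- function(sequence) {
  ch <- seq_chars(toupper(sequence))
  list(chars = ch,
       c = sum(ch == "C"), g = sum(ch == "G"),
       a = sum(ch == "A"), t = sum(ch == "T"))
}

#' GC fraction of a sequence
#'
#' Ambiguous bases (anything outside A/C/G/T) are excluded from both
#' numerator and denominator; case-insensitive.
#'
#' @param sequence DNA string.
#' @return Fraction in [0, 1].
#' @export
gc_fraction <- function(sequence) {
  if (nchar(sequence) == 0L) stopf("empty sequence")
  n <- comp_counts(sequence)
  unamb <- n$a + n$c + n$g + n$t
  if (unamb == 0L) stopf("sequence contains no unambiguous base")
  (n$g + n$c) / unamb
}

#' AT fraction of a sequence
#' @param sequence DNA string.
#' @return Fraction in [0, 1]; complements [gc_fraction()] on unambiguous
#'   input.
#' @export
at_fraction <- function(sequence) {
  n <- comp_counts(sequence)
  unamb <- n$a + n$c + n$g + n$t
  if (unamb == 0L) stopf("sequence contains no unambiguous base")
  (n$a + n$t) / unamb
}

#' Number of CpG dinucleotides
#'
#' A CpG spanning an ambiguous base is not counted.
#'
#' @param sequence DNA string.
#' @return Integer count.
#' @export
cpg_count <- function(sequence) {
  length(cpg_positions(sequence))
}

#' Observed/expected CpG ratio
#'
#' Observed CpG count divided by (#C x #G / length), the expectation under
#' independent base placement.
#'
#' @param sequence DNA string.
#' @return Ratio >= 0; 0 with a warning when the sequence has no C or no G.
#' @export
cpg_obs_exp <- function(sequence) {
  n <- comp_counts(sequence)
  if (n$c == 0L || n$g == 0L) {
    warnf("sequence has no C or no G; observed/expected CpG set to 0")
    return(0)
  }
  cpg_count(sequence) / (n$c * n$g / nchar(sequence))
}

#' Call CpG islands
#'
#' Slides a `min_length`-bp window by 1 bp; windows satisfying all three
#' criteria (GC fraction, observed/expected CpG, implicit length) are merged
#' when they overlap, and each island is the union of its qualifying
#' windows — the maximal extent still covered by windows meeting the
#' criteria. Island-level composition metrics are recomputed on the merged
#' interval.
#'
#' @param sequence DNA string, length >= `min_length`.
#' @param min_length Window size and minimum island length, bp.
#' @param min_gc Minimum window GC fraction.
#' @param min_obs_exp Minimum window observed/expected CpG ratio.
#' @return Data frame sorted by start (0-based half-open): `start`, `end`,
#'   `length`, `gc_fraction`, `cpg_count`, `obs_exp`. Empty when no window
#'   qualifies.
#' @export
find_cgis <- function(sequence, min_length = 200L, min_gc = 0.5,
                      min_obs_exp = 0.6) {
  n <- nchar(sequence)
  if (n < min_length)
    stopf("sequence (%d bp) shorter than min_length (%d bp)", n, min_length)
  ch <- seq_chars(toupper(sequence))
  is_c <- ch == "C"; is_g <- ch == "G"
  is_cpg <- c(is_c[-n] & is_g[-1L], FALSE)
  is_ok <- ch %in% DNA_BASES
  w <- min_length
  csum <- function(x) { s <- cumsum(x); s[w:n] - c(0, s[seq_len(n - w)]) }
  wc <- csum(is_c); wg <- csum(is_g); wok <- csum(is_ok)
  # CpGs fully inside the window: starts in [ws, ws+w-2]
  scpg <- cumsum(is_cpg)
  wcpg <- scpg[(w - 1L):(n - 1L)] - c(0, scpg[seq_len(n - w)])
  gc <- ifelse(wok > 0, (wc + wg) / wok, 0)
  oe <- ifelse(wc > 0 & wg > 0, wcpg / (wc * wg / w), 0)
  qual <- which(gc >= min_gc & oe >= min_obs_exp)  # 1-based window starts
  if (length(qual) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      cpg_count = integer(0), obs_exp = numeric(0)))
  cl <- cluster_1d(qual, qual + w, 0L)
  rows <- lapply(split(qual, cl), function(q) {
    s0 <- min(q) - 1L; s1 <- max(q) + w - 1L
    island <- substr(sequence, s0 + 1L, s1)
    data.frame(start = s0, end = s1, length = s1 - s0,
               gc_fraction = gc_fraction(island),
               cpg_count = cpg_count(island),
               obs_exp = cpg_obs_exp(island))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sequence composition metrics table
#'
#' @param seqs Named character vector of sequences.
#' @return Data frame: `name`, `length`, `gc_fraction`, `cpg_count`,
#'   `obs_exp`.
#' @export
composition_table <- function(seqs) {
  data.frame(name = if (is.null(names(seqs))) as.character(seq_along(seqs))
                    else names(seqs),
             length = nchar(seqs),
             gc_fraction = vapply(seqs, gc_fraction, numeric(1)),
             cpg_count = vapply(seqs, cpg_count, integer(1)),
             obs_exp = vapply(seqs, cpg_obs_exp, numeric(1)),
             row.names = NULL)
}
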