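## Strain-SNP discovery from clone sets and allele-specific read assignment.
## The assignment rule is perfect identity over a minimum overlap: a read
## belongs to a haplotype only if some placement matches it with 100%
## identity over at least `min_overlap` bases covering at least one
## discriminating site, and no such placement exists on the other haplotype.
## "Alignment" is realized as exact substring search: any perfect overlap of
## length >= L contains an exact L-mer, so reads are screened against the
## SNP-covering L-mers of each haplotype.

#' Call strain-discriminating SNPs from two clone sets
#'
#' Per position and strain the consensus is the modal base over clones;
#' positions where the two consensuses differ and both within-strain modal
#' fractions reach `min_support` are reported as strain variants. Clones
#' whose length differs from the reference or whose identity to it falls
#' below 80% are skipped with a warning.
#'
#' @param clones_A,clones_B Character vectors of clone sequences, one per
#'   clone (full-length copies of the reference region).
#' @param reference Reference region, DNA string.
#' @param min_support Minimum within-strain modal fraction.
#' @return Data frame: `position` (0-based), `allele_A`, `allele_B`,
#'   `support_A`, `support_B`. Empty when no position qualifies.
#' @export
call_strain_snps <- function(clones_A, clones_B, reference,
                             min_support = 0.9) {
  reference <- toupper(reference)
  n <- nchar(reference)
  ref_ch <- seq_chars(reference)
  screen <- function(clones, label) {
    clones <- toupper(clones)
    keep <- rep(TRUE, length(clones))
    for (i in seq_along(clones)) {
      if (nchar(clones[i]) != n) {
        keep[i] <- FALSE
      } else if (mean(seq_chars(clones[i]) == ref_ch) < 0.8) {
        keep[i] <- FALSE
      }
    }
    if (any(!keep))
      warnf("skipped %d unalignable clone(s) in strain %s",
            sum(!keep), label)
    clones[keep]
  }
  ca <- screen(clones_A, "A"); cb <- screen(clones_B, "B")
  if (length(ca) < 2L || length(cb) < 2L)
    stopf("need >= 2 alignable clones per strain")
  consensus <- function(clones) {
    m <- matrix(unlist(strsplit(clones, "", fixed = TRUE)),
                nrow = length(clones), byrow = TRUE)
    base <- character(n); frac <- numeric(n)
    for (j in seq_len(n)) {
      tab <- table(m[, j])
      base[j] <- names(tab)[which.max(tab)]
      frac[j] <- max(tab) / length(clones)
    }
    list(base = base, frac = frac)
  }
  a <- consensus(ca); b <- consensus(cb)
  hit <- which(a$base != b$base & a$frac >= min_support &
                 b$frac >= min_support)
  data.frame(position = hit - 1L, allele_A = a$base[hit],
             allele_B = b$base[hit], support_A = a$frac[hit],
             support_B = b$frac[hit])
}

## All `len`-mers of `hap` whose window covers >= 1 of `sites` (0-based);
## returns kmer strings and the number of distinct sites each covers.
snp_window_kmers <- function(hap, sites, len) {
  n <- nchar(hap)
  starts <- unique(unlist(lapply(sites, function(p) {
    lo <- max(0L, p - len + 1L); hi <- min(p, n - len)
    if (hi < lo) integer(0) else seq(lo, hi)
  })))
  starts <- sort(starts)
  covered <- vapply(starts, function(s)
    sum(sites >= s & sites < s + len), integer(1))
  data.frame(kmer = substring(hap, starts + 1L, starts + len),
             n_sites = covered)
}

#' Assign reads to haplotypes by the perfect-identity rule
#'
#' A read is labelled A when it shares an exact `min_overlap`-mer with
#' haplotype A covering at least one discriminating site and shares none
#' with haplotype B (and symmetrically for B); all other reads — including
#' reads shorter than `min_overlap`, reads covering no discriminating site,
#' and reads matching both haplotypes — are uninformative.
#'
#' @param reads Character vector of read sequences (or the `reads` data
#'   frame from [simulate_allelic_reads()]).
#' @param hap_A,hap_B Haplotype sequences (reference with the strain alleles
#'   applied, e.g. via [apply_alleles()]).
#' @param min_overlap Minimum perfect-identity overlap, bp.
#' @return Data frame: `read_id`, `label` ("A"/"B"/"uninformative"),
#'   `matched_overlap` (bp of the longest perfect SNP-covering stretch, 0
#'   for uninformative reads), `sites_covered`.
#' @export
assign_reads <- function(reads, hap_A, hap_B, min_overlap = 30L) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$sequence
  } else {
    ids <- if (is.null(names(reads))) sprintf("read_%05d", seq_along(reads))
           else names(reads)
  }
  sites <- which(seq_chars(hap_A) != seq_chars(hap_B)) - 1L
  ka <- snp_window_kmers(hap_A, sites, min_overlap)
  kb <- snp_window_kmers(hap_B, sites, min_overlap)
  nr <- length(reads)
  label <- rep("uninformative", nr)
  overlap <- integer(nr)
  covered <- integer(nr)
  for (i in seq_len(nr)) {
    L <- nchar(reads[i])
    if (L < min_overlap) next
    st <- seq_len(L - min_overlap + 1L)
    rk <- substring(reads[i], st, st + min_overlap - 1L)
    ia <- match(rk, ka$kmer)
    ib <- match(rk, kb$kmer)
    hit_a <- any(!is.na(ia)); hit_b <- any(!is.na(ib))
    if (hit_a == hit_b) next          # both or neither -> uninformative
    idx <- if (hit_a) ia else ib
    tab <- if (hit_a) ka else kb
    label[i] <- if (hit_a) "A" else "B"
    hits <- which(!is.na(idx))
    runs <- rle(diff(c(-2L, hits)) == 1L)
    # m consecutive matching k-mer starts = one exact stretch of
    # min_overlap + m - 1 bases
    m_consec <- max(c(0L, runs$lengths[runs$values])) + 1L
    overlap[i] <- min_overlap + m_consec - 1L
    covered[i] <- max(tab$n_sites[idx[hits]])
  }
  data.frame(read_id = ids, label = label, matched_overlap = overlap,
             sites_covered = covered)
}

#' Summarize read assignments
#'
#' @param assignments Data frame from [assign_reads()].
#' @return Object of class `assignment_summary`: per-label counts, the
#'   number of informative reads, and fractions of informative reads per
#'   haplotype.
#' @export
summarize_assignments <- function(assignments) {
  counts <- c(A = sum(assignments$label == "A"),
              B = sum(assignments$label == "B"),
              uninformative = sum(assignments$label == "uninformative"))
  informative <- counts[["A"]] + counts[["B"]]
  fractions <- if (informative > 0)
    c(A = counts[["A"]] / informative, B = counts[["B"]] / informative)
  else c(A = NA_real_, B = NA_real_)
  structure(list(counts = counts, total = nrow(assignments),
                 informative = informative, fractions = fractions),
            class = "assignment_summary")
}

#' @export
print.assignment_summary <- function(x, ...) {
  cat(sprintf(
    "assignment_summary: %d reads, %d informative\n  A: %d (%.1f%% of informative)\n  B: %d (%.1f%% of informative)\n  uninformative: %d\n",
    x$total, x$informative,
    x$counts[["A"]], 100 * x$fractions[["A"]],
    x$counts[["B"]], 100 * x$fractions[["B"]],
    x$counts[["uninformative"]]))
  invisible(x)
}
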