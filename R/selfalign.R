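## Seed-based self-alignment. Exact k-mer seeds are grouped by hash; runs of
## consecutive seeds on one diagonal assemble into maximal exact match
## segments, on the forward strand (sequence vs itself) and the reverse
## strand (sequence vs its reverse complement). This replaces an external
## dotplot aligner with a transparent, testable primitive.

kmer_starts <- function(sequence, k) {
  n <- nchar(sequence)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  list(starts = starts[ok], kmers = kmers[ok])
}

## Assemble maximal segments from seed pairs (q, t) sharing a diagonal.
## A maximal exact match of length L >= k contains exactly L-k+1 seeds at
## consecutive q on one diagonal, so runs of consecutive seeds reconstruct
## the maximal matches without per-base extension.
seeds_to_segments <- function(q, t, k, min_segment) {
  if (length(q) == 0L)
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0)))
  d <- t - q
  ord <- order(d, q)
  d <- d[ord]; q <- q[ord]; t <- t[ord]
  new_run <- c(TRUE, d[-1L] != d[-length(d)] | q[-1L] != q[-length(q)] + 1L)
  run_id <- cumsum(new_run)
  len <- tabulate(run_id) + k - 1L
  q0 <- q[new_run]; t0 <- t[new_run]
  keep <- len >= min_segment
  data.frame(q_start = q0[keep] - 1L, q_end = q0[keep] - 1L + len[keep],
             t_start = t0[keep] - 1L, t_end = t0[keep] - 1L + len[keep])
}

group_pairs <- function(groups) {
  qs <- vector("list", length(groups))
  ts <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    pos <- sort(groups[[i]])
    m <- length(pos)
    if (m < 2L) next
    pr <- combn(pos, 2L)
    qs[[i]] <- pr[1L, ]; ts[[i]] <- pr[2L, ]
  }
  list(q = unlist(qs), t = unlist(ts))
}

#' Exact self-alignment match segments on both strands
#'
#' Finds every maximal exact match of length >= `min_segment` between two
#' distinct positions of `sequence` (forward strand) or between `sequence`
#' and its reverse complement (reverse strand). The trivial full-length
#' self-match on the main diagonal is excluded and symmetric duplicates
#' (q,t)/(t,q) are collapsed to the representative with `q_start <= t_start`.
#' All coordinates are 0-based half-open on the input sequence.
#'
#' @param sequence DNA string.
#' @param k Seed length (>= 4); matches shorter than `k` cannot be seeded, so
#'   `min_segment >= k` is required.
#' @param min_segment Minimum reported match length, bp.
#' @return Data frame with columns `q_start`, `q_end`, `t_start`, `t_end`,
#'   `strand` ("forward"/"reverse"), `length`.
#' @export
self_matches <- function(sequence, k = 13L, min_segment = 25L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (k < 4L) stopf("k too small (minimum 4)")
  if (k > n) stopf("k too large for a sequence of length %d", n)
  if (min_segment < k) stopf("min_segment must be >= k")

  fw <- kmer_starts(sequence, k)
  grp <- split(fw$starts, fw$kmers)
  grp <- grp[lengths(grp) >= 2L]
  pairs <- group_pairs(grp)
  fseg <- seeds_to_segments(pairs$q, pairs$t, k, min_segment)
  fseg$strand <- rep("forward", nrow(fseg))

  rcseq <- revcomp(sequence)
  rv <- kmer_starts(rcseq, k)
  rgrp <- split(rv$starts, rv$kmers)
  allf <- split(fw$starts, fw$kmers)
  shared <- intersect(names(allf), names(rgrp))
  qs <- vector("list", length(shared))
  js <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    a <- allf[[shared[i]]]; b <- rgrp[[shared[i]]]
    qs[[i]] <- rep(a, each = length(b))
    js[[i]] <- rep(b, times = length(a))
  }
  rseg <- seeds_to_segments(unlist(qs), unlist(js), k, min_segment)
  if (nrow(rseg)) {
    # map rc coordinates back to the original sequence:
    # rc interval [j, j+L) corresponds to original [n-j-L, n-j)
    t_start <- n - rseg$t_end
    t_end <- n - rseg$t_start
    rseg$t_start <- t_start
    rseg$t_end <- t_end
    swap <- rseg$q_start > rseg$t_start
    tmp_qs <- rseg$q_start[swap]; tmp_qe <- rseg$q_end[swap]
    rseg$q_start[swap] <- rseg$t_start[swap]
    rseg$q_end[swap] <- rseg$t_end[swap]
    rseg$t_start[swap] <- tmp_qs; rseg$t_end[swap] <- tmp_qe
    rseg <- unique(rseg)
  }
  rseg$strand <- rep("reverse", nrow(rseg))

  out <- rbind(fseg, rseg)
  out$length <- out$q_end - out$q_start
  out <- out[order(out$strand, out$q_start, out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned dotplot of self-alignment segments
#'
#' Diagnostic matrices counting matched bases per bin pair; the forward grid
#' is symmetric about the main diagonal. Not used by the callers.
#'
#' @param segments Output of [self_matches()].
#' @param seq_length Length of the aligned sequence, bp.
#' @param bin_size Bin width, bp.
#' @return List with `bin_size`, `forward_counts`, `reverse_counts`
#'   (integer matrices, dimension `ceiling(seq_length / bin_size)`).
#' @export
dotplot <- function(segments, seq_length, bin_size = 500L) {
  nb <- ceiling(seq_length / bin_size)
  fwd <- matrix(0L, nb, nb)
  rev <- matrix(0L, nb, nb)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    idx <- seq(0L, s$length - 1L)
    qb <- (s$q_start + idx) %/% bin_size + 1L
    tb <- if (s$strand == "forward") (s$t_start + idx) %/% bin_size + 1L
          else (s$t_end - 1L - idx) %/% bin_size + 1L
    tab <- table(qb, tb)
    cells <- as.integer(rownames(tab))[row(tab)[tab > 0]]
    cellt <- as.integer(colnames(tab))[col(tab)[tab > 0]]
    vals <- as.integer(tab[tab > 0])
    if (s$strand == "forward") {
      for (j in seq_along(vals)) {
        fwd[cells[j], cellt[j]] <- fwd[cells[j], cellt[j]] + vals[j]
        fwd[cellt[j], cells[j]] <- fwd[cellt[j], cells[j]] + vals[j]
      }
    } else {
      for (j in seq_along(vals)) {
        rev[cells[j], cellt[j]] <- rev[cells[j], cellt[j]] + vals[j]
        rev[cellt[j], cells[j]] <- rev[cellt[j], cells[j]] + vals[j]
      }
    }
  }
  list(bin_size = bin_size, forward_counts = fwd, reverse_counts = rev)
}
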