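## Monomer decomposition of a called tandem array. Because an internal VNTR
## makes monomer length variable (3.8-5.7 kb at the motivating locus), the
## array is phased with a periodic anchor k-mer rather than cut at a fixed
## period, and the cut register is refined against the array's leading edge.

#' Find a periodic anchor k-mer in a tandem array
#'
#' Scans all k-mers with at least two occurrences and scores each by
#' (number of occurrences whose successive spacings lie within 40% of their
#' own median) x (median spacing) — the portion of the array that the
#' periodic recurrence explains. This prefers a once-per-monomer anchor over
#' k-mers of an internal sub-repeat, which recur more often but with a much
#' smaller spacing. Ties break toward more occurrences, then
#' lexicographically, for determinism.
#'
#' @param array_seq DNA string containing >= 2 approximate repeat units.
#' @param k Anchor k-mer length.
#' @return List with `anchor` (the k-mer), `positions` (sorted 0-based
#'   occurrence starts) and `median_spacing`.
#' @export
find_anchor <- function(array_seq, k = 16L) {
  array_seq <- toupper(array_seq)
  km <- kmer_starts(array_seq, k)
  grp <- split(km$starts, km$kmers)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0L) stopf("no periodic anchor")
  n <- nchar(array_seq)
  stats <- lapply(grp, function(pos) {
    pos <- sort(pos)
    d <- diff(pos)
    med <- median(d)
    regular <- 1L + sum(abs(d - med) <= 0.4 * med)
    # explained span cannot exceed the array itself: caps the score of a
    # chance k-mer pair straddling the whole sequence
    c(score = min(regular * med, n), regular = regular, med = med,
      extras = length(pos) - regular)
  })
  score <- vapply(stats, `[[`, numeric(1), "score")
  regular <- vapply(stats, `[[`, numeric(1), "regular")
  extras <- vapply(stats, `[[`, numeric(1), "extras")
  # scores within 5% of the maximum are ties (the cap flattens every
  # near-full-span candidate); tie-break: most regularly spaced
  # occurrences, then fewest off-period extras (which an anchor inside a
  # VNTR copy accumulates), then lexicographic order
  best <- score >= 0.95 * max(score)
  cand <- names(grp)[best]
  reg <- regular[best]; ext <- extras[best]
  cand <- cand[reg == max(reg)]
  ext <- ext[reg == max(reg)]
  anchor <- sort(cand[ext == min(ext)])[1L]
  pos <- sort(grp[[anchor]])
  list(anchor = anchor, positions = pos - 1L,
       median_spacing = median(diff(pos)))
}

## Refine the cut register: the first `probe_len` bases of the array are the
## leading edge of monomer 1; their approximate recurrences mark every
## monomer start directly. Returns 0-based starts, or NULL when the probe is
## not recovered once per anchor.
refine_register <- function(array_seq, anchors, probe_len = 200L,
                            max_mismatch_frac = 0.2) {
  if (nchar(array_seq) < probe_len) return(NULL)
  probe <- substr(array_seq, 1L, probe_len)
  hits <- Biostrings::matchPattern(
    probe, Biostrings::DNAString(array_seq),
    max.mismatch = round(max_mismatch_frac * probe_len))
  st <- sort(BiocGenerics::start(hits)) - 1L
  if (length(st) == 0L) return(NULL)
  # collapse hit clusters closer than half the anchor spacing
  spacing <- median(diff(sort(anchors)))
  cl <- cluster_1d(st, st, max(50L, spacing %/% 4L))
  starts <- vapply(split(st, cl), min, numeric(1))
  starts <- sort(unname(starts))
  if (length(starts) != length(anchors)) return(NULL)
  as.integer(starts)
}

#' Segment a tandem array into monomers
#'
#' Cut points are placed once per anchor occurrence. When the array's
#' leading edge is recovered once per monomer (approximate matching of the
#' first 200 bp), cuts snap to those recurrences, which fixes the otherwise
#' arbitrary phase register of the anchor; otherwise the raw anchor
#' positions are used and partial flanks before the first cut are reported
#' separately. The last monomer ends at the array end.
#'
#' @param array_seq DNA string.
#' @param anchor_positions Sorted 0-based anchor occurrence starts
#'   (>= 2), e.g. from [find_anchor()].
#' @return List of class `monomer_set`: `monomer_intervals` (data frame
#'   `start`, `end`, `length`, 0-based half-open, tiling the spanned
#'   region), `monomers` (character vector of sequences), `flank`
#'   (the partial leading flank interval, possibly empty) and `register`
#'   ("refined" or "anchor").
#' @export
segment_monomers <- function(array_seq, anchor_positions) {
  if (length(anchor_positions) < 2L)
    stopf("need >= 2 anchor positions to segment")
  anchors <- sort(as.integer(anchor_positions))
  cuts <- refine_register(array_seq, anchors)
  register <- "refined"
  if (is.null(cuts)) {
    cuts <- anchors
    register <- "anchor"
  }
  n <- nchar(array_seq)
  starts <- cuts
  ends <- c(cuts[-1L], n)
  iv <- data.frame(start = starts, end = ends, length = ends - starts)
  monomers <- substring(array_seq, starts + 1L, ends)
  structure(list(monomer_intervals = iv, monomers = monomers,
                 flank = c(0L, starts[1L]), register = register),
            class = "monomer_set")
}

#' @export
print.monomer_set <- function(x, ...) {
  cat(sprintf("monomer_set: %d monomers, lengths %d-%d bp (register: %s)\n",
              nrow(x$monomer_intervals), min(x$monomer_intervals$length),
              max(x$monomer_intervals$length), x$register))
  print(x$monomer_intervals)
  invisible(x)
}

#' Pairwise percent-divergence matrix of monomers
#'
#' Each pair is globally aligned (Needleman-Wunsch via
#' \code{Biostrings::pairwiseAlignment}); percent divergence is substituted
#' columns over alignment columns, excluding columns inside gap runs of at
#' least `long_indel` bp. The long-indel exclusion prevents VNTR copy-number
#' differences (kilobase-scale gaps) from inflating a substitution-level
#' divergence estimate.
#'
#' @param monomers Character vector of >= 2 monomer sequences (or a
#'   `monomer_set`).
#' @param long_indel Gap-run length, bp, from which columns are excluded.
#' @return List with `divergence` (symmetric percent matrix, zero diagonal)
#'   and `aligned_columns` (columns counted per pair).
#' @export
divergence_matrix <- function(monomers, long_indel = 50L) {
  if (inherits(monomers, "monomer_set")) monomers <- monomers$monomers
  if (length(monomers) < 2L) stopf("need >= 2 monomers")
  if (any(nchar(monomers) == 0L)) stopf("empty monomer sequence")
  n <- length(monomers)
  div <- matrix(0, n, n)
  cols <- matrix(NA_integer_, n, n)
  diag(cols) <- nchar(monomers)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(
        monomers[i], monomers[j], type = "global",
        substitutionMatrix = mat, gapOpening = 12, gapExtension = 0.5)
      a <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
      b <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
      gap <- a == "-" | b == "-"
      r <- rle(gap)
      long <- rep(r$values & r$lengths >= long_indel, r$lengths)
      denom <- sum(!long)
      subs <- sum(!gap & !long & a != b)
      div[i, j] <- div[j, i] <- 100 * subs / denom
      cols[i, j] <- cols[j, i] <- denom
    }
  }
  list(divergence = div, aligned_columns = cols)
}

#' Detect an internal VNTR and per-monomer copy numbers
#'
#' Runs the self-aligner within each monomer; recurring internal offsets
#' shared across monomers (the same offset family, i.e. multiples of one
#' unit length) define the VNTR unit. Copy number per monomer is one plus
#' the largest internal offset expressed in units: a monomer whose largest
#' internal self-match offset is m unit-lengths carries m+1 copies.
#'
#' @param monomers Character vector of monomer sequences (or a
#'   `monomer_set`).
#' @param k,min_segment Passed to [self_matches()].
#' @param reference Index of the reference monomer for `unit_interval`;
#'   default the shortest monomer.
#' @return List of class `vntr_call`: `unit_length` (bp; NA when no
#'   internal repeat exists anywhere), `unit_interval` (0-based half-open
#'   within the reference monomer, NA when not locatable),
#'   `copies_per_monomer`, `reference_monomer`.
#' @export
detect_vntr <- function(monomers, k = 13L, min_segment = 25L,
                        reference = NULL) {
  if (inherits(monomers, "monomer_set")) monomers <- monomers$monomers
  if (length(monomers) < 2L) stopf("need >= 2 monomers")
  if (is.null(reference)) reference <- which.min(nchar(monomers))
  segs <- lapply(monomers, function(m) {
    s <- self_matches(m, k, min_segment)
    s <- s[s$strand == "forward", , drop = FALSE]
    s$offset <- s$t_start - s$q_start
    s
  })
  offs <- unlist(lapply(segs, function(s) rep(s$offset, s$length)))
  if (length(offs) == 0L) {
    return(structure(list(unit_length = NA_real_,
                          unit_interval = c(NA_integer_, NA_integer_),
                          copies_per_monomer = rep(1L, length(monomers)),
                          reference_monomer = reference),
                     class = "vntr_call"))
  }
  cl <- offset_clusters(offs)
  # unit = smallest offset family (coverage-weighted median of the lowest
  # cluster); larger families are its multiples
  unit <- median(offs[cl == cl[which.min(offs)]])
  copies <- vapply(segs, function(s) {
    if (nrow(s) == 0L) return(1L)
    mult <- round(s$offset / unit)
    ok <- mult >= 1L & abs(s$offset - mult * unit) <= 0.2 * unit
    if (!any(ok)) return(1L)
    1L + as.integer(max(mult[ok]))
  }, integer(1))
  # locate the unit inside the reference monomer via the monomer with the
  # most copies
  donor <- which.max(copies)
  ds <- segs[[donor]]
  ds <- ds[abs(ds$offset - unit) <= 0.2 * unit, , drop = FALSE]
  unit_interval <- c(NA_integer_, NA_integer_)
  if (nrow(ds) > 0L) {
    u_start <- min(ds$q_start)
    unit_seq <- substr(monomers[donor], u_start + 1L, u_start + round(unit))
    hit <- Biostrings::matchPattern(
      unit_seq, Biostrings::DNAString(monomers[reference]),
      max.mismatch = round(0.15 * nchar(unit_seq)))
    if (length(hit) > 0L) {
      hs <- BiocGenerics::start(hit)[1L] - 1L
      unit_interval <- c(hs, hs + nchar(unit_seq))
    }
  }
  structure(list(unit_length = unit, unit_interval = unit_interval,
                 copies_per_monomer = copies,
                 reference_monomer = reference),
            class = "vntr_call")
}

#' @export
print.vntr_call <- function(x, ...) {
  if (is.na(x$unit_length)) {
    cat("vntr_call: no internal repeat detected; all copy numbers 1\n")
  } else {
    cat(sprintf(
      "vntr_call: unit %.0f bp, copies per monomer [%s], reference monomer %d\n",
      x$unit_length, paste(x$copies_per_monomer, collapse = ","),
      x$reference_monomer))
  }
  invisible(x)
}

#' Decompose an array sequence end to end
#'
#' Convenience pipeline: anchor discovery, segmentation, divergence matrix
#' and VNTR detection on one array sequence.
#'
#' @param array_seq DNA string of a (called) tandem array.
#' @param anchor_k Anchor k-mer length.
#' @param k,min_segment Self-aligner parameters for VNTR detection.
#' @return List with `anchor`, `monomer_set`, `divergence` and `vntr`.
#' @export
decompose_array <- function(array_seq, anchor_k = 16L, k = 13L,
                            min_segment = 25L) {
  anc <- find_anchor(array_seq, anchor_k)
  ms <- segment_monomers(array_seq, anc$positions)
  dv <- divergence_matrix(ms)
  vn <- detect_vntr(ms, k = k, min_segment = min_segment)
  list(anchor = anc, monomer_set = ms, divergence = dv, vntr = vn)
}
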