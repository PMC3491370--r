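## Tandem-array and inverted-repeat calling from self-alignment segments.
##
## Periodicity is read from diagonal offsets, not raw segment counts: for
## every base of the clustered footprint we record the smallest offset of a
## segment covering it (the "local period" — the distance to the next
## aligned copy). The dominant local period defines the repeat unit; offsets
## commensurate with one unit give the period statistics, and the copy
## estimate is footprint span / median unit offset. An internal VNTR
## produces a short secondary period (its own unit length) covering only the
## VNTR footprint, which the dominance rule ignores.

cluster_1d <- function(starts, ends, max_gap) {
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  run_max <- cummax(c(-Inf, head(e, -1L)))
  new_cl <- s > run_max + max_gap
  new_cl[1L] <- TRUE
  cl <- cumsum(new_cl)
  out <- integer(length(starts))
  out[ord] <- cl
  out
}

## offsets -> single-linkage clusters with relative gap tolerance
offset_clusters <- function(values, tol = 0.1) {
  uo <- sort(unique(values))
  if (length(uo) == 1L) return(rep(1L, length(values)))
  new_cl <- c(TRUE, diff(uo) > tol * uo[-1L])
  cl_of_uo <- cumsum(new_cl)
  cl_of_uo[match(values, uo)]
}

analyze_cluster <- function(seg, span_start, span_end) {
  span <- span_end - span_start
  minoff <- rep(NA_real_, span)
  ord <- order(seg$offset, decreasing = TRUE)
  for (i in ord) {
    idx <- seq(seg$q_start[i] - span_start + 1L, seg$q_end[i] - span_start)
    minoff[idx] <- seg$offset[i]
  }
  offs <- minoff[!is.na(minoff)]
  cl <- offset_clusters(offs)
  dominant <- which.max(tabulate(cl))
  p_mode <- median(offs[cl == dominant])
  unit <- offs[offs > 0.6 * p_mode & offs < 1.67 * p_mode]
  p_hat <- median(unit)
  list(period_min = min(unit), period_median = p_hat,
       period_max = max(unit),
       copy_estimate = round(span / p_hat))
}

#' Call tandem arrays from self-alignment segments
#'
#' Forward segments are clustered by overlapping footprints (the interval
#' from `q_start` to `t_end`, single linkage with gaps up to `max_gap`); a
#' cluster becomes one call when its footprint spans at least `min_span` bp
#' and its offset distribution implies at least `min_copies` repeat units.
#'
#' @param segments Output of [self_matches()] on one sequence.
#' @param min_span Minimum call footprint, bp.
#' @param min_copies Minimum copy estimate.
#' @param max_gap Maximum gap bridged when clustering segment footprints, bp
#'   (the default bridges VNTR-induced segment breaks within one array).
#' @return Data frame sorted by start: `start`, `end`, `span`,
#'   `copy_estimate`, `period_min`, `period_median`, `period_max`,
#'   `support` (contributing segments). Empty input gives an empty frame.
#' @export
call_tandem_arrays <- function(segments, min_span = 2000L, min_copies = 3L,
                               max_gap = 2000L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      span = integer(0), copy_estimate = numeric(0),
                      period_min = numeric(0), period_median = numeric(0),
                      period_max = numeric(0), support = integer(0))
  fwd <- segments[segments$strand == "forward", , drop = FALSE]
  if (nrow(fwd) == 0L) return(empty)
  fwd$offset <- fwd$t_start - fwd$q_start
  fwd <- fwd[fwd$offset > 0L, , drop = FALSE]
  if (nrow(fwd) == 0L) return(empty)
  cl <- cluster_1d(fwd$q_start, fwd$t_end, max_gap)
  rows <- lapply(split(fwd, cl), function(seg) {
    s0 <- min(seg$q_start); s1 <- max(seg$t_end)
    st <- analyze_cluster(seg, s0, s1)
    data.frame(start = s0, end = s1, span = s1 - s0,
               copy_estimate = st$copy_estimate,
               period_min = st$period_min,
               period_median = st$period_median,
               period_max = st$period_max, support = nrow(seg))
  })
  out <- do.call(rbind, rows)
  out <- out[out$span >= min_span & out$copy_estimate >= min_copies, ,
             drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call inverted repeats from self-alignment segments
#'
#' Reverse-strand segments whose q-interval lies entirely left of their
#' t-interval are clustered by the midpoint of their footprint (anti-diagonal
#' bands share a center); the arms are the union footprints on each side.
#' Clusters with overlapping arms, arms shorter than `min_arm`, spacers
#' beyond `max_spacer`, or arm lengths differing by more than 20% are
#' discarded.
#'
#' @param segments Output of [self_matches()].
#' @param min_arm Minimum arm length, bp.
#' @param max_spacer Maximum gap between arms, bp.
#' @param max_gap Clustering linkage distance on band centers, bp.
#' @return Data frame: `left_start`, `left_end`, `right_start`, `right_end`,
#'   `spacer`, `support`.
#' @export
call_inverted_repeats <- function(segments, min_arm = 500L,
                                  max_spacer = 10000L, max_gap = 2000L) {
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      spacer = integer(0), support = integer(0))
  rev <- segments[segments$strand == "reverse" &
                    segments$q_end <= segments$t_start, , drop = FALSE]
  if (nrow(rev) == 0L) return(empty)
  ctr <- (rev$q_start + rev$t_end) / 2
  cl <- cluster_1d(ctr, ctr, max_gap)
  rows <- lapply(split(rev, cl), function(seg) {
    ls <- min(seg$q_start); le <- max(seg$q_end)
    rs <- min(seg$t_start); re <- max(seg$t_end)
    data.frame(left_start = ls, left_end = le, right_start = rs,
               right_end = re, spacer = rs - le, support = nrow(seg))
  })
  out <- do.call(rbind, rows)
  arm_l <- out$left_end - out$left_start
  arm_r <- out$right_end - out$right_start
  keep <- out$spacer >= 0L & out$spacer <= max_spacer &
    arm_l >= min_arm & arm_r >= min_arm &
    abs(arm_l - arm_r) <= 0.2 * pmax(arm_l, arm_r)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed tandem-repeat survey of a chromosome
#'
#' Runs the self-alignment caller inside sliding windows and reports the
#' largest tandem call per window, emulating a chromosome-wide scan for
#' macrosatellite-scale repeats.
#'
#' @param genome DNA string.
#' @param window Window size, bp (must be >= `step`).
#' @param step Step between window starts, bp.
#' @param k,min_segment Passed to [self_matches()].
#' @param min_span,min_copies,max_gap Passed to [call_tandem_arrays()].
#' @return Data frame with one row per window: `window_start`, `window_end`
#'   (0-based half-open), `largest_span` (0 when no call), `period_median`
#'   (NA when no call), `call_start`, `call_end` (genome coordinates of the
#'   largest call), `n_calls`.
#' @export
survey_chromosome <- function(genome, window = 500000L, step = 250000L,
                              k = 13L, min_segment = 25L, min_span = 2000L,
                              min_copies = 3L, max_gap = 2000L) {
  n <- nchar(genome)
  if (window < step) stopf("window must be >= step")
  if (window > n) {
    warnf("window (%d bp) exceeds genome length (%d bp); using one window",
          window, n)
    starts <- 0L
    window <- n
  } else {
    starts <- seq(0L, n - window, by = step)
    if (max(starts) + window < n) starts <- c(starts, n - window)
  }
  rows <- lapply(starts, function(s) {
    sub <- substr(genome, s + 1L, s + window)
    calls <- call_tandem_arrays(self_matches(sub, k, min_segment),
                                min_span, min_copies, max_gap)
    if (nrow(calls) == 0L)
      return(data.frame(window_start = s, window_end = s + window,
                        largest_span = 0L, period_median = NA_real_,
                        call_start = NA_integer_, call_end = NA_integer_,
                        n_calls = 0L))
    top <- calls[which.max(calls$span), ]
    data.frame(window_start = s, window_end = s + window,
               largest_span = top$span, period_median = top$period_median,
               call_start = s + top$start, call_end = s + top$end,
               n_calls = nrow(calls))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
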