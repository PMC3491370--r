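## Cross-species invariant-window extraction, position weight matrices with
## per-column information content, and IUPAC consensus matching. Inputs are
## pre-aligned (equal-length) homologous sequences; alignment construction
## is out of scope, which keeps the window/PWM logic independently testable.

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stopf("sequences must have equal length (got %s)",
          paste(sort(unique(lens)), collapse = ", "))
  matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
         nrow = length(seqs), byrow = TRUE)
}

#' Extract the cross-species conserved window
#'
#' Invariant columns are alignment positions where every sequence carries
#' the same base; the window is the minimal interval containing all
#' invariant columns (columns inside the window need not themselves be
#' invariant). Invariant under sequence reordering.
#'
#' @param seqs Character vector of >= 2 equal-length (pre-aligned)
#'   sequences.
#' @return Object of class `conserved_window`: `start`, `end` (0-based
#'   half-open; NA with `empty = TRUE` when no column is invariant),
#'   `invariant_columns` (0-based), `n_sequences`.
#' @export
conserved_window <- function(seqs) {
  if (length(seqs) < 2L) stopf("need >= 2 sequences")
  m <- seq_matrix(seqs)
  inv <- which(apply(m, 2L, function(col)
    length(unique(col)) == 1L && col[1L] %in% DNA_BASES))
  if (length(inv) == 0L) {
    return(structure(list(start = NA_integer_, end = NA_integer_,
                          invariant_columns = integer(0),
                          n_sequences = length(seqs), empty = TRUE),
                     class = "conserved_window"))
  }
  structure(list(start = min(inv) - 1L, end = max(inv),
                 invariant_columns = inv - 1L,
                 n_sequences = length(seqs), empty = FALSE),
            class = "conserved_window")
}

#' @export
print.conserved_window <- function(x, ...) {
  if (x$empty) {
    cat("conserved_window: no invariant column\n")
  } else {
    cat(sprintf(
      "conserved_window: [%d, %d) (%d bp), %d invariant columns across %d sequences\n",
      x$start, x$end, x$end - x$start, length(x$invariant_columns),
      x$n_sequences))
  }
  invisible(x)
}

#' Extract the window-restricted sequences
#' @param seqs Equal-length sequences.
#' @param window A `conserved_window` (or 0-based half-open `c(start, end)`).
#' @return Character vector of window subsequences.
#' @export
window_sequences <- function(seqs, window) {
  iv <- if (inherits(window, "conserved_window")) c(window$start, window$end)
        else as.integer(window)
  substring(seqs, iv[1L] + 1L, iv[2L])
}

#' Build a position weight matrix with information content
#'
#' Per-column base counts over equal-length sequences, frequencies with an
#' optional pseudocount ((count + pc) / (n_col + 4 pc)), and information
#' content per column 2 + sum_b f_b log2 f_b bits (0 log 0 := 0; 2 bits is
#' full conservation for a 4-letter alphabet). Ambiguous bases are excluded
#' column-wise from the counts with a warning.
#'
#' @param seqs Character vector of equal-length sequences (typically the
#'   window-restricted set).
#' @param pseudocount Added to every count (default 0, reproducing
#'   logo-style information content).
#' @return Object of class `pwm`: `counts`, `freq` (4 x W matrices, rows
#'   A/C/G/T), `ic` (bits per column), `width`, `n`, `consensus` (majority
#'   base per column).
#' @export
build_pwm <- function(seqs, pseudocount = 0) {
  m <- seq_matrix(seqs)
  W <- ncol(m)
  counts <- vapply(seq_len(W), function(j)
    vapply(DNA_BASES, function(b) sum(m[, j] == b), numeric(1)),
    numeric(4))
  counts <- matrix(counts, nrow = 4L,
                   dimnames = list(DNA_BASES, seq_len(W) - 1L))
  excluded <- nrow(m) - colSums(counts)
  if (any(excluded > 0))
    warnf("%d ambiguous bases excluded from %d column(s)",
          sum(excluded), sum(excluded > 0))
  ncol_eff <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2L, ncol_eff + 4 * pseudocount, "/")
  plogp <- function(f) ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + colSums(plogp(freq))
  consensus <- DNA_BASES[apply(counts, 2L, which.max)]
  structure(list(counts = counts, freq = freq, ic = ic, width = W,
                 n = nrow(m), consensus = paste(consensus, collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, %d sequences, mean IC %.2f bits/column\n",
              x$width, x$n, mean(x$ic)))
  cat(sprintf("consensus: %s\n", x$consensus))
  invisible(x)
}

#' Write a PWM as TSV (rows A/C/G/T plus an IC row)
#' @param pwm A `pwm`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(rbind(pwm$freq, IC = pwm$ic))
  df <- cbind(row = rownames(df), df)
  write_tsv(df, path)
}

revcomp_iupac <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[seq_chars(toupper(motif))]), collapse = "")
}

count_iupac_matches <- function(target_ch, motif_ch) {
  sum(vapply(seq_along(motif_ch), function(i)
    target_ch[i] %in% IUPAC_CLASSES[[motif_ch[i]]], logical(1)))
}

#' Best match of an IUPAC consensus motif within a target sequence
#'
#' Scans every offset on both strands and counts positions where the target
#' base belongs to the motif's IUPAC class; reports the best placement.
#' When the motif is longer than the target, the target is scanned inside
#' the motif instead (the contract is symmetric). Both strands are always
#' scanned, so motif orientation is immaterial.
#'
#' @param target DNA string over A/C/G/T.
#' @param motif IUPAC consensus string.
#' @return Object of class `consensus_match`: `matched_positions`,
#'   `consensus_length`, `offset` (0-based, of the motif within the target,
#'   negative when the target sits inside a longer motif), `strand`.
#' @export
consensus_match <- function(target, motif) {
  target <- toupper(target)
  motif <- toupper(motif)
  if (grepl("[^ACGT]", target)) stopf("target must be plain A/C/G/T")
  if (!all(seq_chars(motif) %in% names(IUPAC_CLASSES)))
    stopf("motif contains non-IUPAC characters")
  lt <- nchar(target); lm <- nchar(motif)
  scan_one <- function(tg, mo, strand) {
    tch <- seq_chars(tg); mch <- seq_chars(mo)
    if (length(mch) <= length(tch)) {
      offs <- 0:(length(tch) - length(mch))
      best <- -1L; bo <- 0L
      for (o in offs) {
        sc <- count_iupac_matches(tch[(o + 1):(o + length(mch))], mch)
        if (sc > best) { best <- sc; bo <- o }
      }
      list(score = best, offset = bo, strand = strand)
    } else {
      offs <- 0:(length(mch) - length(tch))
      best <- -1L; bo <- 0L
      for (o in offs) {
        sc <- count_iupac_matches(tch, mch[(o + 1):(o + length(tch))])
        if (sc > best) { best <- sc; bo <- o }
      }
      list(score = best, offset = -bo, strand = strand)
    }
  }
  fwd <- scan_one(target, motif, "forward")
  rev <- scan_one(target, revcomp_iupac(motif), "reverse")
  best <- if (rev$score > fwd$score) rev else fwd
  structure(list(matched_positions = best$score, consensus_length = lm,
                 offset = best$offset, strand = best$strand),
            class = "consensus_match")
}

#' @export
print.consensus_match <- function(x, ...) {
  cat(sprintf(
    "consensus_match: %d of %d positions (offset %d, %s strand)\n",
    x$matched_positions, x$consensus_length, x$offset, x$strand))
  invisible(x)
}
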