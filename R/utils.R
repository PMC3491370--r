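#' @import Biostrings
#' @importFrom stats median pt rbinom runif rgeom setNames
#' @importFrom utils write.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. uniform over A/C/G/T, giving a background with no
#' repeat structure, so any tandem or inverted call on it is attributable to
#' the caller rather than the simulator.
#'
#' @param length Sequence length in bp.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return A single character string.
#' @export
random_dna <- function(length, seed = NULL) {
  draw <- function() paste(sample(DNA_BASES, length, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Reverse complement of a DNA string
#'
#' @param x Character string over A/C/G/T (case-insensitive; IUPAC ambiguity
#'   codes are complemented too).
#' @return Character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

## Per-base substitution at rate `rate`; replacement drawn uniformly from the
## three other bases. Returns the mutated character vector and the 0-based
## positions touched.
mutate_chars <- function(chars, rate, protect = integer(0)) {
  n <- length(chars)
  hit <- which(runif(n) < rate)
  if (length(protect)) hit <- setdiff(hit, protect + 1L)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  list(chars = chars, positions = hit - 1L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("field '%s' must be a probability in [0, 1]", name)
  invisible(x)
}

check_dna <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stopf("field '%s' must be a non-empty DNA string", name)
  if (grepl("[^ACGTacgt]", x))
    stopf("field '%s' contains non-ACGT characters", name)
  invisible(toupper(x))
}

## ---- plain-text IO ---------------------------------------------------------

#' Read a FASTA file as a named character vector
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV with header
#' @param df Data frame.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
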