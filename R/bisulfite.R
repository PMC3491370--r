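## Clone-level bisulfite methylation calling and the unequal-variance group
## comparison used for male/female methylation profiles. The unit of
## analysis is the per-clone percent methylation (one horizontal line of a
## lollipop diagram), not pooled per-site counts.

## Collapse C->T so bisulfite-converted and untreated sequence can be
## compared in a conversion-invariant frame.
t_space <- function(x) chartr("C", "T", toupper(x))

#' Call per-CpG methylation states for one clone
#'
#' At each reference CpG position the clone base is read as: C = methylated,
#' T = unmethylated, anything else (or a deletion) = absent — the "dash"
#' state produced by CpG-destroying variants. Clones of the same length as
#' the reference are compared in place; other clones are globally aligned to
#' the C->T-collapsed reference frame first. A conversion QC statistic (the
#' fraction of non-CpG reference cytosines reading T) is attached; values
#' below `qc_threshold` are flagged, not dropped.
#'
#' @param reference Untreated reference region, DNA string.
#' @param clone Clone sequence, DNA string.
#' @param clone_id Identifier stored in the profile.
#' @param min_identity Minimum alignment identity (in the collapsed frame)
#'   below which the clone is rejected.
#' @param qc_threshold Conversion QC threshold for flagging.
#' @return Object of class `clone_profile`: `clone_id`, `states` (factor
#'   vector over reference CpG positions, levels methylated/unmethylated/
#'   absent, names = 0-based site positions), `conversion_qc`,
#'   `qc_flag`.
#' @export
call_clone_methylation <- function(reference, clone, clone_id = "clone",
                                   min_identity = 0.8,
                                   qc_threshold = 0.95) {
  reference <- toupper(reference)
  clone <- toupper(clone)
  sites <- cpg_positions(reference)
  if (length(sites) == 0L) stopf("reference region contains no CpG site")
  ref_ch <- seq_chars(reference)
  if (nchar(clone) == nchar(reference)) {
    map <- seq_len(nchar(reference))        # reference pos -> clone pos
    cl_ch <- seq_chars(clone)
  } else {
    aln <- Biostrings::pairwiseAlignment(t_space(clone), t_space(reference),
                                         type = "global")
    pat <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    sub <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    map <- rep(NA_integer_, nchar(reference))
    ref_i <- cumsum(sub != "-")
    cl_i <- cumsum(pat != "-")
    both <- sub != "-" & pat != "-"
    map[ref_i[both]] <- cl_i[both]
    cl_ch <- seq_chars(clone)
  }
  ref_t <- seq_chars(t_space(reference))
  cl_at <- ifelse(is.na(map), NA_character_, cl_ch[map])
  ident <- mean(!is.na(cl_at) & chartr("C", "T", cl_at) == ref_t)
  if (ident < min_identity)
    stopf("clone does not match region (identity %.2f < %.2f)",
          ident, min_identity)
  base_at <- function(p0) {            # 0-based reference position
    m <- map[p0 + 1L]
    if (is.na(m)) NA_character_ else cl_ch[m]
  }
  cb <- vapply(sites, base_at, character(1))
  states <- ifelse(is.na(cb), "absent",
                   ifelse(cb == "C", "methylated",
                          ifelse(cb == "T", "unmethylated", "absent")))
  noncpg_c <- setdiff(which(ref_ch == "C") - 1L, sites)
  nb <- vapply(noncpg_c, base_at, character(1))
  qc <- if (length(nb)) mean(nb == "T", na.rm = TRUE) else NA_real_
  structure(list(clone_id = clone_id,
                 states = factor(setNames(states, sites),
                                 levels = c("methylated", "unmethylated",
                                            "absent")),
                 conversion_qc = qc,
                 qc_flag = is.na(qc) || qc < qc_threshold),
            class = "clone_profile")
}

#' @export
print.clone_profile <- function(x, ...) {
  tab <- table(x$states)
  cat(sprintf("clone_profile %s: %d M / %d U / %d absent; conversion QC %.2f%s\n",
              x$clone_id, tab[["methylated"]], tab[["unmethylated"]],
              tab[["absent"]], x$conversion_qc,
              if (x$qc_flag) " [flagged]" else ""))
  invisible(x)
}

#' Percent methylation of a clone profile
#'
#' 100 x methylated / (methylated + unmethylated); absent sites are excluded
#' from the denominator. A clone with no informative site is undefined (NA
#' with a warning) and should be dropped by the caller.
#'
#' @param profile A `clone_profile` (or a factor/character state vector).
#' @return Percent in [0, 100], or NA.
#' @export
percent_methylation <- function(profile) {
  states <- if (inherits(profile, "clone_profile")) profile$states
            else profile
  m <- sum(states == "methylated")
  u <- sum(states == "unmethylated")
  if (m + u == 0L) {
    warnf("all sites absent; percent methylation undefined")
    return(NA_real_)
  }
  100 * m / (m + u)
}

#' Clone-state matrix in the lollipop-diagram layout
#'
#' @param profiles List of `clone_profile`s.
#' @return Character matrix, rows = clones, columns = CpG positions, values
#'   "M", "U" or "-" — directly renderable as circle diagrams.
#' @export
state_matrix <- function(profiles) {
  codes <- c(methylated = "M", unmethylated = "U", absent = "-")
  m <- t(vapply(profiles,
                function(p) unname(codes[as.character(p$states)]),
                character(length(profiles[[1]]$states))))
  rownames(m) <- vapply(profiles, `[[`, character(1), "clone_id")
  colnames(m) <- names(profiles[[1]]$states)
  m
}

#' Welch two-sample comparison of group percent methylation
#'
#' The two-tailed t-test with differing variance on per-clone percent
#' methylation: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2), degrees of freedom
#' by Welch-Satterthwaite, two-tailed p from the t distribution. Groups may
#' be given as lists of `clone_profile`s or as numeric percent vectors.
#' Clones with undefined percent are dropped; groups with fewer than
#' `warn_below` clones trigger a warning (profiles are conventionally built
#' from at least nine independent clones).
#'
#' @param group1,group2 Lists of `clone_profile`s or numeric vectors of
#'   per-clone percent methylation.
#' @param warn_below Clone count below which a warning is emitted.
#' @return Object of class `methylation_comparison`: group means, sds and
#'   ns, `t`, `df`, `p`, and `flag` ("zero-variance" when both variances
#'   vanish with unequal means, in which case p is reported as the limit 0).
#' @export
compare_groups <- function(group1, group2, warn_below = 9L) {
  pct <- function(g) {
    if (is.numeric(g)) return(g[!is.na(g)])
    v <- vapply(g, percent_methylation, numeric(1))
    v[!is.na(v)]
  }
  x <- pct(group1); y <- pct(group2)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stopf("need >= 2 clones with defined percent methylation per group")
  if (n1 < warn_below || n2 < warn_below)
    warnf("fewer than %d clones in a group (%d, %d)", warn_below, n1, n2)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  flag <- NA_character_
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      t <- 0; df <- n1 + n2 - 2L; p <- 1
    } else {
      t <- sign(m1 - m2) * Inf; df <- n1 + n2 - 2L; p <- 0
      flag <- "zero-variance"
    }
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(mean1 = m1, mean2 = m2, sd1 = sqrt(v1), sd2 = sqrt(v2),
                 n1 = n1, n2 = n2, t = t, df = df, p = p, flag = flag),
            class = "methylation_comparison")
}

#' @export
print.methylation_comparison <- function(x, ...) {
  cat(sprintf(
    "Welch two-sample comparison of percent methylation\n  group 1: mean %.2f (sd %.2f, n %d)\n  group 2: mean %.2f (sd %.2f, n %d)\n  t = %.4f, df = %.2f, two-tailed p = %.4g%s\n",
    x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2, x$t, x$df, x$p,
    if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
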