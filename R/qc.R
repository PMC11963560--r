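#' Global per-dinucleotide methylation statistics
#'
#' For each requested dinucleotide class, reports the number of retained
#' sites, the mean level, the fraction of sites with level exactly zero, and
#' the fraction above each threshold (strictly greater). An absent class
#' yields `n_sites = 0` with `mean_level = NA` so the gap is visible rather
#' than silently dropped.
#'
#' @param tab a `cgmap` data.frame (already filtered as desired).
#' @param contexts dinucleotide classes to summarize (default CA, CC, CG, CT).
#' @param thresholds levels whose exceedance fractions are reported.
#' @return data.frame with one row per dinucleotide: `dinuc`, `n_sites`,
#'   `mean_level`, `fraction_zero`, and one `fraction_gt_<t>` column per
#'   threshold.
#' @export
global_context_stats <- function(tab, contexts = c("CA", "CC", "CG", "CT"),
                                 thresholds = c(0.05, 0.20, 0.80)) {
  stopifnot(is.data.frame(tab))
  out <- lapply(contexts, function(dn) {
    lv <- tab$level[tab$dinuc == dn]
    row <- data.frame(dinuc = dn, n_sites = length(lv),
                      mean_level = mean_or_na(lv),
                      fraction_zero = if (length(lv)) mean(lv == 0) else NA_real_)
    for (t in thresholds)
      row[[sprintf("fraction_gt_%g", t)]] <-
        if (length(lv)) mean(lv > t) else NA_real_
    row
  })
  do.call(rbind, out)
}

#' Cross-sample correlation of methylation levels in one context
#'
#' Pearson correlation of levels at sites (chrom, pos, strand) retained in
#' both tables for the given dinucleotide class. A constant vector makes the
#' correlation undefined; this is reported as NA with a warning, never as 0.
#'
#' @param tab_a,tab_b `cgmap` data.frames for the two samples.
#' @param context dinucleotide class (default `"CG"`).
#' @return list with `r`, `n_shared`, and `defined` (FALSE when a side is
#'   constant or fewer than 2 shared sites exist).
#' @export
context_correlation <- function(tab_a, tab_b, context = "CG") {
  a <- tab_a[tab_a$dinuc == context, , drop = FALSE]
  b <- tab_b[tab_b$dinuc == context, , drop = FALSE]
  key_a <- paste(a$chrom, a$pos, a$strand_base)
  key_b <- paste(b$chrom, b$pos, b$strand_base)
  shared <- intersect(key_a, key_b)
  x <- a$level[match(shared, key_a)]
  y <- b$level[match(shared, key_b)]
  if (length(shared) < 2L || sd(x) == 0 || sd(y) == 0) {
    warning("correlation undefined: fewer than 2 shared sites or a constant sample")
    return(list(r = NA_real_, n_shared = length(shared), defined = FALSE))
  }
  list(r = cor(x, y), n_shared = length(shared), defined = TRUE)
}

#' Strand symmetry of CpG dyads
#'
#' Pairs each forward-strand CG record at position i with the reverse-strand
#' record at i + 1 on the same contig (using the Watson-strand base column:
#' C = forward, G = reverse). Only dyads with both members at coverage
#' `min_coverage` or more are considered; of those with non-zero methylation
#' on both strands (at least one methylated read each), the symmetric dyads
#' are the ones whose absolute level difference is below `diff_threshold`.
#'
#' @param tab a `cgmap` data.frame containing both strands.
#' @param diff_threshold symmetry tolerance on the level difference
#'   (default 0.05, strict: a difference equal to the threshold is
#'   asymmetric).
#' @param min_coverage coverage gate applied to both dyad members
#'   (default 10).
#' @return list of class `symmetry_result`: `n_pairs` (dyads passing the
#'   coverage gate), `n_pairs_nonzero`, `n_symmetric`, `fraction_symmetric`,
#'   `threshold`.
#' @export
strand_symmetry <- function(tab, diff_threshold = 0.05, min_coverage = 10L) {
  cg <- tab[tab$dinuc == "CG" & tab$cov >= min_coverage, , drop = FALSE]
  fwd <- cg[cg$strand_base == "C", , drop = FALSE]
  rev_ <- cg[cg$strand_base == "G", , drop = FALSE]
  key_rev <- paste(rev_$chrom, rev_$pos)
  idx <- match(paste(fwd$chrom, fwd$pos + 1L), key_rev)
  paired <- !is.na(idx)
  m_fwd <- fwd$level[paired]
  m_rev <- rev_$level[idx[paired]]
  nonzero <- m_fwd > 0 & m_rev > 0
  n_nonzero <- sum(nonzero)
  n_sym <- sum(abs(m_fwd[nonzero] - m_rev[nonzero]) < diff_threshold)
  structure(list(n_pairs = sum(paired),
                 n_pairs_nonzero = n_nonzero,
                 n_symmetric = n_sym,
                 fraction_symmetric = if (n_nonzero > 0) n_sym / n_nonzero else NA_real_,
                 threshold = diff_threshold),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf(paste0("CpG dyad symmetry: %d dyads passed coverage, %d with ",
                     "non-zero methylation on both strands,\n  %d (%.1f%%) ",
                     "with |level difference| < %g\n"),
              x$n_pairs, x$n_pairs_nonzero, x$n_symmetric,
              100 * x$fraction_symmetric, x$threshold))
  invisible(x)
}

#' Non-conversion floor estimated from an unmethylated control contig
#'
#' Summarizes the level distribution per dinucleotide class on a control
#' contig assumed unmethylated (typically the mitochondrial genome); the
#' observed levels there are attributed to bisulfite non-conversion.
#'
#' @param tab a `cgmap` data.frame.
#' @param control_contig contig id of the control sequence.
#' @return data.frame per dinucleotide (plus an `all` row): `n_sites`,
#'   `mean`, `q1`, `median`, `q3`.
#' @export
nonconversion_estimate <- function(tab, control_contig) {
  ctrl <- tab[tab$chrom == control_contig, , drop = FALSE]
  if (nrow(ctrl) == 0L) fail("control contig %s absent from table", control_contig)
  groups <- c(split(ctrl$level, ctrl$dinuc), list(all = ctrl$level))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    lv <- groups[[g]]
    q <- quantile(lv, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(dinuc = g, n_sites = length(lv), mean = mean(lv),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' Rank-based comparison of two level distributions
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test. The exact null distribution
#' is used when both samples have at most 25 observations and no ties are
#' present; otherwise the tie-corrected normal approximation (without
#' continuity correction, so identical samples give p = 1).
#'
#' @param levels_a,levels_b numeric vectors, both non-empty.
#' @return list with `p_value`, `statistic` (the Mann-Whitney U of the first
#'   sample), and `method`.
#' @export
compare_context_distributions <- function(levels_a, levels_b) {
  if (length(levels_a) == 0L || length(levels_b) == 0L)
    fail("both level vectors must be non-empty")
  ties <- any(duplicated(c(levels_a, levels_b)))
  exact <- length(levels_a) <= 25 && length(levels_b) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(levels_a, levels_b, exact = exact,
                                     correct = FALSE))
  p <- wt$p.value
  ## zero rank variance (e.g. every observation tied): all relabelings give
  ## the same statistic, so the two-sided p is 1
  if (!is.finite(p)) p <- 1
  list(p_value = p, statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}
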