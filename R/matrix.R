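#' Sites-by-samples methylation matrix
#'
#' Container for cross-sample methylation levels at common cytosine sites.
#' `values` holds levels (NA where a sample lacks qualifying coverage),
#' `covered` the corresponding logical mask, and `sites` the coordinates
#' (one row per matrix row, sorted by chrom then position; forward and
#' reverse records of a dyad are distinct sites).
#'
#' @param values numeric matrix, sites x samples, entries in [0,1] or NA.
#' @param sites data.frame with columns `chrom`, `pos`, `strand_base`, `dinuc`.
#' @param samples character vector of sample ids (column order).
#' @return an object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, sites, samples) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(sites), ncol(values) == length(samples))
  ord <- order(sites$chrom, sites$pos, sites$strand_base)
  values <- values[ord, , drop = FALSE]
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  dimnames(values) <- list(NULL, samples)
  finite <- values[is.finite(values)]
  if (length(finite) && (min(finite) < 0 || max(finite) > 1))
    fail("methylation levels must lie in [0,1]")
  structure(list(values = values, sites = sites, samples = samples,
                 covered = !is.na(values)),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d sites x %d samples (%.1f%% observed)\n",
              nrow(x$values), length(x$samples),
              if (length(x$values)) 100 * mean(x$covered) else 100))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

#' Aggregate per-sample CGmap tables into a common-site matrix
#'
#' A site enters the matrix when it has coverage of at least `min_coverage`
#' in at least `ceiling(min_sample_fraction * n_samples)` samples and matches
#' the requested context; cells below the coverage threshold are missing (NA).
#' Defaults mirror the standard aggregation settings for sparse methylomes
#' (min coverage 10, min sample fraction 0.8, CpG context).
#'
#' @param tables named list of `cgmap` data.frames, one per sample.
#' @param min_coverage minimum per-cell read depth.
#' @param min_sample_fraction minimum fraction of samples covered (ceiling
#'   rounding, boundary inclusive: 0.8 of 17 samples means >= 14).
#' @param context dinucleotide context retained (default `"CG"`).
#' @return a [methylation_matrix()].
#' @export
aggregate_matrix <- function(tables, min_coverage = 10L,
                             min_sample_fraction = 0.8, context = "CG") {
  stopifnot(is.list(tables), length(tables) >= 1L)
  samples <- names(tables) %||% paste0("sample", seq_along(tables))
  if (is.null(names(tables))) names(tables) <- samples
  n <- length(tables)
  need <- ceiling(min_sample_fraction * n)

  keyed <- lapply(samples, function(s) {
    tab <- tables[[s]]
    tab <- tab[tab$context == context, , drop = FALSE]
    key <- paste(tab$chrom, tab$pos, tab$strand_base, sep = "\r")
    list(key = key, tab = tab)
  })
  all_keys <- unique(unlist(lapply(keyed, `[[`, "key")))
  if (length(all_keys) == 0L) {
    return(methylation_matrix(matrix(numeric(), 0, n),
                              data.frame(chrom = character(), pos = integer(),
                                         strand_base = character(),
                                         dinuc = character()), samples))
  }
  values <- matrix(NA_real_, length(all_keys), n, dimnames = list(NULL, samples))
  covcnt <- integer(length(all_keys))
  site_info <- NULL
  for (i in seq_len(n)) {
    k <- keyed[[i]]
    idx <- match(k$key, all_keys)
    ok <- k$tab$cov >= min_coverage
    values[idx[ok], i] <- k$tab$level[ok]
    covcnt[idx[ok]] <- covcnt[idx[ok]] + 1L
    if (is.null(site_info)) {
      site_info <- data.frame(chrom = NA_character_, pos = NA_integer_,
                              strand_base = NA_character_, dinuc = NA_character_,
                              stringsAsFactors = FALSE)[rep(1, length(all_keys)), ]
    }
    fill <- is.na(site_info$chrom[idx])
    site_info$chrom[idx[fill]] <- k$tab$chrom[fill]
    site_info$pos[idx[fill]] <- k$tab$pos[fill]
    site_info$strand_base[idx[fill]] <- k$tab$strand_base[fill]
    site_info$dinuc[idx[fill]] <- k$tab$dinuc[fill]
  }
  keep <- covcnt >= need
  methylation_matrix(values[keep, , drop = FALSE],
                     site_info[keep, , drop = FALSE], samples)
}

#' Impute missing matrix cells by correlated-sample kNN
#'
#' For each missing cell, takes the unweighted mean of the observed levels at
#' that site in the `k` samples most correlated (Pearson, over pairwise
#' complete sites) with the target sample. Observed cells are left
#' bit-identical. Every site must have at least one observed value.
#'
#' @param mat a [methylation_matrix()].
#' @param k number of neighbour samples (default 5; capped at the number of
#'   samples with an observed value at the site).
#' @return a complete [methylation_matrix()] with no missing cells.
#' @export
impute_missing <- function(mat, k = 5L) {
  stopifnot(inherits(mat, "methylation_matrix"))
  v <- mat$values
  if (!anyNA(v)) return(mat)
  if (any(rowSums(!is.na(v)) == 0L))
    fail("cannot impute a site with no observed values")
  n <- ncol(v)
  cc <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0  # constant or non-overlapping pairs carry no signal
  diag(cc) <- -Inf
  for (j in seq_len(n)) {
    miss <- which(is.na(v[, j]))
    if (length(miss) == 0L) next
    ord <- order(cc[, j], decreasing = TRUE)
    for (i in miss) {
      donors <- ord[!is.na(v[i, ord])]
      use <- donors[seq_len(min(k, length(donors)))]
      v[i, j] <- mean(v[i, use])
    }
  }
  out <- mat
  out$values <- v
  out$covered <- mat$covered  # mask still marks originally observed cells
  out
}

#' Restrict a matrix to sites in sufficiently methylated genes
#'
#' Computes, per gene and sample, the unweighted mean level over the matrix
#' sites falling in the gene span, then retains the CpG sites of genes whose
#' mean level is at least `min_gene_level` in at least
#' `ceiling(min_sample_fraction * n_samples)` samples (both thresholds
#' inclusive).
#'
#' @param mat a [methylation_matrix()].
#' @param annotation a [gene_annotation()].
#' @param min_gene_level minimum per-sample mean gene methylation (default
#'   0.10).
#' @param min_sample_fraction minimum fraction of samples meeting it
#'   (default 0.8).
#' @return a [methylation_matrix()] restricted to retained genes' sites, with
#'   attribute `genes_retained` listing the gene ids.
#' @export
filter_gene_matrix <- function(mat, annotation, min_gene_level = 0.10,
                               min_sample_fraction = 0.8) {
  stopifnot(inherits(mat, "methylation_matrix"),
            inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  n <- length(mat$samples)
  need <- ceiling(min_sample_fraction * n)
  site_gene <- rep(NA_character_, nrow(mat$sites))
  for (gi in seq_len(nrow(genes))) {
    hit <- mat$sites$chrom == genes$chrom[gi] &
      mat$sites$pos >= genes$start[gi] & mat$sites$pos <= genes$end[gi]
    site_gene[hit] <- genes$gene_id[gi]
  }
  retained <- character()
  for (gid in unique(stats::na.omit(site_gene))) {
    rows <- which(site_gene == gid)
    gmean <- colMeans(mat$values[rows, , drop = FALSE], na.rm = TRUE)
    if (sum(gmean >= min_gene_level, na.rm = TRUE) >= need)
      retained <- c(retained, gid)
  }
  keep <- !is.na(site_gene) & site_gene %in% retained
  out <- methylation_matrix(mat$values[keep, , drop = FALSE],
                            mat$sites[keep, , drop = FALSE], mat$samples)
  attr(out, "genes_retained") <- retained
  out
}

#' Keep the most variable matrix sites
#'
#' Retains `ceiling(fraction * n_sites)` sites with the largest across-sample
#' variance; ties are broken deterministically (variance descending, then
#' chrom/position/strand ascending).
#'
#' @param mat a [methylation_matrix()] (complete or with NAs; variance uses
#'   observed values).
#' @param fraction fraction of sites to keep, in (0, 1] (default 0.2).
#' @return the filtered [methylation_matrix()].
#' @export
filter_top_variable <- function(mat, fraction = 0.2) {
  stopifnot(inherits(mat, "methylation_matrix"))
  if (fraction <= 0 || fraction > 1) fail("fraction must be in (0,1]")
  ns <- nrow(mat$values)
  if (ns == 0L) fail("matrix has no sites")
  vars <- apply(mat$values, 1, function(x) var(x[!is.na(x)]))
  vars[is.na(vars)] <- 0
  if (all(vars == 0)) fail("all sites are constant; no variability to rank")
  n_keep <- ceiling(fraction * ns)
  ord <- order(-vars, mat$sites$chrom, mat$sites$pos, mat$sites$strand_base)
  keep <- sort(ord[seq_len(n_keep)])
  methylation_matrix(mat$values[keep, , drop = FALSE],
                     mat$sites[keep, , drop = FALSE], mat$samples)
}

#' Collapse strand pairs of a matrix to CpG dyads
#'
#' Averages the forward (C at position i) and reverse (G at i + 1) records of
#' each CpG dyad into one row per dyad, the natural unit for site-level
#' inference since both strands measure the same cytosine pair. Cells where
#' only one strand is observed take that strand's value; unpaired records are
#' kept as-is.
#'
#' @param mat a [methylation_matrix()] of CG-context sites.
#' @return a [methylation_matrix()] with one row per dyad (coordinates of the
#'   forward strand member; `strand_base` set to `"C"`).
#' @export
collapse_dyads <- function(mat) {
  stopifnot(inherits(mat, "methylation_matrix"))
  s <- mat$sites
  fwd <- which(s$strand_base == "C")
  rev_ <- which(s$strand_base == "G")
  rev_key <- paste(s$chrom[rev_], s$pos[rev_])
  partner <- match(paste(s$chrom[fwd], s$pos[fwd] + 1L), rev_key)
  paired_fwd <- fwd[!is.na(partner)]
  paired_rev <- rev_[partner[!is.na(partner)]]
  vals <- mat$values
  dyad_vals <- (ifelse(is.na(vals[paired_fwd, , drop = FALSE]), 0,
                       vals[paired_fwd, , drop = FALSE]) +
                ifelse(is.na(vals[paired_rev, , drop = FALSE]), 0,
                       vals[paired_rev, , drop = FALSE])) /
    ((!is.na(vals[paired_fwd, , drop = FALSE])) +
     (!is.na(vals[paired_rev, , drop = FALSE])))
  dyad_vals[!is.finite(dyad_vals)] <- NA_real_
  lone <- setdiff(seq_len(nrow(vals)), c(paired_fwd, paired_rev))
  out_vals <- rbind(dyad_vals, vals[lone, , drop = FALSE])
  out_sites <- rbind(
    data.frame(chrom = s$chrom[paired_fwd], pos = s$pos[paired_fwd],
               strand_base = "C", dinuc = s$dinuc[paired_fwd],
               stringsAsFactors = FALSE),
    s[lone, c("chrom", "pos", "strand_base", "dinuc"), drop = FALSE])
  methylation_matrix(out_vals, out_sites, mat$samples)
}
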