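#' Parameters for positional methylation profiles
#'
#' @param flank_bp flank length on either side of the gene body (default
#'   3000 bp).
#' @param n_flank_bins fixed-width bins per flank (default 30, i.e. 100 bp
#'   resolution at the default flank).
#' @param n_body_bins equal-fraction bins across the normalized gene body
#'   (default 40).
#' @param context dinucleotide class profiled (default `"CG"`).
#' @param n_deciles gene groups for decile-stratified profiles (default 10).
#' @param aggregation `"gene"` (default): average per-gene bin means so long
#'   genes do not dominate; `"site"`: pool all sites in a bin.
#' @return list of class `metagene_params`.
#' @export
metagene_params <- function(flank_bp = 3000L, n_flank_bins = 30L,
                            n_body_bins = 40L, context = "CG",
                            n_deciles = 10L, aggregation = c("gene", "site")) {
  stopifnot(flank_bp > 0, n_flank_bins >= 1, n_body_bins >= 1)
  structure(list(flank_bp = as.integer(flank_bp),
                 n_flank_bins = as.integer(n_flank_bins),
                 n_body_bins = as.integer(n_body_bins),
                 context = context, n_deciles = as.integer(n_deciles),
                 aggregation = match.arg(aggregation)),
            class = "metagene_params")
}

#' Mean methylation of genomic regions
#'
#' @param tab a `cgmap` data.frame.
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed) and optionally `region_id`.
#' @param weighting `"site"`: unweighted mean of per-site levels;
#'   `"coverage"`: total methylated reads over total reads.
#' @param context restrict to one dinucleotide class (`NULL` = all).
#' @return the input regions with `mean_level` (NA where a region has no
#'   retained sites), `n_sites`, and `has_sites` columns added.
#' @export
region_mean_methylation <- function(tab, regions,
                                    weighting = c("site", "coverage"),
                                    context = NULL) {
  weighting <- match.arg(weighting)
  regions <- as.data.frame(regions)
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    fail("regions need chrom, start, end columns")
  if (any(regions$start > regions$end)) fail("malformed region: start > end")
  if (!is.null(context)) tab <- tab[tab$dinuc == context, , drop = FALSE]
  out <- regions
  out$mean_level <- NA_real_
  out$n_sites <- 0L
  for (i in seq_len(nrow(regions))) {
    hit <- tab$chrom == regions$chrom[i] & tab$pos >= regions$start[i] &
      tab$pos <= regions$end[i]
    n <- sum(hit)
    out$n_sites[i] <- n
    if (n > 0L) {
      out$mean_level[i] <- if (weighting == "site") mean(tab$level[hit])
      else sum(tab$mc[hit]) / sum(tab$cov[hit])
    }
  }
  out$has_sites <- out$n_sites > 0L
  out
}

## --- internal binning engine ------------------------------------------------
## All positional arithmetic is 0-based half-open; a 1-based site position p
## becomes offset p - 1. A site exactly at the TSS lands in the first body
## bin, not the flank.

## signed 5'->3' bin assignment for the upstream-flank/body/downstream-flank
## layout; returns NA for sites outside the profiled window
meta_bin_for_gene <- function(offsets, gene, params) {
  fw <- params$flank_bp / params$n_flank_bins
  if (gene$strand == "+") {
    body_lo <- gene$start - 1L
    body_hi <- gene$end           # half-open
    d <- ifelse(offsets < body_lo, offsets - body_lo,          # negative: upstream
         ifelse(offsets >= body_hi, offsets - body_hi + 1L,    # positive: downstream
                NA))
    body_rel <- (offsets - body_lo) / (body_hi - body_lo)
  } else {
    body_lo <- gene$start - 1L
    body_hi <- gene$end
    ## transcription runs right to left: upstream lies at higher coordinates
    d <- ifelse(offsets >= body_hi, body_hi - 1L - offsets,    # negative: upstream
         ifelse(offsets < body_lo, body_lo - offsets,          # positive: downstream
                NA))
    body_rel <- (body_hi - 1L - offsets) / (body_hi - body_lo)
  }
  in_body <- offsets >= body_lo & offsets < body_hi
  bin <- rep(NA_integer_, length(offsets))
  up <- !in_body & !is.na(d) & d < 0 & d >= -params$flank_bp
  bin[up] <- params$n_flank_bins + 1L + floor(d[up] / fw)     # 1..n_flank
  bin[in_body] <- params$n_flank_bins +
    pmin(floor(body_rel[in_body] * params$n_body_bins), params$n_body_bins - 1L) + 1L
  down <- !in_body & !is.na(d) & d > 0 & d <= params$flank_bp
  bin[down] <- params$n_flank_bins + params$n_body_bins +
    floor((d[down] - 1L) / fw) + 1L
  bin
}

meta_bin_centers <- function(params) {
  fw <- params$flank_bp / params$n_flank_bins
  data.frame(
    bin = seq_len(2L * params$n_flank_bins + params$n_body_bins),
    region = rep(c("upstream", "body", "downstream"),
                 c(params$n_flank_bins, params$n_body_bins, params$n_flank_bins)),
    center = c(-params$flank_bp + (seq_len(params$n_flank_bins) - 0.5) * fw,
               (seq_len(params$n_body_bins) - 0.5) / params$n_body_bins,
               (seq_len(params$n_flank_bins) - 0.5) * fw))
}

## accumulate per-gene bin means into a profile data.frame
combine_bins <- function(per_gene, n_bins, aggregation) {
  mean_level <- rep(NA_real_, n_bins)
  n_sites <- integer(n_bins)
  n_genes <- integer(n_bins)
  if (aggregation == "gene") {
    sums <- numeric(n_bins)
    for (pg in per_gene) {
      n_sites <- n_sites + pg$n
      has <- pg$n > 0L
      sums[has] <- sums[has] + pg$mean[has]
      n_genes <- n_genes + as.integer(has)
    }
    mean_level[n_genes > 0] <- sums[n_genes > 0] / n_genes[n_genes > 0]
  } else {
    sums <- numeric(n_bins)
    for (pg in per_gene) {
      n_sites <- n_sites + pg$n
      has <- pg$n > 0L
      sums[has] <- sums[has] + pg$sum[has]
    }
    mean_level[n_sites > 0] <- sums[n_sites > 0] / n_sites[n_sites > 0]
    n_genes <- NA_integer_
  }
  data.frame(mean_level = mean_level, n_sites = n_sites, n_genes = n_genes)
}

per_gene_bins <- function(levels, bins, n_bins) {
  n <- tabulate(bins, nbins = n_bins)
  sum_ <- numeric(n_bins)
  ok <- !is.na(bins)
  if (any(ok)) {
    agg <- rowsum(levels[ok], bins[ok])
    sum_[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(n = n, sum = sum_, mean = ifelse(n > 0, sum_ / n, NA_real_))
}

#' Meta-gene methylation profile
#'
#' Averages methylation across genes after scaling each gene body to
#' `n_body_bins` equal-fraction bins and attaching `n_flank_bins` fixed-width
#' bins on each flank. Minus-strand genes are flipped so bin 1 is always the
#' far 5' end; flanks running off a contig simply contribute no sites to the
#' affected bins. Genes whose body spans fewer positions than `n_body_bins`
#' are skipped with a warning.
#'
#' @param tab a `cgmap` data.frame (filtered as desired).
#' @param annotation a [gene_annotation()].
#' @param params a [metagene_params()].
#' @return data.frame of class `metagene_profile`: `bin`, `region`, `center`
#'   (bp from the gene boundary for flanks, body fraction for the body),
#'   `mean_level`, `n_sites`, `n_genes`.
#' @export
metagene_profile <- function(tab, annotation, params = metagene_params()) {
  stopifnot(inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  if (nrow(genes) == 0L) fail("annotation contains no genes")
  tab <- tab[tab$dinuc == params$context, , drop = FALSE]
  n_bins <- 2L * params$n_flank_bins + params$n_body_bins
  per_gene <- list()
  skipped <- 0L
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, ]
    if (gene$end - gene$start + 1L < params$n_body_bins) {
      skipped <- skipped + 1L
      next
    }
    near <- tab$chrom == gene$chrom &
      tab$pos >= gene$start - params$flank_bp &
      tab$pos <= gene$end + params$flank_bp
    offs <- tab$pos[near] - 1L
    bins <- meta_bin_for_gene(offs, gene, params)
    per_gene[[length(per_gene) + 1L]] <-
      per_gene_bins(tab$level[near], bins, n_bins)
  }
  if (skipped > 0L)
    warning(sprintf("%d gene(s) shorter than n_body_bins positions skipped", skipped))
  prof <- cbind(meta_bin_centers(params),
                combine_bins(per_gene, n_bins, params$aggregation))
  class(prof) <- c("metagene_profile", "data.frame")
  attr(prof, "n_genes_used") <- length(per_gene)
  prof
}

## gene-body mean CpG level (unweighted site mean, TSS..TES span)
gene_body_means <- function(tab, annotation, context = "CG",
                            weighting = "site") {
  g <- annotation$genes
  regions <- data.frame(chrom = g$chrom, start = g$start, end = g$end)
  rm <- region_mean_methylation(tab, regions, weighting = weighting,
                                context = context)
  data.frame(gene_id = g$gene_id, mean_level = rm$mean_level,
             n_sites = rm$n_sites, stringsAsFactors = FALSE)
}

## split gene ids (already ranked best-first) into n near-equal groups,
## remainder spread from the top
split_deciles <- function(ids, n_groups) {
  n <- length(ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  rep(seq_len(n_groups), sizes)
}

#' Decile-stratified anchored methylation profiles
#'
#' Ranks genes by mean gene-body CpG level (descending; ties broken by gene
#' id), splits them into `n_deciles` equal-size groups (remainder spread from
#' the top), and profiles each group over +/- `flank_bp` around the TSS or
#' TES in fixed-width bins, oriented 5' to 3'.
#'
#' @param tab a `cgmap` data.frame.
#' @param annotation a [gene_annotation()].
#' @param center anchor, `"TSS"` or `"TES"`.
#' @param params a [metagene_params()].
#' @return data.frame of class `decile_profiles`: `decile` (1 = most
#'   methylated), `bin`, `center` (signed bp from the anchor, 5'->3'),
#'   `mean_level`, `n_sites`, `n_genes`; attribute `gene_deciles` maps gene
#'   ids to groups.
#' @export
decile_profiles <- function(tab, annotation, center = c("TSS", "TES"),
                            params = metagene_params()) {
  center <- match.arg(center)
  gm <- gene_body_means(tab, annotation, context = params$context)
  gm <- gm[!is.na(gm$mean_level), , drop = FALSE]
  if (nrow(gm) < params$n_deciles)
    fail("need at least %d genes with computable means, have %d",
         params$n_deciles, nrow(gm))
  gm <- gm[order(-gm$mean_level, gm$gene_id), , drop = FALSE]
  gm$decile <- split_deciles(gm$gene_id, params$n_deciles)

  anchors <- gene_anchors(annotation)
  tab <- tab[tab$dinuc == params$context, , drop = FALSE]
  fw <- params$flank_bp / params$n_flank_bins
  n_bins <- 2L * params$n_flank_bins
  res <- list()
  for (d in seq_len(params$n_deciles)) {
    ids <- gm$gene_id[gm$decile == d]
    per_gene <- list()
    for (gid in ids) {
      a <- anchors[anchors$gene_id == gid, ]
      anchor_off <- (if (center == "TSS") a$tss else a$tes) - 1L
      near <- tab$chrom == a$chrom &
        abs(tab$pos - 1L - anchor_off) <= params$flank_bp
      offs <- tab$pos[near] - 1L
      s <- if (a$strand == "+") offs - anchor_off else anchor_off - offs
      bin <- floor((s + params$flank_bp) / fw) + 1L
      bin[bin < 1L | bin > n_bins] <- NA_integer_
      per_gene[[length(per_gene) + 1L]] <-
        per_gene_bins(tab$level[near], bin, n_bins)
    }
    prof <- combine_bins(per_gene, n_bins, params$aggregation)
    prof$decile <- d
    prof$bin <- seq_len(n_bins)
    prof$center <- -params$flank_bp + (seq_len(n_bins) - 0.5) * fw
    res[[d]] <- prof
  }
  out <- do.call(rbind, res)[, c("decile", "bin", "center", "mean_level",
                                 "n_sites", "n_genes")]
  class(out) <- c("decile_profiles", "data.frame")
  attr(out, "gene_deciles") <- stats::setNames(gm$decile, gm$gene_id)
  out
}

#' Methylation profile by exon rank
#'
#' Restricted to genes with at least `min_exons` exons; each of the first
#' `first_k` exons (in transcription order) is scaled to `bins_per_exon`
#' equal-fraction bins and averaged across genes.
#'
#' @param tab a `cgmap` data.frame.
#' @param annotation a [gene_annotation()].
#' @param min_exons minimum exon count for a gene to qualify (default 5).
#' @param first_k exon ranks profiled (default 4).
#' @param bins_per_exon equal-fraction bins per exon (default 10).
#' @param context dinucleotide class (default `"CG"`).
#' @param aggregation `"gene"` or `"site"` (see [metagene_params()]).
#' @return data.frame: `exon_rank`, `bin`, `rel_pos` (fraction along the
#'   exon, 5'->3'), `mean_level`, `n_sites`, `n_genes`. Empty when no gene
#'   qualifies.
#' @export
exon_position_profile <- function(tab, annotation, min_exons = 5L,
                                  first_k = 4L, bins_per_exon = 10L,
                                  context = "CG",
                                  aggregation = c("gene", "site")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(annotation, "gene_annotation"))
  tab <- tab[tab$dinuc == context, , drop = FALSE]
  exon_counts <- table(annotation$exons$gene_id)
  use_genes <- names(exon_counts)[exon_counts >= min_exons]
  res <- list()
  for (r in seq_len(first_k)) {
    per_gene <- list()
    for (gid in use_genes) {
      ex <- annotation$exons[annotation$exons$gene_id == gid &
                               annotation$exons$rank == r, ]
      if (nrow(ex) != 1L) next
      gene <- annotation$genes[annotation$genes$gene_id == gid, ]
      near <- tab$chrom == gene$chrom & tab$pos >= ex$start & tab$pos <= ex$end
      offs <- tab$pos[near] - 1L
      len <- ex$end - ex$start + 1L
      rel <- if (gene$strand == "+") (offs - (ex$start - 1L)) / len
             else ((ex$end - 1L) - offs) / len
      bin <- pmin(floor(rel * bins_per_exon), bins_per_exon - 1L) + 1L
      per_gene[[length(per_gene) + 1L]] <-
        per_gene_bins(tab$level[near], bin, bins_per_exon)
    }
    prof <- combine_bins(per_gene, bins_per_exon, aggregation)
    prof$exon_rank <- r
    prof$bin <- seq_len(bins_per_exon)
    prof$rel_pos <- (seq_len(bins_per_exon) - 0.5) / bins_per_exon
    res[[r]] <- prof
  }
  out <- do.call(rbind, res)[, c("exon_rank", "bin", "rel_pos", "mean_level",
                                 "n_sites", "n_genes")]
  attr(out, "n_genes_qualifying") <- length(use_genes)
  out
}

#' Decile profiles across the exon-1 / intron-1 junction
#'
#' For genes with at least two exons, averages methylation in fixed bins
#' within +/- `window_bp` of the transcription-order end of exon 1,
#' stratified into deciles by the mean level of exon 1 itself. Single-exon
#' genes have no junction and are excluded.
#'
#' @param tab a `cgmap` data.frame.
#' @param annotation a [gene_annotation()].
#' @param window_bp window on each side of the junction (default 100).
#' @param n_deciles exon-1-level groups (default 10; reduce for small
#'   annotations).
#' @param bin_bp bin width in bp (default 10).
#' @param context dinucleotide class (default `"CG"`).
#' @param aggregation `"gene"` or `"site"`.
#' @return data.frame: `decile` (1 = most methylated exon 1), `bin`,
#'   `center` (signed bp, negative = exonic side), `mean_level`, `n_sites`,
#'   `n_genes`.
#' @export
exon1_boundary_profile <- function(tab, annotation, window_bp = 100L,
                                   n_deciles = 10L, bin_bp = 10L,
                                   context = "CG",
                                   aggregation = c("gene", "site")) {
  aggregation <- match.arg(aggregation)
  tab <- tab[tab$dinuc == context, , drop = FALSE]
  exon_counts <- table(annotation$exons$gene_id)
  multi <- names(exon_counts)[exon_counts >= 2L]
  if (length(multi) < n_deciles)
    fail("need at least %d multi-exon genes, have %d", n_deciles, length(multi))
  e1 <- annotation$exons[annotation$exons$rank == 1L &
                           annotation$exons$gene_id %in% multi, , drop = FALSE]
  genes <- annotation$genes[match(e1$gene_id, annotation$genes$gene_id), ]
  regions <- data.frame(chrom = genes$chrom, start = e1$start, end = e1$end)
  rm <- region_mean_methylation(tab, regions, weighting = "site")
  gm <- data.frame(gene_id = e1$gene_id, mean_level = rm$mean_level,
                   stringsAsFactors = FALSE)
  gm <- gm[!is.na(gm$mean_level), , drop = FALSE]
  gm <- gm[order(-gm$mean_level, gm$gene_id), , drop = FALSE]
  gm$decile <- split_deciles(gm$gene_id, n_deciles)

  n_bins <- as.integer(2L * window_bp / bin_bp)
  res <- list()
  for (d in seq_len(n_deciles)) {
    ids <- gm$gene_id[gm$decile == d]
    per_gene <- list()
    for (gid in ids) {
      ex <- e1[e1$gene_id == gid, ]
      gene <- genes[genes$gene_id == gid, ]
      ## junction offset: first base past exon 1 in transcription order
      jn <- if (gene$strand == "+") ex$end else ex$start - 2L  # 0-based
      near <- tab$chrom == gene$chrom & abs(tab$pos - 1L - jn) <= window_bp
      offs <- tab$pos[near] - 1L
      s <- if (gene$strand == "+") offs - jn else jn - offs
      bin <- floor((s + window_bp) / bin_bp) + 1L
      bin[bin < 1L | bin > n_bins] <- NA_integer_
      per_gene[[length(per_gene) + 1L]] <-
        per_gene_bins(tab$level[near], bin, n_bins)
    }
    prof <- combine_bins(per_gene, n_bins, aggregation)
    prof$decile <- d
    prof$bin <- seq_len(n_bins)
    prof$center <- -window_bp + (seq_len(n_bins) - 0.5) * bin_bp
    res[[d]] <- prof
  }
  out <- do.call(rbind, res)[, c("decile", "bin", "center", "mean_level",
                                 "n_sites", "n_genes")]
  attr(out, "gene_deciles") <- stats::setNames(gm$decile, gm$gene_id)
  out
}

#' Derive intron intervals from an annotation
#'
#' Introns are the gaps between consecutive exons of a gene, in genomic
#' coordinates.
#'
#' @param annotation a [gene_annotation()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_introns <- function(annotation) {
  res <- list()
  for (gid in unique(annotation$exons$gene_id)) {
    ex <- annotation$exons[annotation$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    chrom <- annotation$genes$chrom[annotation$genes$gene_id == gid]
    res[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                             start = ex$end[-nrow(ex)] + 1L,
                             end = ex$start[-1] - 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene_id = character(), chrom = character(),
                                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}

#' Exon-versus-intron methylation comparison
#'
#' Two-sided rank-sum test on per-region mean levels, pooled across regions,
#' together with the group means and (for the second, conditional comparison)
#' the means restricted to regions with non-zero methylation. A paired
#' variant (per-gene exon vs intron means) is available.
#'
#' @param exon_means,intron_means numeric vectors of per-region mean levels.
#' @param paired use a paired signed-rank test (vectors must align).
#' @return list: `exon_mean`, `intron_mean`, `exon_mean_nonzero`,
#'   `intron_mean_nonzero`, `p_value`, `method`.
#' @export
exon_intron_test <- function(exon_means, intron_means, paired = FALSE) {
  exon_means <- exon_means[!is.na(exon_means)]
  intron_means <- intron_means[!is.na(intron_means)]
  if (length(exon_means) == 0L || length(intron_means) == 0L)
    fail("both exon and intron mean vectors must be non-empty")
  cmp <- if (paired) {
    wt <- suppressWarnings(wilcox.test(exon_means, intron_means, paired = TRUE,
                                       correct = FALSE))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1
    list(p_value = p, method = "paired signed-rank")
  } else {
    res <- compare_context_distributions(exon_means, intron_means)
    list(p_value = res$p_value, method = paste("rank-sum,", res$method))
  }
  list(exon_mean = mean(exon_means),
       intron_mean = mean(intron_means),
       exon_mean_nonzero = mean_or_na(exon_means[exon_means > 0]),
       intron_mean_nonzero = mean_or_na(intron_means[intron_means > 0]),
       p_value = cmp$p_value, method = cmp$method)
}
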