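## shared fixtures and independent oracles, all built in code

## quick cgmap constructor; level derived from counts unless given
make_cgmap <- function(chrom, strand_base, pos, dinuc, mc, cov,
                       context = ifelse(dinuc == "CG", "CG",
                                        ifelse(dinuc == "CT", "CHG", "CHH"))) {
  df <- data.frame(chrom = chrom, strand_base = strand_base,
                   pos = as.integer(pos), context = context, dinuc = dinuc,
                   mc = as.integer(mc), cov = as.integer(cov),
                   stringsAsFactors = FALSE)
  df$level <- ifelse(df$cov > 0, df$mc / df$cov, 0)
  df[, c("chrom", "strand_base", "pos", "context", "dinuc", "level", "mc", "cov")]
}

## CG dyad helper: forward C at pos, reverse G at pos + 1, one row each
make_dyad <- function(chrom, pos, mc_fwd, cov_fwd, mc_rev = mc_fwd,
                      cov_rev = cov_fwd) {
  rbind(make_cgmap(chrom, "C", pos, "CG", mc_fwd, cov_fwd),
        make_cgmap(chrom, "G", pos + 1L, "CG", mc_rev, cov_rev))
}

## two-contig, two-gene hand annotation: gP on the plus strand of contigA
## (span 301..500, exons 301-360 and 401-500), gM on the minus strand of
## contigB placed at the mirrored coordinates (span 501..700, exons 641-700
## = rank 1 and 501-600 = rank 2), so the two genes are exact positional
## mirrors of each other on 1000 bp contigs
toy_annotation <- function() {
  contigs <- data.frame(contig = c("ctgA", "ctgB"), length = c(1000L, 1000L),
                        is_mito = FALSE)
  genes <- data.frame(gene_id = c("gM", "gP"),
                      chrom = c("ctgB", "ctgA"),
                      strand = c("-", "+"),
                      start = c(501L, 301L), end = c(700L, 500L),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gP", "gP", "gM", "gM"),
                      rank = c(1L, 2L, 2L, 1L),
                      start = c(301L, 401L, 501L, 641L),
                      end = c(360L, 500L, 600L, 700L))
  gene_annotation(contigs, genes, exons)
}

## mirror of a 1-based position on a 1000 bp contig
mirror_pos <- function(pos) 1001L - as.integer(pos)

## 30-site fixture on the toy annotation: 15 CpG records per gene placed at
## mirrored transcription-relative offsets with identical levels, so the two
## genes must produce identical 5'->3' profiles
toy_sites <- function() {
  ## offsets relative to gP (plus strand): upstream flank, body, downstream
  pos_p <- c(201L, 251L, 299L,            # upstream flank
             301L,                        # exactly at TSS -> first body bin
             320L, 355L, 380L, 401L, 430L, 460L, 480L, 500L,  # body
             501L, 550L, 599L)            # downstream flank
  lev_num <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L)
  cov <- 20L
  tab_p <- make_cgmap("ctgA", "C", pos_p, "CG", lev_num, cov)
  ## gM mirror: same transcription-relative layout on the minus strand
  tab_m <- make_cgmap("ctgB", "G", mirror_pos(pos_p), "CG", lev_num, cov)
  rbind(tab_p, tab_m)
}

## --- independent oracles ----------------------------------------------------

## exact two-tailed permutation p-values for group mean differences by full
## enumeration of label assignments (na of them in group A)
exact_perm_pvals <- function(x, na) {
  x <- as.matrix(x)
  n <- ncol(x)
  combs <- utils::combn(n, na)
  obs <- rowMeans(x[, seq_len(na), drop = FALSE]) -
    rowMeans(x[, -seq_len(na), drop = FALSE])
  ps <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    deltas <- apply(combs, 2, function(idx)
      mean(x[i, idx]) - mean(x[i, -idx]))
    ps[i] <- mean(abs(deltas) >= abs(obs[i]))
  }
  ps
}

## exact two-tailed rank-sum p-value by enumeration of assignments
exact_ranksum_pval <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)])
  combs <- utils::combn(n, length(a))
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

## brute-force per-site meta-gene binning oracle (independent arithmetic:
## walks sites one by one, computing the transcription-direction coordinate
## then cutting with findInterval)
oracle_metagene <- function(tab, ann, params) {
  nf <- params$n_flank_bins; nb <- params$n_body_bins; fl <- params$flank_bp
  n_bins <- 2L * nf + nb
  tab <- tab[tab$dinuc == params$context, , drop = FALSE]
  gene_bin_means <- list()
  n_sites_tot <- integer(n_bins)
  for (gi in seq_len(nrow(ann$genes))) {
    g <- ann$genes[gi, ]
    L <- g$end - g$start + 1L
    if (L < nb) next
    sums <- numeric(n_bins); cnts <- integer(n_bins)
    for (si in seq_len(nrow(tab))) {
      if (tab$chrom[si] != g$chrom) next
      p <- tab$pos[si]
      ## t: transcription coordinate, 0 at TSS, L-1 at the last body base
      t <- if (g$strand == "+") p - g$start else g$end - p
      bin <- NA_integer_
      if (t >= 0 && t < L) {
        bin <- nf + min(floor(t / L * nb), nb - 1L) + 1L
      } else if (t < 0 && t >= -fl) {
        bin <- nf - (floor((-t - 1) / (fl / nf)) + 1L) + 1L
      } else if (t >= L && t < L + fl) {
        bin <- nf + nb + floor((t - L) / (fl / nf)) + 1L
      }
      if (!is.na(bin)) {
        sums[bin] <- sums[bin] + tab$level[si]
        cnts[bin] <- cnts[bin] + 1L
      }
    }
    gene_bin_means[[length(gene_bin_means) + 1L]] <-
      ifelse(cnts > 0, sums / cnts, NA_real_)
    n_sites_tot <- n_sites_tot + cnts
  }
  mean_level <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    v <- vapply(gene_bin_means, `[`, numeric(1), b)
    if (any(!is.na(v))) mean_level[b] <- mean(v[!is.na(v)])
  }
  list(mean_level = mean_level, n_sites = n_sites_tot)
}

## brute-force recount oracle for aggregate_matrix
oracle_aggregate <- function(tables, min_coverage, min_sample_fraction,
                             context = "CG") {
  keys <- unique(unlist(lapply(tables, function(t) {
    t <- t[t$context == context, ]
    paste(t$chrom, t$pos, t$strand_base, sep = "|")
  })))
  need <- ceiling(min_sample_fraction * length(tables))
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    vals <- vapply(tables, function(t) {
      hit <- t$chrom == parts[1] & t$pos == as.integer(parts[2]) &
        t$strand_base == parts[3] & t$context == context &
        t$cov >= min_coverage
      if (any(hit)) t$level[which(hit)[1]] else NA_real_
    }, numeric(1))
    if (sum(!is.na(vals)) >= need) c(key = k, vals) else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  out <- do.call(rbind, lapply(rows, function(r)
    as.numeric(r[-1])))
  keys_kept <- vapply(rows, `[`, "", 1)
  list(keys = keys_kept, values = out)
}

## default small cohort config used by several tests (paper-like structure at
## reduced genome scale for speed)
small_cohort_config <- function(seed, ...) {
  simulation_config(n_contigs = 1L, contig_length = 30000L,
                    mito_length = 8000L, n_genes = 8L, seed = seed, ...)
}
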