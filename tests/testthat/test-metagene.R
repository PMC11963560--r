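test_that("region means support site and coverage weighting and flag empty regions", {
  tab <- rbind(make_cgmap("c1", "C", c(10L, 20L), "CG", c(2L, 4L), 10L),
               make_cgmap("c1", "C", c(110L, 120L), "CG", c(0L, 30L),
                          c(10L, 30L)))
  regions <- data.frame(chrom = "c1", start = c(1L, 100L, 500L),
                        end = c(50L, 200L, 600L))
  site_w <- region_mean_methylation(tab, regions, "site")
  expect_equal(site_w$mean_level[1], 0.3)              # mean(0.2, 0.4)
  cov_w <- region_mean_methylation(tab, regions, "coverage")
  expect_equal(cov_w$mean_level[2], 0.75)              # 30 / 40
  expect_true(is.na(site_w$mean_level[3]))
  expect_false(site_w$has_sites[3])
  expect_error(region_mean_methylation(tab, data.frame(chrom = "c1",
                                                       start = 10L, end = 5L)),
               "malformed")
})

test_that("meta-gene profiles match the brute-force binning oracle bit for bit", {
  ann <- toy_annotation()
  tab <- toy_sites()
  params <- metagene_params(flank_bp = 100L, n_flank_bins = 2L,
                            n_body_bins = 4L)
  prof <- metagene_profile(tab, ann, params)
  orc <- oracle_metagene(tab, ann, params)
  expect_identical(prof$mean_level, orc$mean_level)
  expect_identical(prof$n_sites, orc$n_sites)
  ## sites inside the profiled windows are all accounted for
  expect_equal(sum(prof$n_sites), nrow(tab))
})

test_that("uniform methylomes give flat profiles and strand mirrors are identical", {
  ann <- toy_annotation()
  uniform <- make_cgmap("ctgA", "C", seq(150L, 650L, by = 25L), "CG", 2L, 100L)
  one_gene <- gene_annotation(ann$contigs,
                              ann$genes[ann$genes$gene_id == "gP", ],
                              ann$exons[ann$exons$gene_id == "gP", ])
  params <- metagene_params(flank_bp = 100L, n_flank_bins = 2L,
                            n_body_bins = 4L)
  prof <- metagene_profile(uniform, one_gene, params)
  expect_true(all(abs(prof$mean_level[prof$n_sites > 0] - 0.02) < 1e-12))

  ## minus-strand gene with identical 5'->3' site layout profiles identically
  tab <- toy_sites()
  prof_p <- metagene_profile(tab, gene_annotation(
    ann$contigs, ann$genes[ann$genes$gene_id == "gP", ],
    ann$exons[ann$exons$gene_id == "gP", ]), params)
  prof_m <- metagene_profile(tab, gene_annotation(
    ann$contigs, ann$genes[ann$genes$gene_id == "gM", ],
    ann$exons[ann$exons$gene_id == "gM", ]), params)
  expect_identical(prof_p$mean_level, prof_m$mean_level)
  expect_identical(prof_p$n_sites, prof_m$n_sites)
})

test_that("a site exactly at the TSS falls into the first body bin", {
  ann <- toy_annotation()
  params <- metagene_params(flank_bp = 100L, n_flank_bins = 2L,
                            n_body_bins = 4L)
  at_tss_p <- make_cgmap("ctgA", "C", 301L, "CG", 5L, 10L)
  prof <- metagene_profile(at_tss_p, gene_annotation(
    ann$contigs, ann$genes[ann$genes$gene_id == "gP", ],
    ann$exons[ann$exons$gene_id == "gP", ]), params)
  expect_equal(prof$n_sites[prof$region == "body"][1], 1L)
  expect_equal(sum(prof$n_sites), 1L)
  ## same convention on the minus strand (TSS = genomic end)
  at_tss_m <- make_cgmap("ctgB", "C", 700L, "CG", 5L, 10L)
  prof_m <- metagene_profile(at_tss_m, gene_annotation(
    ann$contigs, ann$genes[ann$genes$gene_id == "gM", ],
    ann$exons[ann$exons$gene_id == "gM", ]), params)
  expect_equal(prof_m$n_sites[prof_m$region == "body"][1], 1L)
})

test_that("short genes are skipped with a warning", {
  contigs <- data.frame(contig = "c1", length = 1000L, is_mito = FALSE)
  genes <- data.frame(gene_id = c("tiny", "ok"), chrom = "c1", strand = "+",
                      start = c(10L, 100L), end = c(14L, 400L))
  exons <- data.frame(gene_id = c("tiny", "ok"), rank = 1L,
                      start = c(10L, 100L), end = c(14L, 400L))
  ann <- gene_annotation(contigs, genes, exons)
  tab <- make_cgmap("c1", "C", c(12L, 200L), "CG", 1L, 10L)
  expect_warning(prof <- metagene_profile(tab, ann,
                                          metagene_params(flank_bp = 50L,
                                                          n_flank_bins = 1L,
                                                          n_body_bins = 10L)),
                 "skipped")
  expect_equal(attr(prof, "n_genes_used"), 1L)
})

test_that("decile grouping splits genes evenly with a deterministic tie-break", {
  ids <- sprintf("g%02d", 1:20)
  expect_equal(as.vector(table(sparsemeth:::split_deciles(ids, 10))),
               rep(2L, 10))
  ids23 <- sprintf("g%02d", 1:23)
  sizes <- as.vector(table(sparsemeth:::split_deciles(ids23, 10)))
  expect_equal(sizes, c(3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))

  ## tie in gene means resolved by gene id (ascending) within the ranking
  contigs <- data.frame(contig = "c1", length = 100000L, is_mito = FALSE)
  starts <- seq(1000L, by = 2000L, length.out = 12)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "c1",
                      strand = "+", start = starts, end = starts + 999L)
  exons <- data.frame(gene_id = genes$gene_id, rank = 1L, start = genes$start,
                      end = genes$end)
  ann <- gene_annotation(contigs, genes, exons)
  ## all genes share level 0.5 except g01 (high) and g12 (low)
  lev <- rep(5L, 12); lev[1] <- 9L; lev[12] <- 1L
  tab <- make_cgmap("c1", "C", starts + 500L, "CG", lev, 10L)
  prof <- decile_profiles(tab, ann, "TSS",
                          metagene_params(flank_bp = 600L, n_flank_bins = 3L))
  dec <- attr(prof, "gene_deciles")
  expect_equal(names(dec)[1], "g01")
  expect_equal(unname(dec["g12"]), 10L)
  ## the ten tied genes fall in id order between them
  mid <- names(dec)[2:11]
  expect_equal(mid, sort(mid))
  expect_error(decile_profiles(tab[1:5, ], ann, "TSS"), "at least 10")
})

test_that("top-decile genes dominate anchored profiles in a heterogeneous cohort", {
  cfg <- simulation_config(seed = 19, n_genes = 60L, n_contigs = 2L,
                           contig_length = 120000L, include_mito = FALSE)
  ann <- generate_annotation(cfg)
  tab <- filter_records(simulate_methylome(ann, list(sample_id = "A",
                                                     age_days = 9), cfg), 10)
  params <- metagene_params(flank_bp = 600L, n_flank_bins = 3L)
  for (anchor in c("TSS", "TES")) {
    prof <- decile_profiles(tab, ann, anchor, params)
    ## compare deciles on the gene-body side of the anchor
    prox_bins <- if (anchor == "TSS") c(4L, 5L) else c(2L, 3L)
    top <- prof$mean_level[prof$decile == 1 & prof$bin %in% prox_bins]
    for (d in 2:10) {
      other <- prof$mean_level[prof$decile == d & prof$bin %in% prox_bins]
      expect_true(all(top > other | is.na(other)),
                  label = sprintf("decile 1 > decile %d at %s", d, anchor))
    }
  }
})

test_that("exon-position profiles respect the exon-count gate and strand order", {
  ## gene with 4 exons excluded; minus-strand exon 1 is the most 3' interval
  contigs <- data.frame(contig = "c1", length = 10000L, is_mito = FALSE)
  genes <- data.frame(gene_id = c("g4", "g5"), chrom = "c1",
                      strand = c("+", "-"),
                      start = c(1000L, 3000L), end = c(1999L, 4499L))
  ex4 <- data.frame(gene_id = "g4", rank = 1:4,
                    start = seq(1000L, by = 250L, length.out = 4),
                    end = seq(1099L, by = 250L, length.out = 4))
  ex5 <- data.frame(gene_id = "g5", rank = 5:1,
                    start = seq(3000L, by = 300L, length.out = 5),
                    end = seq(3099L, by = 300L, length.out = 5))
  ann <- gene_annotation(contigs, genes, rbind(ex4, ex5))
  ## one site in g4 (rank-1 exon) and one in g5's most 3' genomic exon
  tab <- rbind(make_cgmap("c1", "C", 1050L, "CG", 8L, 10L),
               make_cgmap("c1", "C", 4250L, "CG", 6L, 10L))
  prof <- exon_position_profile(tab, ann, min_exons = 5L, first_k = 4L)
  expect_equal(attr(prof, "n_genes_qualifying"), 1L)
  ## the g4 site contributes nothing; the g5 site lands in exon rank 1
  expect_equal(sum(prof$n_sites[prof$exon_rank == 1]), 1L)
  expect_equal(sum(prof$n_sites[prof$exon_rank > 1]), 0L)

  ## generator with a rank-3-peaking boost reproduces the peak at exon 3
  cfg <- simulation_config(seed = 3, decile_spread = 0.2,
                           gene_level_median = 1, exons_per_gene = c(5L, 8L),
                           n_genes = 60L, include_mito = FALSE)
  gann <- generate_annotation(cfg)
  gtab <- filter_records(simulate_methylome(gann, list(sample_id = "A",
                                                       age_days = 9), cfg), 10)
  gprof <- exon_position_profile(gtab, gann)
  rank_means <- tapply(gprof$mean_level, gprof$exon_rank, mean, na.rm = TRUE)
  expect_equal(unname(which.max(rank_means)), 3L)
})

test_that("exon-position profiles match a brute-force oracle on the hand fixture", {
  ## gP exon 1 spans 301..360 (60 bp); sites at fixed offsets with known bins
  ann <- toy_annotation()
  tab <- toy_sites()
  prof <- exon_position_profile(tab, ann, min_exons = 2L, first_k = 2L,
                                bins_per_exon = 3L)
  ## brute force: per gene, per exon rank, bin = floor(rel * 3)
  oracle <- array(list(), c(2, 3))
  acc <- array(0, c(2, 3)); cnt <- array(0L, c(2, 3)); genes_in <- array(0L, c(2, 3))
  for (gid in c("gP", "gM")) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    sums <- array(0, c(2, 3)); ns <- array(0L, c(2, 3))
    for (r in 1:2) {
      e <- ann$exons[ann$exons$gene_id == gid & ann$exons$rank == r, ]
      len <- e$end - e$start + 1L
      sel <- tab$chrom == g$chrom & tab$pos >= e$start & tab$pos <= e$end
      for (i in which(sel)) {
        rel <- if (g$strand == "+") (tab$pos[i] - e$start) / len
               else (e$end - tab$pos[i]) / len
        b <- min(floor(rel * 3), 2) + 1L
        sums[r, b] <- sums[r, b] + tab$level[i]
        ns[r, b] <- ns[r, b] + 1L
      }
    }
    for (r in 1:2) for (b in 1:3) if (ns[r, b] > 0) {
      acc[r, b] <- acc[r, b] + sums[r, b] / ns[r, b]
      genes_in[r, b] <- genes_in[r, b] + 1L
      cnt[r, b] <- cnt[r, b] + ns[r, b]
    }
  }
  for (r in 1:2) for (b in 1:3) {
    got <- prof$mean_level[prof$exon_rank == r & prof$bin == b]
    want <- if (genes_in[r, b] > 0) acc[r, b] / genes_in[r, b] else NA_real_
    expect_identical(got, want)
    expect_identical(prof$n_sites[prof$exon_rank == r & prof$bin == b],
                     cnt[r, b])
  }
})

test_that("exon-1 boundary profiles step down where only exons are methylated", {
  cfg <- simulation_config(seed = 23, n_genes = 60L, n_contigs = 2L,
                           contig_length = 120000L, include_mito = FALSE,
                           cpg_base_level = 0, nonconversion_rate = 0,
                           sample_noise_sd = 0, cpg_spacing = 20,
                           decile_spread = 0.5, gene_level_median = 2)
  ann <- generate_annotation(cfg)
  tab <- filter_records(simulate_methylome(ann, list(sample_id = "A",
                                                     age_days = 9), cfg), 10)
  prof <- exon1_boundary_profile(tab, ann, window_bp = 100L, n_deciles = 5L,
                                 bin_bp = 25L)
  top <- prof[prof$decile == 1, ]
  exonic <- top$mean_level[top$center < 0]
  intronic <- top$mean_level[top$center > 0]
  expect_gt(mean(exonic, na.rm = TRUE), 3 * mean(intronic, na.rm = TRUE))

  ## uniform methylome: flat across the junction
  uni_tab <- tab
  uni_tab$level <- 0.3
  uni_prof <- exon1_boundary_profile(uni_tab, ann, window_bp = 100L,
                                     n_deciles = 5L, bin_bp = 25L)
  lv <- uni_prof$mean_level[!is.na(uni_prof$mean_level)]
  expect_true(all(abs(lv - 0.3) < 1e-12))

  ## single-exon genes are excluded: an annotation of them alone errors
  single <- gene_annotation(
    ann$contigs,
    ann$genes[1:5, ],
    do.call(rbind, lapply(1:5, function(i)
      data.frame(gene_id = ann$genes$gene_id[i], rank = 1L,
                 start = ann$genes$start[i], end = ann$genes$end[i]))))
  expect_error(exon1_boundary_profile(tab, single, n_deciles = 5L),
               "multi-exon")
})

test_that("exon-vs-intron comparison reports pooled means, conditional means and exact p", {
  same <- exon_intron_test(rep(0.1, 5), rep(0.1, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$exon_mean, same$intron_mean)

  res <- exon_intron_test(c(0.3, 0.4, 0.5), c(0.0, 0.1, 0.2))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$exon_mean, 0.4)
  expect_equal(res$intron_mean, 0.1)
  expect_equal(res$intron_mean_nonzero, 0.15)  # zero regions excluded

  ## generator with exonic boost: exons beat introns at n = 200 regions
  cfg <- simulation_config(seed = 29, n_genes = 60L, n_contigs = 2L,
                           contig_length = 120000L, include_mito = FALSE,
                           cpg_spacing = 20)
  ann <- generate_annotation(cfg)
  tab <- filter_records(simulate_methylome(ann, list(sample_id = "A",
                                                     age_days = 9), cfg), 10)
  ex <- merge(ann$exons, ann$genes[, c("gene_id", "chrom")], by = "gene_id")
  exon_means <- region_mean_methylation(tab, ex, context = "CG")$mean_level
  intr <- gene_introns(ann)
  intron_means <- region_mean_methylation(tab, intr, context = "CG")$mean_level
  expect_gt(length(exon_means) + length(intron_means), 200)
  res2 <- exon_intron_test(exon_means, intron_means)
  expect_gt(res2$exon_mean, res2$intron_mean)
  expect_lt(res2$p_value, 0.05)
  expect_error(exon_intron_test(numeric(), 1), "non-empty")
})
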