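test_that("CGmap parsing handles records, empty files, and malformed input", {
  f <- tempfile(fileext = ".CGmap")
  writeLines("c1\tC\t100\tCG\tCG\t0.8\t8\t10", f)
  tab <- read_cgmap(f)
  expect_equal(tab$level, 0.8)
  expect_equal(tab$mc, 8L)
  expect_equal(tab$cov, 10L)
  expect_equal(tab$strand_base, "C")

  writeLines(character(), f)
  expect_equal(nrow(read_cgmap(f)), 0L)

  writeLines(c("c1\tC\t100\tCG\tCG\t0.8\t8\t10",
               "c1\tC\t101\tCG\tCG\t0.8\t8"), f)
  expect_error(read_cgmap(f), "line 2")

  writeLines("c1\tC\tabc\tCG\tCG\t0.8\t8\t10", f)
  expect_error(read_cgmap(f), "line 1")

  writeLines("c1\tC\t100\tCG\tCG\t0.8\t11\t10", f)  # mc > cov
  expect_error(read_cgmap(f), "mc <= cov")

  writeLines("c1\tC\t100\tCHH\tCG\t0.8\t8\t10", f)  # context inconsistent
  expect_error(read_cgmap(f), "dinucleotide CG")
})

test_that("CGmap write/read round-trips losslessly, plain and gzipped", {
  tab <- rbind(make_dyad("c1", 100L, 7L, 13L, 5L, 11L),
               make_cgmap("c2", "G", 55L, "CA", 1L, 30L))
  for (ext in c(".CGmap", ".CGmap.gz")) {
    f <- tempfile(fileext = ext)
    write_cgmap(tab, f)
    back <- read_cgmap(f)
    expect_equal(back, tab, ignore_attr = TRUE)
  }
})

test_that("coverage/contig filtering is inclusive at the threshold and idempotent", {
  tab <- make_cgmap(c("c1", "c1", "contig_bad"), "C", c(10L, 20L, 30L), "CG",
                    c(1L, 2L, 3L), c(9L, 10L, 50L))
  f <- filter_records(tab, min_coverage = 10)
  expect_equal(f$pos, c(20L, 30L))           # cov 9 dropped, cov 10 kept
  f2 <- filter_records(tab, min_coverage = 10, contig_whitelist = "c1")
  expect_equal(f2$pos, 20L)                  # off-whitelist contig dropped
  f3 <- filter_records(tab, min_coverage = 10, contig_whitelist = character())
  expect_equal(f3, f, ignore_attr = TRUE)    # empty whitelist = no contig filter
  expect_equal(filter_records(f2, 10, "c1"), f2, ignore_attr = TRUE)  # idempotent
})

test_that("CIGAR match filtering sums M operations with an inclusive threshold", {
  sam <- function(cigar) paste("r", "0", "c1", "1", "60", cigar, sep = "\t")
  kept <- cigar_match_filter(c(sam("100M"), sam("30M20I10M"), sam("50M"),
                               sam("25M5D25M"), sam("49M1S"), sam("*")))
  cig <- vapply(strsplit(kept, "\t"), `[`, "", 6)
  ## 100M (100), 50M (50, boundary kept), 25M5D25M (50) stay;
  ## 30M20I10M (40) and 49M1S (49) fall below 50; "*" unmapped dropped
  expect_equal(cig, c("100M", "50M", "25M5D25M"))
  expect_error(cigar_match_filter(sam("10Q")), "malformed CIGAR")
})

test_that("matrix aggregation matches a brute-force recount and applies the sample fraction", {
  ## 5 samples; site A covered >= 10 in 4/5 (kept at 0.8), site B in 3/5 (dropped)
  mk <- function(covA, covB) rbind(make_cgmap("c1", "C", 100L, "CG", 1L, covA),
                                   make_cgmap("c1", "C", 200L, "CG", 2L, covB),
                                   make_cgmap("c1", "C", 300L, "CA", 3L, 50L))
  tables <- list(s1 = mk(10L, 10L), s2 = mk(12L, 12L), s3 = mk(15L, 15L),
                 s4 = mk(10L, 9L), s5 = mk(9L, 8L))
  mat <- aggregate_matrix(tables, min_coverage = 10, min_sample_fraction = 0.8)
  expect_equal(nrow(mat$values), 1L)
  expect_equal(mat$sites$pos, 100L)          # site B excluded, CA context excluded
  expect_equal(unname(is.na(mat$values[1, ])),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))

  ## randomized fixture vs oracle
  set.seed(4)
  tables2 <- lapply(1:3, function(i) {
    pos <- seq(10L, 200L, by = 10L)
    cov <- sample(5:20, length(pos), replace = TRUE)
    make_cgmap("c1", "C", pos, "CG", pmin(cov, sample(0:5, length(pos), TRUE)), cov)
  })
  names(tables2) <- paste0("s", 1:3)
  mat2 <- aggregate_matrix(tables2, min_coverage = 10, min_sample_fraction = 0.8)
  orc <- oracle_aggregate(tables2, 10, 0.8)
  expect_equal(nrow(mat2$values), length(orc$keys))
  key_mat <- paste(mat2$sites$chrom, mat2$sites$pos, mat2$sites$strand_base,
                   sep = "|")
  ord <- match(key_mat, orc$keys)
  expect_true(all(!is.na(ord)))
  expect_equal(unname(mat2$values), unname(orc$values[ord, , drop = FALSE]))

  empty <- aggregate_matrix(list(a = make_cgmap("c1", "C", 1L, "CG", 1L, 2L)),
                            min_coverage = 10)
  expect_equal(dim(empty$values), c(0L, 1L))
  expect_equal(empty$samples, "a")
})

test_that("kNN imputation preserves observed cells and recovers duplicated samples", {
  v <- matrix(c(0.1, 0.2, 0.3,
                0.1, 0.2, 0.3,
                0.5, 0.5, 0.5,
                0.9, 0.8, 0.7), nrow = 4, byrow = TRUE)
  sites <- data.frame(chrom = "c1", pos = 1:4 * 10L, strand_base = "C",
                      dinuc = "CG")
  mat <- methylation_matrix(v, sites, c("a", "b", "c"))
  expect_identical(impute_missing(mat)$values, mat$values)  # no missing: identity

  ## one missing cell, k = 2, both neighbours observed at 0.5
  v2 <- v; v2[3, 1] <- NA
  m2 <- impute_missing(methylation_matrix(v2, sites, c("a", "b", "c")), k = 2)
  expect_equal(unname(m2$values[3, 1]), 0.5)
  expect_identical(m2$values[-3, ], mat$values[-3, ])       # observed untouched

  ## duplicate-sample matrix: masked cell recovers the duplicate's value
  set.seed(8)
  base <- runif(20, 0, 1)
  v3 <- cbind(a = base, b = base, c = runif(20), d = runif(20))
  v3[7, "a"] <- NA
  sites3 <- data.frame(chrom = "c1", pos = seq_len(20) * 5L,
                       strand_base = "C", dinuc = "CG")
  m3 <- impute_missing(methylation_matrix(v3, sites3, colnames(v3)), k = 1)
  expect_equal(unname(m3$values[7, "a"]), base[7])

  v4 <- matrix(c(NA, NA, 0.2, 0.3), nrow = 2, byrow = TRUE)
  expect_error(impute_missing(methylation_matrix(
    v4, sites[1:2, ], c("a", "b"))), "no observed values")
})

test_that("gene-level matrix filtering applies both thresholds inclusively", {
  ## one gene spanning sites 100..200 on c1; 17 samples
  ann <- gene_annotation(
    contigs = data.frame(contig = "c1", length = 1000L, is_mito = FALSE),
    genes = data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                       start = 100L, end = 200L),
    exons = data.frame(gene_id = "g1", rank = 1L, start = 100L, end = 200L))
  n <- 17L
  build <- function(gene_level, n_meeting) {
    ## sample j meets the level iff j <= n_meeting
    vals <- vapply(seq_len(n), function(j)
      if (j <= n_meeting) gene_level else 0.01, numeric(1))
    v <- rbind(vals, vals)  # two sites in the gene, same level
    sites <- data.frame(chrom = "c1", pos = c(120L, 150L), strand_base = "C",
                        dinuc = "CG")
    methylation_matrix(v, sites, paste0("s", seq_len(n)))
  }
  ## mean 0.12 in 15/17 samples (88%) -> retained
  kept <- filter_gene_matrix(build(0.12, 15L), ann)
  expect_equal(nrow(kept$values), 2L)
  ## mean 0.12 in 13/17 (76%) -> removed (need ceiling(0.8*17) = 14)
  gone <- filter_gene_matrix(build(0.12, 13L), ann)
  expect_equal(nrow(gone$values), 0L)
  ## boundaries exactly met: level exactly 0.10 in exactly 14 samples -> kept
  edge <- filter_gene_matrix(build(0.10, 14L), ann)
  expect_equal(attr(edge, "genes_retained"), "g1")
})

test_that("top-variability filtering keeps ceiling(fraction * n) sites deterministically", {
  set.seed(2)
  n <- 10L
  v <- pmin(pmax(matrix(rnorm(n * 6, 0.5, 0.001), n, 6), 0), 1)
  planted <- c(2L, 9L)
  v[planted, ] <- rep(c(0.05, 0.95, 0.05, 0.95, 0.05, 0.95), each = 2)
  sites <- data.frame(chrom = "c1", pos = seq_len(n) * 10L, strand_base = "C",
                      dinuc = "CG")
  mat <- methylation_matrix(v, sites, paste0("s", 1:6))
  top <- filter_top_variable(mat, fraction = 0.2)
  expect_equal(nrow(top$values), 2L)          # 10 sites, 20% -> 2
  expect_equal(top$sites$pos, planted * 10L)  # exactly the planted sites
  expect_equal(filter_top_variable(mat, 1.0)$values, mat$values)  # identity
  const <- methylation_matrix(matrix(0.5, 3, 4),
                              data.frame(chrom = "c1", pos = 1:3,
                                         strand_base = "C", dinuc = "CG"),
                              paste0("s", 1:4))
  expect_error(filter_top_variable(const), "constant")
})
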