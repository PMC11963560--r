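#' Configuration of the synthetic methylome generator
#'
#' Defines the study conditions emulated by the generator: a small multi-contig
#' genome with an unmethylated mitochondrial control contig, gene models with
#' 5'-biased exonic CpG methylation peaking at exon 3, log-normal between-gene
#' heterogeneity (so decile stratification has signal), negative-binomial
#' sequencing coverage, a bisulfite non-conversion floor applied to every
#' cytosine, and an optional linear-in-age effect at designated age-CpGs.
#'
#' Observed methylation at a cytosine with true level p is
#' Binomial(coverage, clip(p + epsilon)) / coverage, where epsilon is
#' `nonconversion_rate`; the two strand records of a CpG dyad share one true
#' level, so symmetry holds by construction up to binomial noise.
#'
#' @param n_contigs number of nuclear contigs.
#' @param contig_length length of each nuclear contig (bp).
#' @param include_mito include an unmethylated mitochondrial contig.
#' @param mito_length mitochondrial contig length (bp).
#' @param n_genes genes packed across the nuclear contigs.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_length_range,intron_length_range bp ranges for exon/intron sizes.
#' @param mean_coverage negative-binomial mean read depth per cytosine record.
#' @param mito_coverage_factor multiplier on `mean_coverage` for the
#'   mitochondrial contig (high copy number; the elevated depth is what makes
#'   the control contig informative about the non-conversion floor).
#' @param coverage_dispersion negative-binomial size parameter (smaller =
#'   longer-tailed coverage).
#' @param nonconversion_rate epsilon, the non-conversion error floor in [0,1].
#' @param cpg_base_level background true CpG methylation outside exons.
#' @param exon_boost scale of the additive exonic methylation boost; the
#'   per-rank weight peaks at exon 3.
#' @param decile_spread sdlog of the log-normal per-gene methylation
#'   multiplier (between-gene heterogeneity).
#' @param gene_level_median median of the per-gene multiplier.
#' @param sample_noise_sd sd of per-dyad, per-sample biological noise added to
#'   the true level (shared by both strands of a dyad).
#' @param age_effect_per_day methylation-level change per day of age at each
#'   designated age-CpG (0 for a null cohort).
#' @param n_age_cpgs number of age-responsive CpG dyads.
#' @param age_cpg_base true level of an age-CpG at age 0.
#' @param cpg_spacing mean spacing (bp) between CpG dyads.
#' @param noncpg_per_cpg non-CpG cytosines simulated per CpG dyad.
#' @param seed master integer seed; required before any simulation.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_contigs = 2L,
                              contig_length = 100000L,
                              include_mito = TRUE,
                              mito_length = 15000L,
                              n_genes = 40L,
                              exons_per_gene = c(3L, 8L),
                              exon_length_range = c(80L, 200L),
                              intron_length_range = c(100L, 250L),
                              mean_coverage = 60,
                              mito_coverage_factor = 4,
                              coverage_dispersion = 8,
                              nonconversion_rate = 0.005,
                              cpg_base_level = 0.01,
                              exon_boost = 0.05,
                              decile_spread = 1.6,
                              gene_level_median = 0.3,
                              sample_noise_sd = 0.01,
                              age_effect_per_day = 0,
                              n_age_cpgs = 0L,
                              age_cpg_base = 0.05,
                              cpg_spacing = 45,
                              noncpg_per_cpg = 2,
                              seed = NULL) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              include_mito = isTRUE(include_mito),
              mito_length = as.integer(mito_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              mean_coverage = mean_coverage,
              mito_coverage_factor = mito_coverage_factor,
              coverage_dispersion = coverage_dispersion,
              nonconversion_rate = nonconversion_rate,
              cpg_base_level = cpg_base_level,
              exon_boost = exon_boost,
              decile_spread = decile_spread,
              gene_level_median = gene_level_median,
              sample_noise_sd = sample_noise_sd,
              age_effect_per_day = age_effect_per_day,
              n_age_cpgs = as.integer(n_age_cpgs),
              age_cpg_base = age_cpg_base,
              cpg_spacing = cpg_spacing,
              noncpg_per_cpg = noncpg_per_cpg,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$nonconversion_rate < 0 || cfg$nonconversion_rate > 1)
    fail("nonconversion_rate must be in [0,1]")
  if (length(cfg$exons_per_gene) != 2L || cfg$exons_per_gene[1] > cfg$exons_per_gene[2])
    fail("exons_per_gene must be c(min, max)")
  if (cfg$n_contigs < 1L) fail("need at least one nuclear contig")
  if (cfg$mean_coverage <= 0) fail("mean_coverage must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

#' Sample sheet for the default three-age-group cohort design
#'
#' 17 female samples in three groups: young (9 days), mature (22 to 27 days)
#' and old (51 to 58 days), with group sizes 5/6/6.
#'
#' @param n_young,n_mature,n_old group sizes.
#' @return data.frame with columns `sample_id`, `age_days`, `group`.
#' @export
cohort_design <- function(n_young = 5L, n_mature = 6L, n_old = 6L) {
  ages <- c(rep(9L, n_young),
            as.integer(round(seq(22, 27, length.out = n_mature))),
            as.integer(round(seq(51, 58, length.out = n_old))))
  grp <- c(rep("young", n_young), rep("mature", n_mature), rep("old", n_old))
  data.frame(sample_id = sprintf("S%02d", seq_along(ages)),
             age_days = ages,
             group = factor(grp, levels = c("young", "mature", "old")),
             stringsAsFactors = FALSE)
}

## per-exon-rank weight of the additive methylation boost: rises to a peak
## at exon 3, then decays -- the 5'-biased gene-body pattern
exon_rank_weight <- function(rank) {
  w <- c(0.55, 0.85, 1, 0.7)
  ifelse(rank <= 4, w[pmin(rank, 4)], 0.5 * 0.85^(rank - 4))
}

#' Generate a synthetic gene annotation
#'
#' Packs `n_genes` non-overlapping multi-exon genes onto the nuclear contigs
#' (alternating strands, random gaps); the mitochondrial contig, if present,
#' carries no genes. Fails explicitly when the requested genes cannot fit.
#'
#' @param config a [simulation_config()] with a `seed`.
#' @return a [gene_annotation()].
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) fail("simulation_config$seed must be set")
  set.seed(config$seed)
  contigs <- data.frame(
    contig = paste0("contig", seq_len(config$n_contigs)),
    length = rep(config$contig_length, config$n_contigs),
    is_mito = FALSE, stringsAsFactors = FALSE)
  if (config$include_mito) {
    contigs <- rbind(contigs, data.frame(contig = "mito",
                                         length = config$mito_length,
                                         is_mito = TRUE))
  }
  n_genes <- config$n_genes
  genes <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = character(), rank = integer(),
                      start = integer(), end = integer(), stringsAsFactors = FALSE)
  if (n_genes > 0L) {
    per_contig <- diff(round(seq(0, n_genes, length.out = config$n_contigs + 1)))
    gid <- 0L
    buffer <- 200L  # minimum intergenic gap
    for (ci in seq_len(config$n_contigs)) {
      cursor <- buffer + 1L
      for (k in seq_len(per_contig[ci])) {
        gid <- gid + 1L
        n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
        ex_len <- sample(seq(config$exon_length_range[1], config$exon_length_range[2]),
                         n_ex, replace = TRUE)
        in_len <- if (n_ex > 1)
          sample(seq(config$intron_length_range[1], config$intron_length_range[2]),
                 n_ex - 1L, replace = TRUE) else integer()
        gene_len <- sum(ex_len) + sum(in_len)
        gap <- sample(seq(buffer, buffer + 300L), 1L)
        start <- cursor + gap
        end <- start + gene_len - 1L
        if (end > config$contig_length - buffer)
          fail("cannot pack %d genes onto %d contig(s) of %d bp",
               n_genes, config$n_contigs, config$contig_length)
        strand <- if (gid %% 2L == 0L) "-" else "+"
        gene_id <- sprintf("g%03d", gid)
        ex_start <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
        ex_end <- ex_start + ex_len - 1L
        genomic_order <- seq_len(n_ex)
        rank <- if (strand == "+") genomic_order else rev(genomic_order)
        genes <- rbind(genes, data.frame(gene_id = gene_id,
                                         chrom = contigs$contig[ci],
                                         strand = strand, start = start,
                                         end = end, stringsAsFactors = FALSE))
        exons <- rbind(exons, data.frame(gene_id = gene_id, rank = rank,
                                         start = ex_start, end = ex_end))
        cursor <- end + 1L
      }
    }
  }
  gene_annotation(contigs, genes, exons)
}

## Deterministic site layout + true methylation levels shared by all samples
## of a cohort. Uses its own RNG stream seeded from config$seed so that
## per-sample draws never perturb the template.
methylome_template <- function(annotation, config) {
  if (is.null(config$seed)) fail("simulation_config$seed must be set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  place_grid <- function(len, spacing) {
    n <- max(0L, floor(len / spacing) - 1L)
    if (n == 0L) return(integer())
    pos <- round(seq_len(n) * spacing + runif(n, -spacing / 3, spacing / 3))
    pos <- pos[pos >= 2 & pos <= len - 1]
    pos <- pos[c(TRUE, diff(pos) >= 3)]  # keep dyads disjoint
    as.integer(pos)
  }

  cpg <- do.call(rbind, lapply(seq_len(nrow(annotation$contigs)), function(i) {
    ctg <- annotation$contigs$contig[i]
    pos <- place_grid(annotation$contigs$length[i], config$cpg_spacing)
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = ctg, pos = pos, is_mito = annotation$contigs$is_mito[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cpg)) cpg <- data.frame(chrom = character(), pos = integer(),
                                      is_mito = logical())

  ## non-CpG cytosines, split between CHG and CHH contexts
  noncpg <- do.call(rbind, lapply(seq_len(nrow(annotation$contigs)), function(i) {
    ctg <- annotation$contigs$contig[i]
    spacing <- config$cpg_spacing / max(config$noncpg_per_cpg, 1e-9)
    pos <- place_grid(annotation$contigs$length[i], spacing)
    pos <- pos + 1L  # offset so they rarely collide with dyads
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = ctg, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(noncpg)) noncpg <- data.frame(chrom = character(), pos = integer())
  ## drop collisions with dyad positions (either member)
  dyad_keys <- c(paste(cpg$chrom, cpg$pos), paste(cpg$chrom, cpg$pos + 1L))
  noncpg <- noncpg[!(paste(noncpg$chrom, noncpg$pos) %in% dyad_keys), , drop = FALSE]

  ## per-gene log-normal methylation multiplier
  genes <- annotation$genes
  gene_mult <- stats::setNames(
    rlnorm(nrow(genes), meanlog = log(config$gene_level_median),
           sdlog = config$decile_spread),
    genes$gene_id)

  ## map each dyad to gene/exon rank (position of the forward C)
  cpg$gene_id <- NA_character_
  cpg$exon_rank <- NA_integer_
  if (nrow(genes) > 0L && nrow(cpg) > 0L) {
    for (gi in seq_len(nrow(genes))) {
      hit <- cpg$chrom == genes$chrom[gi] & cpg$pos >= genes$start[gi] &
        cpg$pos <= genes$end[gi]
      cpg$gene_id[hit] <- genes$gene_id[gi]
    }
    ex <- annotation$exons
    exg <- merge(ex, genes[, c("gene_id", "chrom")], by = "gene_id")
    for (ei in seq_len(nrow(exg))) {
      hit <- cpg$chrom == exg$chrom[ei] & cpg$pos >= exg$start[ei] &
        cpg$pos <= exg$end[ei]
      cpg$exon_rank[hit] <- exg$rank[ei]
    }
  }

  ## true levels
  level <- rep(config$cpg_base_level, nrow(cpg))
  in_exon <- !is.na(cpg$exon_rank)
  if (any(in_exon)) {
    level[in_exon] <- config$cpg_base_level +
      gene_mult[cpg$gene_id[in_exon]] * config$exon_boost *
      exon_rank_weight(cpg$exon_rank[in_exon])
  }
  level[cpg$is_mito] <- 0
  cpg$true_level <- clip01(level)

  ## designate age-responsive dyads among nuclear non-mito CpGs
  cpg$is_age_cpg <- FALSE
  if (config$n_age_cpgs > 0L) {
    eligible <- which(!cpg$is_mito)
    if (length(eligible) < config$n_age_cpgs)
      fail("not enough CpG dyads to place %d age-CpGs", config$n_age_cpgs)
    idx <- sort(sample(eligible, config$n_age_cpgs))
    cpg$is_age_cpg[idx] <- TRUE
  }

  list(cpg = cpg, noncpg = noncpg, gene_mult = gene_mult)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one sample's CGmap methylome
#'
#' Draws per-record coverage from a negative binomial and methylated counts
#' from Binomial(coverage, clip(true level + epsilon)). Both strand records of
#' a CpG dyad share one true level (symmetric by construction); non-CpG
#' cytosines and all mitochondrial cytosines have true level 0, so their
#' observed levels reflect only the non-conversion floor. Age-CpGs get
#' `age_cpg_base + age_effect_per_day * age_days`. Records with zero coverage
#' are omitted, as in real methylation calls.
#'
#' @param annotation a [gene_annotation()] generated with the same config.
#' @param sample one-row data.frame (or list) with `sample_id`, `age_days`.
#' @param config a [simulation_config()] with a `seed`.
#' @param template internal: precomputed [methylome_template] (shared across
#'   a cohort so all samples see the same sites and true levels).
#' @return a `cgmap` data.frame (see [read_cgmap()]).
#' @export
simulate_methylome <- function(annotation, sample, config, template = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) fail("simulation_config$seed must be set")
  if (is.null(template)) template <- methylome_template(annotation, config)
  sample <- as.list(sample)
  stopifnot(!is.null(sample$sample_id), !is.null(sample$age_days))

  set.seed(sample_seed(config$seed, as.character(sample$sample_id)))
  cpg <- template$cpg
  eps <- config$nonconversion_rate

  true_level <- cpg$true_level
  if (any(cpg$is_age_cpg)) {
    true_level[cpg$is_age_cpg] <- config$age_cpg_base +
      config$age_effect_per_day * as.numeric(sample$age_days)
  }
  ## per-dyad biological noise, shared by the two strands; control contig
  ## stays exactly unmethylated
  if (config$sample_noise_sd > 0 && nrow(cpg) > 0L) {
    noise <- rnorm(nrow(cpg), 0, config$sample_noise_sd)
    noise[cpg$is_mito] <- 0
    true_level <- true_level + noise
  }
  true_level <- clip01(true_level)
  p_obs <- clip01(true_level + eps)

  mito_contigs <- annotation$contigs$contig[annotation$contigs$is_mito]
  draw_records <- function(chrom, pos, strand_base, context, dinuc, p) {
    n <- length(pos)
    mu <- ifelse(chrom %in% mito_contigs,
                 config$mean_coverage * config$mito_coverage_factor,
                 config$mean_coverage)
    cov <- rnbinom(n, mu = mu, size = config$coverage_dispersion)
    mc <- rbinom(n, cov, p)
    keep <- cov > 0L
    data.frame(chrom = chrom[keep], strand_base = strand_base[keep],
               pos = pos[keep], context = context[keep], dinuc = dinuc[keep],
               level = mc[keep] / cov[keep], mc = mc[keep], cov = cov[keep],
               stringsAsFactors = FALSE)
  }

  recs <- list()
  if (nrow(cpg) > 0L) {
    recs$fwd <- draw_records(cpg$chrom, cpg$pos, rep("C", nrow(cpg)),
                             rep("CG", nrow(cpg)), rep("CG", nrow(cpg)), p_obs)
    recs$rev <- draw_records(cpg$chrom, cpg$pos + 1L, rep("G", nrow(cpg)),
                             rep("CG", nrow(cpg)), rep("CG", nrow(cpg)), p_obs)
  }
  noncpg <- template$noncpg
  if (nrow(noncpg) > 0L) {
    n <- nrow(noncpg)
    dinuc <- sample(c("CA", "CC", "CT"), n, replace = TRUE)
    context <- ifelse(dinuc == "CA", "CHH", ifelse(dinuc == "CC", "CHH", "CHG"))
    strand_base <- sample(c("C", "G"), n, replace = TRUE)
    recs$noncpg <- draw_records(noncpg$chrom, noncpg$pos, strand_base, context,
                                dinuc, rep(clip01(eps), n))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- empty_cgmap()
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cgmap", "data.frame")
  out
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one CGmap file per sample (optionally gzipped), the shared GFF3 and
#' BED annotation, and a metadata TSV. Per-sample seeds are derived
#' deterministically from the master seed and sample id, so the same master
#' seed reproduces the cohort byte for byte.
#'
#' @param config a [simulation_config()] with a `seed`.
#' @param specs data.frame with columns `sample_id`, `age_days`, `group`
#'   (e.g. from [cohort_design()]); ids must be unique.
#' @param dir output directory (created if needed).
#' @param gzip write `.CGmap.gz` instead of plain `.CGmap`.
#' @return invisibly, a list with `annotation`, `metadata`, and the vector of
#'   CGmap `paths`.
#' @export
generate_cohort <- function(config, specs, dir, gzip = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  specs <- as.data.frame(specs)
  if (nrow(specs) == 0L) fail("cohort specs must be non-empty")
  if (anyDuplicated(specs$sample_id)) fail("duplicate sample ids in cohort specs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  template <- methylome_template(ann, config)
  write_annotation_gff3(ann, file.path(dir, "annotation.gff3"))
  write_annotation_bed(ann, file.path(dir, "annotation.bed"))
  paths <- character(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    tab <- simulate_methylome(ann, specs[i, ], config, template = template)
    ext <- if (gzip) ".CGmap.gz" else ".CGmap"
    paths[i] <- file.path(dir, paste0(specs$sample_id[i], ext))
    write_cgmap(tab, paths[i])
  }
  meta <- data.frame(sample_id = specs$sample_id,
                     age_days = specs$age_days,
                     group = as.character(specs$group))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(annotation = ann, metadata = meta, paths = paths,
                 template = template))
}
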