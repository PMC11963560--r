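#' Gene annotation container
#'
#' Bundles contigs, genes and exons for a (real or simulated) genome.
#' Coordinates are 1-based closed throughout this container, matching GFF3;
#' positional profiling converts to 0-based half-open internally. Exons are
#' stored with a `rank` column giving their order along the direction of
#' transcription (rank 1 = most 5' exon, i.e. the most 3' genomic interval
#' for a minus-strand gene).
#'
#' @param contigs data.frame with columns `contig` (character), `length`
#'   (integer bp) and `is_mito` (logical; at most one control contig).
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based closed genomic span).
#' @param exons data.frame with columns `gene_id`, `rank`, `start`, `end`.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(contigs, genes, exons) {
  contigs <- as.data.frame(contigs)
  genes <- as.data.frame(genes)
  exons <- as.data.frame(exons)
  stopifnot(all(c("contig", "length", "is_mito") %in% names(contigs)))
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  stopifnot(all(c("gene_id", "rank", "start", "end") %in% names(exons)))
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$gene_id)) fail("duplicate gene ids in annotation")
    if (!all(genes$strand %in% c("+", "-"))) fail("gene strand must be '+' or '-'")
    if (!all(genes$chrom %in% contigs$contig)) fail("gene on unknown contig")
    if (any(genes$start > genes$end)) fail("gene start > end")
    if (!all(exons$gene_id %in% genes$gene_id)) fail("exon references unknown gene")
    if (!all(genes$gene_id %in% exons$gene_id)) fail("gene without exons")
  }
  obj <- structure(list(contigs = contigs, genes = genes, exons = exons),
                   class = "gene_annotation")
  validate_annotation(obj)
  obj
}

## check non-overlap of genes per contig and of exons within genes,
## and that exon ranks follow transcription order
validate_annotation <- function(ann) {
  genes <- ann$genes
  if (nrow(genes) == 0L) return(invisible(ann))
  for (ctg in unique(genes$chrom)) {
    g <- genes[genes$chrom == ctg, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      fail("overlapping genes on contig %s", ctg)
  }
  for (gid in genes$gene_id) {
    gene <- genes[genes$gene_id == gid, ]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    if (nrow(ex) < 1L) fail("gene %s has no exons", gid)
    if (any(ex$start < gene$start) || any(ex$end > gene$end))
      fail("exon outside gene span for %s", gid)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      fail("overlapping exons in gene %s", gid)
    genomic_rank <- ex$rank
    expected <- if (gene$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    if (!identical(as.integer(genomic_rank), as.integer(expected)))
      fail("exon ranks of gene %s do not follow transcription order", gid)
  }
  invisible(ann)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d contig(s) (%s), %d gene(s), %d exon(s)\n",
              nrow(x$contigs),
              paste0(x$contigs$contig, "[", x$contigs$length, "bp]",
                     ifelse(x$contigs$is_mito, "*", ""), collapse = ", "),
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Transcription start / end sites of annotated genes
#'
#' @param ann a [gene_annotation()].
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`, `tes`
#'   (1-based; `tss` is the 5' end of the gene on its own strand).
#' @export
gene_anchors <- function(ann) {
  g <- ann$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = ifelse(g$strand == "+", g$start, g$end),
             tes = ifelse(g$strand == "+", g$end, g$start),
             stringsAsFactors = FALSE)
}

#' Write an annotation to GFF3
#'
#' Genes become `gene` features and exons `exon` features with `Parent`
#' attributes; contig lengths are recorded as sequence-region directives.
#'
#' @param ann a [gene_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  seqlens <- stats::setNames(ann$contigs$length, ann$contigs$contig)
  pragmas <- sprintf("##sequence-region %s 1 %d", ann$contigs$contig,
                     ann$contigs$length)
  if (nrow(ann$genes) == 0L) {
    writeLines(c("##gff-version 3", pragmas), path)
    return(invisible(path))
  }
  if (nrow(ann$genes) > 0) {
    g <- ann$genes
    gg <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
    S4Vectors::mcols(gg)$type <- "gene"
    S4Vectors::mcols(gg)$ID <- g$gene_id
    S4Vectors::mcols(gg)$Parent <- IRanges::CharacterList(rep(list(character()), nrow(g)))
    e <- merge(ann$exons, g[, c("gene_id", "chrom", "strand")], by = "gene_id")
    ee <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                 strand = e$strand)
    S4Vectors::mcols(ee)$type <- "exon"
    S4Vectors::mcols(ee)$ID <- paste0(e$gene_id, ".exon", e$rank)
    S4Vectors::mcols(ee)$Parent <- IRanges::CharacterList(as.list(e$gene_id))
    gr <- c(gg, ee)
  } else {
    gr <- GenomicRanges::GRanges(seqnames = factor(character(), levels = ann$contigs$contig),
                                 ranges = IRanges::IRanges())
    S4Vectors::mcols(gr)$type <- character()
    S4Vectors::mcols(gr)$ID <- character()
  }
  GenomeInfoDb::seqlevels(gr) <- ann$contigs$contig
  GenomeInfoDb::seqlengths(gr) <- seqlens
  rtracklayer::export(gr, path, format = "gff3")
  ## rtracklayer does not emit sequence-region directives; add them so contig
  ## lengths (including featureless contigs) survive the round trip
  lines <- readLines(path)
  header <- grep("^##gff-version", lines)[1]
  writeLines(c(lines[seq_len(header)], pragmas,
               lines[-seq_len(header)]), path)
  invisible(path)
}

#' Write gene spans to BED6
#'
#' @param ann a [gene_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  g <- ann$genes
  if (nrow(g) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  S4Vectors::mcols(gr)$name <- g$gene_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 files must carry `gene` and `exon` features linked by `Parent`
#' attributes; exon ranks are recomputed from genomic order and strand so
#' external annotations need no explicit rank attribute. BED input yields
#' single-exon genes spanning each record. Contig lengths come from
#' sequence-region directives when present, otherwise from the rightmost
#' feature. A contig named like `mito`/`chrM`/`MT` is flagged as the
#' mitochondrial control.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param contig_lengths optional named vector overriding contig lengths.
#' @return a [gene_annotation()].
#' @export
read_annotation <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) fail("annotation file not found: %s", path)
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  pragma_lens <- integer()
  if (fmt == "gff3") {
    ## sequence-region directives carry contig lengths rtracklayer ignores
    hdr <- grep("^##sequence-region",
                readLines(path, n = 200L), value = TRUE)
    if (length(hdr)) {
      parts <- strsplit(trimws(hdr), "\\s+")
      pragma_lens <- stats::setNames(
        vapply(parts, function(p) as.integer(p[4]), integer(1)),
        vapply(parts, `[`, "", 2))
    }
  }
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "bed") {
    genes <- data.frame(
      gene_id = S4Vectors::mcols(gr)$name %||% paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = genes$gene_id, rank = 1L,
                        start = genes$start, end = genes$end)
  } else {
    type <- as.character(S4Vectors::mcols(gr)$type)
    gg <- gr[type == "gene"]
    ee <- gr[type == "exon"]
    genes <- data.frame(
      gene_id = as.character(S4Vectors::mcols(gg)$ID),
      chrom = as.character(GenomicRanges::seqnames(gg)),
      strand = as.character(GenomicRanges::strand(gg)),
      start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
      stringsAsFactors = FALSE)
    parent <- vapply(S4Vectors::mcols(ee)$Parent, function(p) as.character(p)[1], "")
    exons <- data.frame(gene_id = parent,
                        start = GenomicRanges::start(ee),
                        end = GenomicRanges::end(ee), stringsAsFactors = FALSE)
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    exons$rank <- NA_integer_
    for (gid in unique(exons$gene_id)) {
      idx <- which(exons$gene_id == gid)
      strand <- genes$strand[match(gid, genes$gene_id)]
      exons$rank[idx] <- if (identical(strand, "-")) rev(seq_along(idx)) else seq_along(idx)
    }
  }
  seqlens <- GenomeInfoDb::seqlengths(gr)
  contig_names <- unique(c(names(pragma_lens), names(seqlens)[!is.na(seqlens)],
                           genes$chrom))
  lens <- vapply(contig_names, function(ctg) {
    if (!is.null(contig_lengths) && ctg %in% names(contig_lengths))
      return(as.integer(contig_lengths[[ctg]]))
    if (ctg %in% names(pragma_lens)) return(pragma_lens[[ctg]])
    if (ctg %in% names(seqlens) && !is.na(seqlens[[ctg]]))
      return(as.integer(seqlens[[ctg]]))
    as.integer(max(genes$end[genes$chrom == ctg], 1L))
  }, integer(1))
  contigs <- data.frame(contig = contig_names, length = lens,
                        is_mito = grepl("^(mito|chrm|mt)", contig_names,
                                        ignore.case = TRUE),
                        stringsAsFactors = FALSE)
  gene_annotation(contigs, genes,
                  exons[, c("gene_id", "rank", "start", "end")])
}
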