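## CGmap: 8-column TSV of per-cytosine methylation calls
##   chrom, Watson-strand base (C = forward cytosine, G = reverse), 1-based
##   position, context (CG/CHG/CHH), dinucleotide (CA/CC/CG/CT), methylation
##   level, methylated read count, total read count.

CGMAP_COLS <- c("chrom", "strand_base", "pos", "context", "dinuc",
                "level", "mc", "cov")

empty_cgmap <- function() {
  out <- data.frame(chrom = character(), strand_base = character(),
                    pos = integer(), context = character(), dinuc = character(),
                    level = numeric(), mc = integer(), cov = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("cgmap", "data.frame")
  out
}

#' Read a CGmap file
#'
#' Parses a plain or gzipped 8-column CGmap TSV into a validated `cgmap`
#' data.frame. Every row is checked against the format invariants
#' (0 <= mc <= cov, level = mc/cov when cov > 0, dinucleotide CG if and only
#' if context CG); violations raise an error naming the offending line.
#'
#' @param path file path (`.CGmap` or `.CGmap.gz`).
#' @return a `cgmap` data.frame with columns `chrom`, `strand_base`, `pos`,
#'   `context`, `dinuc`, `level`, `mc`, `cov`.
#' @export
read_cgmap <- function(path) {
  if (!file.exists(path)) fail("CGmap file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(empty_cgmap())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 8L)
  if (length(bad))
    fail("line %d of %s: expected 8 tab-separated fields, found %d",
         bad[1], path, nfield[bad[1]])
  m <- matrix(unlist(parts), ncol = 8L, byrow = TRUE)
  suppressWarnings({
    pos <- as.integer(m[, 3])
    level <- as.numeric(m[, 6])
    mc <- as.integer(m[, 7])
    cov <- as.integer(m[, 8])
  })
  bad <- which(is.na(pos) | is.na(level) | is.na(mc) | is.na(cov))
  if (length(bad))
    fail("line %d of %s: non-numeric position, level or counts", bad[1], path)
  out <- data.frame(chrom = m[, 1], strand_base = m[, 2], pos = pos,
                    context = m[, 4], dinuc = m[, 5], level = level,
                    mc = mc, cov = cov, stringsAsFactors = FALSE)
  validate_cgmap(out, path)
  class(out) <- c("cgmap", "data.frame")
  out
}

validate_cgmap <- function(tab, path = "<cgmap>") {
  line_of <- function(idx) idx[1]
  bad <- which(!(tab$strand_base %in% c("C", "G")))
  if (length(bad)) fail("line %d of %s: strand base must be C or G", line_of(bad), path)
  bad <- which(tab$mc < 0 | tab$cov < 0 | tab$mc > tab$cov)
  if (length(bad)) fail("line %d of %s: need 0 <= mc <= cov", line_of(bad), path)
  has_cov <- tab$cov > 0
  bad <- which(has_cov & abs(tab$level - tab$mc / tab$cov) > 1e-6)
  if (length(bad)) fail("line %d of %s: level != mc/cov", line_of(bad), path)
  bad <- which((tab$dinuc == "CG") != (tab$context == "CG"))
  if (length(bad))
    fail("line %d of %s: dinucleotide CG must pair with context CG", line_of(bad), path)
  invisible(tab)
}

#' Write a CGmap file
#'
#' Lossless counterpart of [read_cgmap()]; levels are written with enough
#' digits that `read_cgmap(write_cgmap(x))` round-trips. Gzip output is chosen
#' from the file extension.
#'
#' @param tab a `cgmap` data.frame.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  lines <- sprintf("%s\t%s\t%d\t%s\t%s\t%s\t%d\t%d",
                   tab$chrom, tab$strand_base, tab$pos, tab$context, tab$dinuc,
                   formatC(tab$level, digits = 10, format = "g"),
                   tab$mc, tab$cov)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Coverage and contig filtering of CGmap records
#'
#' Retains records with coverage at or above `min_coverage` (threshold
#' inclusive: a site covered by exactly `min_coverage` reads is kept) and,
#' when a contig whitelist is given, records on whitelisted contigs only.
#' An empty whitelist disables the contig filter. Row order is preserved and
#' the operation is idempotent.
#'
#' @param tab a `cgmap` data.frame.
#' @param min_coverage minimum read depth per site (default 10).
#' @param contig_whitelist character vector of contigs to keep; `NULL` or
#'   empty keeps all.
#' @return the filtered `cgmap` data.frame.
#' @export
filter_records <- function(tab, min_coverage = 10L, contig_whitelist = NULL) {
  stopifnot(is.data.frame(tab))
  if (min_coverage < 1) fail("min_coverage must be >= 1")
  keep <- tab$cov >= min_coverage
  if (!is.null(contig_whitelist) && length(contig_whitelist) > 0)
    keep <- keep & tab$chrom %in% contig_whitelist
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cgmap", "data.frame")
  out
}

#' Filter SAM records by total CIGAR match length
#'
#' Computes the summed length of M operations in each record's CIGAR string
#' and keeps records with at least `min_matches` matched bases (records with
#' exactly `min_matches` are kept; only those below the threshold are
#' excluded). Unmapped records (CIGAR `*`) are dropped.
#'
#' @param sam_lines character vector of SAM alignment lines (no header), or a
#'   data.frame with a `cigar` column.
#' @param min_matches minimum summed M-operation length (default 50).
#' @return the retained subset, same type as the input.
#' @export
cigar_match_filter <- function(sam_lines, min_matches = 50L) {
  if (is.data.frame(sam_lines)) {
    cigars <- sam_lines$cigar
  } else {
    fields <- strsplit(sam_lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 6L)
    if (length(short)) fail("SAM record %d has fewer than 6 fields", short[1])
    cigars <- vapply(fields, `[`, "", 6L)
  }
  nm <- vapply(cigars, cigar_matches, numeric(1))
  keep <- !is.na(nm) & nm >= min_matches
  if (is.data.frame(sam_lines)) sam_lines[keep, , drop = FALSE] else sam_lines[keep]
}

## summed M-operation length of one CIGAR; NA for unmapped "*"
cigar_matches <- function(cigar) {
  if (identical(cigar, "*")) return(NA_real_)
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    fail("malformed CIGAR string: %s", cigar)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.numeric(sub("[MIDNSHP=X]$", "", ops))
  sum(lens[grepl("M$", ops)])
}
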