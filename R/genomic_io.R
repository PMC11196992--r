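## Readers/writers for the genomic formats the pipeline touches.  BED input
## is parsed by hand so that malformed lines can be reported by line number;
## coverage and BEDGRAPH go through GenomicRanges/rtracklayer.

.parse_bed_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = lineno[keep])
}

.bed_error <- function(lineno, msg) {
  stop("BED parse error at line ", lineno, ": ", msg, call. = FALSE)
}

#' Read gene models from a BED file
#'
#' Parses BED3/BED6 gene models into a `GRanges` with a `gene_id` metadata
#' column.  Column 4 supplies the gene identifier when present; otherwise
#' identifiers `gene_1`, `gene_2`, ... are assigned in file order.  Strand
#' must come from column 6 or from `default_strand`.  Coordinates are
#' converted from BED (0-based, half-open) to `GRanges` (1-based, closed).
#'
#' Malformed lines (fewer than 3 columns, non-numeric or negative start,
#' start >= end, invalid strand) abort with an error naming the offending
#' line number.
#'
#' @param path Path to a BED file.  Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param default_strand Strand (`"+"` or `"-"`) to assume when column 6 is
#'   absent.  Without it, a strand-less record is an error.
#' @return `GRanges` with `mcols` column `gene_id`.
#' @seealso [collapse_genes()], [read_reads_bed()]
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t5000\tGeneA\t0\t+", bed)
#' read_gene_bed(bed)
read_gene_bed <- function(path, default_strand = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- .parse_bed_lines(path)
  if (length(p$lines) == 0L) stop("no gene records in ", path, call. = FALSE)
  fields <- strsplit(p$lines, "\t", fixed = TRUE)
  n <- length(fields)
  chrom <- character(n); start0 <- integer(n); end0 <- integer(n)
  gene_id <- character(n); strand <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]; ln <- p$lineno[i]
    if (length(f) < 3L) .bed_error(ln, "fewer than 3 columns")
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) .bed_error(ln, "non-numeric coordinates")
    if (s < 0L) .bed_error(ln, "negative start coordinate")
    if (s >= e) .bed_error(ln, sprintf("start (%d) must be < end (%d)", s, e))
    st <- if (length(f) >= 6L) f[6] else default_strand %||% NA_character_
    if (is.na(st)) .bed_error(ln, "no strand column and no 'default_strand' given")
    if (!st %in% c("+", "-")) .bed_error(ln, paste0("invalid strand '", st, "'"))
    chrom[i] <- f[1]; start0[i] <- s; end0[i] <- e; strand[i] <- st
    gene_id[i] <- if (length(f) >= 4L && nzchar(f[4])) f[4] else paste0("gene_", i)
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  mcols(gr)$gene_id <- gene_id
  gr
}

#' Collapse gene models sharing an identifier
#'
#' When several models carry the same `gene_id` (isoforms), they are merged
#' into the union span on their common chromosome and strand, so the gene
#' keeps the most upstream TSS with respect to its strand and gets exactly
#' one stalling index.  Models of one identifier on different chromosomes
#' or strands are an error.
#'
#' @param genes `GRanges` with a `gene_id` column, as from [read_gene_bed()].
#' @return `GRanges`, one range per unique `gene_id`, in first-occurrence
#'   order.
#' @export
collapse_genes <- function(genes) {
  stopifnot(is(genes, "GRanges"), !is.null(mcols(genes)$gene_id))
  ids <- mcols(genes)$gene_id
  if (!anyDuplicated(ids)) return(genes)
  first <- !duplicated(ids)
  out_ids <- ids[first]
  idx <- split(seq_along(ids), factor(ids, levels = out_ids))
  merged <- lapply(idx, function(i) {
    chr <- unique(as.character(seqnames(genes)[i]))
    str <- unique(as.character(strand(genes)[i]))
    if (length(chr) > 1L || length(str) > 1L)
      stop("gene_id '", ids[i[1]],
           "' maps to more than one chromosome or strand", call. = FALSE)
    c(min(start(genes)[i]), max(end(genes)[i]))
  })
  se <- do.call(rbind, merged)
  gr <- GRanges(vapply(idx, function(i) as.character(seqnames(genes)[i[1]]), ""),
                IRanges(se[, 1], se[, 2]),
                strand = vapply(idx, function(i) as.character(strand(genes)[i[1]]), ""))
  mcols(gr)$gene_id <- out_ids
  names(gr) <- NULL
  gr
}

#' Read mapped reads from a BED file
#'
#' Reads BED intervals (first three columns; any further columns are
#' ignored) into an unstranded `GRanges`, sorted by chromosome and start.
#' Pol II ChIP fragments are not strand-informative, so read strand is
#' dropped.  An empty file yields an empty `GRanges` with a warning.
#'
#' @inheritParams read_gene_bed
#' @return Sorted unstranded `GRanges`, one range per read.
#' @export
read_reads_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- .parse_bed_lines(path)
  if (length(p$lines) == 0L) {
    warning("no reads in ", path, "; returning an empty read set")
    return(GRanges())
  }
  fields <- strsplit(p$lines, "\t", fixed = TRUE)
  n <- length(fields)
  chrom <- character(n); start0 <- integer(n); end0 <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]; ln <- p$lineno[i]
    if (length(f) < 3L) .bed_error(ln, "fewer than 3 columns")
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) .bed_error(ln, "non-numeric coordinates")
    if (s < 0L) .bed_error(ln, "negative start coordinate")
    if (s >= e) .bed_error(ln, sprintf("start (%d) must be < end (%d)", s, e))
    chrom[i] <- f[1]; start0[i] <- s; end0[i] <- e
  }
  gr <- GenomeInfoDb::sortSeqlevels(GRanges(chrom, IRanges(start0 + 1L, end0)))
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals to BED
#'
#' Writes a `GRanges` as BED (0-based, half-open).  A `gene_id` column, when
#' present, becomes BED column 4 and the strand column 6; otherwise plain
#' BED3 is written.
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  chrom <- as.character(seqnames(gr))
  s0 <- start(gr) - 1L; e0 <- end(gr)
  if (!is.null(mcols(gr)$gene_id)) {
    df <- data.frame(chrom, s0, e0, mcols(gr)$gene_id, 0L,
                     as.character(strand(gr)))
  } else {
    df <- data.frame(chrom, s0, e0)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-base coverage from a read set
#'
#' Computes the read-depth track of a read set: at every base the depth is
#' the number of reads overlapping it.  Zero-depth runs are omitted,
#' matching the BEDGRAPH `-bg` convention of `genomeCoverageBed`.
#'
#' @param reads `GRanges` of mapped reads.
#' @return `GRanges` of non-overlapping, sorted runs with an integer
#'   `score` column (depth >= 1); empty input gives an empty track.
#' @export
coverage_from_reads <- function(reads) {
  stopifnot(is(reads, "GRanges"))
  if (length(reads) == 0L) {
    gr <- GRanges()
    mcols(gr)$score <- integer(0)
    return(gr)
  }
  gr <- as(coverage(reads), "GRanges")
  gr <- gr[mcols(gr)$score > 0]
  strand(gr) <- "*"
  mcols(gr)$score <- as.integer(mcols(gr)$score)
  sort(gr, ignore.strand = TRUE)
}

#' Write or read a BEDGRAPH coverage track
#'
#' Thin wrappers over [rtracklayer::export()] / [rtracklayer::import()]
#' for run-length coverage tracks (`GRanges` with a numeric `score`).
#'
#' @param track `GRanges` with a `score` column, as from
#'   [coverage_from_reads()].
#' @param path File path.
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph`
#'   returns the track `GRanges`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is(track, "GRanges"), !is.null(mcols(track)$score))
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rtracklayer::import(path, format = "bedGraph")
}

#' Write or read a tab-separated table
#'
#' All tabular outputs of the pipeline are plain TSV: header line, UTF-8,
#' `.` decimal separator, no quoting, no row names.
#'
#' @param df A data frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` returns a
#'   data frame.
#' @export
write_tsv <- function(df, path) {
  stopifnot(is.data.frame(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             encoding = "UTF-8", check.names = FALSE)
}
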