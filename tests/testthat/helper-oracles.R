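suppressPackageStartupMessages(library(GenomicRanges))

# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the package's own code paths: counting is done
# base by base / window by window in plain R.

# Exhaustive sliding-window maximum: every integer window start w in
# [lo, hi], count reads [rs0, re0) (0-based half-open) overlapping
# [w, w + window) by >= 1 bp.
naive_window_max <- function(rs0, re0, lo, hi, window) {
  if (hi < lo || length(rs0) == 0L) return(0L)
  best <- 0L
  for (w in lo:hi) {
    cnt <- sum(rs0 < w + window & re0 > w)
    if (cnt > best) best <- cnt
  }
  best
}

# Per-base depth by direct accumulation over 1-based positions 1..len.
naive_depth <- function(reads_gr, len) {
  depth <- integer(len)
  for (i in seq_along(reads_gr)) {
    s <- GenomicRanges::start(reads_gr)[i]
    e <- GenomicRanges::end(reads_gr)[i]
    depth[s:e] <- depth[s:e] + 1L
  }
  depth
}

# Expand a coverage-track GRanges back to a per-base depth vector.
track_depth <- function(track, len) {
  depth <- integer(len)
  for (i in seq_along(track)) {
    s <- GenomicRanges::start(track)[i]
    e <- GenomicRanges::end(track)[i]
    depth[s:e] <- depth[s:e] + S4Vectors::mcols(track)$score[i]
  }
  depth
}

# Random unstranded reads on one chromosome, 0-based starts in
# [lo0, hi0), lengths in len_range.
random_reads <- function(n, lo0, hi0, len_range = c(20L, 60L),
                         chrom = "chr1") {
  if (n == 0L) return(GenomicRanges::GRanges())
  s0 <- sample(seq.int(lo0, hi0 - 1L), n, replace = TRUE)
  len <- sample(seq.int(len_range[1], len_range[2]), n, replace = TRUE)
  sort(GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, width = len)),
       ignore.strand = TRUE)
}

# One stranded gene model as a length-1 GRanges (1-based coords).
make_gene <- function(chrom, start1, end1, strand, id = "g") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), strand)
  S4Vectors::mcols(gr)$gene_id <- id
  gr
}

# Reads engineered to give exact per-window counts over a 600 bp tiling
# starting at 1-based position `first_start`: window k receives counts[k]
# fully-contained 50 bp reads.
reads_with_window_counts <- function(counts, first_start, chrom = "chr1") {
  s <- unlist(mapply(function(k, cnt) {
    if (cnt == 0) return(integer(0))
    rep(first_start + (k - 1L) * 600L + 100L, cnt)
  }, seq_along(counts), counts, SIMPLIFY = FALSE))
  if (length(s) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, width = 50L))
}

# Scaled-down simulator settings for unit tests (same class structure as
# the defaults, smaller genome).
small_sim_config <- function(seed = 1L, n_genes = 120L, ...) {
  sim_config(n_genes = n_genes, chrom_length = 2.5e6, seed = seed, ...)
}
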