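## Stalling index: per-gene contrast between promoter-proximal and
## gene-body Pol II occupancy.
##
## SI = log2((P + c) / (B + c)) where P is the highest read count over
## 600 bp sliding windows within a 5 kb region centred on the TSS, B is
## the median read count over non-overlapping 600 bp windows tiling the
## rest of the gene, and c is a pseudocount keeping the ratio finite.

#' Promoter window and gene-body intervals for one gene
#'
#' Splits a gene model into the 5' proximal region (a 600 bp window centred
#' on the TSS) and the gene body (the rest of the gene model).  The TSS is
#' the strand-dependent end of the model: BED start for `+`, BED end for
#' `-` (reported as a 0-based junction coordinate).  The promoter window is
#' `[tss - window/2, tss + window/2)` in 0-based coordinates, clipped at
#' the chromosome start; a clipped window narrower than `window` is used
#' as-is with a warning.
#'
#' @param gene A length-1 `GRanges` with a `gene_id` column.
#' @param window Promoter window width in bp (default 600).
#' @return A list with elements `gene_id`, `tss` (0-based), `prg5`
#'   (`IRanges`, 1-based), `body` (`IRanges`, possibly 2 intervals when the
#'   promoter window is interior to the gene span, possibly empty), and
#'   `short_body` (`TRUE` when the body is narrower than `window`, so no
#'   full body window fits).
#' @export
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000), "+",
#'                             gene_id = "GeneA")
#' derive_regions(g)
derive_regions <- function(gene, window = 600L) {
  stopifnot(is(gene, "GRanges"), length(gene) == 1L)
  .assert_scalar_number(window, "window", min = 2)
  half <- as.integer(window %/% 2L)
  str <- as.character(strand(gene))
  if (!str %in% c("+", "-")) stop("gene strand must be '+' or '-'", call. = FALSE)
  tss0 <- if (str == "+") start(gene) - 1L else end(gene)
  prg5 <- IRanges(max(1L, tss0 - half + 1L), tss0 + half)
  if (width(prg5) < window)
    warning("promoter window clipped at chromosome start for gene ",
            mcols(gene)$gene_id %||% "<unnamed>")
  body <- setdiff(IRanges(start(gene), end(gene)), prg5)
  list(gene_id = as.character(mcols(gene)$gene_id %||% NA_character_),
       tss = tss0,
       prg5 = prg5,
       body = body,
       short_body = sum(width(body)) < window)
}

## Maximum sliding-window read count given 0-based read coords on one
## chromosome.  Window starts w (0-based) run over seq(lo, hi, step); a
## read [s, e) overlaps window [w, w + window) iff w in [s - window + 1,
## e - 1].  Counting at the grid points uses two sorted searches.
.window_max_kernel <- function(rs0, re0, lo, hi, window, step) {
  if (hi < lo) return(0L)
  a <- rs0 - window + 1L
  b <- re0 - 1L
  keep <- b >= lo & a <= hi
  if (!any(keep)) return(0L)
  a <- sort(a[keep]); b <- sort(b[keep])
  w <- seq.int(lo, hi, by = step)
  max(findInterval(w, a) - findInterval(w - 1L, b))
}

#' Maximal promoter-proximal window read count
#'
#' Counts reads in `window`-bp sliding windows (start positions `step` bp
#' apart) across the `2 * flank` bp region centred on the TSS and returns
#' the highest count.  A read counts toward a window when it overlaps it by
#' at least one base.  With `step = 1` the scan is exhaustive over every
#' possible window placement.  Windows are clipped at the chromosome start;
#' a chromosome with no reads gives 0.
#'
#' @param reads `GRanges` of mapped reads (strand ignored).
#' @param chrom Chromosome of the gene.
#' @param tss TSS position, 0-based (see [derive_regions()]).
#' @param window Window width in bp (default 600).
#' @param flank Half-width of the scanned region in bp (default 2500, i.e.
#'   a 5 kb region centred on the TSS).
#' @param step Distance between window start positions in bp (default 1).
#' @return Integer: the maximal window read count.
#' @export
promoter_window_max <- function(reads, chrom, tss, window = 600L,
                                flank = 2500L, step = 1L) {
  stopifnot(is(reads, "GRanges"))
  .assert_scalar_number(step, "step", min = 1)
  .assert_scalar_number(window, "window", min = 1)
  .assert_scalar_number(flank, "flank", min = 1)
  r <- reads[as.character(seqnames(reads)) == chrom]
  if (length(r) == 0L) return(0L)
  lo <- max(0L, as.integer(tss) - as.integer(flank))
  hi <- as.integer(tss) + as.integer(flank) - as.integer(window)
  .window_max_kernel(start(r) - 1L, end(r), lo, hi,
                     as.integer(window), as.integer(step))
}

#' Median gene-body window read count
#'
#' Tiles each gene-body interval left-to-right with non-overlapping
#' `window`-bp windows, dropping any trailing fragment shorter than
#' `window`, counts the reads overlapping (>= 1 bp) each window, and
#' returns the median count together with the number of windows.  The
#' median of an even number of windows is the mean of the two central
#' values.
#'
#' @inheritParams promoter_window_max
#' @param body `IRanges` of gene-body intervals (1-based, non-overlapping),
#'   as from [derive_regions()].
#' @return List with `body_median` (`NA` when no full window fits) and
#'   `n_windows`.
#' @export
body_median <- function(reads, chrom, body, window = 600L) {
  stopifnot(is(reads, "GRanges"), is(body, "IRanges"))
  wins <- .tile_body(body, as.integer(window))
  if (length(wins) == 0L)
    return(list(body_median = NA_real_, n_windows = 0L))
  r <- reads[as.character(seqnames(reads)) == chrom]
  counts <- countOverlaps(wins, ranges(r))
  list(body_median = median(counts), n_windows = length(wins))
}

## Non-overlapping `window`-bp tiling of each interval, trailing fragments
## dropped.
.tile_body <- function(body, window) {
  n <- width(body) %/% window
  if (sum(n) == 0L) return(IRanges())
  s <- unlist(lapply(which(n > 0L), function(i) {
    start(body)[i] + window * seq.int(0L, n[i] - 1L)
  }), use.names = FALSE)
  IRanges(s, width = window)
}

## Vectorised body-window starts for many genes at once (plain integer
## arithmetic; equivalent to setdiff(gene span, promoter) + .tile_body per
## gene).  gs/ge: 1-based gene spans; ps/pe: 1-based promoter windows.
## Returns 1-based window starts and the owning gene index, windows ordered
## left-to-right within each gene.
.body_windows_vec <- function(gs, ge, ps, pe, window) {
  g <- seq_along(gs)
  int_s <- c(gs, pmax(gs, pe + 1L))
  int_e <- c(pmin(ge, ps - 1L), ge)
  idx <- c(g, g)
  ok <- int_e >= int_s
  int_s <- int_s[ok]; idx <- idx[ok]
  n <- (int_e[ok] - int_s + 1L) %/% window
  keep <- n > 0L
  int_s <- int_s[keep]; idx <- idx[keep]; n <- n[keep]
  ord <- order(idx, int_s)
  int_s <- int_s[ord]; idx <- idx[ord]; n <- n[ord]
  if (length(n) == 0L) return(list(start = integer(0), gene = integer(0)))
  list(start = rep(int_s, n) + window * (sequence(n) - 1L),
       gene = rep(idx, n))
}

#' Stalling index from promoter and body counts
#'
#' `si = log2((promoter_max + pseudocount) / (body_median + pseudocount))`.
#' The pseudocount keeps the index finite when the gene body is read-free;
#' the index is 0 whenever promoter and body counts agree, positive when
#' Pol II accumulates at the promoter, and negative when the body dominates.
#'
#' @param promoter_max Highest promoter window count (vectorised).
#' @param body_median Median gene-body window count (vectorised).
#' @param pseudocount Positive pseudocount added to both counts (default 1).
#' @return Numeric vector of log2 stalling indices.
#' @export
#' @examples
#' stalling_index(10, 1)   # log2(11/2)
#' stalling_index(0, 7)    # log2(1/8) = -3
stalling_index <- function(promoter_max, body_median, pseudocount = 1) {
  .assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop("'pseudocount' must be > 0", call. = FALSE)
  if (any(promoter_max < 0, na.rm = TRUE) || any(body_median < 0, na.rm = TRUE))
    stop("read counts must be non-negative", call. = FALSE)
  log2((promoter_max + pseudocount) / (body_median + pseudocount))
}

#' Per-gene stalling index table
#'
#' Runs the whole scoring over a gene set: collapses models sharing a
#' `gene_id` (union span, so the most upstream TSS per strand is kept),
#' derives promoter and body regions, computes the maximal promoter window
#' count and the median body window count, and forms the stalling index.
#'
#' Genes whose body holds no full `window`-bp window are flagged
#' `short_gene` and get `si = NA`; they must be excluded from distribution
#' analysis (and [find_pause_cutoff()] does so).  Genes with a read-free
#' body are flagged `zero_body`; their index is finite thanks to the
#' pseudocount.
#'
#' @param genes `GRanges` of gene models with a `gene_id` column.
#' @param reads `GRanges` of mapped reads (strand ignored).
#' @inheritParams promoter_window_max
#' @inheritParams stalling_index
#' @param collapse Collapse gene models sharing a `gene_id` first
#'   (default `TRUE`).
#' @return Data frame with columns `gene_id`, `promoter_max`,
#'   `body_median`, `n_body_windows`, `si` and `flag`
#'   (`ok`/`short_gene`/`zero_body`), one row per collapsed gene, in input
#'   order.
#' @export
si_table <- function(genes, reads, window = 600L, flank = 2500L, step = 1L,
                     pseudocount = 1, collapse = TRUE) {
  stopifnot(is(genes, "GRanges"), is(reads, "GRanges"))
  if (collapse) genes <- collapse_genes(genes)
  n <- length(genes)
  str <- as.character(strand(genes))
  if (!all(str %in% c("+", "-")))
    stop("all genes must be stranded ('+' or '-')", call. = FALSE)
  tss0 <- ifelse(str == "+", start(genes) - 1L, end(genes))
  window <- as.integer(window); flank <- as.integer(flank)
  step <- as.integer(step); half <- window %/% 2L

  ## promoter scan: one overlap query for all genes, then a per-gene sweep
  scan <- GRanges(seqnames(genes),
                  IRanges(pmax(1L, tss0 - flank + 1L), tss0 + flank))
  hits <- findOverlaps(scan, reads, ignore.strand = TRUE)
  by_gene <- split(subjectHits(hits), factor(queryHits(hits), levels = seq_len(n)))
  rs0_all <- start(reads) - 1L; re0_all <- end(reads)
  promoter_max <- vapply(seq_len(n), function(i) {
    j <- by_gene[[i]]
    if (length(j) == 0L) return(0L)
    lo <- max(0L, tss0[i] - flank)
    hi <- tss0[i] + flank - window
    as.integer(.window_max_kernel(rs0_all[j], re0_all[j], lo, hi, window, step))
  }, integer(1))

  ## body windows: tile all genes at once, one countOverlaps call
  bw <- .body_windows_vec(start(genes), end(genes),
                          pmax(1L, tss0 - half + 1L), tss0 + half, window)
  n_windows <- tabulate(bw$gene, nbins = n)
  body_med <- rep(NA_real_, n)
  has <- n_windows > 0L
  if (any(has)) {
    all_wins <- GRanges(as.character(seqnames(genes))[bw$gene],
                        IRanges(bw$start, width = window))
    counts <- countOverlaps(all_wins, reads, ignore.strand = TRUE)
    med <- vapply(split(counts, factor(bw$gene, levels = which(has))),
                  function(x) median(as.numeric(x)), numeric(1))
    body_med[has] <- med
  }

  si <- rep(NA_real_, n)
  si[has] <- stalling_index(promoter_max[has], body_med[has], pseudocount)
  flag <- ifelse(!has, "short_gene",
                 ifelse(body_med == 0, "zero_body", "ok"))
  data.frame(gene_id = mcols(genes)$gene_id,
             promoter_max = promoter_max,
             body_median = body_med,
             n_body_windows = n_windows,
             si = si,
             flag = flag,
             stringsAsFactors = FALSE)
}
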