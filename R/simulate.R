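## Synthetic data with planted truth: gene models, Pol II read placements,
## fold-change tables and qPCR Ct tables.  The generator emulates the two
## ChIP profile archetypes (a sharp TSS-proximal read pile over a faint
## body for paused genes; body-wide signal for constitutively elongating
## genes) and three expression dynamics (transient immediate-early
## induction, late rise, flat), so the whole pipeline can be validated
## end to end against known labels.

#' Configuration for the synthetic-data generator
#'
#' Collects and validates every knob of the simulator.  The defaults are
#' the study conditions used throughout the package's validation: 2000
#' genes on one 30 Mb chromosome, 30% paused / 50% elongating / 20%
#' silent, a mean of 200 reads in the promoter pile of a paused gene
#' against 2 reads per 600 bp body window, 40 reads per body window for
#' elongating genes, and immediate-early dynamics planted in ~1.2% of
#' paused genes.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param gene_length Length-2 vector: min and max gene length (bp),
#'   sampled uniformly.
#' @param proportions Named vector of class proportions
#'   (`paused`, `elongating`, `silent`); must sum to 1.
#' @param lambda_peak Mean read count of the promoter-proximal pile of a
#'   paused gene (Poisson).
#' @param lambda_body_low Mean reads per 600 bp body window of a paused
#'   gene (Poisson).
#' @param lambda_body_high Mean reads per 600 bp body window of an
#'   elongating gene (Poisson).
#' @param peak_spread Standard deviation (bp) of read starts around the
#'   TSS in the promoter pile.
#' @param background_per_kb Genome-wide uniform background read rate,
#'   reads per kb.
#' @param iegs_among_paused Probability that a paused gene carries
#'   immediate-early expression dynamics.
#' @param late_among_elongating Probability that an elongating gene
#'   carries late-rising dynamics (the rest are flat).
#' @param fc_mean Named list of length-2 vectors `c(log2fc_1h, log2fc_2h)`
#'   class means for `IEG`, `late`, `flat`.
#' @param fc_sd Named vector of per-class log2FC standard deviations.
#' @param sigma_ct Standard deviation of qPCR Ct measurement noise
#'   (cycles).
#' @param ct_reference Reference-gene Ct level (cycles).
#' @param ct_target_base Target-gene Ct level in the control condition.
#' @param n_ct_replicates Replicate measurements per gene and condition.
#' @param read_length Read length in bp.
#' @param window Body window width used by the read generator (bp); keep
#'   equal to the scoring window.
#' @param min_gene_gap Minimal gap between adjacent genes (bp); 6 kb keeps
#'   5 kb promoter scans from touching a neighbour.
#' @param seed Master seed; every sub-generator derives its own stream
#'   from it, so each component is reproducible in isolation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       chrom = "chrS",
                       chrom_length = 3e7,
                       gene_length = c(3000L, 8000L),
                       proportions = c(paused = 0.3, elongating = 0.5,
                                       silent = 0.2),
                       lambda_peak = 200,
                       lambda_body_low = 2,
                       lambda_body_high = 40,
                       peak_spread = 150,
                       background_per_kb = 0.1,
                       iegs_among_paused = 0.012,
                       late_among_elongating = 0.15,
                       fc_mean = list(IEG = c(3.5, 1.0),
                                      late = c(1.0, 2.5),
                                      flat = c(0, 0)),
                       fc_sd = c(IEG = 0.3, late = 0.3, flat = 0.2),
                       sigma_ct = 0.2,
                       ct_reference = 20,
                       ct_target_base = 25,
                       n_ct_replicates = 2L,
                       read_length = 36L,
                       window = 600L,
                       min_gene_gap = 6000L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), chrom = chrom,
              chrom_length = as.numeric(chrom_length),
              gene_length = as.integer(gene_length),
              proportions = proportions,
              lambda_peak = lambda_peak, lambda_body_low = lambda_body_low,
              lambda_body_high = lambda_body_high, peak_spread = peak_spread,
              background_per_kb = background_per_kb,
              iegs_among_paused = iegs_among_paused,
              late_among_elongating = late_among_elongating,
              fc_mean = fc_mean, fc_sd = fc_sd, sigma_ct = sigma_ct,
              ct_reference = ct_reference, ct_target_base = ct_target_base,
              n_ct_replicates = as.integer(n_ct_replicates),
              read_length = as.integer(read_length),
              window = as.integer(window),
              min_gene_gap = as.integer(min_gene_gap),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("'n_genes' must be >= 1", call. = FALSE)
  if (length(cfg$gene_length) != 2L || cfg$gene_length[1] > cfg$gene_length[2] ||
      cfg$gene_length[1] < 1L)
    stop("'gene_length' must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  p <- cfg$proportions
  if (!setequal(names(p), c("paused", "elongating", "silent")) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("'proportions' must be named paused/elongating/silent, ",
         "non-negative, summing to 1", call. = FALSE)
  rates <- c(cfg$lambda_peak, cfg$lambda_body_low, cfg$lambda_body_high,
             cfg$background_per_kb, cfg$peak_spread, cfg$sigma_ct)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates and spreads must be finite and >= 0", call. = FALSE)
  for (f in c("iegs_among_paused", "late_among_elongating"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate gene models with planted class labels
#'
#' Places `n_genes` non-overlapping genes (>= `min_gene_gap` apart, so
#' promoter scans never collide) on one chromosome, assigns strands at
#' random, draws a Pol II class (`paused`/`elongating`/`silent`) per gene
#' with the configured proportions, and an expression class
#' (`IEG`/`late`/`flat`): paused genes are IEG with probability
#' `iegs_among_paused` (else flat), elongating genes late with probability
#' `late_among_elongating` (else flat), silent genes flat.  Deterministic
#' per seed.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (`GRanges` with `gene_id`) and `truth`
#'   (data frame `gene_id`, `pol2_class`, `expr_class`).
#' @export
simulate_genes <- function(config) {
  stopifnot(is(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genes"), {
    n <- config$n_genes
    len <- sample(seq.int(config$gene_length[1], config$gene_length[2]),
                  n, replace = TRUE)
    margin <- 6000
    slack <- config$chrom_length - 2 * margin - sum(len) -
      (n - 1) * config$min_gene_gap
    if (slack < 0)
      stop("genes do not fit: increase 'chrom_length' to at least ",
           format(2 * margin + sum(len) + (n - 1) * config$min_gene_gap,
                  scientific = FALSE), " bp", call. = FALSE)
    offsets <- sort(runif(n, 0, slack))
    start0 <- round(margin + offsets +
                      cumsum(c(0, len[-n] + config$min_gene_gap)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gr <- GRanges(config$chrom, IRanges(start0 + 1, start0 + len),
                  strand = strand)
    mcols(gr)$gene_id <- sprintf("sim_%04d", seq_len(n))

    pol2 <- sample(rep(names(config$proportions),
                       .class_counts(config$proportions, n)))
    expr <- ifelse(pol2 == "paused",
                   ifelse(runif(n) < config$iegs_among_paused, "IEG", "flat"),
            ifelse(pol2 == "elongating",
                   ifelse(runif(n) < config$late_among_elongating,
                          "late", "flat"),
                   "flat"))
    list(genes = gr,
         truth = data.frame(gene_id = mcols(gr)$gene_id,
                            pol2_class = pol2, expr_class = expr,
                            stringsAsFactors = FALSE))
  })
}

## Integer class counts from proportions (largest-remainder rounding).
.class_counts <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  setNames(as.integer(k), names(p))
}

#' Simulate Pol II ChIP reads for labelled genes
#'
#' Per-gene read placement by class: a paused gene receives
#' `Poisson(lambda_peak)` reads with start positions
#' `Normal(tss, peak_spread)` plus `Poisson(lambda_body_low)` reads
#' uniform in each full 600 bp body window; an elongating gene receives
#' `Poisson(lambda_body_high)` reads per body window and no promoter pile;
#' a silent gene receives nothing.  Uniform background reads are added
#' genome-wide at `background_per_kb`.  All reads have fixed length
#' `read_length` and are clipped to the chromosome.  Deterministic per
#' seed.
#'
#' @param genes `GRanges` from [simulate_genes()].
#' @param truth Truth table from [simulate_genes()].
#' @param config A [sim_config()].
#' @return Sorted unstranded `GRanges` of reads.
#' @export
simulate_reads <- function(genes, truth, config) {
  stopifnot(is(config, "sim_config"), is(genes, "GRanges"),
            length(genes) == nrow(truth))
  with_seed(derive_seed(config$seed, "reads"), {
    L <- config$read_length
    win <- config$window
    half <- win %/% 2L
    str <- as.character(strand(genes))
    tss0 <- ifelse(str == "+", start(genes) - 1L, end(genes))
    cls <- truth$pol2_class[match(mcols(genes)$gene_id, truth$gene_id)]

    starts <- numeric(0)

    ## promoter piles of paused genes
    paused <- which(cls == "paused")
    if (length(paused)) {
      npk <- rpois(length(paused), config$lambda_peak)
      mu <- rep(tss0[paused], npk)
      starts <- c(starts, round(rnorm(sum(npk), mu, config$peak_spread)))
    }

    ## body windows (low rate for paused, high for elongating)
    active <- which(cls %in% c("paused", "elongating"))
    if (length(active)) {
      bw <- .body_windows_vec(start(genes)[active], end(genes)[active],
                              pmax(1L, tss0[active] - half + 1L),
                              tss0[active] + half, win)
      if (length(bw$start)) {
        wrate <- ifelse(cls[active][bw$gene] == "paused",
                        config$lambda_body_low, config$lambda_body_high)
        nw <- rpois(length(bw$start), wrate)
        starts <- c(starts,
                    rep(bw$start - 1, nw) + floor(runif(sum(nw)) * win))
      }
    }

    ## uniform background
    nbg <- rpois(1, config$background_per_kb * config$chrom_length / 1000)
    starts <- c(starts, floor(runif(nbg) * (config$chrom_length - L)))

    starts <- pmin(pmax(starts, 0), config$chrom_length - L)
    reads <- GRanges(config$chrom, IRanges(starts + 1, width = L))
    sort(reads, ignore.strand = TRUE)
  })
}

#' Simulate a log2 fold-change table from planted expression classes
#'
#' Per-class Gaussian draws around the configured `(log2fc_1h, log2fc_2h)`
#' means: IEG genes are high at 1 h and lower at 2 h (transient
#' induction), late genes rise from 1 h to 2 h, flat genes sit near 0.
#' Deterministic per seed.
#'
#' @inheritParams simulate_reads
#' @return Data frame with columns `gene_id`, `log2fc_1h`, `log2fc_2h`.
#' @export
simulate_fc_table <- function(truth, config) {
  stopifnot(is(config, "sim_config"))
  with_seed(derive_seed(config$seed, "fc"), {
    cls <- truth$expr_class
    mu <- do.call(rbind, config$fc_mean[cls])
    sd <- config$fc_sd[cls]
    n <- nrow(truth)
    data.frame(gene_id = truth$gene_id,
               log2fc_1h = rnorm(n, mu[, 1], sd),
               log2fc_2h = rnorm(n, mu[, 2], sd),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a replicate qPCR Ct table consistent with planted fold changes
#'
#' Builds Ct measurements whose 2^-ddCt quantification recovers the
#' realized fold-change table: the reference gene sits at a constant Ct,
#' the target gene's control-condition Ct at `ct_target_base`, and its Ct
#' in condition `PH_1h` (`PH_2h`) is shifted down by the planted
#' `log2fc_1h` (`log2fc_2h`); every measurement gets
#' `Normal(0, sigma_ct)` noise.  With `sigma_ct = 0` the construction is
#' exactly invertible by [ddct_table()].  Deterministic per seed.
#'
#' @param fc Fold-change table from [simulate_fc_table()].
#' @param config A [sim_config()].
#' @return Data frame with columns `gene_id`, `condition`
#'   (`prePH`/`PH_1h`/`PH_2h`), `replicate`, `ct_target`, `ct_reference`.
#' @export
simulate_ct_table <- function(fc, config) {
  stopifnot(is(config, "sim_config"))
  .check_expr_table(fc)
  with_seed(derive_seed(config$seed, "ct"), {
    reps <- config$n_ct_replicates
    conds <- c(prePH = 0, PH_1h = NA, PH_2h = NA)
    rows <- expand.grid(replicate = seq_len(reps),
                        condition = names(conds),
                        gene_id = fc$gene_id,
                        stringsAsFactors = FALSE)[, 3:1]
    i <- match(rows$gene_id, fc$gene_id)
    shift <- ifelse(rows$condition == "PH_1h", fc$log2fc_1h[i],
                    ifelse(rows$condition == "PH_2h", fc$log2fc_2h[i], 0))
    n <- nrow(rows)
    rows$ct_target <- config$ct_target_base - shift +
      rnorm(n, 0, config$sigma_ct)
    rows$ct_reference <- config$ct_reference + rnorm(n, 0, config$sigma_ct)
    rows
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genes()], [simulate_reads()],
#' [simulate_fc_table()] and [simulate_ct_table()] under one master seed.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `truth`, `reads`, `fc`, `ct` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genes(config)
  reads <- simulate_reads(g$genes, g$truth, config)
  fc <- simulate_fc_table(g$truth, config)
  ct <- simulate_ct_table(fc, config)
  list(genes = g$genes, truth = g$truth, reads = reads, fc = fc, ct = ct,
       config = config)
}

#' Accuracy of pause calls against planted truth
#'
#' Restricts to genes planted as `paused` or `elongating` (the two classes
#' the cutoff is meant to separate), calls a gene paused when
#' `si >= cutoff`, and reports sensitivity, specificity and balanced
#' accuracy.
#'
#' @param si_tab Stalling-index table from [si_table()].
#' @param truth Truth table from [simulate_genes()].
#' @param cutoff Stalling-index cutoff.
#' @return List with `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `n_paused`, `n_elongating`.
#' @export
evaluate_pause_calls <- function(si_tab, truth, cutoff) {
  .assert_scalar_number(cutoff, "cutoff")
  m <- merge(si_tab, truth, by = "gene_id")
  m <- m[m$pol2_class %in% c("paused", "elongating") & is.finite(m$si), ]
  called <- m$si >= cutoff
  sens <- mean(called[m$pol2_class == "paused"])
  spec <- mean(!called[m$pol2_class == "elongating"])
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       n_paused = sum(m$pol2_class == "paused"),
       n_elongating = sum(m$pol2_class == "elongating"))
}
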