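## Expression dynamics: differential-expression calls on a fold-change
## table, the paused-IEG candidate filter, and relative qPCR
## quantification by the 2^-ddCt method.

.check_expr_table <- function(expr) {
  need <- c("gene_id", "log2fc_1h", "log2fc_2h")
  miss <- setdiff(need, names(expr))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(expr)
}

.norm_id <- function(x) tolower(trimws(x))

#' Differentially expressed genes per time point
#'
#' A gene is differentially expressed at a time point when
#' `|log2FC| >= fc_threshold` there (boundary inclusive).  Returns the
#' per-time-point gene sets and their union.
#'
#' @param expr Data frame with columns `gene_id`, `log2fc_1h`, `log2fc_2h`.
#' @param fc_threshold Positive threshold on `|log2FC|` (default 2).
#' @return List with character vectors `de_1h`, `de_2h` and `de_union`.
#' @export
classify_de <- function(expr, fc_threshold = 2) {
  .check_expr_table(expr)
  .assert_scalar_number(fc_threshold, "fc_threshold")
  if (fc_threshold <= 0) stop("'fc_threshold' must be > 0", call. = FALSE)
  de1 <- expr$gene_id[abs(expr$log2fc_1h) >= fc_threshold]
  de2 <- expr$gene_id[abs(expr$log2fc_2h) >= fc_threshold]
  list(de_1h = de1, de_2h = de2, de_union = union(de1, de2))
}

#' Candidate paused immediate-early genes
#'
#' Intersects the stalling-index table with the fold-change table and
#' applies the selection used to nominate paused-IEG candidates: strong
#' induction at 1 h that has already receded by 2 h, i.e.
#' `log2fc_1h >= fc1_min` and `log2fc_1h >= log2fc_2h + delta_min`,
#' together with a high stalling index, `si >= si_stringent` (stringent
#' mode) or `si >= si_relaxed` (relaxed mode).  All comparisons are
#' inclusive.  Every stringent call is by construction also a relaxed call.
#'
#' Gene identifiers are matched case-insensitively after trimming
#' whitespace; genes present in only one table are skipped and reported in
#' the `unmatched` attribute of the result (and via a message).  No common
#' genes at all is an error.
#'
#' @param si_tab Data frame with columns `gene_id` and `si`, as from
#'   [si_table()]; rows with non-finite `si` are ignored.
#' @param expr Data frame with columns `gene_id`, `log2fc_1h`, `log2fc_2h`.
#' @param mode `"stringent"` or `"relaxed"`.
#' @param fc1_min Minimum 1 h log2 fold change (default 2.5).
#' @param delta_min Minimum excess of the 1 h over the 2 h log2 fold
#'   change (default 1, i.e. a 2-fold difference).
#' @param si_stringent Stringent stalling-index threshold (default 3.7).
#' @param si_relaxed Relaxed stalling-index threshold (default 2.5).
#' @return Data frame of the genes passing the selected mode, columns
#'   `gene_id`, `si`, `log2fc_1h`, `log2fc_2h`, `passes_stringent`,
#'   `passes_relaxed`, sorted by decreasing `si`.  Attribute `unmatched`
#'   lists identifiers found in only one input.
#' @export
select_candidates <- function(si_tab, expr, mode = c("stringent", "relaxed"),
                              fc1_min = 2.5, delta_min = 1,
                              si_stringent = 3.7, si_relaxed = 2.5) {
  mode <- match.arg(mode)
  .check_expr_table(expr)
  if (!all(c("gene_id", "si") %in% names(si_tab)))
    stop("stalling-index table lacks 'gene_id'/'si' columns", call. = FALSE)
  for (p in c("fc1_min", "delta_min", "si_stringent", "si_relaxed"))
    .assert_scalar_number(get(p), p)

  si_key <- .norm_id(si_tab$gene_id)
  ex_key <- .norm_id(expr$gene_id)
  common <- intersect(si_key, ex_key)
  if (length(common) == 0L) {
    if (nrow(si_tab) == 0L && nrow(expr) == 0L) {
      out <- data.frame(gene_id = character(0), si = numeric(0),
                        log2fc_1h = numeric(0), log2fc_2h = numeric(0),
                        passes_stringent = logical(0),
                        passes_relaxed = logical(0))
      attr(out, "unmatched") <- character(0)
      return(out)
    }
    stop("no gene identifiers shared between the stalling-index and ",
         "expression tables", call. = FALSE)
  }
  unmatched <- c(setdiff(si_tab$gene_id, si_tab$gene_id[si_key %in% common]),
                 setdiff(expr$gene_id, expr$gene_id[ex_key %in% common]))
  if (length(unmatched))
    message(length(unmatched), " gene identifier(s) present in only one table")

  si_m <- si_tab[match(common, si_key), , drop = FALSE]
  ex_m <- expr[match(common, ex_key), , drop = FALSE]
  df <- data.frame(gene_id = si_m$gene_id,
                   si = si_m$si,
                   log2fc_1h = ex_m$log2fc_1h,
                   log2fc_2h = ex_m$log2fc_2h,
                   stringsAsFactors = FALSE)
  df <- df[is.finite(df$si), , drop = FALSE]
  fc_ok <- df$log2fc_1h >= fc1_min & df$log2fc_1h >= df$log2fc_2h + delta_min
  df$passes_stringent <- fc_ok & df$si >= si_stringent
  df$passes_relaxed <- fc_ok & df$si >= si_relaxed
  keep <- if (mode == "stringent") df$passes_stringent else df$passes_relaxed
  out <- df[keep, , drop = FALSE]
  out <- out[order(-out$si), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Relative fold change by the 2^-ddCt method
#'
#' Normalises the target gene's cycle threshold to a reference
#' (housekeeping) gene within each condition and compares conditions:
#' `dCt = ct_target - ct_reference` per condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `= 2^-ddCt` (linear
#' scale).  Vectorised; invariant to any constant shift applied to all
#' four cycle thresholds.
#'
#' @param ct_target_treated,ct_ref_treated Target and reference Ct in the
#'   treated condition.
#' @param ct_target_control,ct_ref_control Target and reference Ct in the
#'   control condition.
#' @return Linear fold change(s), `2^-ddCt`.
#' @export
#' @examples
#' ddct_fold_change(23, 20, 25, 20)  # target drops 2 cycles -> 4
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Fold changes from a replicate Ct table
#'
#' Averages replicate Ct values (arithmetic mean on the Ct scale) per gene
#' and condition, then computes the 2^-ddCt fold change of every non-control
#' condition against `control`.
#'
#' @param ct Data frame with columns `gene_id`, `condition`, `ct_target`,
#'   `ct_reference` (one row per replicate measurement).
#' @param control Name of the control condition (e.g. `"prePH"`).
#' @return Data frame with columns `gene_id`, `condition`, `fold_change`
#'   and `log2_fold_change`.
#' @export
ddct_table <- function(ct, control) {
  need <- c("gene_id", "condition", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!control %in% ct$condition)
    stop("control condition '", control, "' absent from Ct table",
         call. = FALSE)
  key <- interaction(ct$gene_id, ct$condition, drop = TRUE)
  agg <- data.frame(gene_id = tapply(ct$gene_id, key, `[`, 1),
                    condition = tapply(ct$condition, key, `[`, 1),
                    ct_target = as.numeric(tapply(ct$ct_target, key, mean)),
                    ct_reference = as.numeric(tapply(ct$ct_reference, key, mean)),
                    stringsAsFactors = FALSE)
  ctrl <- agg[agg$condition == control, , drop = FALSE]
  trt <- agg[agg$condition != control, , drop = FALSE]
  i <- match(trt$gene_id, ctrl$gene_id)
  if (anyNA(i))
    stop("gene(s) without a '", control, "' measurement: ",
         paste(unique(trt$gene_id[is.na(i)]), collapse = ", "), call. = FALSE)
  fc <- ddct_fold_change(trt$ct_target, trt$ct_reference,
                         ctrl$ct_target[i], ctrl$ct_reference[i])
  out <- data.frame(gene_id = trt$gene_id, condition = trt$condition,
                    fold_change = fc, log2_fold_change = log2(fc),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
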