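# Mapping-accuracy evaluation against simulated ground truth.

#' Evaluate mappings against simulated ground truth
#'
#' Under the `position_pm5` rule a read is correctly mapped when its
#' reported chromosome and strand match the truth and the reported leftmost
#' position is within `tolerance` bases (default +/- 5 bp) of the true
#' origin. The `coverage80` rule (intended for long reads) additionally
#' requires that at least `min_coverage` of the read's bases are aligned
#' (`M` operations; default 80%). Unmapped reads are counted separately.
#'
#' @param sam Path to a SAM file, or a data frame with columns `qname`,
#'   `mapped`, `rname`/`chrom`, `pos`, `strand`, `aligned_frac`.
#' @param truth Data frame with columns `read_id`, `chrom`, `strand`,
#'   `true_start` (e.g. from [simulate_reads()] or [parse_truth_names()]),
#'   or a path to a tab-separated file with those columns. Every read in
#'   the SAM must be present.
#' @param rule `"position_pm5"` or `"coverage80"`.
#' @param tolerance Position tolerance in bases (default 5).
#' @param min_coverage Minimum aligned read fraction for `coverage80`
#'   (default 0.8).
#' @return A list of class `eval_report`: `n_reads`, `n_correct`,
#'   `n_incorrect`, `n_unmapped`, `pct_correct`, `pct_incorrect`,
#'   `pct_unmapped` (percentages rounded to 2 decimals) and `rule`.
#' @export
evaluate_mappings <- function(sam, truth,
                              rule = c("position_pm5", "coverage80"),
                              tolerance = 5L, min_coverage = 0.8) {
  rule <- match.arg(rule)
  df <- if (is.data.frame(sam)) {
    sam$rname <- if (!is.null(sam$rname)) sam$rname else sam$chrom
    sam
  } else {
    parse_sam(sam)
  }
  if (is.character(truth) && length(truth) == 1L)
    truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  idx <- match(df$qname, truth$read_id)
  if (anyNA(idx))
    stop("read id missing from truth table: ",
         df$qname[which(is.na(idx))[1L]])
  tr <- truth[idx, ]
  mapped <- df$mapped
  pos_ok <- mapped & df$rname == tr$chrom & df$strand == tr$strand &
    abs(df$pos - tr$true_start) <= tolerance
  correct <- if (rule == "coverage80")
    pos_ok & df$aligned_frac >= min_coverage else pos_ok
  n <- nrow(df)
  n_unmapped <- sum(!mapped)
  n_correct <- sum(correct)
  n_incorrect <- n - n_unmapped - n_correct
  structure(list(
    n_reads = n, n_correct = n_correct, n_incorrect = n_incorrect,
    n_unmapped = n_unmapped,
    pct_correct = round(100 * n_correct / n, 2),
    pct_incorrect = round(100 * n_incorrect / n, 2),
    pct_unmapped = round(100 * n_unmapped / n, 2),
    rule = rule
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Mapping evaluation (%s): %d reads\n  correct   %8.2f%% (%d)\n  incorrect %8.2f%% (%d)\n  unmapped  %8.2f%% (%d)\n",
    x$rule, x$n_reads, x$pct_correct, x$n_correct, x$pct_incorrect,
    x$n_incorrect, x$pct_unmapped, x$n_unmapped))
  invisible(x)
}
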