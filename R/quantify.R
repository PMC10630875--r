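#' Summarize lariat calls for one sample
#'
#' Lariats per million = `n_lariat_reads / (total_reads / 1e6)`. The
#' denominator is the total number of sequenced reads in the library (both
#' mates counted); passing the unmapped-read input count instead is allowed
#' but misrepresents library size, so it must be done explicitly and is
#' flagged with a warning by [run_pipeline()].
#'
#' @param calls Lariat call table (only rows matching `sample_id` are
#'   counted).
#' @param total_reads Library-size denominator; must be positive.
#' @param sample_id Sample label.
#' @param group Optional group label (e.g. condition).
#' @return One-row data.table: `sample_id`, `group`, `n_lariat_reads`,
#'   `total_reads`, `lariats_per_million`.
#' @export
summarize_sample <- function(calls, total_reads, sample_id, group = NA_character_) {
  if (!is.numeric(total_reads) || length(total_reads) != 1L || total_reads <= 0) {
    stop("total_reads must be a single positive number", call. = FALSE)
  }
  n <- if (nrow(calls)) sum(calls$sample_id == sample_id) else 0L
  data.table(sample_id = sample_id, group = group,
             n_lariat_reads = as.integer(n),
             total_reads = as.numeric(total_reads),
             lariats_per_million = n / (total_reads / 1e6))
}

#' Compare lariat burden between two groups
#'
#' Fold enrichment is the ratio of unrounded group means of
#' lariats-per-million; Welch's unpaired two-sample t-test on the per-million
#' values is reported alongside (statistic and p-value are `NA` when either
#' group has fewer than two samples).
#'
#' @param summaries Row-bound output of [summarize_sample()], one row per
#'   sample, with `group` set.
#' @param group_a,group_b Group labels; the fold is `mean(a) / mean(b)`.
#' @return One-row data.table: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_lpm_a`, `mean_lpm_b`, `mean_count_a`, `mean_count_b`,
#'   `fold_enrichment` (`NA` with a `fold_defined = FALSE` flag when
#'   `mean_lpm_b` is zero), `t_statistic`, `p_value`.
#' @export
compare_groups <- function(summaries, group_a, group_b) {
  a <- summaries[summaries$group == group_a, ]
  b <- summaries[summaries$group == group_b, ]
  if (nrow(a) < 1L || nrow(b) < 1L) {
    stop("each group needs at least one sample", call. = FALSE)
  }
  mean_a <- mean(a$lariats_per_million)
  mean_b <- mean(b$lariats_per_million)
  fold_defined <- mean_b > 0
  fold <- if (fold_defined) mean_a / mean_b else NA_real_
  tt <- if (nrow(a) >= 2L && nrow(b) >= 2L) {
    t.test(a$lariats_per_million, b$lariats_per_million, var.equal = FALSE)
  } else NULL
  data.table(
    group_a = group_a, group_b = group_b, n_a = nrow(a), n_b = nrow(b),
    mean_lpm_a = mean_a, mean_lpm_b = mean_b,
    mean_count_a = mean(a$n_lariat_reads), mean_count_b = mean(b$n_lariat_reads),
    fold_enrichment = fold, fold_defined = fold_defined,
    t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value)
}
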