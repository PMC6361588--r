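#' Tally differentially expressed genes
#'
#' Counts genes below the adjusted-p threshold, splits them by the sign
#' of the log2 fold change, and reports up/down percentages rounded to
#' the nearest integer (the reporting convention of DE summaries:
#' e.g. counts of 118 up and 257 down read as 31% / 69%).
#'
#' @param table DE tibble with columns `log2fc` and `padj` (see
#'   [read_de_table()]); must be non-empty.
#' @param alpha adjusted-p threshold, default 0.01.
#' @return one-row tibble: `n_total` (DE genes), `n_up`, `n_down`,
#'   `pct_up`, `pct_down`. With zero DE genes the percentages are `NA`
#'   (flagged by a warning), not an error.
#' @examples
#' tab <- synthetic_de_table(n_up = 118, n_down = 257, n_null = 1000)
#' report_de_fractions(tab)
#' @export
report_de_fractions <- function(table, alpha = 0.01) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_arg("`table` must be a non-empty data frame")
  }
  if (!all(c("log2fc", "padj") %in% names(table))) {
    stop_input("DE table needs `log2fc` and `padj` columns")
  }
  de <- table[!is.na(table$padj) & table$padj < alpha, , drop = FALSE]
  n_up <- sum(de$log2fc > 0)
  n_down <- sum(de$log2fc < 0)
  if (n_up + n_down == 0L) {
    warn(paste0("no DE genes at alpha = ", alpha,
                "; percentages undefined"))
    pct_up <- pct_down <- NA_real_
  } else {
    pct_up <- round(100 * n_up / (n_up + n_down))
    pct_down <- round(100 * n_down / (n_up + n_down))
  }
  tibble(n_total = nrow(de), n_up = n_up, n_down = n_down,
         pct_up = pct_up, pct_down = pct_down)
}

#' Synthetic differential-expression table
#'
#' Builds a DE table with prescribed counts of upregulated genes
#' (`padj` below `alpha`, positive `log2fc`), downregulated genes, and
#' null genes (`padj` uniform above `alpha`). Used by the demo pipeline
#' and as a worked-example input to [report_de_fractions()].
#'
#' @param n_up,n_down,n_null gene counts per stratum.
#' @param alpha the significance threshold the strata respect
#'   (default 0.01).
#' @param seed RNG seed.
#' @return tibble `gene_id`, `log2fc`, `padj`.
#' @export
synthetic_de_table <- function(n_up, n_down, n_null = 10000L,
                               alpha = 0.01, seed = 1L) {
  n <- n_up + n_down + n_null
  with_seed(as.integer(seed) + 5L, {
    tibble(
      gene_id = sprintf("gene_%05d", seq_len(n)),
      log2fc = c(runif(n_up, 0.3, 3), -runif(n_down, 0.3, 3),
                 stats::rnorm(n_null, 0, 0.2)),
      padj = c(runif(n_up + n_down, 0, alpha * 0.999),
               runif(n_null, alpha, 1))
    )[sample.int(n), ]
  })
}
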