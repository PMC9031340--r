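#' Reference five-fold accuracy tables
#'
#' Published per-fold accuracies of the alpha sweep on two recurrence
#' cohorts (head-neck and lung), shipped as plain CSV under `extdata`. Each
#' row holds the five fold accuracies at one entropic index together with the
#' tabulated average, sample SD and paired p-value against the Shannon
#' baseline (`alpha = 1`, p-value `NA`). Two obvious decimal-point typos in
#' the printed source were repaired during transcription; a handful of rows
#' whose printed summaries do not reproduce from their own fold values are
#' flagged by [reference_row_consistent()].
#'
#' @param cohort `"headneck"` or `"lung"`.
#' @return Data frame with columns `alpha`, `fold1..fold5`, `average`, `sd`,
#'   `p_value`.
#' @export
reference_sweep_table <- function(cohort = c("headneck", "lung")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", paste0(cohort, "_alpha_sweep.csv"),
                      package = "thcnet", mustWork = TRUE)
  utils::read.csv(path)
}

#' Which reference rows reproduce from their own fold values?
#'
#' A row is consistent when the tabulated average and SD equal the recomputed
#' mean and sample SD after two-decimal rounding, and (off the Shannon row)
#' the tabulated p-value matches the recomputed one-sided paired t-test
#' p-value at the printed precision. Inconsistent rows are typographical
#' defects of the source table.
#'
#' @param table A data frame from [reference_sweep_table()].
#' @return Logical vector, one entry per row.
#' @export
reference_row_consistent <- function(table) {
  folds <- as.matrix(table[, paste0("fold", 1:5)])
  shannon <- folds[table$alpha == 1, ]
  vapply(seq_len(nrow(table)), function(i) {
    f <- folds[i, ]
    if (round(mean(f), 2) != table$average[i]) return(FALSE)
    if (round(stats::sd(f), 2) != table$sd[i]) return(FALSE)
    if (table$alpha[i] == 1) return(TRUE)
    p <- compare_to_shannon(f, shannon)
    printed <- table$p_value[i]
    dec <- nchar(sub("^[0-9]+\\.", "", format(printed, scientific = FALSE)))
    abs(p - printed) <= 10^(-dec) / 2 + 1e-12
  }, logical(1))
}
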