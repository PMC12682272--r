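# Machine-readable summary reports.

#' Write a TSV + JSON summary of fusion fates and mixing
#'
#' Aggregates the pipeline's headline numbers: how many reference
#' chromosomes participate in fusions, the per-pair normalized turbulence
#' with its mixed/sharp classification, and the fused-pair quartiles. The
#' JSON and TSV carry the same fields.
#'
#' @param fates data.frame from [chromosomeFates()], or the list returned
#'   by [countFused()].
#' @param mixing data.frame from [mixingSweep()] (columns `ref1`, `ref2`,
#'   `query`, `n`, `t_norm`); may be empty.
#' @param outPrefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the summary list, invisibly.
#' @export
summaryReport <- function(fates, mixing, outPrefix) {
  assert_string(outPrefix, "outPrefix")
  if (is.data.frame(fates)) {
    fused <- fates$fate == "fused"
    n_fused <- sum(fused)
    total <- nrow(fates)
  } else if (is.list(fates) && all(c("nFused", "total") %in% names(fates))) {
    n_fused <- fates$nFused
    total <- fates$total
  } else {
    stop("'fates' must come from chromosomeFates() or countFused()")
  }
  quart <- if (nrow(mixing) >= 4L) fusedPairQuartiles(mixing$t_norm) else
    c(Q1 = NA_real_, Q3 = NA_real_)
  mixing$class <- if (nrow(mixing)) {
    if (anyNA(quart)) rep(NA_character_, nrow(mixing))
    else vapply(mixing$t_norm, classifyFusedPair, "", quartiles = quart)
  } else character(0)
  summary <- list(n_fused = n_fused, n_unfused = total - n_fused,
                  total = total,
                  turbulence_q1 = unname(quart[1]),
                  turbulence_q3 = unname(quart[2]),
                  pairs = mixing)
  tsv <- paste0(outPrefix, ".tsv")
  con <- file(tsv, "w")
  writeLines(c(sprintf("#n_fused\t%d", summary$n_fused),
               sprintf("#n_unfused\t%d", summary$n_unfused),
               sprintf("#total\t%d", summary$total),
               sprintf("#turbulence_q1\t%s", format(summary$turbulence_q1)),
               sprintf("#turbulence_q3\t%s", format(summary$turbulence_q3))),
             con)
  if (nrow(mixing))
    utils::write.table(mixing, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  close(con)
  jsonlite::write_json(summary, paste0(outPrefix, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(summary)
}
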