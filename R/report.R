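## Experiment-level summaries: per-condition mean +/- SEM, pairwise
## one-tailed comparisons against a reference condition, tiers, and
## machine-readable report output.

## Pull a scalar out of heterogeneous replicate results.
resultValue <- function(r) {
  if (is(r, "RuptureEvent")) return(peakForce(r, "pN"))
  if (is(r, "DDGResult")) return(deltaG(r))
  if (is(r, "FreeEnergyEstimate")) return(deltaG(r))
  if (is.numeric(r) && length(r) == 1) return(r)
  oxStop("unsupported replicate result type", "oxfold_type_error")
}

#' Summarize a seeded experiment against a reference condition
#'
#' `results` maps condition labels to replicate outcomes (numeric vectors,
#' or lists of [RuptureEvent-class] / [DDGResult-class] /
#' [FreeEnergyEstimate-class] objects).  Every non-reference condition is
#' compared to the reference with a one-tailed Student t-test and the
#' p-value classified into significance tiers.
#'
#' @param results named list of replicate outcomes per condition.
#' @param design list with elements `reference` (condition label),
#'   `alternative` (`"a_less"` to test condition < reference, the
#'   direction appropriate for oxidation-weakened rupture forces, or
#'   `"a_greater"`), and optional `unit`, `welch` and `provenance`
#'   (free-form seeds/config identifiers carried into the report).
#' @return list of class `"oxfoldExperimentSummary"` with elements
#'   `conditions` (mean/SEM per condition) and `comparisons` (pairwise
#'   tests, tiers).
#' @export
summarizeExperiment <- function(results, design) {
  if (is.null(design$reference) || !design$reference %in% names(results))
    oxStop("design$reference must name a condition in results",
           "oxfold_config_error")
  alternative <- if (is.null(design$alternative)) "a_less"
                 else design$alternative
  welch <- isTRUE(design$welch)
  values <- lapply(results, function(cond)
    vapply(if (is.list(cond)) cond else as.list(cond), resultValue,
           numeric(1)))
  bad <- names(values)[vapply(values, length, integer(1)) < 2]
  if (length(bad))
    oxStop(paste("conditions with < 2 replicates:",
                 paste(bad, collapse = ", ")), "oxfold_config_error")
  ms <- t(vapply(values, meanSem, numeric(2)))
  conditions <- data.frame(condition = names(values), n = vapply(
    values, length, integer(1)), mean = ms[, "mean"], sem = ms[, "sem"],
    row.names = NULL)
  ref <- design$reference
  others <- setdiff(names(values), ref)
  comparisons <- do.call(rbind, lapply(others, function(cond) {
    p <- oneTailedT(values[[cond]], values[[ref]], alternative,
                    welch = welch)
    data.frame(group_a = cond, group_b = ref,
               mean_a = mean(values[[cond]]), mean_b = mean(values[[ref]]),
               sem_a = sd(values[[cond]]) / sqrt(length(values[[cond]])),
               sem_b = sd(values[[ref]]) / sqrt(length(values[[ref]])),
               p_value = p, tier = classifyP(p))
  }))
  structure(list(conditions = conditions, comparisons = comparisons,
                 design = list(reference = ref, alternative = alternative,
                               unit = design$unit, welch = welch,
                               provenance = design$provenance)),
            class = "oxfoldExperimentSummary")
}

#' @export
print.oxfoldExperimentSummary <- function(x, ...) {
  cat("Experiment summary (reference:", x$design$reference, ")\n")
  print(x$conditions, row.names = FALSE)
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("Comparisons (one-tailed", x$design$alternative, "):\n")
    print(x$comparisons[, c("group_a", "group_b", "p_value", "tier")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write an experiment summary as JSON, TSV and text
#'
#' Emits `report.json`, `report.tsv` (the comparisons table) and
#' `report.txt` into `dir`.
#'
#' @param summary result of [summarizeExperiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(summary, dir) {
  stopifnot(inherits(summary, "oxfoldExperimentSummary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(conditions = summary$conditions, comparisons = summary$comparisons,
         design = summary$design[!vapply(summary$design, is.null,
                                         logical(1))]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write.table(summary$comparisons, file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(summary))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
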