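## Replicate-level statistics: mean +/- SEM, one-tailed Student t-tests
## and the significance tiers used for force-peak comparisons.

#' Mean and standard error of the mean
#'
#' SEM = sample standard deviation (n - 1 denominator) / sqrt(n); the
#' error bar convention for replicate simulation averages (n = 3 in the
#' reference protocol).
#'
#' @param values numeric vector, length >= 2.
#' @return named numeric c(mean =, sem =).
#' @export
meanSem <- function(values) {
  if (length(values) < 2)
    oxStop("need at least 2 replicates for a SEM", "oxfold_domain_error")
  c(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}

#' One-tailed two-sample Student t-test
#'
#' Pooled-variance t statistic on n_a + n_b - 2 degrees of freedom
#' (`welch = TRUE` switches to the Welch statistic, provided because
#' which variance treatment the n = 3 comparisons used is a protocol
#' ambiguity).  `alternative = "a_less"` tests whether group a's mean is
#' below group b's.  Degenerate inputs with zero pooled variance return
#' p = 0.5 for equal means and 0 or 1 per direction otherwise.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param alternative `"a_less"` or `"a_greater"`.
#' @param welch use the Welch (unpooled) statistic.
#' @return one-sided p-value.
#' @export
oneTailedT <- function(a, b, alternative = c("a_less", "a_greater"),
                       welch = FALSE) {
  alternative <- match.arg(alternative)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    oxStop("both groups need at least 2 values", "oxfold_domain_error")
  diff <- mean(a) - mean(b)
  if (welch) {
    vab <- var(a) / na + var(b) / nb
    if (vab == 0) {
      return(if (diff == 0) 0.5 else if (xor(diff < 0,
        alternative == "a_less")) 1 else 0)
    }
    tstat <- diff / sqrt(vab)
    df <- vab^2 / ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    if (sp2 == 0) {
      return(if (diff == 0) 0.5 else if (xor(diff < 0,
        alternative == "a_less")) 1 else 0)
    }
    tstat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (alternative == "a_less") pt(tstat, df) else pt(tstat, df,
                                                     lower.tail = FALSE)
}

#' Classify a p-value into significance tiers
#'
#' Below 0.05: statistically significant; between 0.05 and 0.10:
#' marginally significant; otherwise not significant.  Boundaries are
#' half-open: p = 0.05 is marginal, p = 0.10 is not significant.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector: `"significant"`, `"marginal"` or
#'   `"not_significant"`.
#' @export
classifyP <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    oxStop("p-values must lie in [0, 1]", "oxfold_domain_error")
  ifelse(p < 0.05, "significant",
         ifelse(p < 0.10, "marginal", "not_significant"))
}
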