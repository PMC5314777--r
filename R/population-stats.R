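# Summary statistics for smFISH per-cell transcript counts and the
# growth-competition population-fraction formula.

#' Summary of a per-cell mRNA count sample
#'
#' Mean, sample standard deviation and CV (= SD / mean) of smFISH transcript
#' counts. CVs are conventionally reported at 2 decimal places; the full
#' precision is retained in the returned object. The CV is computed by the
#' same estimator as [cv()].
#'
#' @param counts Non-negative integer vector (n >= 2, positive mean).
#' @param gene Optional gene label.
#' @param digits Decimal places for the rounded CV.
#' @return List of class `cap_count_summary`: `gene`, `n`, `mean`, `sd`,
#'   `cv`, `cv_rounded`.
#' @export
count_summary <- function(counts, gene = NULL, digits = 2) {
  if (length(counts) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (mean(counts) <= 0) stop("mean count must be positive", call. = FALSE)
  structure(list(gene = gene, n = length(counts), mean = mean(counts),
                 sd = sd(counts), cv = cv(counts),
                 cv_rounded = round(cv(counts), digits)),
            class = "cap_count_summary")
}

#' @export
print.cap_count_summary <- function(x, ...) {
  cat(if (!is.null(x$gene)) paste0(x$gene, ": ") else "",
      round(x$mean, 1), " ± ", round(x$sd, 1),
      " mRNAs/cell (CV = ", format(x$cv_rounded, nsmall = 2),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Growth-competition population fraction
#'
#' Percentage of the tested strain in a mixed culture after a competition
#' assay, from colony counts on selective plates before (t0) and after (t98)
#' the competition:
#' 100 * r_t / (r_t + r_c), with r_t = tested(t98)/tested(t0) and
#' r_c = competitor(t98)/competitor(t0). The result is invariant to plating
#' dilution (scaling both t0 counts, or both t98 counts, by a constant).
#'
#' @param tested_t0,tested_t98 Colony counts of the tested strain.
#' @param competitor_t0,competitor_t98 Colony counts of the competitor.
#' @return Percentage (0-100).
#' @export
competition_fraction <- function(tested_t0, tested_t98,
                                 competitor_t0, competitor_t98) {
  counts <- c(tested_t0, tested_t98, competitor_t0, competitor_t98)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all colony counts must be positive", call. = FALSE)
  r_t <- tested_t98 / tested_t0
  r_c <- competitor_t98 / competitor_t0
  100 * r_t / (r_t + r_c)
}
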