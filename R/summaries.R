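#' @include validator.R
NULL

## Descriptive statistics over validated reports: the distribution
## summaries (calculated mass, ion score, peptide length) and the
## tier-by-strain cross-tabulation.

#' Summarize a set of evidence reports
#'
#' Builds one distribution summary per variable --- calculated
#' monoisotopic mass (`mr_calc`, 250 Da bins), ion score (width-5 bins)
#' and peptide length (width-5 bins starting at 0, so the 15-19 bin is
#' directly reportable) --- plus a tier-by-strain contingency table.
#' Quartiles use the default `stats::quantile` type; histogram bin counts
#' always sum to n.
#'
#' @param reports non-empty list of [EvidenceReport-class].
#' @return list with elements `distributions` (named list of per-variable
#'   summaries, each a list with `variable`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `histogram` data.frame (`bin`, `lower`, `upper`,
#'   `count`), `modeBin`) and `tierByStrain` (a table).
#' @export
summarizeReports <- function(reports) {
  if (!length(reports)) stop("no reports to summarize")
  tab <- reportTable(reports)
  vars <- list(mr_calc = list(x = tab$mr_calc, width = 250),
               ion_score = list(x = tab$ion_score, width = 5),
               peptide_length = list(x = tab$peptide_length, width = 5))
  distributions <- lapply(names(vars), function(v) {
    x <- vars[[v]]$x
    w <- vars[[v]]$width
    lower <- floor(x / w) * w
    breaks <- seq(0, max(lower) + w, by = w)
    counts <- vapply(breaks[-length(breaks)], function(b)
      sum(lower == b), integer(1))
    hist <- data.frame(
      bin = sprintf("%g-%g", breaks[-length(breaks)],
                    breaks[-1] - ifelse(v == "peptide_length", 1, 0)),
      lower = breaks[-length(breaks)], upper = breaks[-1], count = counts)
    rownames(hist) <- NULL
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(variable = v, n = length(x), min = min(x), q1 = q[1],
         median = q[2], q3 = q[3], max = max(x), histogram = hist,
         modeBin = hist$bin[which.max(hist$count)])
  })
  names(distributions) <- names(vars)
  strain <- tab$source_strain
  strain[is.na(strain)] <- "unknown"
  tierByStrain <- table(tier = factor(tab$tier,
                                      levels = c("rejected", "candidate",
                                                 "high", "very_high")),
                        strain = strain)
  list(distributions = distributions, tierByStrain = tierByStrain)
}

#' Export distribution summaries as CSV
#'
#' Writes one row per variable with the five-number summary and the modal
#' bin, next to a long-format histogram file (`<path>_hist.csv`).
#'
#' @param summary result of [summarizeReports()].
#' @param path output CSV for the five-number summaries.
#' @return the path, invisibly.
#' @export
writeSummaryTable <- function(summary, path) {
  rows <- do.call(rbind, lapply(summary$distributions, function(d)
    data.frame(variable = d$variable, n = d$n, min = d$min, q1 = d$q1,
               median = d$median, q3 = d$q3, max = d$max,
               mode_bin = d$modeBin, stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  hist <- do.call(rbind, lapply(summary$distributions, function(d) {
    h <- d$histogram; h$variable <- d$variable; h
  }))
  utils::write.csv(hist, sub("\\.csv$", "_hist.csv", path),
                   row.names = FALSE)
  invisible(path)
}
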