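## Model-selection statistics. For a summary phi (an order-parameter time
## series or a crocker matrix), the distance from the reference to each of
## 100 runs of a model is a Euclidean / Frobenius norm; the difference of
## ensemble means D = D_con - D_int with a Bonferroni-corrected confidence
## interval D +/- R95 decides which model is more faithful: the interval
## excluding zero from above prefers the interactive model, from below the
## control model.

#' Euclidean distance between two aligned series
#'
#' \eqn{\sqrt{\sum_s (a_s - b_s)^2}} over the frames where both series are
#' defined; frames with a missing value in either series are dropped
#' pairwise before summing.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
seriesDistance <- function(a, b) {
  if (length(a) != length(b))
    stop("series must have equal length after frame alignment")
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no overlapping defined frames")
  sqrt(sum((a[keep] - b[keep])^2))
}

#' Frobenius distance between two crockers
#'
#' \eqn{\sqrt{\sum_{\epsilon,t} (A - B)^2}} of the Betti matrices; the
#' matrix analogue of [seriesDistance()] on the vectorized crockers.
#'
#' @param a,b [Crocker-class] objects on identical grids.
#' @return Non-negative scalar.
#' @export
crockerDistance <- function(a, b) {
  if (!identical(dim(a@betti), dim(b@betti)) || !.sameGrid(a, b))
    stop("crockers must share identical grids")
  sqrt(sum((a@betti - b@betti)^2))
}

#' Mean distance from a reference to an ensemble of runs
#'
#' Applies a distance to the reference summary and every run summary and
#' averages; the per-run distances are kept for interval construction.
#'
#' @param reference A summary object (numeric series or [Crocker-class]).
#' @param runs Non-empty list of summaries of the same type.
#' @param metric Distance function, e.g. [seriesDistance()] or
#'   [crockerDistance()].
#' @return List with `mean` and `distances`.
#' @export
ensembleMeanDistance <- function(reference, runs, metric) {
  if (!length(runs)) stop("empty ensemble")
  d <- vapply(runs, function(r) metric(reference, r), numeric(1))
  list(mean = mean(d), distances = d)
}

#' Decide model preference from two distance ensembles
#'
#' Given per-run distances of the interactive and control ensembles to a
#' common reference, computes `D = mean(con) - mean(int)` and a
#' Bonferroni-corrected two-sample confidence radius `r95` for the
#' difference of means (Welch unpooled-variance interval at level
#' `alpha / nComparisons`). Verdict: `"interactive"` when `D - r95 > 0`,
#' `"control"` when `D + r95 < 0`, else `"inconclusive"`. The default
#' correction `nComparisons = 81` matches a nine-measure-by-nine-experiment
#' study design.
#'
#' @param intDistances,conDistances Per-run distances (>= 2 each).
#' @param measure Label recorded in the result.
#' @param nComparisons Bonferroni divisor.
#' @param alpha Family-wise significance level.
#' @return A [ComparisonResult-class].
#' @examples
#' compareModels(c(1, 1.1, 0.9), c(5, 5.2, 4.8), measure = "d_a")
#' @export
compareModels <- function(intDistances, conDistances, measure = "measure",
                          nComparisons = 81L, alpha = 0.05) {
  nI <- length(intDistances); nC <- length(conDistances)
  if (nI < 2L || nC < 2L)
    stop("need at least 2 runs per ensemble")
  if (any(intDistances < 0) || any(conDistances < 0))
    stop("distances must be non-negative")
  alphaC <- alpha / nComparisons
  dInt <- mean(intDistances); dCon <- mean(conDistances)
  D <- dCon - dInt
  vI <- stats::var(intDistances) / nI
  vC <- stats::var(conDistances) / nC
  se <- sqrt(vI + vC)
  if (se == 0) {
    r95 <- 0
  } else {
    df <- (vI + vC)^2 / (vI^2 / (nI - 1L) + vC^2 / (nC - 1L))
    r95 <- stats::qt(1 - alphaC / 2, df) * se
  }
  verdict <- if (D - r95 > 0) "interactive"
             else if (D + r95 < 0) "control"
             else "inconclusive"
  new("ComparisonResult", measure = measure, dInt = dInt, dCon = dCon,
      D = D, r95 = r95, alphaCorrected = alphaC, verdict = verdict,
      intDistances = as.numeric(intDistances),
      conDistances = as.numeric(conDistances))
}

#' @rdname accessors
#' @export
setMethod("verdict", "ComparisonResult", function(object) object@verdict)

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult [%s]: D = %.4g, R95 = %.4g -> %s\n",
              object@measure, object@D, object@r95, object@verdict))
  cat(sprintf("  D_int = %.4g (n = %d), D_con = %.4g (n = %d), alpha' = %.3g\n",
              object@dInt, length(object@intDistances),
              object@dCon, length(object@conDistances),
              object@alphaCorrected))
})

#' Tabulate comparison results
#'
#' One row per comparison with the difference of means, confidence radius
#' and verdict — the tabular report of a model-selection study.
#'
#' @param results List of [ComparisonResult-class] objects (may be empty).
#' @param experiment Optional vector of experiment labels recycled across
#'   rows.
#' @return Data frame with columns `experiment` (if given), `measure`,
#'   `D_int`, `D_con`, `D`, `R95`, `verdict`.
#' @export
resultsTable <- function(results, experiment = NULL) {
  tab <- data.frame(measure = character(), D_int = numeric(),
                    D_con = numeric(), D = numeric(), R95 = numeric(),
                    verdict = character())
  if (length(results)) {
    tab <- do.call(rbind, lapply(results, function(r)
      data.frame(measure = r@measure, D_int = r@dInt, D_con = r@dCon,
                 D = r@D, R95 = r@r95, verdict = r@verdict)))
  }
  if (!is.null(experiment) && nrow(tab))
    tab <- cbind(experiment = rep(experiment, length.out = nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}
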