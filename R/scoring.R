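## Weighted overall score: Total = wA * S_A + wN * S_N, with S_A the
## number of axioms satisfied (0..6) and S_N the number of benchmark
## families passed (0..6). Scores stay on the 0..6 scale.

.checkWeights <- function(wA, wN) {
  if (wA < 0 || wN < 0 || abs(wA + wN - 1) > 1e-12)
    stop("weights must be nonnegative and sum to 1")
}

#' Weighted total score
#'
#' @param sA axiomatic score (axioms satisfied, 0..6).
#' @param sN numerical score (families passed, 0..6).
#' @param wA,wN nonnegative weights summing to 1.
#' @return the weighted sum `wA * sA + wN * sN`.
#' @examples
#' scoreTotal(5, 6)          # 5.5
#' scoreTotal(5, 3, 1, 0)    # pure axiomatic weighting
#' @export
scoreTotal <- function(sA, sN, wA = 0.5, wN = 0.5) {
  .checkWeights(wA, wN)
  if (sA < 0 || sA > 6 || sN < 0 || sN > 6) stop("scores must lie in 0..6")
  wA * sA + wN * sN
}

#' Combine the two batteries into a ranked scoreboard
#'
#' One scorecard per measure: axiomatic score from the axiom battery,
#' numerical score from the numerical battery, and their weighted total.
#' Sorted by decreasing total; ties broken alphabetically by measure id.
#'
#' @param axiomBattery an [AxiomBattery-class] object.
#' @param numericalBattery a [NumericalBattery-class] object covering the
#'   same measure set.
#' @param wA,wN nonnegative weights summing to 1 (defaults 0.5/0.5, equal
#'   importance).
#' @return a [ScoreBoard-class] object.
#' @examples
#' \donttest{
#' ax <- runAxiomBattery(corpusMaxN = 4)
#' nm <- runNumericalBattery()
#' scoreTable(scoreCards(ax, nm))
#' }
#' @export
scoreCards <- function(axiomBattery, numericalBattery, wA = 0.5, wN = 0.5) {
  .checkWeights(wA, wN)
  sA <- satisfiedCounts(axiomBattery)
  sN <- passedCounts(numericalBattery)
  if (!setequal(names(sA), names(sN)))
    stop("the two batteries cover different measure sets")
  measures <- sort(names(sA))
  tb <- data.frame(
    measure = measures,
    axiomatic = as.integer(sA[measures]),
    numerical = as.integer(sN[measures]),
    wA = wA, wN = wN,
    total = wA * sA[measures] + wN * sN[measures],
    row.names = NULL
  )
  tb <- tb[order(-tb$total, tb$measure), , drop = FALSE]
  rownames(tb) <- NULL
  new("ScoreBoard", table = tb)
}
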