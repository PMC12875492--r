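## S4 result containers for the two batteries and the combined scoring.

AXIOM_IDS <- c("P1", "P2", "P3", "P4", "P5", "P6")
AXIOM_SUB_IDS <- c("P1a", "P1b", "P1c", "P2", "P3", "P4", "P5", "P6")
VERDICT_LEVELS <- c("satisfied-in-corpus", "violated", "asserted-violated")

#' AxiomBattery: compliance of the measures with the six postulates
#'
#' Result of [runAxiomBattery()]. The `verdicts` slot is a character matrix
#' (measures x P1..P6) with entries `"satisfied-in-corpus"`, `"violated"`
#' or `"asserted-violated"`; P1 aggregates the three calibration
#' sub-postulates (single node, complete graph, empty graph) as their
#' conjunction, with the sub-verdicts kept in `detail`. `witnesses` maps
#' `"<measure>:<axiom>"` to the violating graph (0-based edge list, order,
#' optional saturation node). The satisfied count per measure is the number
#' of axioms with no violation recorded.
#'
#' @slot verdicts character matrix, measures x P1..P6.
#' @slot detail character matrix, measures x P1a..P6.
#' @slot counts named integer vector of satisfied axioms (0..6).
#' @slot witnesses named list of violation witnesses.
#' @slot corpusSize number of corpus graphs swept.
#' @slot seed seed that fixed the isomorphism-check permutation stream.
#' @exportClass AxiomBattery
setClass("AxiomBattery", slots = c(
  verdicts = "matrix",
  detail = "matrix",
  counts = "integer",
  witnesses = "list",
  corpusSize = "integer",
  seed = "integer"
))

setValidity("AxiomBattery", function(object) {
  v <- object@verdicts
  if (!identical(colnames(v), AXIOM_IDS))
    return("verdict columns must be P1..P6")
  if (!all(v %in% VERDICT_LEVELS))
    return("verdicts must be satisfied-in-corpus/violated/asserted-violated")
  ok <- rowSums(v == "satisfied-in-corpus")
  if (!identical(unname(object@counts[rownames(v)]), as.integer(ok)))
    return("satisfied counts must equal the number of axioms without a violation")
  TRUE
})

#' NumericalBattery: trajectory behavior over the canonical families
#'
#' Result of [runNumericalBattery()]. `verdicts` is a logical pass/fail
#' matrix (measures x families); `trajectories` holds one value vector per
#' measure/family pair, aligned with `grid`.
#'
#' @slot verdicts logical matrix, measures x the six graph families.
#' @slot counts named integer vector of passed families (0..6).
#' @slot trajectories named list (`"<measure>:<family>"`) of value vectors.
#' @slot grid the increasing n-grid used.
#' @slot criteria named character vector family -> criterion kind.
#' @slot thetaHigh,thetaLow thresholds of the approach criteria.
#' @exportClass NumericalBattery
setClass("NumericalBattery", slots = c(
  verdicts = "matrix",
  counts = "integer",
  trajectories = "list",
  grid = "numeric",
  criteria = "character",
  thetaHigh = "numeric",
  thetaLow = "numeric"
))

setValidity("NumericalBattery", function(object) {
  if (!is.logical(object@verdicts)) return("verdicts must be logical")
  if (!identical(unname(object@counts[rownames(object@verdicts)]),
                 as.integer(rowSums(object@verdicts))))
    return("passed counts must equal the number of passing families")
  if (is.unsorted(object@grid, strictly = TRUE))
    return("n-grid must be strictly increasing")
  TRUE
})

#' ScoreBoard: weighted overall ranking of the measures
#'
#' Result of [scoreCards()]. One row per measure with its axiomatic score
#' (axioms satisfied, 0..6), numerical score (families passed, 0..6), the
#' weights, and the weighted total, sorted by decreasing total with
#' alphabetical tie-break.
#'
#' @slot table data.frame with columns measure, axiomatic, numerical, wA,
#'   wN, total.
#' @exportClass ScoreBoard
setClass("ScoreBoard", slots = c(table = "data.frame"))

setValidity("ScoreBoard", function(object) {
  tb <- object@table
  need <- c("measure", "axiomatic", "numerical", "wA", "wN", "total")
  if (!all(need %in% names(tb))) return("missing scorecard columns")
  if (any(abs(tb$wA + tb$wN - 1) > 1e-12)) return("weights must sum to 1")
  if (any(abs(tb$total - (tb$wA * tb$axiomatic + tb$wN * tb$numerical)) > 1e-12))
    return("total must be the weighted sum of the two scores")
  TRUE
})
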