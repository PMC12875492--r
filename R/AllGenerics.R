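## Accessor generics and show methods for the result containers.

#' Accessors for battery and scoring results
#'
#' `axiomVerdicts()` / `benchmarkVerdicts()` return the verdict matrices;
#' `satisfiedCounts()` / `passedCounts()` the per-measure 0..6 scores;
#' `witnesses()` the recorded violation witnesses; `trajectories()` the
#' measure-by-family value trajectories; `scoreTable()` the ranked
#' scorecard data.frame.
#'
#' @param object an [AxiomBattery-class], [NumericalBattery-class] or
#'   [ScoreBoard-class] object.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("axiomVerdicts", function(object) standardGeneric("axiomVerdicts"))

#' @rdname accessors
#' @export
setGeneric("satisfiedCounts", function(object) standardGeneric("satisfiedCounts"))

#' @rdname accessors
#' @export
setGeneric("witnesses", function(object) standardGeneric("witnesses"))

#' @rdname accessors
#' @export
setGeneric("benchmarkVerdicts", function(object) standardGeneric("benchmarkVerdicts"))

#' @rdname accessors
#' @export
setGeneric("passedCounts", function(object) standardGeneric("passedCounts"))

#' @rdname accessors
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(object) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setMethod("axiomVerdicts", "AxiomBattery", function(object) object@verdicts)

#' @rdname accessors
#' @export
setMethod("satisfiedCounts", "AxiomBattery", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("witnesses", "AxiomBattery", function(object) object@witnesses)

#' @rdname accessors
#' @export
setMethod("benchmarkVerdicts", "NumericalBattery", function(object) object@verdicts)

#' @rdname accessors
#' @export
setMethod("passedCounts", "NumericalBattery", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("trajectories", "NumericalBattery", function(object) object@trajectories)

#' @rdname accessors
#' @export
setMethod("scoreTable", "ScoreBoard", function(object) object@table)

.markGrid <- function(m) {
  marks <- ifelse(m == "satisfied-in-corpus", "ok",
           ifelse(m == "asserted-violated", "X*", "X"))
  dimnames(marks) <- dimnames(m)
  marks
}

setMethod("show", "AxiomBattery", function(object) {
  cat(sprintf("AxiomBattery: %d measures x 6 postulates (corpus: %d graphs, seed %d)\n",
              nrow(object@verdicts), object@corpusSize, object@seed))
  out <- cbind(.markGrid(object@verdicts),
               satisfied = object@counts[rownames(object@verdicts)])
  print(as.data.frame(out))
  cat("('X*' = violation asserted by a limiting argument, no finite witness)\n")
})

setMethod("show", "NumericalBattery", function(object) {
  cat(sprintf("NumericalBattery: %d measures x %d families (n-grid: %s)\n",
              nrow(object@verdicts), ncol(object@verdicts),
              paste(object@grid, collapse = ", ")))
  marks <- ifelse(object@verdicts, "pass", "fail")
  dimnames(marks) <- dimnames(object@verdicts)
  out <- cbind(marks, passed = object@counts[rownames(object@verdicts)])
  print(as.data.frame(out))
})

setMethod("show", "ScoreBoard", function(object) {
  cat("ScoreBoard: weighted overall performance (0..6 scale)\n")
  print(object@table, row.names = FALSE)
})
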