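## Numerical battery: measure trajectories over the six canonical graph
## families as the order grows, judged against per-family expectations.
##
## Expected behavior per family: the star realizes maximal centralization
## (exactly 1 at every order); rings and complete graphs are perfectly
## homogeneous (exactly 0); the perturbed star should regain centralization
## as the single rewired edge becomes negligible (approach 1); the
## perturbed ring and perturbed complete graph register a genuine but
## vanishing asymmetry (nonzero at small order, approach 0).

#' Graph family ids and generators
#'
#' The six canonical families of the numerical battery, with their
#' deterministic generators and minimum admissible orders.
#'
#' @return `graphFamilies()`: character vector of family ids;
#'   `familyGenerator()`: a function of `n`; `familyMinOrder()`: an
#'   integer.
#' @param family a family id.
#' @export
graphFamilies <- function() {
  c("star", "ring", "complete",
    "perturbed_star", "perturbed_ring", "perturbed_complete")
}

#' @rdname graphFamilies
#' @export
familyGenerator <- function(family) {
  switch(match.arg(family, graphFamilies()),
    star = makeStar, ring = makeRing, complete = makeComplete,
    perturbed_star = perturbStar, perturbed_ring = perturbRing,
    perturbed_complete = perturbComplete)
}

#' @rdname graphFamilies
#' @export
familyMinOrder <- function(family) {
  switch(match.arg(family, graphFamilies()),
    star = 1L, ring = 3L, complete = 1L,
    perturbed_star = 4L, perturbed_ring = 4L, perturbed_complete = 3L)
}

#' Default trajectory criteria
#'
#' Maps each family to the criterion kind its expected behavior demands:
#' `exact-one` (every value equals 1 within the measure's tolerance),
#' `exact-zero`, `approach-one` (final value at least `thetaHigh`) or
#' `approach-zero` (a genuine nonzero response at the smallest order,
#' final value at most `thetaLow`).
#'
#' @return named character vector, family id -> criterion kind.
#' @export
defaultCriteria <- function() {
  c(star = "exact-one", ring = "exact-zero", complete = "exact-zero",
    perturbed_star = "approach-one", perturbed_ring = "approach-zero",
    perturbed_complete = "approach-zero")
}

#' Measure trajectory over a graph family
#'
#' @param measure a measure id.
#' @param family a family id.
#' @param nGrid increasing vector of orders, all at least the family's
#'   minimum admissible order.
#' @return data.frame with columns `n` and `value`, plus attributes
#'   `measure` and `family`.
#' @examples
#' trajectory("NHD", "ring", c(21, 41))$value   # 2/(n-1)
#' @export
trajectory <- function(measure, family, nGrid) {
  measure <- match.arg(measure, centralizationMeasures())
  family <- match.arg(family, graphFamilies())
  if (any(nGrid < familyMinOrder(family)))
    stop("n-grid below the minimum admissible order for family ", family)
  gen <- familyGenerator(family)
  values <- vapply(nGrid, function(n)
    unname(.computeMeasures(gen(n), measure)[1]), numeric(1))
  structure(data.frame(n = nGrid, value = values),
            measure = measure, family = family)
}

#' Judge a trajectory against a criterion
#'
#' @param values trajectory values (aligned with an increasing n-grid).
#' @param criterion one of `"exact-one"`, `"exact-zero"`, `"approach-one"`,
#'   `"approach-zero"`.
#' @param tolerance equality tolerance for the exact criteria and the
#'   nonzero-response floor of `approach-zero`.
#' @param thetaHigh,thetaLow approach thresholds, judged at the largest
#'   order of the grid.
#' @return logical pass/fail.
#' @export
evaluateCriterion <- function(values, criterion, tolerance = 1e-9,
                              thetaHigh = 0.9, thetaLow = 0.05) {
  criterion <- match.arg(criterion, c("exact-one", "exact-zero",
                                      "approach-one", "approach-zero"))
  if (!length(values)) stop("empty trajectory")
  last <- values[length(values)]
  switch(criterion,
    "exact-one" = all(abs(values - 1) <= tolerance),
    "exact-zero" = all(abs(values) <= tolerance),
    "approach-one" = last >= thetaHigh,
    "approach-zero" = values[1] > tolerance && last <= thetaLow)
}

#' Run the numerical battery
#'
#' Evaluates every requested measure over the six families on the n-grid
#' (each family's generator is invoked once per order and all measures are
#' read off the same graph) and judges each trajectory with the family's
#' criterion.
#'
#' @param measures measure ids to assess.
#' @param nGrid increasing vector of orders.
#' @param thetaHigh,thetaLow approach thresholds (defaults 0.9 and 0.05,
#'   judged at the largest grid order).
#' @param criteria named character vector family -> criterion kind.
#' @return a [NumericalBattery-class] object.
#' @examples
#' \donttest{
#' nb <- runNumericalBattery(nGrid = c(5, 10, 20))
#' passedCounts(nb)
#' }
#' @export
runNumericalBattery <- function(measures = centralizationMeasures(),
                                nGrid = c(5, 10, 20, 50, 100, 200),
                                thetaHigh = 0.9, thetaLow = 0.05,
                                criteria = defaultCriteria()) {
  measures <- match.arg(measures, centralizationMeasures(), several.ok = TRUE)
  if (is.unsorted(nGrid, strictly = TRUE)) stop("n-grid must be increasing")
  families <- names(criteria)
  stopifnot(all(families %in% graphFamilies()))
  verdicts <- matrix(NA, length(measures), length(families),
                     dimnames = list(measures, families))
  traj <- list()
  for (f in families) {
    if (any(nGrid < familyMinOrder(f)))
      stop("n-grid below the minimum admissible order for family ", f)
    gen <- familyGenerator(f)
    tr <- vapply(nGrid, function(n)
      .computeMeasures(gen(n), measures), numeric(length(measures)))
    tr <- matrix(tr, nrow = length(measures),
                 dimnames = list(measures, NULL))
    for (m in measures) {
      traj[[paste(m, f, sep = ":")]] <- tr[m, ]
      verdicts[m, f] <- evaluateCriterion(tr[m, ], criteria[[f]],
                                          tolerance = measureTolerance(m),
                                          thetaHigh = thetaHigh,
                                          thetaLow = thetaLow)
    }
  }
  counts <- as.integer(rowSums(verdicts))
  names(counts) <- measures
  new("NumericalBattery", verdicts = verdicts, counts = counts,
      trajectories = traj, grid = as.numeric(nGrid), criteria = criteria,
      thetaHigh = thetaHigh, thetaLow = thetaLow)
}
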