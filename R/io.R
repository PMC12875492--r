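## File I/O, run configuration, and the largest-component triplet pipeline.
##
## Edge-list text format: one edge per line as two whitespace-separated
## tokens; lines starting with '#' are comments; a single-token line
## declares an isolated node. Node labels are arbitrary strings, mapped to
## 0-based integers in order of first appearance and kept as the vertex
## attribute "label".

#' Read a graph from a file
#'
#' Supports the whitespace edge-list format (primary), GML and GraphML
#' (via igraph). The result is simplified to an undirected simple graph:
#' duplicate edges and self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param format `"edgelist"`, `"gml"` or `"graphml"`.
#' @return an igraph graph with vertex attribute `label` carrying the
#'   original node labels.
#' @export
readGraph <- function(path, format = c("edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format != "edgelist") {
    g <- igraph::read_graph(path, format = format)
    g <- .asSimpleUndirected(g, path)
    if (is.null(igraph::vertex_attr(g, "label")))
      igraph::V(g)$label <- as.character(seq_len(igraph::vcount(g)) - 1L)
    return(g)
  }
  lines <- readLines(path, warn = FALSE)
  labels <- character(0)
  idOf <- function(tok) {
    hit <- match(tok, labels)
    if (is.na(hit)) {
      labels <<- c(labels, tok)
      hit <- length(labels)
    }
    hit - 1L
  }
  edges <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) next
    if (length(toks) == 1) { idOf(toks[1]); next }
    if (length(toks) != 2)
      stop("format error at line ", i, ": expected 1 or 2 tokens, got ",
           length(toks))
    edges[[length(edges) + 1L]] <- c(idOf(toks[1]), idOf(toks[2]))
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2)
  g <- igraph::make_empty_graph(length(labels), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el + 1L))
  g <- .asSimpleUndirected(g, path)
  igraph::V(g)$label <- labels
  g
}

.asSimpleUndirected <- function(g, path) {
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) < before)
    warning(sprintf("%s: dropped %d duplicate edge(s)/self-loop(s)",
                    path, before - igraph::ecount(g)))
  g
}

#' Write a graph as a whitespace edge list
#'
#' Isolated nodes are written as single-token lines so that a round trip
#' preserves the node set. Labels from the vertex attribute `label` are
#' used when present, 0-based indices otherwise.
#'
#' @param g an igraph graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  labs <- igraph::vertex_attr(g, "label")
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(g)) - 1L)
  el <- igraph::as_edgelist(g, names = FALSE)
  lines <- sprintf("%s %s", labs[el[, 1]], labs[el[, 2]])
  isolated <- setdiff(seq_len(igraph::vcount(g)), unique(as.vector(el)))
  writeLines(c(lines, labs[isolated]), path)
  invisible(path)
}

#' Centralization triplet report with largest-component handling
#'
#' Applies the three best-behaved measures - normalized betweenness,
#' closeness and degree centralization - to one or more graphs. For a
#' disconnected graph the path-based measures (and, for comparability, all
#' three) are computed on the largest connected component, and the report
#' flags this. Input order is preserved, so a list of temporal snapshots
#' yields a time series.
#'
#' @param graphs a list of igraph graphs, a single graph, or a character
#'   vector of edge-list file paths.
#' @param names optional row labels (file names are used for paths).
#' @return data.frame with columns `name`, `n`, `m`, `dmin`, `dmean`,
#'   `dmax`, `lccSize`, `lccUsed`, `NBC`, `NCC`, `NDC`.
#' @examples
#' tripletReport(list(makeStar(20), makeRing(20)))
#' @export
tripletReport <- function(graphs, names = NULL) {
  if (is.character(graphs)) {
    if (is.null(names)) names <- basename(graphs)
    graphs <- lapply(graphs, readGraph)
  }
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  if (is.null(names)) names <- paste0("graph", seq_along(graphs))
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    d <- igraph::degree(g)
    lcc <- largestComponent(g)
    used <- igraph::vcount(lcc) < igraph::vcount(g)
    v <- .computeMeasures(lcc, c("NBC", "NCC", "NDC"), nccAsNA = TRUE)
    data.frame(name = names[i], n = igraph::vcount(g), m = igraph::ecount(g),
               dmin = if (length(d)) min(d) else 0,
               dmean = if (length(d)) mean(d) else 0,
               dmax = if (length(d)) max(d) else 0,
               lccSize = igraph::vcount(lcc), lccUsed = used,
               NBC = v[["NBC"]], NCC = v[["NCC"]], NDC = v[["NDC"]])
  })
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------

#' Run configuration
#'
#' `defaultConfig()` returns the full set of tunables with their defaults;
#' `readConfig()`/`writeConfig()` round-trip a configuration through YAML
#' (or JSON, chosen by file extension), filling unspecified fields with
#' the defaults.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @param config a configuration list.
#' @return a named list with elements `measures`, `wA`, `wN`, `nGrid`,
#'   `thetaHigh`, `thetaLow`, `corpusMaxN`, `seed`.
#' @export
defaultConfig <- function() {
  list(
    measures = centralizationMeasures(),
    wA = 0.5, wN = 0.5,
    nGrid = c(5, 10, 20, 50, 100, 200),
    thetaHigh = 0.9, thetaLow = 0.05,
    corpusMaxN = 5L, seed = 1L
  )
}

#' @rdname defaultConfig
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- defaultConfig()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  cfg$corpusMaxN <- as.integer(cfg$corpusMaxN)
  cfg$seed <- as.integer(cfg$seed)
  .checkWeights(cfg$wA, cfg$wN)
  cfg
}

#' @rdname defaultConfig
#' @export
writeConfig <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

## ---------------------------------------------------------------------
## Report serialization
## ---------------------------------------------------------------------

#' Serialize a battery or scoreboard report
#'
#' Writes an [AxiomBattery-class], [NumericalBattery-class] or
#' [ScoreBoard-class] object as JSON (verdicts plus witnesses or
#' trajectories) or as a CSV matrix laid out with measures as rows.
#'
#' @param object the result object.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(object, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is(object, "AxiomBattery")) {
    if (format == "csv") {
      tb <- as.data.frame(axiomVerdicts(object))
      tb$satisfied <- satisfiedCounts(object)[rownames(tb)]
      utils::write.csv(cbind(measure = rownames(tb), tb), path,
                       row.names = FALSE)
    } else {
      jsonlite::write_json(list(
        verdicts = as.data.frame(axiomVerdicts(object)),
        satisfied = as.list(satisfiedCounts(object)),
        witnesses = witnesses(object),
        corpusSize = object@corpusSize, seed = object@seed
      ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    }
  } else if (is(object, "NumericalBattery")) {
    if (format == "csv") {
      tb <- as.data.frame(benchmarkVerdicts(object))
      tb$passed <- passedCounts(object)[rownames(tb)]
      utils::write.csv(cbind(measure = rownames(tb), tb), path,
                       row.names = FALSE)
    } else {
      jsonlite::write_json(list(
        verdicts = as.data.frame(benchmarkVerdicts(object)),
        passed = as.list(passedCounts(object)),
        grid = object@grid, criteria = as.list(object@criteria),
        thetaHigh = object@thetaHigh, thetaLow = object@thetaLow,
        trajectories = trajectories(object)
      ), path, auto_unbox = TRUE, digits = NA)
    }
  } else if (is(object, "ScoreBoard")) {
    if (format == "csv") utils::write.csv(scoreTable(object), path,
                                          row.names = FALSE)
    else jsonlite::write_json(scoreTable(object), path, auto_unbox = TRUE,
                              digits = NA)
  } else if (is.data.frame(object)) {
    if (format == "csv") utils::write.csv(object, path, row.names = FALSE)
    else jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report object")
  invisible(path)
}
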