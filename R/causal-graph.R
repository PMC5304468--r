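#' Construct a causal graph
#'
#' A causal graph is a directed graph over named variables in which an edge
#' `tail -> head` asserts that the tail has a direct causal effect on the
#' head. Graphs are the hypothesis objects of the package: candidate causal
#' structures scored against evidence and grouped into equivalence classes.
#'
#' Self-loops are never allowed. Unless `allow_cycles = TRUE` the edge set
#' must be acyclic (a topological order must exist). With `allow_cycles =
#' TRUE` each unordered variable pair may be in any of the four relation
#' states: no edge, forward, backward, or both orientations (feedback).
#'
#' @param variables character vector of unique variable names (order is
#'   retained and used for deterministic display and pair enumeration).
#' @param edges two-column object (matrix or data frame) of `tail`, `head`
#'   character pairs, or `NULL` for an edgeless graph.
#' @param allow_cycles logical; the graph space this graph is drawn from.
#'   Note that d-separation is only generally sound for acyclic graphs; for
#'   cyclic graphs this package reads independencies off the same trail
#'   criterion as a documented approximation (sigma-separation is out of
#'   scope).
#' @return an object of class `causal_graph` with fields `variables`,
#'   `amat` (0/1 adjacency matrix, `amat[i, j] == 1` iff edge i -> j) and
#'   `allow_cycles`.
#' @examples
#' chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' chain
#' @export
causal_graph <- function(variables, edges = NULL, allow_cycles = FALSE) {
  variables <- as.character(variables)
  if (length(variables) < 1L) stop_input("a causal graph needs at least one variable")
  if (anyDuplicated(variables)) stop_input("variable names must be unique")
  n <- length(variables)
  amat <- matrix(0L, n, n, dimnames = list(variables, variables))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop_input("edges must have two columns (tail, head)")
    storage.mode(edges) <- "character"
    unknown <- setdiff(unique(c(edges)), variables)
    if (length(unknown) > 0L) {
      stop_input(paste0("unknown variable(s) in edges: ", paste(unknown, collapse = ", ")))
    }
    if (any(edges[, 1L] == edges[, 2L])) stop_input("self-loops are not allowed")
    amat[edges] <- 1L
  }
  g <- structure(
    list(variables = variables, amat = amat, allow_cycles = isTRUE(allow_cycles)),
    class = "causal_graph"
  )
  if (!g$allow_cycles && !is_acyclic(g)) {
    stop_input("edge set contains a cycle but allow_cycles is FALSE")
  }
  g
}

graph_from_amat <- function(amat, variables, allow_cycles = FALSE) {
  dimnames(amat) <- list(variables, variables)
  structure(
    list(variables = variables, amat = amat, allow_cycles = isTRUE(allow_cycles)),
    class = "causal_graph"
  )
}

#' Edge list of a causal graph
#'
#' @param graph a `causal_graph`.
#' @return data frame with character columns `tail` and `head`, one row per
#'   directed edge, ordered row-major in the adjacency matrix.
#' @export
graph_edges <- function(graph) {
  idx <- which(t(graph$amat) == 1L)  # transpose => row-major order
  n <- length(graph$variables)
  tails <- graph$variables[((idx - 1L) %/% n) + 1L]
  heads <- graph$variables[((idx - 1L) %% n) + 1L]
  data.frame(tail = tails, head = heads, stringsAsFactors = FALSE)
}

#' Test whether a graph is acyclic
#'
#' Iteratively strips zero-in-degree vertices; the graph is acyclic iff all
#' vertices can be removed (a topological order exists).
#'
#' @param graph a `causal_graph`.
#' @return logical scalar.
#' @export
is_acyclic <- function(graph) {
  amat_is_acyclic(graph$amat)
}

amat_is_acyclic <- function(amat) {
  n <- nrow(amat)
  alive <- rep(TRUE, n)
  repeat {
    indeg <- colSums(amat[alive, alive, drop = FALSE])
    src <- which(indeg == 0L)
    if (length(src) == 0L) break
    alive[which(alive)[src]] <- FALSE
    if (!any(alive)) return(TRUE)
  }
  !any(alive)
}

#' Intervention surgery on a causal graph
#'
#' Models an ideal intervention (the do-operator): forcing the value of each
#' intervened variable removes the causal influence of its parents, so all
#' edges whose head lies in the intervention set are deleted. All other
#' edges are preserved. Surgery is idempotent.
#'
#' @param graph a `causal_graph`.
#' @param interventions character vector of intervened variables (may be
#'   empty, in which case the graph is returned unchanged).
#' @return the manipulated `causal_graph`.
#' @examples
#' g <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' graph_edges(manipulate(g, "Y"))  # only Y -> Z survives
#' @export
manipulate <- function(graph, interventions = character()) {
  interventions <- as.character(interventions)
  unknown <- setdiff(interventions, graph$variables)
  if (length(unknown) > 0L) {
    stop_input(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(interventions) == 0L) return(graph)
  amat <- graph$amat
  amat[, interventions] <- 0L
  graph_from_amat(amat, graph$variables, graph$allow_cycles)
}

#' @export
print.causal_graph <- function(x, ...) {
  ed <- graph_edges(x)
  cat(sprintf(
    "causal graph: %d variables, %d edges%s\n",
    length(x$variables), nrow(ed), if (x$allow_cycles) " (cyclic space)" else ""
  ))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  if (nrow(ed) > 0L) {
    cat("  edges:", paste(ed$tail, "->", ed$head, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.causal_graph <- function(x, ...) {
  ed <- graph_edges(x)
  if (nrow(ed) == 0L) "(no edges)" else paste(ed$tail, "->", ed$head, collapse = ", ")
}

## ---- graph I/O -----------------------------------------------------------

#' Read / write causal graphs as edge-list text
#'
#' The format is one `tail<TAB>head` line per edge. Isolated variables are
#' written as a line containing just the variable name, so the round trip is
#' exact. Variable order is taken from first appearance in the file.
#'
#' @param path file path.
#' @param allow_cycles passed to [causal_graph()].
#' @return `read_graph_edgelist` returns a `causal_graph`;
#'   `write_graph_edgelist` returns `path` invisibly.
#' @export
read_graph_edgelist <- function(path, allow_cycles = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) > 2L
  if (any(bad)) stop_input(sprintf("malformed edge-list line: %s", lines[bad][1L]))
  vars <- unique(unlist(parts))
  ed <- do.call(rbind, parts[lengths(parts) == 2L])
  causal_graph(vars, ed, allow_cycles = allow_cycles)
}

#' @rdname read_graph_edgelist
#' @param graph a `causal_graph`.
#' @export
write_graph_edgelist <- function(graph, path) {
  ed <- graph_edges(graph)
  isolated <- setdiff(graph$variables, unique(c(ed$tail, ed$head)))
  ## keep first-appearance order consistent with graph$variables on re-read:
  ## emit edges for each tail in variable order, then isolated names
  lines <- character(0)
  if (nrow(ed) > 0L) lines <- paste(ed$tail, ed$head, sep = "\t")
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Convert a causal graph to an igraph object
#'
#' Used for interoperability and for DOT / GraphML export; all causal
#' computations in this package (d-separation, enumeration, optimization)
#' operate on the native representation.
#'
#' @param graph a `causal_graph`.
#' @return an `igraph` directed graph with the same vertices and edges.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$amat, mode = "directed")
}

#' Export a causal graph to DOT or GraphML
#'
#' @param graph a `causal_graph`.
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(graph), path, format = format)
  invisible(path)
}

## structural identity, used for class membership checks
same_graph <- function(a, b) {
  identical(a$variables, b$variables) && identical(a$amat == 1L, b$amat == 1L)
}
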