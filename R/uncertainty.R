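## Uncertainty (underdetermination) metrics for an equivalence class:
## graph count, degrees of freedom, and per-pair edge entropy.

EDGE_RELATIONS <- c("none", "forward", "backward", "both")

#' Edge relation of a variable pair in a graph
#'
#' Every unordered pair of variables is in exactly one of four relation
#' states: `none` (no edge), `forward` (`a -> b` with `a`, `b` in the
#' order given), `backward` (`a <- b`), or `both` (feedback, `a <-> b`,
#' only in the cyclic space).
#'
#' @param graph a `causal_graph`.
#' @param pair character vector of two distinct variable names.
#' @return one of `"none"`, `"forward"`, `"backward"`, `"both"`.
#' @export
edge_relation <- function(graph, pair) {
  if (length(pair) != 2L || pair[1L] == pair[2L]) {
    stop_input("pair must be two distinct variable names")
  }
  unknown <- setdiff(pair, graph$variables)
  if (length(unknown) > 0L) {
    stop_input(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  fw <- graph$amat[pair[1L], pair[2L]] == 1L
  bw <- graph$amat[pair[2L], pair[1L]] == 1L
  if (fw && bw) "both" else if (fw) "forward" else if (bw) "backward" else "none"
}

## all unordered pairs of a class's variables, in variable order
class_pairs <- function(cls) {
  if (length(cls$variables) < 2L) return(list())
  pr <- utils::combn(cls$variables, 2L, simplify = FALSE)
  pr
}

#' Empirical edge-relation distribution of a pair over a class
#'
#' The fraction of class members exhibiting each of the four edge
#' relations for the given pair. These are empirical class fractions (how
#' underdetermined the pair still is), not posterior probabilities.
#'
#' @param cls an `equivalence_class` (non-empty).
#' @param pair character vector of two distinct variable names in the
#'   class.
#' @return an object of class `edge_distribution`: list with `pair` and
#'   `probs`, a named numeric vector over
#'   `c("none", "forward", "backward", "both")` summing to 1.
#' @examples
#' chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' cls <- equivalence_class(chain)
#' edge_distribution(cls, c("X", "Y"))$probs  # forward 1/3, backward 2/3
#' @export
edge_distribution <- function(cls, pair) {
  if (length(cls$members) == 0L) stop_input("class must be non-empty")
  unknown <- setdiff(pair, cls$variables)
  if (length(unknown) > 0L) {
    stop_input(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  rels <- vapply(cls$members, edge_relation, character(1L), pair = pair)
  probs <- vapply(EDGE_RELATIONS, function(r) mean(rels == r), numeric(1L))
  structure(list(pair = pair, probs = probs), class = "edge_distribution")
}

#' Shannon entropy of an edge-relation distribution
#'
#' Base-2 entropy `H = -sum p log2 p` over the four edge relations,
#' including only nonzero terms (`0 log 0` is taken as 0). Ranges from 0
#' bits (relation fully determined) to 2 bits (uniform over all four
#' relations).
#'
#' @param dist an `edge_distribution`, or a bare numeric vector of
#'   fractions summing to 1.
#' @return entropy in bits.
#' @examples
#' edge_entropy(c(1 / 3, 2 / 3))  # 0.918 bits
#' @export
edge_entropy <- function(dist) {
  p <- if (inherits(dist, "edge_distribution")) dist$probs else as.numeric(dist)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_input("edge-relation fractions must be non-negative and sum to 1")
  }
  p <- p[p > 0]
  max(0, -sum(p * log2(p)))
}

#' Degrees of freedom of an equivalence class
#'
#' Each variable pair has four possible edge relations, so once one is
#' instantiated three degrees of freedom remain; a graph on `n` variables
#' has `3 * choose(n, 2)` in total. For a class, each pair contributes the
#' number of distinct relations still exhibited across members minus one:
#' the count of undetermined instantiations.
#'
#' @param cls an `equivalence_class` (non-empty).
#' @return list with `dof` (integer) and `dof_fraction`
#'   (`dof / (3 * choose(n, 2))`).
#' @examples
#' chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' degrees_of_freedom(equivalence_class(chain))  # dof 2, fraction 2/9
#' @export
degrees_of_freedom <- function(cls) {
  if (length(cls$members) == 0L) stop_input("class must be non-empty")
  pairs <- class_pairs(cls)
  per_pair <- vapply(pairs, function(pr) {
    rels <- vapply(cls$members, edge_relation, character(1L), pair = pr)
    length(unique(rels)) - 1L
  }, integer(1L))
  n <- length(cls$variables)
  total <- 3 * choose(n, 2)
  dof <- sum(per_pair)
  list(dof = as.integer(dof), dof_fraction = if (total > 0) dof / total else 0)
}

#' Uncertainty report for an equivalence class
#'
#' Bundles the three underdetermination metrics: the member count, the
#' degrees of freedom (with the fraction of the `3 * choose(n, 2)`
#' maximum), and the per-pair edge entropies with their sum and mean. The
#' sum is the default ranking key for planning (richer scale); the mean is
#' reported alongside. All pairs, including fully determined ones, count
#' toward the mean's denominator.
#'
#' @param cls an `equivalence_class` (non-empty).
#' @return an object of class `uncertainty_report`: `graph_count`, `dof`,
#'   `dof_fraction`, `edge_entropies` (named by "a--b"),
#'   `class_entropy_sum`, `class_entropy_mean`.
#' @export
uncertainty_report <- function(cls) {
  if (length(cls$members) == 0L) stop_input("class must be non-empty")
  pairs <- class_pairs(cls)
  ent <- vapply(pairs, function(pr) edge_entropy(edge_distribution(cls, pr)),
                numeric(1L))
  names(ent) <- vapply(pairs, paste, character(1L), collapse = "--")
  dof <- degrees_of_freedom(cls)
  structure(
    list(
      graph_count = length(cls$members),
      dof = dof$dof,
      dof_fraction = dof$dof_fraction,
      edge_entropies = ent,
      class_entropy_sum = sum(ent),
      class_entropy_mean = if (length(ent)) mean(ent) else 0
    ),
    class = "uncertainty_report"
  )
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("uncertainty report: %d graph(s)\n", x$graph_count))
  cat(sprintf("  degrees of freedom: %d (%.1f%% of maximum)\n",
              x$dof, 100 * x$dof_fraction))
  for (nm in names(x$edge_entropies)) {
    cat(sprintf("  H(%s) = %.3f bits\n", nm, x$edge_entropies[[nm]]))
  }
  cat(sprintf("  class entropy: sum %.3f, mean %.3f bits\n",
              x$class_entropy_sum, x$class_entropy_mean))
  invisible(x)
}

#' Serialize an uncertainty report
#'
#' `report_to_json` writes the full report as JSON; `report_to_tsv`
#' writes a flat table with one row per variable pair plus a summary row.
#'
#' @param report an `uncertainty_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_to_tsv <- function(report, path) {
  df <- data.frame(
    pair = c(names(report$edge_entropies), "(class)"),
    entropy_bits = c(unname(report$edge_entropies), report$class_entropy_sum),
    graph_count = report$graph_count,
    dof = report$dof,
    dof_fraction = report$dof_fraction,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
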