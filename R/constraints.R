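## Translation of research-map evidence into weighted causal-structure
## constraints, and the weighted constraint optimizer (exhaustive weighted
## max-satisfiability at desk scale) with forward inference to the
## equivalence class.

#' Construct a causal-structure constraint
#'
#' A weighted (in)dependence statement `a _||_ b | C || J` (or its
#' negation). The weight expresses confidence in the statement; the
#' optimizer minimizes the total weight of unsatisfied constraints.
#'
#' @param query an [independence_query()].
#' @param independent `TRUE` if independence is asserted, `FALSE` if
#'   dependence.
#' @param weight non-negative finite number.
#' @return an object of class `causal_constraint`.
#' @export
causal_constraint <- function(query, independent, weight = 1) {
  stopifnot(inherits(query, "independence_query"))
  weight <- as.numeric(weight)
  if (is.na(weight) || !is.finite(weight) || weight < 0) {
    stop_input("weight must be a non-negative finite number")
  }
  structure(
    list(query = query, independent = isTRUE(independent), weight = weight),
    class = "causal_constraint"
  )
}

#' @export
print.causal_constraint <- function(x, ...) {
  key <- query_key(x$query)
  if (!x$independent) key <- sub("_||_", "~||~", key, fixed = TRUE)
  cat(sprintf("%s  (weight %g)%s\n", key, x$weight,
              if (x$independent) "" else "  [dependence asserted]"))
  invisible(x)
}

#' Translate a research-map edge into causal-structure constraints
#'
#' An empirical edge from agent `A` to target `T` backed by intervention
#' experiments translates to the constraint that `A` and `T` are
#' (in)dependent given the empty set when intervening on `A`
#' (`J = {A}`, `C = 0`); non-intervention experiments give the purely
#' observational constraint (`J = 0`). Excitatory and inhibitory edges
#' assert dependence (the constraint grammar carries no sign, so the
#' excitatory/inhibitory distinction is deliberately dropped here);
#' no-connection edges assert independence, under the same `J` as the
#' recorded experiments. One constraint is emitted per kind-class
#' (intervention / non-intervention) present among the edge's records;
#' repetition counts influence the constraint only through the edge score,
#' which is used as the weight.
#'
#' Hypothetical edges carry no evidence and are skipped (with a notice)
#' unless `include_hypothetical` is set, in which case they become
#' low-weight (`hypothetical_weight`) observational dependence constraints
#' so that stated hypotheses can softly inform the optimization.
#'
#' @param edge an [rm_edge()].
#' @param scorer scoring function for the weight, see [score_edge()].
#' @param include_hypothetical map hypothetical edges to epsilon-weight
#'   constraints instead of skipping them.
#' @param hypothetical_weight the epsilon weight (default 0.01).
#' @return list of `causal_constraint` (possibly empty).
#' @export
translate_edge <- function(edge, scorer = surrogate_score,
                           include_hypothetical = FALSE,
                           hypothetical_weight = 0.01) {
  if (edge$hypothetical) {
    if (!include_hypothetical) {
      message(sprintf("skipping hypothetical edge %s -> %s (no evidence)",
                      edge$agent, edge$target))
      return(list())
    }
    q <- independence_query(edge$agent, edge$target)
    return(list(causal_constraint(q, independent = edge$relation == "no_connection",
                                  weight = hypothetical_weight)))
  }
  recs <- concordant_records(edge)
  kinds <- vapply(recs, `[[`, character(1L), "kind")
  w <- scorer(recs)
  indep <- edge$relation == "no_connection"
  out <- list()
  if (any(kinds %in% c("pos_int", "neg_int"))) {
    q <- independence_query(edge$agent, edge$target, interventions = edge$agent)
    out[[length(out) + 1L]] <- causal_constraint(q, indep, w)
  }
  if (any(kinds %in% c("pos_nonint", "neg_nonint"))) {
    q <- independence_query(edge$agent, edge$target)
    out[[length(out) + 1L]] <- causal_constraint(q, indep, w)
  }
  out
}

#' Translate a research map into causal-structure constraints
#'
#' Concatenates [translate_edge()] over the map's edges in their stored
#' order (deterministic).
#'
#' @inheritParams translate_edge
#' @param map a `research_map`.
#' @return list of `causal_constraint`.
#' @export
translate_map <- function(map, scorer = surrogate_score,
                          include_hypothetical = FALSE,
                          hypothetical_weight = 0.01) {
  out <- list()
  for (e in map$edges) {
    out <- c(out, translate_edge(e, scorer = scorer,
                                 include_hypothetical = include_hypothetical,
                                 hypothetical_weight = hypothetical_weight))
  }
  out
}

#' Total weight of constraints a graph violates
#'
#' @param graph a `causal_graph`.
#' @param constraints list of `causal_constraint`; all constraint
#'   variables must be in the graph.
#' @return sum of the weights of constraints whose asserted (in)dependence
#'   disagrees with [holds()] on the graph. Additive over constraint-list
#'   concatenation.
#' @export
unsat_cost <- function(graph, constraints) {
  cost <- 0
  for (cn in constraints) {
    vars <- c(cn$query$a, cn$query$b, cn$query$conditioning, cn$query$interventions)
    missing <- setdiff(vars, graph$variables)
    if (length(missing) > 0L) {
      stop_input(paste0("constraint mentions variable(s) not in graph: ",
                        paste(missing, collapse = ", ")))
    }
    if (holds(graph, cn$query) != cn$independent) cost <- cost + cn$weight
  }
  cost
}

#' Find the graphs minimizing the weight of unsatisfied constraints
#'
#' Exhaustive weighted maximum-satisfiability over the enumerated graph
#' space: every graph is scored with [unsat_cost()] and all graphs
#' achieving the minimum are returned (no arbitrary tie-breaking; display
#' order is the deterministic enumeration order). At the desk scales this
#' package targets (n within the enumeration caps) exhaustive search is
#' exact; larger instances would need a clause-encoded solver backend,
#' which is out of scope.
#'
#' @param constraints list of `causal_constraint`.
#' @param variables character vector of variable names spanning the
#'   constraints (extra variables allowed).
#' @param allow_cycles search the cyclic space.
#' @param space optional explicit list of candidate graphs (overrides
#'   enumeration).
#' @return an object of class `optimization_result`: `best_graphs` (list),
#'   `best_cost`, and `per_constraint`, a satisfaction table for the first
#'   best graph.
#' @export
optimize_graphs <- function(constraints, variables, allow_cycles = FALSE,
                            space = NULL) {
  variables <- as.character(variables)
  cvars <- unique(unlist(lapply(constraints, function(cn)
    c(cn$query$a, cn$query$b, cn$query$conditioning, cn$query$interventions))))
  missing <- setdiff(cvars, variables)
  if (length(missing) > 0L) {
    stop_input(paste0("constraints mention variable(s) outside `variables`: ",
                      paste(missing, collapse = ", ")))
  }
  space <- space %||% tryCatch(
    enumerate_graphs(variables, allow_cycles = allow_cycles),
    causalplanr_resource_error = function(e) stop_resource(paste0(
      conditionMessage(e),
      "; exhaustive optimization needs the materialized space (consider a solver backend)"
    ))
  )
  costs <- vapply(space, unsat_cost, numeric(1L), constraints = constraints)
  best <- min(costs)
  idx <- which(abs(costs - best) < 1e-12)
  rep_graph <- space[[idx[1L]]]
  per_constraint <- data.frame(
    constraint = vapply(constraints, function(cn) query_key(cn$query), character(1L)),
    independent = vapply(constraints, `[[`, logical(1L), "independent"),
    weight = vapply(constraints, `[[`, numeric(1L), "weight"),
    satisfied = vapply(constraints, function(cn)
      holds(rep_graph, cn$query) == cn$independent, logical(1L)),
    stringsAsFactors = FALSE
  )
  structure(
    list(best_graphs = space[idx], best_cost = best, per_constraint = per_constraint,
         variables = variables, allow_cycles = allow_cycles),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("optimization: %d optimal graph(s), cost %g\n",
              length(x$best_graphs), x$best_cost))
  if (length(x$best_graphs) <= 5L) for (g in x$best_graphs) cat("  ", format(g), "\n")
  invisible(x)
}

#' Forward inference: from optimal graphs to their equivalence class
#'
#' Recovers every graph in the space that is indistinguishable from an
#' optimal graph under the given settings. When several optima have
#' different independence signatures, the union of their classes is
#' returned and the number of distinct signatures is recorded in the
#' `n_signatures` attribute.
#'
#' @param result an `optimization_result`.
#' @param settings list of `independence_query` (default: observational
#'   settings over the result's variables).
#' @param space candidate graphs (default: enumeration matching the
#'   optimization space).
#' @return an `equivalence_class` containing every optimal graph.
#' @export
forward_infer <- function(result, settings = NULL, space = NULL) {
  stopifnot(inherits(result, "optimization_result"))
  settings <- settings %||% observational_settings(result$variables)
  space <- space %||% enumerate_graphs(result$variables,
                                       allow_cycles = result$allow_cycles)
  sigs <- vapply(result$best_graphs, function(g)
    paste(signature(g, settings), collapse = ""), character(1L))
  usigs <- unique(sigs)
  members <- Filter(function(g)
    paste(signature(g, settings), collapse = "") %in% usigs, space)
  cls <- new_equivalence_class(members, settings, result$variables)
  attr(cls, "n_signatures") <- length(usigs)
  cls
}

## ---- constraint TSV I/O --------------------------------------------------

#' Read / write constraints as TSV
#'
#' Columns: `a`, `b`, `C` (comma-separated list or `-`), `J` (idem),
#' `independent` (0/1), `weight`. This is the raw-constraint entry point
#' that bypasses research-map translation.
#'
#' @param path file path.
#' @return `read_constraints` returns a list of `causal_constraint`;
#'   `write_constraints` returns `path` invisibly.
#' @export
read_constraints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("a", "b", "C", "J", "independent", "weight")
  if (!all(need %in% names(df))) {
    stop_input(paste0("constraint TSV needs columns: ", paste(need, collapse = ", ")))
  }
  parse_set <- function(x) {
    x <- trimws(x)
    if (x == "-" || x == "") character() else trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  lapply(seq_len(nrow(df)), function(i) {
    causal_constraint(
      independence_query(df$a[i], df$b[i],
                         conditioning = parse_set(df$C[i]),
                         interventions = parse_set(df$J[i])),
      independent = df$independent[i] %in% c("1", "TRUE", "true"),
      weight = as.numeric(df$weight[i])
    )
  })
}

#' @rdname read_constraints
#' @param constraints list of `causal_constraint`.
#' @export
write_constraints <- function(constraints, path) {
  fmt_set <- function(x) if (length(x) == 0L) "-" else paste(x, collapse = ",")
  df <- data.frame(
    a = vapply(constraints, function(cn) cn$query$a, character(1L)),
    b = vapply(constraints, function(cn) cn$query$b, character(1L)),
    C = vapply(constraints, function(cn) fmt_set(cn$query$conditioning), character(1L)),
    J = vapply(constraints, function(cn) fmt_set(cn$query$interventions), character(1L)),
    independent = as.integer(vapply(constraints, `[[`, logical(1L), "independent")),
    weight = vapply(constraints, `[[`, numeric(1L), "weight"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## variables spanned by a constraint list, in order of first appearance
constraint_variables <- function(constraints) {
  unique(unlist(lapply(constraints, function(cn)
    c(cn$query$a, cn$query$b, cn$query$conditioning, cn$query$interventions))))
}
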