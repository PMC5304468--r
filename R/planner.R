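## Experiment ranking. Two complementary strategies:
##  (a) on an equivalence class: pick the experiment whose outcome would
##      most reduce the class's uncertainty (pair uncertainty first, then
##      partition-based information gain);
##  (b) on a research map: pick the experiment that would add the most
##      evidence (pioneering, weakest-link, single-edge convergence /
##      consistency, multi-edge convergence).

#' Construct a candidate experiment
#'
#' A measurable query a planner can rank: test the relation between an
#' agent and a target with one of the four experiment kinds. Intervention
#' kinds measure the query `agent _||_ target | C || {agent}`;
#' non-intervention kinds the purely observational `agent _||_ target | C`.
#'
#' @param agent,target distinct variable names.
#' @param kind one of `"pos_int"`, `"neg_int"`, `"pos_nonint"`,
#'   `"neg_nonint"`.
#' @param conditioning optional conditioning set `C` (default empty).
#' @return an object of class `candidate_experiment` with the derived
#'   `query` field.
#' @export
candidate_experiment <- function(agent, target, kind = "pos_int",
                                 conditioning = character()) {
  kind <- match.arg(kind, EXPERIMENT_KINDS)
  interventions <- if (kind %in% c("pos_int", "neg_int")) agent else character()
  structure(
    list(agent = as.character(agent), target = as.character(target), kind = kind,
         query = independence_query(agent, target, conditioning = conditioning,
                                    interventions = interventions)),
    class = "candidate_experiment"
  )
}

#' Default candidate-experiment grammar
#'
#' For every ordered pair `(a, t)` one interventional candidate
#' (intervene on the agent, `J = {a}`, `C` empty) and, per unordered pair,
#' one observational candidate (`J` empty). Positive and negative variants
#' of a kind measure the same query, so for class-based ranking a single
#' representative of each kind-class is generated (`pos_int`,
#' `pos_nonint`); the positive/negative distinction matters only for
#' research-map evidence bookkeeping. With `conditioning_max = 1`
#' candidates conditioning on each single third variable are added.
#'
#' @param variables character vector of variable names.
#' @param conditioning_max 0 (default) or 1; largest conditioning set.
#' @return list of `candidate_experiment`.
#' @export
candidate_experiments <- function(variables, conditioning_max = 0L) {
  variables <- as.character(variables)
  out <- list()
  conds <- function(a, t) {
    cc <- list(character())
    if (conditioning_max >= 1L) {
      for (v in sort(setdiff(variables, c(a, t)))) cc[[length(cc) + 1L]] <- v
    }
    cc
  }
  for (a in variables) {
    for (t in setdiff(variables, a)) {
      for (cc in conds(a, t)) {
        out[[length(out) + 1L]] <- candidate_experiment(a, t, "pos_int", cc)
      }
    }
  }
  ## observational: symmetric in (a, t), emit once per unordered pair
  if (length(variables) >= 2L) {
    prs <- utils::combn(sort(variables), 2L)
    for (k in seq_len(ncol(prs))) {
      for (cc in conds(prs[1L, k], prs[2L, k])) {
        out[[length(out) + 1L]] <-
          candidate_experiment(prs[1L, k], prs[2L, k], "pos_nonint", cc)
      }
    }
  }
  out
}

#' @export
print.candidate_experiment <- function(x, ...) {
  cat(sprintf("experiment %s on (%s, %s): %s\n", x$kind, x$agent, x$target,
              query_key(x$query)))
  invisible(x)
}

#' Possible outcomes of an experiment on an equivalence class
#'
#' Partitions the class members by the answer each implies to the
#' experiment's query. At most two cells (dependent / independent); empty
#' cells are omitted. Each cell is the equivalence class that would result
#' if the experiment returned that outcome.
#'
#' @param exp a `candidate_experiment`.
#' @param cls an `equivalence_class`.
#' @return named list of `equivalence_class` cells, names in
#'   `c("dependent", "independent")`.
#' @export
possible_outcomes <- function(exp, cls) {
  ans <- vapply(cls$members, holds, logical(1L), query = exp$query)
  out <- list()
  if (any(!ans)) {
    out$dependent <- new_equivalence_class(cls$members[!ans],
                                           c(cls$settings, list(exp$query)),
                                           cls$variables)
  }
  if (any(ans)) {
    out$independent <- new_equivalence_class(cls$members[ans],
                                             c(cls$settings, list(exp$query)),
                                             cls$variables)
  }
  out
}

## class-level uncertainty under one metric
class_uncertainty <- function(cls, metric) {
  switch(metric,
    count = length(cls$members),
    dof = degrees_of_freedom(cls)$dof,
    entropy_sum = uncertainty_report(cls)$class_entropy_sum,
    stop_input(paste0("unknown metric: ", metric))
  )
}

#' Information gain of an experiment on an equivalence class
#'
#' How much class uncertainty the experiment would remove. In `expected`
#' mode the post-experiment uncertainty is averaged over the outcome cells
#' weighted by their empirical class fractions; in `worst_case` mode the
#' largest-uncertainty cell is assumed. Expected gain is always
#' non-negative for the entropy metric (concavity) and zero for
#' experiments whose outcome is already determined by the class.
#'
#' @param exp a `candidate_experiment`.
#' @param cls an `equivalence_class`.
#' @param metric `"count"`, `"dof"`, or `"entropy_sum"`.
#' @param mode `"expected"` or `"worst_case"`.
#' @return the gain (same units as the metric).
#' @export
information_gain <- function(exp, cls, metric = c("entropy_sum", "dof", "count"),
                             mode = c("expected", "worst_case")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  cells <- possible_outcomes(exp, cls)
  u0 <- class_uncertainty(cls, metric)
  u_cells <- vapply(cells, class_uncertainty, numeric(1L), metric = metric)
  sizes <- vapply(cells, function(cl) length(cl$members), numeric(1L))
  post <- switch(mode,
    expected = sum(sizes / length(cls$members) * u_cells),
    worst_case = max(u_cells)
  )
  u0 - post
}

## current uncertainty about the pair an experiment tests: the primary
## ranking key (the class's most underdetermined pairs come first)
pair_uncertainty <- function(cls, pair, metric) {
  if (metric == "count") return(NA_real_)
  rels <- vapply(cls$members, edge_relation, character(1L), pair = pair)
  switch(metric,
    dof = length(unique(rels)) - 1,
    entropy_sum = edge_entropy(vapply(EDGE_RELATIONS, function(r)
      mean(rels == r), numeric(1L)))
  )
}

#' Rank candidate experiments on an equivalence class
#'
#' Experiments are ranked primarily by the current uncertainty of the pair
#' they test (its edge entropy for `entropy_sum`, its undetermined
#' relation count for `dof`): the class's most underdetermined pairs are
#' prioritized. Within a pair, candidates are ordered by the
#' partition-based [information_gain()] (so interventional candidates beat
#' observational ones whose outcome the class already determines), and
#' remaining ties break lexicographically by (agent, target, kind). For
#' the `count` metric, which has no per-pair analogue, information gain is
#' the primary key.
#'
#' @param cls an `equivalence_class`.
#' @param candidates list of `candidate_experiment` (default: the full
#'   default grammar over the class's variables).
#' @param metric,mode see [information_gain()].
#' @return a `ranked_plan`: data frame with one row per candidate, columns
#'   `agent`, `target`, `kind`, `pair_uncertainty`, `info_gain`,
#'   `posterior_sizes`, sorted best-first; `metric` and `mode` attributes
#'   record the settings.
#' @export
rank_experiments <- function(cls, candidates = NULL,
                             metric = c("entropy_sum", "dof", "count"),
                             mode = c("expected", "worst_case")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  candidates <- candidates %||% candidate_experiments(cls$variables)
  if (length(candidates) == 0L) stop_input("need at least one candidate")
  rows <- lapply(candidates, function(exp) {
    cells <- possible_outcomes(exp, cls)
    data.frame(
      agent = exp$agent, target = exp$target, kind = exp$kind,
      pair_uncertainty = pair_uncertainty(cls, c(exp$agent, exp$target), metric),
      info_gain = information_gain(exp, cls, metric, mode),
      posterior_sizes = paste(vapply(cells, function(cl)
        length(cl$members), numeric(1L)), collapse = "|"),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  primary <- if (metric == "count") df$info_gain else df$pair_uncertainty
  ord <- order(-primary, -df$info_gain, df$agent, df$target, df$kind,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "metric") <- metric
  attr(df, "mode") <- mode
  attr(df, "candidates") <- candidates[ord]
  class(df) <- c("ranked_plan", "data.frame")
  df
}

## ---- research-map evidence rules ----------------------------------------

#' Pioneering candidates of a research map
#'
#' The pioneering rule: when a map's edges imply a spanning connection --
#' a directed path of length at least two through excitatory or inhibitory
#' edges (hypothetical ones included) -- and the spanned `(agent, target)`
#' pair has no direct empirical edge, testing that pair can significantly
#' inform the model. No-connection edges never extend a path.
#'
#' @param map a `research_map`.
#' @return data frame with columns `agent`, `target`, deduplicated and
#'   sorted lexicographically.
#' @export
pioneering_candidates <- function(map) {
  vars <- map$phenomena$name
  n <- length(vars)
  if (n == 0L) return(data.frame(agent = character(), target = character()))
  adj <- matrix(FALSE, n, n, dimnames = list(vars, vars))
  direct_emp <- matrix(FALSE, n, n, dimnames = list(vars, vars))
  for (e in map$edges) {
    if (e$relation %in% c("excitatory", "inhibitory")) {
      adj[e$agent, e$target] <- TRUE
    }
    if (!e$hypothetical) direct_emp[e$agent, e$target] <- TRUE
  }
  ## walks of length >= 2 (boolean closure)
  reach2 <- matrix(FALSE, n, n)
  pow <- adj
  for (len in 2:max(2L, n)) {
    pow <- (pow %*% adj) > 0
    reach2 <- reach2 | pow
    if (!any(pow)) break
  }
  hit <- which(reach2 & !direct_emp & !diag(TRUE, n), arr.ind = TRUE)
  out <- data.frame(agent = vars[hit[, 1L]], target = vars[hit[, 2L]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$agent, out$target, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weakest-link edge of a research map
#'
#' The weakest-link rule: among empirical edges, the one with the lowest
#' evidence score should receive the next experiment. Ties break
#' lexicographically by (agent, target).
#'
#' @param map a `research_map`.
#' @param scorer see [score_edge()].
#' @return the minimum-score `rm_edge`.
#' @export
weakest_link <- function(map, scorer = surrogate_score) {
  emp <- Filter(function(e) !e$hypothetical, map$edges)
  if (length(emp) == 0L) stop_input("map has no empirical edges")
  scores <- vapply(emp, function(e) e$score %||% score_edge(e, scorer), numeric(1L))
  agents <- vapply(emp, `[[`, character(1L), "agent")
  targets <- vapply(emp, `[[`, character(1L), "target")
  ord <- order(scores, agents, targets, method = "radix")
  emp[[ord[1L]]]
}

#' Suggest experiment kinds for an edge
#'
#' Single-edge planning by the integration principles: experiment kinds
#' absent from the edge's records come first (convergence -- a new type of
#' evidence is worth most), then the present kinds in ascending order of
#' their repetition counts (consistency -- the least-replicated type
#' next). Ties and the absent group are ordered lexicographically by kind
#' token, so the ordering is stable.
#'
#' @param edge an empirical [rm_edge()].
#' @return character vector: all four kinds, best-first.
#' @export
suggest_experiment_kinds <- function(edge) {
  if (edge$hypothetical) stop_input("hypothetical edges have no records to extend")
  reps <- stats::setNames(rep(0L, length(EXPERIMENT_KINDS)), EXPERIMENT_KINDS)
  for (r in edge$records) reps[r$kind] <- reps[r$kind] + r$repetitions
  kinds <- sort(EXPERIMENT_KINDS)
  kinds[order(reps[kinds] > 0, reps[kinds], kinds, method = "radix")]
}

#' Multi-edge convergence tie-break
#'
#' When several experiment kinds would be equally convergent for the
#' chosen edge, pick the kind least represented among the experiments
#' recorded across the whole map (methodological diversity lowers the
#' chance of systematic artifacts). Ties break lexicographically.
#'
#' @param map a `research_map`.
#' @param tied_kinds non-empty character vector of kind tokens.
#' @return a single kind token.
#' @export
multi_edge_convergence <- function(map, tied_kinds) {
  if (length(tied_kinds) == 0L) stop_input("tied_kinds must be non-empty")
  tied_kinds <- vapply(tied_kinds, match.arg, character(1L),
                       choices = EXPERIMENT_KINDS, USE.NAMES = FALSE)
  totals <- stats::setNames(rep(0L, length(EXPERIMENT_KINDS)), EXPERIMENT_KINDS)
  for (e in map$edges) for (r in e$records) {
    totals[r$kind] <- totals[r$kind] + r$repetitions
  }
  tied_kinds <- sort(unique(tied_kinds))
  tied_kinds[order(totals[tied_kinds], tied_kinds, method = "radix")][1L]
}
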