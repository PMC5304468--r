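## Synthetic ground truths and the closed-loop planning simulation:
## equivalence class -> rank experiments -> perform (exact oracle) ->
## refine class -> repeat until the truth is identified or the budget is
## spent.

#' Simulation configuration
#'
#' @param n_variables number of variables (2 up to the enumeration cap).
#'   Default 3, the scale of the worked examples this package targets.
#' @param edge_density probability that each eligible ordered pair carries
#'   an edge in the random ground truth. Default 0.5: all graphs in the
#'   acyclic space are plausible truths.
#' @param allow_cycles sample (and search) the cyclic space.
#' @param policy `"entropy_greedy"` (rank by entropy), `"dof_greedy"`
#'   (rank by degrees of freedom), or `"random"` (uniform candidate
#'   choice; the baseline).
#' @param budget maximum number of experiments (>= 1). Default
#'   `n_variables * (n_variables - 1)`: one per interventional candidate.
#' @param seed integer seed; every random choice in the simulation flows
#'   from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_variables = 3L, edge_density = 0.5,
                              allow_cycles = FALSE,
                              policy = c("entropy_greedy", "dof_greedy", "random"),
                              budget = NULL, seed = 1L) {
  n_variables <- as.integer(n_variables)
  cap <- if (allow_cycles) DEFAULT_CAP_CYCLIC else DEFAULT_CAP_ACYCLIC
  if (is.na(n_variables) || n_variables < 2L || n_variables > cap) {
    stop_input(sprintf("n_variables must be in [2, %d]", cap))
  }
  if (edge_density < 0 || edge_density > 1) stop_input("edge_density must be in [0, 1]")
  policy <- match.arg(policy)
  budget <- as.integer(budget %||% (n_variables * (n_variables - 1L)))
  if (is.na(budget) || budget < 1L) stop_input("budget must be >= 1")
  structure(
    list(n_variables = n_variables, edge_density = edge_density,
         allow_cycles = isTRUE(allow_cycles), policy = policy,
         budget = budget, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

sim_variables <- function(n) paste0("V", seq_len(n))

#' Sample a random ground-truth causal graph
#'
#' Acyclic mode first samples a uniform variable order and then includes
#' each order-respecting pair independently with probability
#' `edge_density`; cyclic mode includes each ordered pair independently.
#' Fully reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return a `causal_graph`.
#' @export
random_graph <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sample_truth(config)
}

## sampling body, callable without reseeding (run_loop seeds once)
sample_truth <- function(config) {
  vars <- sim_variables(config$n_variables)
  n <- length(vars)
  amat <- matrix(0L, n, n, dimnames = list(vars, vars))
  if (config$allow_cycles) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && stats::runif(1) < config$edge_density) amat[i, j] <- 1L
    }
  } else {
    ord <- sample(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (which(ord == i) < which(ord == j) && stats::runif(1) < config$edge_density) {
        amat[i, j] <- 1L
      }
    }
  }
  graph_from_amat(amat, vars, config$allow_cycles)
}

#' Exact experiment outcome under a ground truth
#'
#' The outcome of performing an experiment on a known truth, expressed as
#' the causal-structure constraint it would contribute: the queried
#' (in)dependence as the truth implies it (surgery + d-separation), with
#' weight 1. The oracle is exact -- no finite-sample noise -- matching the
#' constraint-level abstraction of the planning framework.
#'
#' @param truth a `causal_graph`.
#' @param exp a `candidate_experiment`.
#' @return a `causal_constraint`.
#' @export
oracle_outcome <- function(truth, exp) {
  causal_constraint(exp$query, independent = holds(truth, exp$query), weight = 1)
}

## ---- cached per-space tables --------------------------------------------

## For repeated simulations over the same space, precompute for every graph
## in the space: answers to the observational settings, answers to the
## candidate queries, and the edge relation of every pair. All subsequent
## loop steps are table lookups.
space_tables <- function(n, allow_cycles) {
  key <- paste0("n", n, if (allow_cycles) "c" else "a")
  hit <- .cpr_cache[[key]]
  if (!is.null(hit)) return(hit)
  vars <- sim_variables(n)
  space <- enumerate_graphs(vars, allow_cycles = allow_cycles)
  settings <- observational_settings(vars)
  candidates <- candidate_experiments(vars)
  obs <- t(vapply(space, function(g)
    vapply(settings, function(q) holds(g, q), logical(1L)),
    logical(length(settings))))
  cand <- t(vapply(space, function(g)
    vapply(candidates, function(e) holds(g, e$query), logical(1L)),
    logical(length(candidates))))
  pairs <- utils::combn(vars, 2L, simplify = FALSE)
  rel <- t(vapply(space, function(g)
    vapply(pairs, function(pr) edge_relation(g, pr), character(1L)),
    character(length(pairs))))
  enc <- vapply(space, function(g) paste(g$amat, collapse = ""), character(1L))
  out <- list(space = space, settings = settings, candidates = candidates,
              obs = obs, cand = cand, rel = rel, enc = enc, pairs = pairs)
  .cpr_cache[[key]] <- out
  out
}

## metric of a member subset, from the relation table
subset_uncertainty <- function(rel, idx, metric) {
  switch(metric,
    count = length(idx),
    dof = sum(apply(rel[idx, , drop = FALSE], 2L, function(x)
      length(unique(x)) - 1L)),
    entropy_sum = sum(apply(rel[idx, , drop = FALSE], 2L, function(x) {
      p <- table(x) / length(x)
      -sum(p * log2(p))
    }))
  )
}

#' Run one closed-loop planning simulation
#'
#' Samples (or accepts) a ground truth, starts from its full observational
#' equivalence class, and repeatedly: ranks the default candidate
#' experiments under the configured policy, performs the top one on the
#' exact oracle, and refines the class with the resulting constraint.
#' Stops when the class is a singleton (the truth is identified) or the
#' budget is spent. The truth is a member of the class at every step, and
#' class size, entropy and degrees of freedom never increase along the
#' trajectory.
#'
#' @param config a [simulation_config()].
#' @param truth optional `causal_graph` ground truth over the variables
#'   `V1..Vn` (default: sampled from the config).
#' @return an object of class `trajectory`: `steps` (data frame with one
#'   row per experiment: agent, target, kind, outcome, class size, entropy
#'   sum, dof after the step), `identified`, `truth`, `config`.
#' @export
run_loop <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tab <- space_tables(config$n_variables, config$allow_cycles)
  truth <- truth %||% sample_truth(config)
  t_idx <- match(paste(truth$amat, collapse = ""), tab$enc)
  if (is.na(t_idx)) stop_input("truth is not a graph of the configured space")

  ## initial class: members matching the truth's observational signature
  members <- which(apply(tab$obs, 1L, function(row)
    all(row == tab$obs[t_idx, ])))
  n_cand <- length(tab$candidates)
  cand_pair <- vapply(tab$candidates, function(e)
    paste(sort(c(e$agent, e$target)), collapse = "--"), character(1L))
  pair_names <- vapply(tab$pairs, function(pr) paste(pr, collapse = "--"),
                       character(1L))
  metric <- switch(config$policy, entropy_greedy = "entropy_sum",
                   dof_greedy = "dof", random = NULL)

  steps <- data.frame(
    step = integer(), agent = character(), target = character(),
    kind = character(), independent = logical(), class_size = integer(),
    entropy_sum = numeric(), dof = integer(), stringsAsFactors = FALSE
  )
  for (step in seq_len(config$budget)) {
    if (length(members) == 1L) break
    if (is.null(metric)) {
      pick <- sample.int(n_cand, 1L)
    } else {
      ## pair uncertainty of each candidate's pair over current members
      pu <- vapply(seq_len(n_cand), function(ci) {
        pj <- match(cand_pair[ci], pair_names)
        x <- tab$rel[members, pj]
        if (metric == "dof") length(unique(x)) - 1 else {
          p <- table(x) / length(x)
          -sum(p * log2(p))
        }
      }, numeric(1L))
      u0 <- subset_uncertainty(tab$rel, members, metric)
      gain <- vapply(seq_len(n_cand), function(ci) {
        ans <- tab$cand[members, ci]
        cells <- list(members[!ans], members[ans])
        cells <- cells[lengths(cells) > 0L]
        post <- sum(vapply(cells, function(idx)
          length(idx) / length(members) * subset_uncertainty(tab$rel, idx, metric),
          numeric(1L)))
        u0 - post
      }, numeric(1L))
      ag <- vapply(tab$candidates, `[[`, character(1L), "agent")
      tg <- vapply(tab$candidates, `[[`, character(1L), "target")
      kd <- vapply(tab$candidates, `[[`, character(1L), "kind")
      pick <- order(-pu, -gain, ag, tg, kd, method = "radix")[1L]
    }
    exp <- tab$candidates[[pick]]
    outcome <- tab$cand[t_idx, pick]
    members <- members[tab$cand[members, pick] == outcome]
    steps[nrow(steps) + 1L, ] <- list(
      step, exp$agent, exp$target, exp$kind, outcome, length(members),
      subset_uncertainty(tab$rel, members, "entropy_sum"),
      as.integer(subset_uncertainty(tab$rel, members, "dof"))
    )
  }
  structure(
    list(steps = steps, identified = length(members) == 1L,
         final_class_size = length(members), truth = truth, config = config),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d step(s), truth %s (%d variables, policy %s, seed %d)\n",
    nrow(x$steps), if (x$identified) "identified" else "not identified",
    x$config$n_variables, x$config$policy, x$config$seed
  ))
  if (nrow(x$steps) > 0L) print(x$steps, row.names = FALSE)
  invisible(x)
}
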