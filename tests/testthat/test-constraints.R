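test_that("edge translation follows the kind-class and relation rules", {
  e <- rm_edge("A", "T", "excitatory", list(rec("pos_int")))
  cons <- translate_edge(e)
  expect_length(cons, 1L)
  expect_identical(cons[[1L]]$query$interventions, "A")
  expect_identical(cons[[1L]]$query$conditioning, character(0))
  expect_false(cons[[1L]]$independent)
  expect_equal(cons[[1L]]$weight, 0.125)
  ## no-connection with a non-intervention record: observational independence
  nc <- rm_edge("N-ras", "hippocampal learning", "no_connection",
                list(rec("pos_nonint", "no_connection")))
  cn <- translate_edge(nc)
  expect_length(cn, 1L)
  expect_identical(cn[[1L]]$query$interventions, character(0))
  expect_true(cn[[1L]]$independent)
  ## both kind-classes present: two constraints, same pair, J = {agent} and J = {}
  both <- rm_edge("A", "T", "excitatory",
                  list(rec("pos_int"), rec("pos_nonint")))
  cb <- translate_edge(both)
  expect_length(cb, 2L)
  expect_setequal(vapply(cb, function(x) length(x$query$interventions), integer(1L)),
                  c(0L, 1L))
  ## hypothetical edges: skipped by default, epsilon-weighted on request
  hyp <- rm_edge("A", "T", "excitatory", hypothetical = TRUE)
  expect_message(none <- translate_edge(hyp), "hypothetical")
  expect_length(none, 0L)
  eps <- translate_edge(hyp, include_hypothetical = TRUE)
  expect_length(eps, 1L)
  expect_equal(eps[[1L]]$weight, 0.01)
})

test_that("translate_map concatenates per-edge constraints deterministically", {
  map <- research_map(c("X", "Y", "Z"), list(
    rm_edge("X", "Y", "excitatory", list(rec("pos_int"))),
    rm_edge("Y", "Z", "excitatory", list(rec("pos_int"))),
    rm_edge("X", "Z", "no_connection", list(rec("pos_nonint", "no_connection")))
  ))
  cons <- translate_map(map)
  expect_length(cons, 3L)
  expect_identical(vapply(cons, function(cn) query_key(cn$query), character(1L)),
                   c("X_||_Y | - || X", "Y_||_Z | - || Y", "X_||_Z | - || -"))
  only_hyp <- research_map(c("A", "B"), list(
    rm_edge("A", "B", "excitatory", hypothetical = TRUE)
  ))
  expect_length(suppressMessages(translate_map(only_hyp)), 0L)
})

test_that("unsat_cost sums the weights of violated constraints and is additive", {
  gxy <- causal_graph(c("X", "Y"), rbind(c("X", "Y")))
  gyx <- causal_graph(c("X", "Y"), rbind(c("Y", "X")))
  dep <- causal_constraint(independence_query("X", "Y", interventions = "X"),
                           independent = FALSE, weight = 0.5)
  expect_equal(unsat_cost(gxy, list(dep)), 0)
  expect_equal(unsat_cost(gyx, list(dep)), 0.5)
  expect_equal(unsat_cost(gyx, list()), 0)
  other <- causal_constraint(independence_query("X", "Y"), TRUE, 0.3)
  expect_equal(unsat_cost(gyx, list(dep, other)),
               unsat_cost(gyx, list(dep)) + unsat_cost(gyx, list(other)))
  expect_error(
    unsat_cost(gxy, list(causal_constraint(independence_query("X", "Q"), TRUE))),
    class = "causalplanr_input_error"
  )
})

test_that("the optimizer recovers conflict-free chain constraints at zero cost", {
  ## observational dependence of the adjacent pairs + X _||_ Z | Y
  map <- research_map(c("X", "Y", "Z"), list(
    rm_edge("X", "Y", "excitatory", list(rec("pos_nonint"))),
    rm_edge("Y", "Z", "excitatory", list(rec("pos_nonint")))
  ))
  cons <- c(translate_map(map),
            list(causal_constraint(independence_query("X", "Z", conditioning = "Y"),
                                   TRUE, 0.5)))
  res <- optimize_graphs(cons, c("X", "Y", "Z"))
  expect_equal(res$best_cost, 0)
  fmts <- vapply(res$best_graphs, format, character(1L))
  expect_true("X -> Y, Y -> Z" %in% fmts)
  ## exactly the three-chain equivalence class attains cost zero
  expect_setequal(fmts, c("X -> Y, Y -> Z", "Y -> X, Y -> Z", "Y -> X, Z -> Y"))
  expect_true(all(res$per_constraint$satisfied))
})

test_that("directly conflicting constraints cost the smaller weight", {
  q <- independence_query("X", "Y")
  cons <- list(causal_constraint(q, TRUE, 0.3), causal_constraint(q, FALSE, 0.1))
  res <- optimize_graphs(cons, c("X", "Y"))
  expect_equal(res$best_cost, 0.1)
  ## empty constraint set: every graph is optimal at cost 0
  res0 <- optimize_graphs(list(), c("X", "Y"))
  expect_equal(res0$best_cost, 0)
  expect_identical(length(res0$best_graphs), 3L)
})

test_that("the optimizer matches an independent brute-force argmin on random instances", {
  kinds <- c("pos_int", "neg_int", "pos_nonint", "neg_nonint")
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(2:4, 1L, prob = c(0.45, 0.45, 0.10))
    vars <- LETTERS[seq_len(n)]
    n_cons <- sample(1:5, 1L)
    cons <- lapply(seq_len(n_cons), function(i) {
      ab <- sample(vars, 2L)
      rest <- setdiff(vars, ab)
      cc <- if (length(rest) > 0L && stats::runif(1) < 0.3) {
        sample(rest, sample(length(rest), 1L))
      } else character()
      jj <- if (stats::runif(1) < 0.5) ab[1L] else character()
      causal_constraint(
        independence_query(ab[1L], ab[2L], conditioning = cc, interventions = jj),
        independent = stats::runif(1) < 0.5,
        weight = round(stats::runif(1), 3)
      )
    })
    res <- optimize_graphs(cons, vars)
    ora <- oracle_optimize(cons, vars)
    expect_equal(res$best_cost, ora$best_cost, tolerance = 1e-10,
                 info = paste("seed", seed))
    expect_identical(length(res$best_graphs), as.integer(ora$n_best),
                     info = paste("seed", seed))
  }
})

test_that("forward inference recovers the full class of the optimum", {
  vars <- c("X", "Y", "Z")
  base <- list(
    causal_constraint(independence_query("X", "Y"), FALSE, 0.25),
    causal_constraint(independence_query("Y", "Z"), FALSE, 0.25),
    causal_constraint(independence_query("X", "Z", conditioning = "Y"), TRUE, 0.5)
  )
  ## one interventional constraint pins the optimum to the true chain
  pin <- causal_constraint(independence_query("X", "Y", interventions = "X"),
                           FALSE, 0.25)
  res <- optimize_graphs(c(base, list(pin)), vars)
  expect_identical(length(res$best_graphs), 1L)
  expect_identical(format(res$best_graphs[[1L]]), "X -> Y, Y -> Z")
  ## forward inference under observational settings recovers all three
  cls <- forward_infer(res)
  expect_identical(length(cls$members), 3L)
  fmts <- vapply(cls$members, format, character(1L))
  for (g in res$best_graphs) expect_true(format(g) %in% fmts)
  ## adding interventional settings collapses the class onto the chain
  cls2 <- forward_infer(res, c(observational_settings(vars),
                               interventional_settings(vars)))
  expect_identical(vapply(cls2$members, format, character(1L)),
                   "X -> Y, Y -> Z")
  ## with several optima of different signatures the union is returned
  res3 <- optimize_graphs(base, vars)
  expect_identical(length(res3$best_graphs), 3L)
  cls3 <- forward_infer(res3, c(observational_settings(vars),
                                interventional_settings(vars)))
  expect_identical(length(cls3$members), 3L)
  expect_identical(attr(cls3, "n_signatures"), 3L)
  ## empty settings: the whole space
  cls4 <- forward_infer(res, settings = list())
  expect_identical(length(cls4$members), 25L)
})

test_that("constraint TSV round trip preserves every field", {
  cons <- list(
    causal_constraint(independence_query("X", "Y", interventions = "X"), FALSE, 0.25),
    causal_constraint(independence_query("X", "Z", conditioning = "Y"), TRUE, 0.5),
    causal_constraint(independence_query("Y", "Z"), FALSE, 1)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(cons, path)
  back <- read_constraints(path)
  expect_length(back, 3L)
  for (i in seq_along(cons)) {
    expect_identical(query_key(back[[i]]$query), query_key(cons[[i]]$query))
    expect_identical(back[[i]]$independent, cons[[i]]$independent)
    expect_equal(back[[i]]$weight, cons[[i]]$weight)
  }
})
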