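test_that("possible outcomes partition the class by the queried answer", {
  cls <- chain_class()
  cells <- possible_outcomes(candidate_experiment("X", "Y", "pos_int"), cls)
  expect_setequal(names(cells), c("dependent", "independent"))
  expect_identical(format(cells$dependent$members[[1L]]), "X -> Y, Y -> Z")
  expect_identical(length(cells$independent$members), 2L)
  ## an observationally determined query yields a single cell
  obs <- possible_outcomes(candidate_experiment("X", "Z", "pos_nonint"), cls)
  expect_identical(names(obs), "dependent")
  expect_identical(length(obs$dependent$members), 3L)
  single <- equivalence_class(causal_graph(c("X", "Y", "Z")))
  one <- possible_outcomes(candidate_experiment("X", "Y", "pos_int"), single)
  expect_length(one, 1L)
})

test_that("information gain matches the hand-computed partition arithmetic", {
  cls <- chain_class()
  exp_xy <- candidate_experiment("X", "Y", "pos_int")
  ## 1.837 - [(1/3) * 0 + (2/3) * 1] = 2 log2(3) - 2 bits
  expect_equal(information_gain(exp_xy, cls, "entropy_sum", "expected"),
               2 * log2(3) - 2, tolerance = 1e-9)
  expect_equal(information_gain(exp_xy, cls, "entropy_sum", "expected"),
               1.170, tolerance = 1e-3)
  expect_equal(information_gain(exp_xy, cls, "entropy_sum", "worst_case"),
               uncertainty_report(cls)$class_entropy_sum - 1, tolerance = 1e-9)
  expect_equal(information_gain(exp_xy, cls, "dof", "expected"),
               2 - (2 / 3) * 1, tolerance = 1e-9)
  expect_equal(information_gain(exp_xy, cls, "count", "expected"),
               3 - ((1 / 3) * 1 + (2 / 3) * 2), tolerance = 1e-9)
  ## single-outcome experiments gain nothing in either mode
  obs_xz <- candidate_experiment("X", "Z", "pos_nonint")
  expect_equal(information_gain(obs_xz, cls, "entropy_sum", "expected"), 0)
  expect_equal(information_gain(obs_xz, cls, "entropy_sum", "worst_case"), 0)
})

test_that("expected information gain is non-negative over all 3-variable observational classes", {
  vars <- c("A", "B", "C")
  space <- enumerate_graphs(vars)
  settings <- observational_settings(vars)
  sigs <- vapply(space, function(g) paste(signature(g, settings), collapse = ""),
                 character(1L))
  candidates <- candidate_experiments(vars)
  for (i in match(unique(sigs), sigs)) {
    cls <- equivalence_class(space[[i]], settings, space)
    for (exp in candidates) {
      for (metric in c("count", "dof", "entropy_sum")) {
        g_exp <- information_gain(exp, cls, metric, "expected")
        expect_gte(g_exp, -1e-12)
        ## worst case never beats the expectation from above
        expect_lte(information_gain(exp, cls, metric, "worst_case"),
                   g_exp + 1e-12)
      }
    }
  }
})

test_that("ranking prioritizes the undetermined pairs, then informative experiments", {
  cls <- chain_class()
  for (metric in c("entropy_sum", "dof")) {
    plan <- rank_experiments(cls, metric = metric)
    expect_identical(nrow(plan), 9L)  # permutation of the default candidates
    tested_pair <- function(r) paste(sort(c(plan$agent[r], plan$target[r])),
                                     collapse = "")
    pairs <- vapply(seq_len(nrow(plan)), tested_pair, character(1L))
    ## every (X,Y)- and (Y,Z)-experiment strictly above every (X,Z)-experiment
    expect_identical(which(pairs == "XZ"), 7:9)
    ## within a pair, interventional candidates precede the observational one
    expect_identical(plan$kind[1L], "pos_int")
    expect_true(all(plan$info_gain[plan$kind == "pos_int" & pairs != "XZ"] >
                      plan$info_gain[plan$kind == "pos_nonint" & pairs != "XZ"][1L]))
  }
  ## gains in the plan match independently recomputed information gains
  plan <- rank_experiments(cls, metric = "entropy_sum")
  for (r in seq_len(nrow(plan))) {
    exp <- candidate_experiment(plan$agent[r], plan$target[r], plan$kind[r])
    expect_equal(plan$info_gain[r], information_gain(exp, cls, "entropy_sum"),
                 tolerance = 1e-12)
  }
  ## singleton class: all gains zero, lexicographic order
  single <- equivalence_class(causal_graph(c("X", "Y", "Z")))
  p0 <- rank_experiments(single)
  expect_true(all(p0$info_gain == 0))
  expect_identical(p0$agent, sort(p0$agent))
  ## 2-variable dependent class: interventions outrank observation
  cls2 <- equivalence_class(causal_graph(c("X", "Y"), rbind(c("X", "Y"))))
  p2 <- rank_experiments(cls2)
  expect_identical(p2$kind, c("pos_int", "pos_int", "pos_nonint"))
  expect_gt(p2$info_gain[1L], p2$info_gain[3L])
})

test_that("pioneering candidates span paths without direct empirical edges", {
  simple <- research_map(c("X", "Y", "Z"), list(
    rm_edge("X", "Y", "excitatory", list(rec("pos_int"))),
    rm_edge("Y", "Z", "excitatory", list(rec("pos_int")))
  ))
  expect_identical(pioneering_candidates(simple),
                   data.frame(agent = "X", target = "Z", stringsAsFactors = FALSE))
  ## a direct empirical X -> Z edge removes the candidate
  closed <- research_map(c("X", "Y", "Z"), list(
    rm_edge("X", "Y", "excitatory", list(rec("pos_int"))),
    rm_edge("Y", "Z", "excitatory", list(rec("pos_int"))),
    rm_edge("X", "Z", "excitatory", list(rec("pos_int")))
  ))
  expect_identical(nrow(pioneering_candidates(closed)), 0L)
  ## hypothetical edges extend paths; no-connection edges never do
  fig1 <- read_map(system.file("extdata", "costa2002_map_synthetic.json",
                               package = "causalplanr"))
  pio <- pioneering_candidates(fig1)
  expect_true(any(pio$agent == "NF1" & pio$target == "LTP"))
  expect_false(any(pio$agent == "N-ras"))
  ## (NF1, hippocampal learning) is spanned but already tested directly
  expect_false(any(pio$agent == "NF1" & pio$target == "hippocampal learning"))
})

test_that("the weakest link is the minimum-score empirical edge", {
  map <- two_edge_map(score_xy = 0.250, score_yz = 0.125)
  wl <- weakest_link(map)
  expect_identical(c(wl$agent, wl$target), c("Y", "Z"))
  ## oracle: full scan of empirical scores
  emp_scores <- vapply(Filter(function(e) !e$hypothetical, map$edges),
                       function(e) e$score %||% score_edge(e), numeric(1L))
  expect_equal(wl$score, min(emp_scores))
  one <- research_map(c("A", "B"), list(
    rm_edge("A", "B", "excitatory", list(rec("pos_int")))
  ))
  expect_identical(weakest_link(one)$agent, "A")
  ## exact tie: lexicographically first (agent, target)
  tie <- two_edge_map(score_xy = 0.2, score_yz = 0.2)
  expect_identical(weakest_link(tie)$agent, "X")
  hyp_only <- research_map(c("A", "B"), list(
    rm_edge("A", "B", "excitatory", hypothetical = TRUE)
  ))
  expect_error(weakest_link(hyp_only), class = "causalplanr_input_error")
})

test_that("kind suggestions follow convergence then consistency", {
  only_pos <- rm_edge("A", "B", "excitatory", list(rec("pos_int", reps = 3L)))
  sug <- suggest_experiment_kinds(only_pos)
  expect_identical(sug, c("neg_int", "neg_nonint", "pos_nonint", "pos_int"))
  all_equal <- rm_edge("A", "B", "excitatory",
                       list(rec("pos_int"), rec("neg_int"),
                            rec("pos_nonint"), rec("neg_nonint")))
  expect_identical(suggest_experiment_kinds(all_equal),
                   c("neg_int", "neg_nonint", "pos_int", "pos_nonint"))
  mixed <- rm_edge("A", "B", "excitatory",
                   list(rec("pos_int", reps = 3L), rec("neg_int", reps = 1L)))
  sug2 <- suggest_experiment_kinds(mixed)
  expect_lt(match("neg_int", sug2), match("pos_int", sug2))
  expect_identical(sug2[1:2], c("neg_nonint", "pos_nonint"))  # absent first
})

test_that("multi-edge convergence picks the least represented kind map-wide", {
  map <- research_map(c("A", "B", "C"), list(
    rm_edge("A", "B", "excitatory", list(rec("neg_int", reps = 5L))),
    rm_edge("B", "C", "excitatory", list(rec("neg_int", reps = 3L),
                                         rec("pos_int", reps = 1L)))
  ))
  expect_identical(multi_edge_convergence(map, c("pos_int", "neg_int")), "pos_int")
  expect_identical(multi_edge_convergence(map, c("pos_nonint", "neg_nonint")),
                   "neg_nonint")  # both zero: lexicographic
  expect_identical(multi_edge_convergence(map, "neg_int"), "neg_int")
  expect_error(multi_edge_convergence(map, character()),
               class = "causalplanr_input_error")
})
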