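## Research maps: the evidence representation. Nodes are biological
## phenomena; directed edges are causal assertions typed excitatory /
## inhibitory / no-connection, annotated with the experiment records that
## support them and an evidence score in [0, 1).

EXPERIMENT_KINDS <- c("pos_int", "neg_int", "pos_nonint", "neg_nonint")
KIND_SYMBOLS <- c(
  pos_int = "\u2191", neg_int = "\u2193",
  pos_nonint = "\u2205\u2191", neg_nonint = "\u2205\u2193"
)
RELATIONS <- c("excitatory", "inhibitory", "no_connection")

#' Construct an experiment record
#'
#' One entry of empirical support for a research-map edge. The four kinds
#' mirror the four experiment types: in a positive / negative intervention
#' the agent's quantity or probability is actively increased / decreased;
#' in a positive / negative non-intervention the increase / decrease is
#' observed without intervening. `repetitions` counts how many times the
#' experiment was repeated with the same result (the consistency
#' principle).
#'
#' @param kind one of `"pos_int"`, `"neg_int"`, `"pos_nonint"`,
#'   `"neg_nonint"` (rendered as the arrow symbols in display output).
#' @param observed_relation the relation the experiment supported:
#'   `"excitatory"`, `"inhibitory"`, or `"no_connection"`.
#' @param repetitions positive integer.
#' @param citation optional free-text provenance.
#' @return an object of class `experiment_record`.
#' @export
experiment_record <- function(kind, observed_relation, repetitions = 1L,
                              citation = NULL) {
  kind <- match.arg(kind, EXPERIMENT_KINDS)
  observed_relation <- match.arg(observed_relation, RELATIONS)
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1L) stop_input("repetitions must be >= 1")
  structure(
    list(kind = kind, observed_relation = observed_relation,
         repetitions = repetitions, citation = citation),
    class = "experiment_record"
  )
}

#' Construct a research-map edge
#'
#' @param agent,target phenomenon names (distinct).
#' @param relation `"excitatory"` (agent promotes target), `"inhibitory"`
#'   (agent inhibits target), or `"no_connection"` (no measurable effect).
#' @param records list of [experiment_record()]; must be non-empty unless
#'   `hypothetical`.
#' @param hypothetical logical; hypothetical edges are putative assertions
#'   carrying no empirical evidence (no records, no score) used to give a
#'   map structure.
#' @param score optional pinned evidence score in `[0, 1)`; computed by
#'   [score_edge()] when `NULL`.
#' @return an object of class `rm_edge`.
#' @export
rm_edge <- function(agent, target, relation, records = list(),
                    hypothetical = FALSE, score = NULL) {
  relation <- match.arg(relation, RELATIONS)
  if (identical(agent, target)) stop_input("agent and target must be distinct")
  if (hypothetical && length(records) > 0L) {
    stop_input("hypothetical edges carry no experiment records")
  }
  if (!hypothetical && length(records) == 0L) {
    stop_input("empirical edges need at least one experiment record")
  }
  if (!is.null(score) && (score < 0 || score >= 1)) {
    stop_input("score must lie in [0, 1)")
  }
  structure(
    list(agent = as.character(agent), target = as.character(target),
         relation = relation, hypothetical = isTRUE(hypothetical),
         records = records, score = score),
    class = "rm_edge"
  )
}

#' Construct a research map
#'
#' @param phenomena character vector of phenomenon names, or a data frame
#'   with columns `name` and optionally `ontology_id` (an opaque
#'   identifier passed through unchanged; node identity is by name).
#' @param edges list of [rm_edge()]; at most one edge per ordered
#'   (agent, target) pair.
#' @return an object of class `research_map`.
#' @export
research_map <- function(phenomena = character(), edges = list()) {
  if (is.character(phenomena)) {
    phenomena <- data.frame(name = phenomena, ontology_id = NA_character_,
                            stringsAsFactors = FALSE)
  }
  phenomena <- as.data.frame(phenomena, stringsAsFactors = FALSE)
  if (nrow(phenomena) > 0L && !"name" %in% names(phenomena)) {
    stop_input("phenomena need a `name` column")
  }
  if (!"ontology_id" %in% names(phenomena)) phenomena$ontology_id <- NA_character_
  if (anyDuplicated(phenomena$name)) stop_input("phenomenon names must be unique")
  if (any(!nzchar(phenomena$name))) stop_input("phenomenon names must be non-empty")
  keys <- vapply(edges, function(e) paste0(e$agent, "\r", e$target), character(1L))
  if (anyDuplicated(keys)) {
    stop_input("at most one edge per ordered (agent, target) pair")
  }
  endpoints <- unique(unlist(lapply(edges, function(e) c(e$agent, e$target))))
  missing <- setdiff(endpoints, phenomena$name)
  if (length(missing) > 0L) {
    stop_input(paste0("edge endpoints not in phenomena: ", paste(missing, collapse = ", ")))
  }
  structure(list(phenomena = phenomena, edges = edges), class = "research_map")
}

#' @export
print.research_map <- function(x, ...) {
  cat(sprintf("research map: %d phenomena, %d edges\n",
              nrow(x$phenomena), length(x$edges)))
  for (e in x$edges) {
    syms <- if (e$hypothetical) "(hypothetical)" else {
      paste0("[", paste(vapply(e$records, function(r)
        paste0(KIND_SYMBOLS[[r$kind]], "x", r$repetitions), character(1L)),
        collapse = " "), "]  score ", format(round(score_edge(e), 3)))
    }
    arrow <- switch(e$relation, excitatory = "->", inhibitory = "-|",
                    no_connection = "-o")
    cat(sprintf("  %s %s %s  %s\n", e$agent, arrow, e$target, syms))
  }
  invisible(x)
}

## ---- evidence scoring ----------------------------------------------------

#' Evidence score of a research-map edge
#'
#' The score operationalizes the two integration principles: *consistency*
#' (repeating an experiment with the same result strengthens evidence) and
#' *convergence* (agreement across different experiment types strengthens
#' it more). The published ResearchMaps score calculation is not public,
#' so this package uses a clearly labelled surrogate:
#'
#' \deqn{s = (1 - 2^{-r}) \cdot k / 4}
#'
#' where `r` is the total number of repetitions across the edge's records
#' and `k` the number of distinct experiment kinds present (1..4). The
#' surrogate is strictly increasing in `r` at fixed `k` and in `k` at
#' fixed `r`, lies in `[0, 1)`, and tends to `k/4` as `r` grows: evidence
#' from a single experiment type saturates at 1/4, and only full
#' methodological convergence can approach 1. Scoring is pluggable via the
#' `scorer` argument.
#'
#' Records whose observed relation conflicts with the edge's majority
#' relation are dropped from `r` and `k` with a warning (the map keeps a
#' single relation per edge).
#'
#' @param edge an empirical [rm_edge()].
#' @param scorer function(records) -> score; defaults to
#'   [surrogate_score()].
#' @return score in `[0, 1)`.
#' @examples
#' e <- rm_edge("X", "Y", "excitatory",
#'              list(experiment_record("pos_int", "excitatory", 1)))
#' score_edge(e)  # 0.125
#' @export
score_edge <- function(edge, scorer = surrogate_score) {
  if (edge$hypothetical) stop_input("hypothetical edges have no score")
  recs <- concordant_records(edge, warn = TRUE)
  scorer(recs)
}

#' @rdname score_edge
#' @param records list of [experiment_record()].
#' @export
surrogate_score <- function(records) {
  if (length(records) == 0L) return(0)
  r <- sum(vapply(records, `[[`, integer(1L), "repetitions"))
  k <- length(unique(vapply(records, `[[`, character(1L), "kind")))
  (1 - 2^(-r)) * k / 4
}

## majority-relation filter: keep records concordant with the edge's
## majority relation (ties favour the edge's declared relation, then
## lexicographic order)
concordant_records <- function(edge, warn = FALSE) {
  rels <- vapply(edge$records, `[[`, character(1L), "observed_relation")
  if (length(unique(rels)) <= 1L) return(edge$records)
  reps <- vapply(edge$records, `[[`, integer(1L), "repetitions")
  tot <- tapply(reps, rels, sum)
  top <- names(tot)[tot == max(tot)]
  majority <- if (edge$relation %in% top) edge$relation else sort(top)[1L]
  if (warn) {
    warning(sprintf(
      "edge %s -> %s has conflicting experiment records; scoring only the %d concordant with the majority relation '%s'",
      edge$agent, edge$target, sum(rels == majority), majority
    ), call. = FALSE)
  }
  edge$records[rels == majority]
}

## ---- validation ----------------------------------------------------------

#' Validate a research map
#'
#' Checks every structural invariant and returns the violations as data
#' (not errors), one row per problem: self-loop edges, hypothetical edges
#' carrying records, empirical edges without records, unknown endpoints,
#' duplicate edges, scores outside `[0, 1)`, bad repetition counts.
#'
#' @param map a `research_map` (or a raw list with the same shape, so
#'   partially-broken inputs can still be diagnosed).
#' @return data frame with columns `where` and `rule`; zero rows iff the
#'   map is valid.
#' @export
validate_map <- function(map) {
  out <- data.frame(where = character(), rule = character(), stringsAsFactors = FALSE)
  add <- function(where, rule) {
    out[nrow(out) + 1L, ] <<- list(where, rule)
  }
  ph <- map$phenomena
  if (anyDuplicated(ph$name)) add("phenomena", "duplicate phenomenon names")
  if (any(!nzchar(ph$name))) add("phenomena", "empty phenomenon name")
  keys <- vapply(map$edges, function(e) paste0(e$agent, " -> ", e$target), character(1L))
  dup <- unique(keys[duplicated(keys)])
  for (d in dup) add(d, "duplicate (agent, target) edge")
  for (i in seq_along(map$edges)) {
    e <- map$edges[[i]]
    lab <- paste0(e$agent, " -> ", e$target)
    if (identical(e$agent, e$target)) add(lab, "agent equals target")
    if (!all(c(e$agent, e$target) %in% ph$name)) add(lab, "endpoint not among phenomena")
    if (isTRUE(e$hypothetical)) {
      if (length(e$records) > 0L) add(lab, "hypothetical edge carries experiment records")
      if (!is.null(e$score)) add(lab, "hypothetical edge carries a score")
    } else {
      if (length(e$records) == 0L) add(lab, "empirical edge without experiment records")
      if (!is.null(e$score) && (e$score < 0 || e$score >= 1)) {
        add(lab, "score outside [0, 1)")
      }
    }
    for (r in e$records) {
      if (!r$kind %in% EXPERIMENT_KINDS) add(lab, "unknown experiment kind")
      if (is.na(r$repetitions) || r$repetitions < 1L) add(lab, "repetitions < 1")
    }
  }
  out
}

## ---- JSON I/O ------------------------------------------------------------

#' Read / write research maps as JSON
#'
#' Schema: `{"phenomena": [{"name", "ontology_id"?}], "edges": [{"agent",
#' "target", "relation", "hypothetical", "records": [{"kind",
#' "observed_relation", "repetitions", "citation"?}], "score"?}]}`.
#' Experiment kinds are serialized as the ASCII tokens `pos_int`,
#' `neg_int`, `pos_nonint`, `neg_nonint`; the arrow symbols are used only
#' in rendered output. Writing then reading is the identity on valid maps.
#'
#' @param path file path.
#' @param recompute_scores if `TRUE` (default) edge scores are recomputed
#'   from the records on read; if `FALSE` a `score` present in the file is
#'   kept pinned.
#' @return `read_map` returns a `research_map`; `write_map` returns `path`
#'   invisibly.
#' @export
read_map <- function(path, recompute_scores = TRUE) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_input(paste0("cannot parse JSON: ", conditionMessage(e)))
  )
  ph <- doc$phenomena %||% list()
  phenomena <- data.frame(
    name = vapply(ph, function(p) {
      if (is.null(p$name)) stop_input("phenomenon missing `name` (at $.phenomena)")
      as.character(p$name)
    }, character(1L)),
    ontology_id = vapply(ph, function(p) {
      if (is.null(p$ontology_id)) NA_character_ else as.character(p$ontology_id)
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  edges <- lapply(seq_along(doc$edges %||% list()), function(i) {
    e <- doc$edges[[i]]
    at <- sprintf("$.edges[%d]", i)
    for (f in c("agent", "target", "relation")) {
      if (is.null(e[[f]])) stop_input(sprintf("edge missing `%s` (at %s)", f, at))
    }
    if (!e$relation %in% RELATIONS) {
      stop_input(sprintf("unknown relation '%s' (at %s)", e$relation, at))
    }
    records <- lapply(e$records %||% list(), function(r) {
      if (is.null(r$kind) || !r$kind %in% EXPERIMENT_KINDS) {
        stop_input(sprintf("bad or missing record kind (at %s.records)", at))
      }
      experiment_record(
        r$kind,
        r$observed_relation %||% e$relation,
        r$repetitions %||% 1L,
        r$citation
      )
    })
    hyp <- isTRUE(e$hypothetical)
    score <- if (!recompute_scores && !hyp) e$score else NULL
    rm_edge(e$agent, e$target, e$relation, records, hypothetical = hyp, score = score)
  })
  tryCatch(
    research_map(phenomena, edges),
    causalplanr_input_error = function(err) {
      stop_input(paste0(conditionMessage(err), " (at $.edges)"))
    }
  )
}

#' @rdname read_map
#' @param map a `research_map`.
#' @export
write_map <- function(map, path) {
  doc <- list(
    phenomena = lapply(seq_len(nrow(map$phenomena)), function(i) {
      p <- list(name = map$phenomena$name[i])
      if (!is.na(map$phenomena$ontology_id[i])) p$ontology_id <- map$phenomena$ontology_id[i]
      p
    }),
    edges = lapply(map$edges, function(e) {
      out <- list(
        agent = e$agent, target = e$target, relation = e$relation,
        hypothetical = e$hypothetical,
        records = lapply(e$records, function(r) {
          rec <- list(kind = r$kind, observed_relation = r$observed_relation,
                      repetitions = r$repetitions)
          if (!is.null(r$citation)) rec$citation <- r$citation
          rec
        })
      )
      if (!e$hypothetical) out$score <- e$score %||% score_edge(e)
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export a research map to DOT
#'
#' Renders the three relation types with the conventional arrowheads
#' (sharp for excitatory, flat/tee for inhibitory, dotted line with a
#' circular head for no-connection), hypothetical edges in gray, and the
#' experiment symbols as edge labels.
#'
#' @param map a `research_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
map_to_dot <- function(map, path) {
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph research_map {")
  for (nm in map$phenomena$name) lines <- c(lines, paste0("  ", q(nm), ";"))
  for (e in map$edges) {
    attrs <- switch(e$relation,
      excitatory = 'arrowhead=normal',
      inhibitory = 'arrowhead=tee',
      no_connection = 'arrowhead=odot, style=dotted'
    )
    if (e$hypothetical) {
      attrs <- paste0(attrs, ', color=gray, fontcolor=gray')
    } else {
      lab <- paste(vapply(e$records, function(r)
        paste0(KIND_SYMBOLS[[r$kind]], if (r$repetitions > 1L) paste0("x", r$repetitions) else ""),
        character(1L)), collapse = " ")
      attrs <- paste0(attrs, ', label=', q(lab))
    }
    lines <- c(lines, paste0("  ", q(e$agent), " -> ", q(e$target), " [", attrs, "];"))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
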