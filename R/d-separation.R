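#' d-separation
#'
#' Decides whether a graph implies the conditional independence of `a` and
#' `b` given a conditioning set, by the standard trail-blocking criterion:
#' a path is blocked when it passes through a conditioned chain or fork
#' node, or through a collider that is neither conditioned nor has a
#' conditioned descendant. `a` and `b` are d-separated iff every path
#' between them is blocked.
#'
#' The implementation is the linear-time reachability ("Bayes-ball")
#' algorithm rather than path enumeration; an exhaustive path-enumeration
#' oracle is used to validate it in the test suite. For graphs drawn from
#' the cyclic space the same trail criterion is applied; this is a
#' documented approximation (d-separation is not generally sound for cyclic
#' models).
#'
#' @param graph a `causal_graph`.
#' @param a,b distinct variable names, neither in `conditioning`.
#' @param conditioning character vector of conditioned variables (possibly
#'   empty).
#' @return `TRUE` iff `a` and `b` are d-separated given `conditioning`.
#' @examples
#' chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' d_separated(chain, "X", "Z", "Y")  # TRUE
#' d_separated(chain, "X", "Z")       # FALSE
#' @export
d_separated <- function(graph, a, b, conditioning = character()) {
  vars <- graph$variables
  conditioning <- as.character(conditioning)
  unknown <- setdiff(c(a, b, conditioning), vars)
  if (length(unknown) > 0L) {
    stop_input(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  if (identical(a, b)) stop_input("a and b must be distinct")
  if (a %in% conditioning || b %in% conditioning) {
    stop_input("a and b must not be in the conditioning set")
  }
  amat <- graph$amat
  n <- nrow(amat)
  ai <- match(a, vars); bi <- match(b, vars)
  ci <- match(conditioning, vars)
  in_c <- rep(FALSE, n); in_c[ci] <- TRUE

  ## nodes that are in C or have a descendant in C (activate colliders)
  anc_c <- in_c
  repeat {
    ## parents of any flagged node become flagged (ancestors of C)
    new <- (amat %*% anc_c) > 0
    grown <- new & !anc_c
    if (!any(grown)) break
    anc_c <- anc_c | grown
  }

  parents <- lapply(seq_len(n), function(j) which(amat[, j] == 1L))
  children <- lapply(seq_len(n), function(i) which(amat[i, ] == 1L))

  ## reachability over (node, direction) states; direction "up" = arrived
  ## from a child (traveling against an arrow), "down" = arrived from a
  ## parent (traveling along an arrow)
  seen_up <- rep(FALSE, n); seen_down <- rep(FALSE, n)
  queue <- list(c(ai, 1L))  # 1 = up, 2 = down
  while (length(queue) > 0L) {
    st <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    v <- st[1L]; dir <- st[2L]
    if (dir == 1L) {
      if (seen_up[v]) next
      seen_up[v] <- TRUE
      if (!in_c[v]) {
        if (v == bi) return(FALSE)
        for (p in parents[[v]]) queue[[length(queue) + 1L]] <- c(p, 1L)
        for (ch in children[[v]]) queue[[length(queue) + 1L]] <- c(ch, 2L)
      }
    } else {
      if (seen_down[v]) next
      seen_down[v] <- TRUE
      if (!in_c[v]) {
        if (v == bi) return(FALSE)
        for (ch in children[[v]]) queue[[length(queue) + 1L]] <- c(ch, 2L)
      }
      if (anc_c[v]) {  # collider at v is active
        for (p in parents[[v]]) queue[[length(queue) + 1L]] <- c(p, 1L)
      }
    }
  }
  TRUE
}

#' Construct an independence query
#'
#' An independence query is the atomic measurable statement of the
#' framework: is `a` independent of `b` given conditioning set `C`, under
#' interventions on `J`? Written `a _||_ b | C || J`. Both `C` and `J` may
#' be empty; non-intervention experiments have `J` empty.
#'
#' The `(a, b)` pair is canonicalized to lexicographic order so that
#' queries are symmetric in their endpoints.
#'
#' @param a,b distinct variable names, neither in `conditioning`.
#' @param conditioning character vector `C` (conditioned variables).
#' @param interventions character vector `J` (intervened variables; may
#'   include `a` or `b`, as when intervening on the agent of an edge).
#' @return an object of class `independence_query`.
#' @export
independence_query <- function(a, b, conditioning = character(),
                               interventions = character()) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != 1L || length(b) != 1L) stop_input("a and b must be single names")
  if (identical(a, b)) stop_input("a and b must be distinct")
  conditioning <- sort(unique(as.character(conditioning)))
  interventions <- sort(unique(as.character(interventions)))
  if (a %in% conditioning || b %in% conditioning) {
    stop_input("conditioning set must not contain a or b")
  }
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  structure(
    list(a = a, b = b, conditioning = conditioning, interventions = interventions),
    class = "independence_query"
  )
}

query_key <- function(q) {
  paste0(
    q$a, "_||_", q$b,
    " | ", if (length(q$conditioning)) paste(q$conditioning, collapse = ",") else "-",
    " || ", if (length(q$interventions)) paste(q$interventions, collapse = ",") else "-"
  )
}

#' @export
print.independence_query <- function(x, ...) {
  cat(query_key(x), "\n")
  invisible(x)
}

#' Evaluate an independence query on a graph
#'
#' Applies intervention surgery for the query's intervention set `J`
#' (removing all edges into intervened variables), then reads the
#' conditional independence off the manipulated graph by d-separation.
#'
#' @param graph a `causal_graph`.
#' @param query an `independence_query`.
#' @return `TRUE` iff the graph implies the queried independence.
#' @examples
#' g <- causal_graph(c("X", "Y"), rbind(c("Y", "X")))
#' q <- independence_query("X", "Y", interventions = "X")
#' holds(g, q)  # TRUE: intervening on X severs Y -> X
#' @export
holds <- function(graph, query) {
  stopifnot(inherits(query, "independence_query"))
  d_separated(
    manipulate(graph, query$interventions),
    query$a, query$b, query$conditioning
  )
}

#' Default observational query settings
#'
#' All unordered variable pairs crossed with all conditioning subsets of
#' the remaining variables (up to `max_conditioning`), with empty
#' intervention sets. These settings define observational Markov
#' equivalence: graphs indistinguishable without intervening.
#'
#' @param variables character vector of variable names.
#' @param max_conditioning largest conditioning-set size to include
#'   (default: unlimited).
#' @return list of `independence_query`.
#' @export
observational_settings <- function(variables, max_conditioning = Inf) {
  variables <- as.character(variables)
  n <- length(variables)
  out <- list()
  if (n < 2L) return(out)
  pairs <- utils::combn(sort(variables), 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    rest <- setdiff(variables, c(a, b))
    sizes <- 0:min(length(rest), max_conditioning)
    for (s in sizes) {
      if (s == 0L) {
        out[[length(out) + 1L]] <- independence_query(a, b)
      } else {
        subs <- utils::combn(sort(rest), s, simplify = FALSE)
        for (cc in subs) {
          out[[length(out) + 1L]] <- independence_query(a, b, conditioning = cc)
        }
      }
    }
  }
  out
}

#' Single-variable interventional query settings
#'
#' For each ordered pair `(j, t)` adds the query `j _||_ t | 0 || {j}`:
#' intervene on `j`, measure `t`.
#'
#' @param variables character vector of variable names.
#' @return list of `independence_query`.
#' @export
interventional_settings <- function(variables) {
  variables <- as.character(variables)
  out <- list()
  for (j in variables) {
    for (t in setdiff(variables, j)) {
      out[[length(out) + 1L]] <- independence_query(j, t, interventions = j)
    }
  }
  out
}

#' Independence signature of a graph
#'
#' The vector of answers a graph gives to a set of independence queries:
#' its observable fingerprint under the chosen experimental settings. Two
#' graphs with equal signatures are indistinguishable by those settings.
#'
#' @param graph a `causal_graph`.
#' @param settings list of `independence_query`.
#' @return named logical vector (`TRUE` = independent), names are query
#'   keys.
#' @export
signature <- function(graph, settings) {
  vapply(settings, function(q) holds(graph, q), logical(1L),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(settings, query_key, character(1L)))
}
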