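## Exhaustive enumeration of small graph spaces, analytic counting, and
## equivalence-class construction.

DEFAULT_CAP_ACYCLIC <- 6L
DEFAULT_CAP_CYCLIC <- 5L

#' Count the graphs in a space
#'
#' Analytic counts, available above the materialization cap. The cyclic
#' space over n variables has `2^(n(n-1))` directed graphs (each ordered
#' pair independently present or absent); the acyclic space is counted by
#' Robinson's recurrence for labeled DAGs:
#' `a(n) = sum_{k=1..n} (-1)^(k+1) C(n,k) 2^(k(n-k)) a(n-k)`, `a(0) = 1`.
#'
#' @param n number of variables.
#' @param allow_cycles logical; which space to count.
#' @return the count as a double (exact for the sizes of interest; e.g.
#'   3781503 labeled DAGs and 2^30 digraphs on 6 variables).
#' @export
count_graphs <- function(n, allow_cycles = FALSE) {
  n <- as.integer(n)
  if (n < 0L) stop_input("n must be non-negative")
  if (allow_cycles) return(2^(n * (n - 1L)))
  count_dags(n)
}

#' @rdname count_graphs
#' @export
count_dags <- function(n) {
  n <- as.integer(n)
  a <- numeric(n + 1L)
  a[1L] <- 1  # a(0)
  if (n >= 1L) {
    for (m in 1:n) {
      terms <- vapply(1:m, function(k) {
        (-1)^(k + 1) * choose(m, k) * 2^(k * (m - k)) * a[m - k + 1L]
      }, numeric(1L))
      a[m + 1L] <- sum(terms)
    }
  }
  a[n + 1L]
}

## unordered pair index matrix for n variables, row-major (i < j)
pair_index <- function(n) {
  if (n < 2L) return(matrix(integer(0), nrow = 2L))
  utils::combn(n, 2L)
}

#' Enumerate all causal graphs over a variable set
#'
#' Yields every distinct graph in the chosen space exactly once, in
#' lexicographic order of the adjacency encoding (row-major 0/1 vector of
#' ordered pairs), so enumeration is fully reproducible. The acyclic space
#' is generated per unordered pair over the three acyclic relation states
#' and filtered for global acyclicity; the cyclic space spans all
#' `2^(n(n-1))` digraphs.
#'
#' The number of graphs is super-exponential in n (over three million
#' labeled DAGs, and `2^30` digraphs, at n = 6), so materialization is
#' capped: by default n <= 6 acyclic and n <= 5 cyclic. Counts above the
#' cap are available analytically via [count_graphs()].
#'
#' @param variables character vector of variable names.
#' @param allow_cycles logical; enumerate the cyclic space.
#' @param cap override of the variable-count cap (use with care: the
#'   returned list is exponential in size).
#' @return list of `causal_graph`.
#' @export
enumerate_graphs <- function(variables, allow_cycles = FALSE, cap = NULL) {
  variables <- as.character(variables)
  n <- length(variables)
  cap <- as.integer(cap %||% if (allow_cycles) DEFAULT_CAP_CYCLIC else DEFAULT_CAP_ACYCLIC)
  if (n < 1L) stop_input("need at least one variable")
  if (n > cap) {
    stop_resource(sprintf(
      "enumeration of %d variables exceeds the cap of %d (%s space, %s graphs); raise `cap` to override or use count_graphs() for the count",
      n, cap, if (allow_cycles) "cyclic" else "acyclic",
      format(count_graphs(n, allow_cycles), big.mark = ",")
    ))
  }
  if (n == 1L) {
    return(list(causal_graph(variables, NULL, allow_cycles = allow_cycles)))
  }
  amats <- if (allow_cycles) enum_amats_cyclic(n) else enum_amats_acyclic(n)
  ## lexicographic order of the row-major off-diagonal adjacency encoding
  keys <- vapply(amats, function(m) paste(t(m)[!diag(n)], collapse = ""), character(1L))
  amats <- amats[order(keys, method = "radix")]
  lapply(amats, graph_from_amat, variables = variables, allow_cycles = allow_cycles)
}

enum_amats_acyclic <- function(n) {
  pairs <- pair_index(n)
  m <- ncol(pairs)
  ## states per unordered pair: 0 none, 1 i->j, 2 j->i
  grid <- as.matrix(expand.grid(rep(list(0:2), m), KEEP.OUT.ATTRS = FALSE))
  out <- vector("list", nrow(grid))
  kept <- 0L
  for (r in seq_len(nrow(grid))) {
    amat <- matrix(0L, n, n)
    st <- grid[r, ]
    fw <- st == 1L; bw <- st == 2L
    amat[cbind(pairs[1L, fw], pairs[2L, fw])] <- 1L
    amat[cbind(pairs[2L, bw], pairs[1L, bw])] <- 1L
    if (amat_is_acyclic(amat)) {
      kept <- kept + 1L
      out[[kept]] <- amat
    }
  }
  out[seq_len(kept)]
}

enum_amats_cyclic <- function(n) {
  m <- n * (n - 1L)
  off <- which(!diag(n))  # column-major positions of off-diagonal cells
  total <- 2^m
  out <- vector("list", total)
  for (i in seq_len(total)) {
    bits <- as.integer(intToBits(i - 1L))[seq_len(m)]
    amat <- matrix(0L, n, n)
    amat[off] <- bits
    out[[i]] <- amat
  }
  out
}

#' Construct an equivalence class
#'
#' The set of graphs in a space that answer a set of independence queries
#' exactly as a reference graph does. With purely observational settings
#' this is the observational Markov equivalence class; adding
#' interventional queries refines it (never enlarges it).
#'
#' @param reference a `causal_graph`.
#' @param settings list of `independence_query` defining equivalence
#'   (default: all observational queries over the reference's variables).
#' @param space list of candidate `causal_graph` to search (default: the
#'   enumerated acyclic space over the reference's variables; the cyclic
#'   space must be requested explicitly by passing it here).
#' @return an object of class `equivalence_class` with fields `members`
#'   (list of graphs, reference's signature guaranteed represented),
#'   `settings`, and `variables`.
#' @examples
#' chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' cls <- equivalence_class(chain)
#' length(cls$members)  # 3
#' @export
equivalence_class <- function(reference, settings = NULL, space = NULL) {
  settings <- settings %||% observational_settings(reference$variables)
  space <- space %||% enumerate_graphs(reference$variables, allow_cycles = FALSE)
  ref_sig <- signature(reference, settings)
  members <- Filter(function(g) identical(unname(signature(g, settings)), unname(ref_sig)), space)
  if (length(members) == 0L) {
    ## reference not drawn from the space (e.g. cyclic reference, acyclic
    ## space): include it so the class is non-empty and truthful
    members <- list(reference)
  }
  new_equivalence_class(members, settings, reference$variables)
}

new_equivalence_class <- function(members, settings, variables) {
  structure(
    list(members = members, settings = settings, variables = variables),
    class = "equivalence_class"
  )
}

#' @export
print.equivalence_class <- function(x, ...) {
  cat(sprintf(
    "equivalence class: %d graph(s) over {%s}, %d defining queries\n",
    length(x$members), paste(x$variables, collapse = ", "), length(x$settings)
  ))
  if (length(x$members) <= 10L) {
    for (g in x$members) cat("  ", format(g), "\n")
  }
  invisible(x)
}

## refine a class by the answer to one query: keep members whose holds()
## equals `independent`
refine_class <- function(cls, query, independent) {
  keep <- Filter(function(g) holds(g, query) == independent, cls$members)
  new_equivalence_class(keep, c(cls$settings, list(query)), cls$variables)
}
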