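#' @useDynLib sagescore, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Coverage cost table for one element
#'
#' A coverage cost table assigns a cost to every possible coverage
#' (number of incident matching pairs) of one element. Costs are stored
#' for coverages `0 .. max_finite_coverage` as a contiguous numeric
#' vector; any coverage beyond the last entry has implicit cost
#' `+Inf` (that coverage is forbidden).
#'
#' @param costs Numeric vector of finite costs; `costs[i + 1]` is the
#'   cost of coverage `i`.
#' @param element_id Optional identifier used in error messages.
#' @return An object of class `coverage_table`.
#' @examples
#' # a read: penalty 100 when unmatched, free when matched once,
#' # forbidden to match twice
#' coverage_table(c(100, 0))
#' @export
coverage_table <- function(costs, element_id = NULL) {
  costs <- as.numeric(costs)
  if (length(costs) < 1L)
    stop("coverage table needs at least the coverage-0 cost")
  if (any(!is.finite(costs)))
    stop("coverage table entries must be finite (omit trailing +Inf)")
  structure(costs, class = "coverage_table", element_id = element_id)
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("<coverage_table", if (!is.null(attr(x, "element_id")))
    paste0("'", attr(x, "element_id"), "'") else "",
    "coverages 0..", length(x) - 1L, ">\n")
  print(unclass(x))
  invisible(x)
}

# cost of coverage i under table (plain numeric vector ok); Inf beyond end
cov_cost <- function(table, i) {
  out <- rep(Inf, length(i))
  ok <- i >= 0L & i < length(table)
  out[ok] <- table[i[ok] + 1L]
  out
}

#' Test midpoint convexity of a coverage cost table
#'
#' A table is convex when `cost(i) <= (cost(i-1) + cost(i+1)) / 2` at
#' every interior coverage, treating coverages beyond the table end as
#' `+Inf`. Convexity is what permits the exact min-cost-flow solution;
#' it is checked, never assumed.
#'
#' @param table A [coverage_table()] or plain numeric cost vector.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_convex(coverage_table((5 - 0:8)^2)) # quadratic: TRUE
#' is_convex(coverage_table(c(0, 5, 0)))  # spike: FALSE
#' @export
is_convex <- function(table) {
  v <- as.numeric(table)
  n <- length(v)
  if (n <= 2L) return(TRUE)  # boundary terms involve +Inf
  i <- 2:(n - 1L)
  all(v[i] <= (v[i - 1L] + v[i + 1L]) / 2 + 1e-12)
}

#' Construct a CSM matching instance
#'
#' A matching instance holds the two element sets of the bipartite
#' problem -- reads `X` and template segments `Y` in the genomic
#' application -- together with sparse pairwise matching costs and one
#' coverage cost table per element. A pair absent from `pairs` has
#' matching cost `+Inf` (it can never be matched).
#'
#' @param x_ids,y_ids Character vectors of element identifiers; the two
#'   sets must be disjoint and free of duplicates.
#' @param pairs `data.frame` with columns `x`, `y` (identifiers, or
#'   integer indices into `x_ids`/`y_ids`) and `cost` (finite numeric).
#' @param x_tables,y_tables Lists of coverage cost tables (numeric
#'   vectors), one per element, in the order of `x_ids`/`y_ids`.
#' @return An object of class `matching_instance`.
#' @export
matching_instance <- function(x_ids, y_ids, pairs, x_tables, y_tables) {
  x_ids <- as.character(x_ids); y_ids <- as.character(y_ids)
  if (anyDuplicated(x_ids) || anyDuplicated(y_ids) ||
      length(intersect(x_ids, y_ids)) > 0L)
    stop("x_ids and y_ids must be disjoint and duplicate-free")
  if (length(x_tables) != length(x_ids) || length(y_tables) != length(y_ids))
    stop("need one coverage table per element")
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0L) {
    if (is.character(pairs$x) || is.factor(pairs$x)) {
      ix <- match(as.character(pairs$x), x_ids)
      iy <- match(as.character(pairs$y), y_ids)
      if (anyNA(ix) || anyNA(iy))
        stop("pairs reference unknown element ids")
    } else {
      ix <- as.integer(pairs$x); iy <- as.integer(pairs$y)
      if (any(ix < 1L | ix > length(x_ids)) || any(iy < 1L | iy > length(y_ids)))
        stop("pair indices out of range")
    }
    cost <- as.numeric(pairs$cost)
    if (any(!is.finite(cost)))
      stop("pair costs must be finite (omit +Inf pairs)")
    key <- (ix - 1) * length(y_ids) + iy
    if (anyDuplicated(key))
      stop("duplicate (x, y) pairs")
    pairs <- data.frame(x = ix, y = iy, cost = cost)
  } else {
    pairs <- data.frame(x = integer(), y = integer(), cost = numeric())
  }
  x_tables <- lapply(x_tables, as.numeric)
  y_tables <- lapply(y_tables, as.numeric)
  structure(list(x_ids = x_ids, y_ids = y_ids, pairs = pairs,
                 x_tables = x_tables, y_tables = y_tables),
            class = "matching_instance")
}

#' @export
print.matching_instance <- function(x, ...) {
  cat("<matching_instance ", length(x$x_ids), " x ", length(x$y_ids),
      " elements, ", nrow(x$pairs), " finite pairs>\n", sep = "")
  invisible(x)
}

#' Construct a many-to-many matching
#'
#' @param x,y Parallel character vectors of element identifiers; row `i`
#'   is the pair `(x[i], y[i])`.
#' @return `data.frame` of class `csm_matching` with columns `x`, `y`.
#' @export
csm_matching <- function(x = character(), y = character()) {
  m <- data.frame(x = as.character(x), y = as.character(y))
  if (anyDuplicated(paste0(m$x, "\r", m$y)))
    stop("a matching is a set: duplicate pairs are not allowed")
  class(m) <- c("csm_matching", "data.frame")
  m
}

# per-element coverages of a matching, as integer vectors over the
# instance's element order
matching_coverages <- function(instance, m) {
  ix <- match(m$x, instance$x_ids)
  iy <- match(m$y, instance$y_ids)
  if (anyNA(ix) || anyNA(iy))
    stop("invalid instance/matching: pair references unknown element")
  list(ix = ix, iy = iy,
       cx = tabulate(ix, nbins = length(instance$x_ids)),
       cy = tabulate(iy, nbins = length(instance$y_ids)))
}

#' Cost of a matching under a CSM instance
#'
#' Evaluates the coverage-sensitive cost: the sum of matching costs of
#' the chosen pairs plus, for every element of both sets, the coverage
#' cost at that element's realised coverage. Any infinite term
#' (a non-candidate pair, or a coverage past a table's end) makes the
#' total `+Inf`.
#'
#' @param instance A [matching_instance()].
#' @param m A [csm_matching()].
#' @return A single number, possibly `Inf`.
#' @export
matching_cost <- function(instance, m) {
  cv <- matching_coverages(instance, m)
  wm <- 0
  if (nrow(m) > 0L) {
    key  <- (cv$ix - 1) * length(instance$y_ids) + cv$iy
    pkey <- (instance$pairs$x - 1) * length(instance$y_ids) + instance$pairs$y
    hit <- match(key, pkey)
    if (anyNA(hit)) return(Inf)
    wm <- sum(instance$pairs$cost[hit])
  }
  wcx <- sum(vapply(seq_along(instance$x_tables), function(j)
    cov_cost(instance$x_tables[[j]], cv$cx[j]), numeric(1)))
  wcy <- sum(vapply(seq_along(instance$y_tables), function(j)
    cov_cost(instance$y_tables[[j]], cv$cy[j]), numeric(1)))
  wm + wcx + wcy
}

#' Sum of all coverage-0 costs (the empty-matching cost)
#'
#' @param instance A [matching_instance()].
#' @return `sum(w_c(z, 0))` over all elements; the cost of the empty
#'   matching, and the constant that converts flow cost to matching cost.
#' @export
instance_delta <- function(instance) {
  sum(vapply(instance$x_tables, `[`, numeric(1), 1L)) +
    sum(vapply(instance$y_tables, `[`, numeric(1), 1L))
}

#' Exact CSM by exhaustive enumeration (verification oracle)
#'
#' Enumerates every subset of the finite-cost pairs and returns a
#' minimum-cost matching. Exponential in the number of pairs; only
#' usable on tiny instances, where it serves as the independent oracle
#' for the flow solver.
#'
#' @param instance A [matching_instance()].
#' @param max_pairs Refuse instances with more finite pairs than this
#'   (default 20, i.e. at most 2^20 subsets).
#' @return List with elements `matching` (a [csm_matching()]) and
#'   `cost`. Ties are broken deterministically: pairs are ordered by
#'   (x id, y id) and the lexicographically smallest optimal subset of
#'   pair indices is returned.
#' @export
brute_force_csm <- function(instance, max_pairs = 20L) {
  np <- nrow(instance$pairs)
  if (np > max_pairs)
    stop("instance has ", np, " finite pairs; enumeration bound is ", max_pairs)
  ord <- order(instance$x_ids[instance$pairs$x], instance$y_ids[instance$pairs$y])
  p <- instance$pairs[ord, , drop = FALSE]
  nx <- length(instance$x_ids); ny <- length(instance$y_ids)
  best_cost <- Inf
  best_sets <- list()
  total <- if (np == 0L) 1 else 2^np
  chunk <- 65536L
  start <- 0
  while (start < total) {
    masks <- start + seq_len(min(chunk, total - start)) - 1
    # bit matrix: rows = subsets, cols = pairs
    B <- if (np > 0L)
      matrix(bitwAnd(rep(masks, np) %/% rep(2^(seq_len(np) - 1), each = length(masks)), 1),
             nrow = length(masks))
    else matrix(0, nrow = 1L, ncol = 0L)
    cost <- if (np > 0L) as.numeric(B %*% p$cost) else 0
    covx <- B %*% outer(p$x, seq_len(nx), "==") * 1
    covy <- B %*% outer(p$y, seq_len(ny), "==") * 1
    for (j in seq_len(nx)) cost <- cost + cov_cost(instance$x_tables[[j]], covx[, j])
    for (j in seq_len(ny)) cost <- cost + cov_cost(instance$y_tables[[j]], covy[, j])
    cmin <- min(cost)
    if (cmin < best_cost - 1e-12) {
      best_cost <- cmin
      best_sets <- list()
    }
    if (cmin <= best_cost + 1e-12) {
      hit <- which(cost <= best_cost + 1e-12)
      best_sets <- c(best_sets, lapply(masks[hit], function(mk)
        which(bitwAnd(mk %/% 2^(seq_len(np) - 1), 1) == 1L)))
    }
    start <- start + chunk
  }
  # lexicographically smallest index set among the optima
  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    if (k > 0L) {
      d <- which(a[seq_len(k)] != b[seq_len(k)])
      if (length(d) > 0L) return(a[d[1L]] < b[d[1L]])
    }
    length(a) < length(b)
  }
  pick <- best_sets[[1L]]
  for (s in best_sets) if (lex_less(s, pick)) pick <- s
  m <- csm_matching(instance$x_ids[p$x[pick]], instance$y_ids[p$y[pick]])
  list(matching = m, cost = best_cost)
}

#' Encode maximum-cardinality bipartite matching as a CSM instance
#'
#' The classical (partial, one-to-one) maximum bipartite matching
#' problem is the CSM special case with matching cost -1 on every graph
#' edge and coverage costs 0 at coverages 0 and 1, `+Inf` beyond, so
#' the CSM optimum equals minus the maximum matching size.
#'
#' @param edges `data.frame` with character columns `x`, `y` listing the
#'   graph's edges.
#' @param x_ids,y_ids Optional full vertex shores (default: the vertices
#'   seen in `edges`).
#' @return A [matching_instance()].
#' @export
encode_bipartite_matching <- function(edges,
                                      x_ids = unique(as.character(edges$x)),
                                      y_ids = unique(as.character(edges$y))) {
  if (length(x_ids) == 0L || length(y_ids) == 0L)
    stop("vertex shores must be nonempty")
  tab01 <- c(0, 0)
  matching_instance(
    x_ids, y_ids,
    data.frame(x = as.character(edges$x), y = as.character(edges$y),
               cost = rep(-1, nrow(edges))),
    x_tables = rep(list(tab01), length(x_ids)),
    y_tables = rep(list(tab01), length(y_ids)))
}

#' Write a CSM instance as plain text
#'
#' One-line-per-record text serialization used for fixtures and the
#' `oracle` command: `X`/`Y` lines list element ids, `P x y cost` lines
#' the finite pairs, and `C id c0 c1 ...` lines the coverage tables.
#'
#' @param instance A [matching_instance()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path) {
  if (any(grepl("[[:space:]]", c(instance$x_ids, instance$y_ids))))
    stop("element ids must not contain whitespace")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# sagescore CSM instance v1", con)
  writeLines(paste(c("X", instance$x_ids), collapse = " "), con)
  writeLines(paste(c("Y", instance$y_ids), collapse = " "), con)
  if (nrow(instance$pairs) > 0L)
    writeLines(sprintf("P %s %s %.17g",
                       instance$x_ids[instance$pairs$x],
                       instance$y_ids[instance$pairs$y],
                       instance$pairs$cost), con)
  ids <- c(instance$x_ids, instance$y_ids)
  tabs <- c(instance$x_tables, instance$y_tables)
  writeLines(vapply(seq_along(ids), function(j)
    paste(c("C", ids[j], sprintf("%.17g", tabs[[j]])), collapse = " "),
    character(1)), con)
  invisible(path)
}

#' Read a CSM instance written by [write_instance()]
#'
#' @param path Input file path.
#' @return A [matching_instance()].
#' @export
read_instance <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  tok <- strsplit(trimws(ln), "[[:space:]]+")
  tag <- vapply(tok, `[`, character(1), 1L)
  grab <- function(t) tok[tag == t]
  xs <- grab("X"); ys <- grab("Y")
  if (length(xs) != 1L || length(ys) != 1L)
    stop("instance file needs exactly one X line and one Y line")
  x_ids <- xs[[1L]][-1L]; y_ids <- ys[[1L]][-1L]
  pl <- grab("P")
  pairs <- if (length(pl) > 0L)
    data.frame(x = vapply(pl, `[`, character(1), 2L),
               y = vapply(pl, `[`, character(1), 3L),
               cost = as.numeric(vapply(pl, `[`, character(1), 4L)))
  else data.frame(x = character(), y = character(), cost = numeric())
  cl <- grab("C")
  cids <- vapply(cl, `[`, character(1), 2L)
  ctabs <- lapply(cl, function(t) as.numeric(t[-(1:2)]))
  mx <- match(x_ids, cids); my <- match(y_ids, cids)
  if (anyNA(mx) || anyNA(my))
    stop("missing coverage table for some element")
  matching_instance(x_ids, y_ids, pairs, ctabs[mx], ctabs[my])
}
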