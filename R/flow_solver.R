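INF_CAP <- .Machine$integer.max %/% 4L

#' Build the min-cost flow network of a convex CSM instance
#'
#' Reduces a convex-coverage-cost instance to a layered flow network
#' `s -> C^X -> X -> Y -> C^Y -> t`. Unit-capacity edges `(c^X_i, x)`
#' carry the difference cost `w_c(x, i) - w_c(x, i - 1)` (and
#' symmetrically on the `Y` side), so that routing `k` units through an
#' element accumulates exactly its coverage cost at coverage `k`
#' relative to coverage 0; `(x, y)` edges carry the matching costs.
#' Convexity makes each element's difference costs non-decreasing in
#' `i`, which is asserted at build time. Edges whose cost would be
#' `+Inf` (coverage beyond a table's end) are omitted.
#'
#' @param instance A [matching_instance()] whose coverage tables all
#'   pass [is_convex()].
#' @return An object of class `flow_network`: list with `edges`
#'   (`data.frame` of from, to, cap, cost, layer and bookkeeping
#'   columns), `delta`, node counts and id maps.
#' @export
build_network <- function(instance) {
  nx <- length(instance$x_ids); ny <- length(instance$y_ids)
  for (j in seq_len(nx)) if (!is_convex(instance$x_tables[[j]]))
    stop("non-convex coverage table for element '", instance$x_ids[j], "'")
  for (j in seq_len(ny)) if (!is_convex(instance$y_tables[[j]]))
    stop("non-convex coverage table for element '", instance$y_ids[j], "'")

  d_x <- tabulate(instance$pairs$x, nbins = nx)
  d_y <- tabulate(instance$pairs$y, nbins = ny)
  # edges (c^X_i, x) exist for i = 1..min(d_x, last finite coverage)
  nex <- pmin(d_x, vapply(instance$x_tables, length, integer(1)) - 1L)
  ney <- pmin(d_y, vapply(instance$y_tables, length, integer(1)) - 1L)
  n_cx <- max(nex, 0L); n_cy <- max(ney, 0L)

  # node numbering: s=1, t=2, X, Y, C^X, C^Y
  xo <- 2L; yo <- xo + nx; cxo <- yo + ny; cyo <- cxo + n_cx
  n_nodes <- cyo + n_cy

  empty_layer <- data.frame(from = integer(), to = integer(), cap = integer(),
                            cost = numeric(), layer = character(),
                            aux1 = integer(), aux2 = integer())
  e1 <- if (n_cx > 0L)
    data.frame(from = 1L, to = cxo + seq_len(n_cx), cap = INF_CAP,
               cost = 0, layer = "E1", aux1 = 0L, aux2 = seq_len(n_cx))
  else empty_layer
  xj <- rep(seq_len(nx), nex)
  xi <- sequence(nex)
  e2 <- if (length(xj) > 0L)
    data.frame(from = cxo + xi, to = xo + xj, cap = 1L,
               cost = vapply(seq_along(xj), function(k) {
                 tb <- instance$x_tables[[xj[k]]]
                 tb[xi[k] + 1L] - tb[xi[k]]
               }, numeric(1)),
               layer = "E2", aux1 = xj, aux2 = xi)
  else empty_layer
  po <- order(instance$pairs$x, instance$pairs$y)
  p <- instance$pairs[po, , drop = FALSE]
  e3 <- if (nrow(p) > 0L)
    data.frame(from = xo + p$x, to = yo + p$y, cap = 1L, cost = p$cost,
               layer = "E3", aux1 = p$x, aux2 = p$y)
  else empty_layer
  yj <- rep(seq_len(ny), ney)
  yi <- sequence(ney)
  e4 <- if (length(yj) > 0L)
    data.frame(from = yo + yj, to = cyo + yi, cap = 1L,
               cost = vapply(seq_along(yj), function(k) {
                 tb <- instance$y_tables[[yj[k]]]
                 tb[yi[k] + 1L] - tb[yi[k]]
               }, numeric(1)),
               layer = "E4", aux1 = yj, aux2 = yi)
  else empty_layer
  e5 <- if (n_cy > 0L)
    data.frame(from = cyo + seq_len(n_cy), to = 2L, cap = INF_CAP,
               cost = 0, layer = "E5", aux1 = 0L, aux2 = seq_len(n_cy))
  else empty_layer
  edges <- rbind(e1, e2, e3, e4, e5)

  # difference costs must be non-decreasing per element (convexity);
  # E2/E4 rows are ordered by (element, i) so adjacent rows of one
  # element are consecutive difference costs
  bad2 <- which(diff(e2$cost) < -1e-9 & diff(e2$aux1) == 0L)
  if (length(bad2) > 0L)
    stop("internal: E2 difference costs not non-decreasing for '",
         instance$x_ids[e2$aux1[bad2[1L]]], "'")
  bad4 <- which(diff(e4$cost) < -1e-9 & diff(e4$aux1) == 0L)
  if (length(bad4) > 0L)
    stop("internal: E4 difference costs not non-decreasing for '",
         instance$y_ids[e4$aux1[bad4[1L]]], "'")

  structure(list(n_nodes = n_nodes, s = 1L, t = 2L,
                 nx = nx, ny = ny, n_cx = n_cx, n_cy = n_cy,
                 n_x_edges = nex, n_y_edges = ney,
                 edges = edges, delta = instance_delta(instance),
                 x_ids = instance$x_ids, y_ids = instance$y_ids),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat("<flow_network ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges, delta = ", format(x$delta), ">\n", sep = "")
  invisible(x)
}

#' Minimum-cost integer flow of unconstrained value
#'
#' Solves min-cost flow over all feasible flow values: augmentation
#' along successive shortest paths continues while the cheapest
#' residual `s`-`t` path still has negative cost. Zero flow is always
#' feasible, so the optimal cost is never positive.
#'
#' @param network A [build_network()] result.
#' @return Object of class `integer_flow`: list with `flow` (integer
#'   per network edge, in edge order), `value` and `cost`.
#' @export
min_cost_free_flow <- function(network) {
  e <- network$edges
  res <- mcf_free_flow(network$n_nodes, network$s, network$t,
                       as.integer(e$from), as.integer(e$to),
                       as.integer(e$cap), as.numeric(e$cost))
  structure(list(flow = res$flow, value = res$value, cost = res$cost),
            class = "integer_flow")
}

#' Matching induced by a flow
#'
#' The matched pairs are exactly the saturated read-to-segment (`E3`)
#' edges of the flow.
#'
#' @param flow An `integer_flow` (or plain integer vector over edges).
#' @param network The network the flow lives on.
#' @return A [csm_matching()].
#' @export
extract_matching <- function(flow, network) {
  fv <- if (inherits(flow, "integer_flow")) flow$flow else as.integer(flow)
  sel <- network$edges$layer == "E3" & fv == 1L
  csm_matching(network$x_ids[network$edges$aux1[sel]],
               network$y_ids[network$edges$aux2[sel]])
}

#' Cost of an explicit flow on a network
#'
#' @param network A `flow_network`.
#' @param flow Integer vector of per-edge flows (network edge order), or
#'   an `integer_flow`.
#' @return `sum(flow * cost)` over the edges.
#' @export
flow_cost <- function(network, flow) {
  fv <- if (inherits(flow, "integer_flow")) flow$flow else as.numeric(flow)
  sum(fv * network$edges$cost)
}

#' Canonical flow of a matching
#'
#' Builds the flow that routes one unit through each matched pair,
#' entering element `x` through `(c^X_1, x), ..., (c^X_{c_M(x)}, x)` and
#' leaving `y` through its first `c_M(y)` difference edges. Its cost
#' equals the matching's coverage-sensitive cost minus the
#' empty-matching constant `delta`, which is the identity the solver's
#' self-check relies on.
#'
#' @param network A `flow_network`.
#' @param m A [csm_matching()] with finite cost on the underlying
#'   instance.
#' @return An `integer_flow`.
#' @export
canonical_flow <- function(network, m) {
  ix <- match(m$x, network$x_ids)
  iy <- match(m$y, network$y_ids)
  if (anyNA(ix) || anyNA(iy)) stop("matching references unknown element")
  cx <- tabulate(ix, nbins = network$nx)
  cy <- tabulate(iy, nbins = network$ny)
  if (any(cx > network$n_x_edges) || any(cy > network$n_y_edges))
    stop("matching has infinite cost (coverage beyond table support)")
  e <- network$edges
  fv <- integer(nrow(e))
  sel3 <- which(e$layer == "E3")
  key <- (as.numeric(ix) - 1) * network$ny + iy
  ekey <- (as.numeric(e$aux1[sel3]) - 1) * network$ny + e$aux2[sel3]
  hit <- match(key, ekey)
  if (anyNA(hit)) stop("matching pair is not a finite-cost candidate")
  fv[sel3[hit]] <- 1L
  sel2 <- e$layer == "E2"
  fv[sel2] <- as.integer(e$aux2[sel2] <= cx[e$aux1[sel2]])
  sel4 <- e$layer == "E4"
  fv[sel4] <- as.integer(e$aux2[sel4] <= cy[e$aux1[sel4]])
  # E1/E5 carry whatever conservation requires
  sel1 <- which(e$layer == "E1")
  fv[sel1] <- vapply(e$aux2[sel1], function(i) sum(cx >= i), integer(1))
  sel5 <- which(e$layer == "E5")
  fv[sel5] <- vapply(e$aux2[sel5], function(i) sum(cy >= i), integer(1))
  structure(list(flow = fv, value = sum(fv[sel1]),
                 cost = flow_cost(network, fv)),
            class = "integer_flow")
}

#' Check capacity and conservation constraints of a flow
#'
#' @param network A `flow_network`.
#' @param flow Integer vector or `integer_flow`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_flow <- function(network, flow) {
  fv <- if (inherits(flow, "integer_flow")) flow$flow else as.integer(flow)
  e <- network$edges
  if (any(fv < 0L) || any(fv > e$cap)) stop("capacity violation")
  inflow  <- tabulate(e$to,   nbins = network$n_nodes) * 0
  outflow <- inflow
  for (k in seq_len(nrow(e))) {
    outflow[e$from[k]] <- outflow[e$from[k]] + fv[k]
    inflow[e$to[k]]    <- inflow[e$to[k]]    + fv[k]
  }
  interior <- setdiff(seq_len(network$n_nodes), c(network$s, network$t))
  if (any(inflow[interior] != outflow[interior]))
    stop("flow conservation violated")
  invisible(TRUE)
}

#' Solve a convex CSM instance exactly
#'
#' Builds the flow network, finds a minimum-cost integer flow of free
#' value, and reads the optimal matching off the saturated
#' read-to-segment edges. The optimal matching cost is the flow cost
#' plus the empty-matching constant `delta`; as a self-check the
#' returned cost is recomputed directly from the matching with
#' [matching_cost()] and the two must agree.
#'
#' @param instance A [matching_instance()] with convex coverage costs.
#' @return List with `matching` (a [csm_matching()]), `cost` (the CSM
#'   optimum), plus the underlying `flow` and `network`.
#' @export
solve_csm <- function(instance) {
  network <- build_network(instance)
  flow <- min_cost_free_flow(network)
  m <- extract_matching(flow, network)
  cost <- flow$cost + network$delta
  check <- matching_cost(instance, m)
  if (!is.finite(check) || abs(check - cost) > 1e-6 * max(1, abs(cost)))
    stop("internal consistency error: flow cost + delta = ", cost,
         " but direct matching cost = ", check)
  list(matching = m, cost = cost, flow = flow, network = network)
}

#' Dump a flow network as TSV (debugging aid)
#'
#' @param network A `flow_network`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_network_tsv <- function(network, path) {
  e <- network$edges
  utils::write.table(
    data.frame(from = e$from, to = e$to, layer = e$layer,
               capacity = ifelse(e$cap >= INF_CAP, "Inf", e$cap),
               cost = e$cost),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
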