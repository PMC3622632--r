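# Shared tiny fixtures, built in code.

# two reads, one segment; read tables {0:10, 1:0}, segment (2 - i)^2
instance_A <- function() {
  matching_instance(
    c("x1", "x2"), "y1",
    data.frame(x = c("x1", "x2"), y = c("y1", "y1"), cost = c(1, 2)),
    x_tables = list(c(10, 0), c(10, 0)),
    y_tables = list((2 - (0:2))^2))
}

# two reads, two segments; the cheap pile-up on y1 fights the coverage
# target of 1 per segment; c22 is the cost of the alternative placement
instance_B <- function(c22 = 1) {
  matching_instance(
    c("x1", "x2"), c("y1", "y2"),
    data.frame(x = c("x1", "x2", "x2"), y = c("y1", "y1", "y2"),
               cost = c(0, 0, c22)),
    x_tables = list(c(10, 0), c(10, 0)),
    y_tables = list((1 - (0:2))^2, (1 - (0:1))^2))
}

# random convex table: cumulative sums of sorted increments
rand_convex_table <- function(max_cov) {
  cumsum(c(runif(1, 0, 12), sort(runif(max_cov, -6, 6))))
}

rand_convex_instance <- function(max_x = 5L, max_y = 4L, max_pairs = 12L) {
  nx <- sample(seq_len(max_x), 1L)
  ny <- sample(seq_len(max_y), 1L)
  x_ids <- paste0("x", seq_len(nx))
  y_ids <- paste0("y", seq_len(ny))
  grid <- expand.grid(x = x_ids, y = y_ids, stringsAsFactors = FALSE)
  np <- sample(seq_len(min(nrow(grid), max_pairs)), 1L)
  sel <- grid[sample(nrow(grid), np), , drop = FALSE]
  matching_instance(
    x_ids, y_ids,
    data.frame(x = sel$x, y = sel$y, cost = sample(0:20, np, replace = TRUE)),
    x_tables = replicate(nx, rand_convex_table(sample(1:3, 1L)),
                         simplify = FALSE),
    y_tables = replicate(ny, rand_convex_table(sample(1:4, 1L)),
                         simplify = FALSE))
}

# random matching over an instance's finite pairs, filtered to finite
# total cost (per-element coverage within table support)
rand_finite_matching <- function(instance) {
  np <- nrow(instance$pairs)
  if (np == 0L) return(csm_matching())
  for (attempt in 1:50) {
    k <- sample(0:np, 1L)
    if (k == 0L) return(csm_matching())
    sel <- sort(sample(np, k))
    m <- csm_matching(instance$x_ids[instance$pairs$x[sel]],
                      instance$y_ids[instance$pairs$y[sel]])
    if (is.finite(matching_cost(instance, m))) return(m)
  }
  csm_matching()
}

# small simulation fixture reused across tests
sim_fixture <- function(seed = 7, coverage = 8, error_rate = 0.005,
                        blocks = c("B1", "B2", "B3")) {
  lib <- make_block_library(3, c(2000, 2000), 0.90, seed = seed)
  tpl <- render_haplotype(haplotype_architecture(blocks, 150), lib)
  reads <- simulate_reads(tpl, coverage, seed = seed + 1,
                          error_rate = error_rate)
  list(lib = lib, template = tpl, reads = reads)
}
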