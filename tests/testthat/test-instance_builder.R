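test_that("segment_template cuts fixed-length segments with scaled lambda", {
  p <- scoring_params()
  s <- segment_template(2500, 50, p)
  expect_equal(s$starts, c(0, 1000, 2000))
  expect_equal(s$ends, c(1000, 2000, 2500))
  expect_equal(s$lambda, c(20, 20, 10))  # last segment scaled by 500/1000

  s0 <- segment_template(1000, 0, p)
  expect_equal(length(s0$starts), 1L)
  expect_equal(s0$lambda, 0)

  # the scale of the published experiments: 166 segments, lambda = 150
  s166 <- segment_template(166000, 24900, p)
  expect_equal(length(s166$starts), 166L)
  expect_true(all(s166$lambda == 150))

  expect_error(segment_template(0, 10, p), "positive")
})

test_that("lambda sums to the read count for arbitrary lengths", {
  p <- scoring_params()
  set.seed(11)
  for (rep in 1:20) {
    len <- sample(500:5000, 1); n <- sample(0:400, 1)
    s <- segment_template(len, n, p)
    expect_equal(sum(s$lambda), n, tolerance = 1e-9)
    expect_equal(s$ends[length(s$ends)], len)
    expect_true(all(s$ends - s$starts <= p$segment_length))
  }
})

test_that("pair_cost applies the concordant/discordant rules", {
  p <- scoring_params()
  expect_equal(pair_cost(30, 40, TRUE, p), 70)
  expect_equal(pair_cost(30, NA, FALSE, p), 120)   # 30 + 90
  expect_equal(pair_cost(NA, 25, FALSE, p), 115)
  expect_equal(pair_cost(0, 0, TRUE, p), 0)
  expect_true(is.na(pair_cost(NA, NA, FALSE, p)))
  expect_error(pair_cost(30, NA, TRUE, p), "both end costs")
  expect_error(pair_cost(30, 40, FALSE, p), "per end")
})

test_that("build_instance maps placements onto segments correctly", {
  p <- scoring_params()
  s <- segment_template(3000, 1, p)
  # one placement in segment 2 of 3
  ps <- placement_set("r1", data.frame(read = "r1", pos = 1500, cost = 5,
                                       concordant = TRUE))
  inst <- build_instance(ps, s, p)
  expect_equal(nrow(inst$pairs), 1L)
  expect_equal(inst$y_ids[inst$pairs$y], "seg00002")
  expect_equal(inst$pairs$cost, 5)
  # read coverage table is {0: penalty, 1: 0}
  expect_equal(inst$x_tables[[1L]], c(100, 0))
  # segment tables are the quadratic deviation at integer coverages
  expect_equal(inst$y_tables[[2L]], (s$lambda[2L] - (0:1))^2)

  # several placements inside one segment collapse to the minimum cost
  ps2 <- placement_set("r1", data.frame(read = c("r1", "r1"),
                                        pos = c(100, 700), cost = c(7, 3),
                                        concordant = TRUE))
  inst2 <- build_instance(ps2, s, p)
  expect_equal(nrow(inst2$pairs), 1L)
  expect_equal(inst2$pairs$cost, 3)

  # placements in different segments stay distinct candidates, and the
  # read can take at most one of them (coverage 2 is off-table)
  ps3 <- placement_set("r1", data.frame(read = c("r1", "r1"),
                                        pos = c(100, 2400), cost = c(0, 0),
                                        concordant = TRUE))
  inst3 <- build_instance(ps3, s, p)
  expect_equal(nrow(inst3$pairs), 2L)
  sol <- solve_csm(inst3)
  expect_lte(nrow(sol$matching), 1L)

  expect_error(build_instance(
    placement_set("r1", data.frame(read = "r1", pos = 3000, cost = 0,
                                   concordant = TRUE)), s, p),
    "beyond template")
})

test_that("unmapped reads stay in X and lambdas count every read", {
  p <- scoring_params()
  ps <- placement_set(c("r1", "r2", "r3"),
                      data.frame(read = "r2", pos = 10, cost = 4,
                                 concordant = TRUE))
  s <- segment_template(2000, length(ps$read_ids), p)
  inst <- build_instance(ps, s, p)
  expect_setequal(inst$x_ids, c("r1", "r2", "r3"))
  expect_equal(sum(s$lambda), 3)
  sol <- solve_csm(inst)
  # r1 and r3 can only pay the unmatched penalty
  expect_equal(sol$cost,
               matching_cost(inst, sol$matching))
})

test_that("generated coverage tables are convex for any lambda and p >= 1", {
  set.seed(21)
  for (rep in 1:30) {
    lam <- runif(1, 0, 40)
    p <- scoring_params(coverage_exponent = sample(c(1, 1.5, 2, 3), 1),
                        coverage_cost_kind = sample(c("polynomial", "linear"), 1))
    s <- segment_template(1000, rpois(1, lam), p)
    ps <- placement_set("r1", data.frame(read = "r1", pos = 0, cost = 0,
                                         concordant = TRUE))
    inst <- build_instance(ps, s, p)
    expect_true(all(vapply(inst$y_tables, is_convex, logical(1))))
    expect_true(all(vapply(inst$x_tables, is_convex, logical(1))))
  }
})

test_that("build_instance is invariant to placement order", {
  p <- scoring_params()
  set.seed(31)
  pl <- data.frame(read = sample(c("a", "b", "c"), 30, TRUE),
                   pos = sample(0:4999, 30), cost = sample(0:90, 30, TRUE),
                   concordant = TRUE)
  s <- segment_template(5000, 3, p)
  i1 <- build_instance(placement_set(c("a", "b", "c"), pl), s, p)
  shuf <- pl[sample(nrow(pl)), ]
  i2 <- build_instance(placement_set(c("a", "b", "c"), shuf), s, p)
  o1 <- i1$pairs[order(i1$pairs$x, i1$pairs$y), ]
  o2 <- i2$pairs[order(i2$pairs$x, i2$pairs$y), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("flat coverage costs reduce the score to the naive limit", {
  fx <- sim_fixture(seed = 19, coverage = 4)
  ps <- exhaustive_map(fx$reads, fx$template)
  flat <- scoring_params(coverage_cost_kind = "flat")
  sc <- score_template(ps, nchar(fx$template), flat)
  bc <- best_costs(ps)
  expect_equal(sc$sage_score,
               sum(pmin(flat$unmatched_penalty, bc)), tolerance = 1e-9)
})

test_that("load_placements reads SAM records with the documented flags", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:tpl\tLN:5000",
    # concordant pair at POS 101/401 (1-based), costs 30 + 0
    "p1\t99\ttpl\t101\t0\t100M\t=\t401\t0\t*\t*\tXC:i:30\tHI:i:1",
    "p1\t147\ttpl\t401\t0\t100M\t=\t101\t0\t*\t*\tXC:i:0\tHI:i:1",
    # second candidate of the same pair
    "p1\t99\ttpl\t1101\t0\t100M\t=\t1401\t0\t*\t*\tXC:i:60\tHI:i:2",
    "p1\t147\ttpl\t1401\t0\t100M\t=\t1101\t0\t*\t*\tXC:i:30\tHI:i:2",
    # discordant single-end hit of another read
    "p2\t65\ttpl\t2001\t0\t100M\t*\t0\t0\t*\t*\tXC:i:0\tHI:i:1",
    # fully unmapped pair
    "p3\t77\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "p3\t141\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  ps <- load_placements(sam)
  expect_setequal(ps$read_ids, c("p1", "p2", "p3"))
  pl <- ps$placements
  p1 <- pl[ps$read_ids[pl$read] == "p1", ]
  expect_equal(nrow(p1), 2L)                   # two candidate pairs
  expect_setequal(p1$pos, c(100, 1100))        # 0-based first-mate positions
  expect_setequal(p1$cost, c(30, 90))
  expect_true(all(p1$concordant))
  p2 <- pl[ps$read_ids[pl$read] == "p2", ]
  expect_equal(p2$pos, 2000)
  expect_equal(p2$cost, 0 + 90)                # discordant penalty added
  expect_false(p2$concordant)
  expect_equal(sum(ps$read_ids[pl$read] == "p3"), 0L)
  expect_true(is.infinite(best_costs(ps)[match("p3", ps$read_ids)]))
})

test_that("load_placements errors on records without the cost tag", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:tpl\tLN:5000",
    "p1\t65\ttpl\t101\t0\t100M\t*\t0\t0\t*\t*"), sam)
  expect_error(load_placements(sam), "cost tag.*p1")
})

test_that("load_placements restricts to a named template", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:tplA\tLN:5000",
    "@SQ\tSN:tplB\tLN:5000",
    "p1\t65\ttplA\t101\t0\t100M\t*\t0\t0\t*\t*\tXC:i:0\tHI:i:1",
    "p1\t65\ttplB\t201\t0\t100M\t*\t0\t0\t*\t*\tXC:i:0\tHI:i:2"), sam)
  psA <- load_placements(sam, template_id = "tplA")
  expect_equal(nrow(psA$placements), 1L)
  expect_equal(psA$placements$pos, 100)
  # no restriction: both references concatenated in header order
  ps <- load_placements(sam)
  expect_setequal(ps$placements$pos, c(100, 5000 + 200))
  expect_error(load_placements(sam, template_id = "nope"), "not in SAM header")
})

test_that("parameter files round-trip and reject unknown keys", {
  p <- scoring_params(segment_length = 500, unmatched_penalty = 80,
                      coverage_cost_kind = "linear", coverage_exponent = 1)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params_file(p, path)
  q <- read_params_file(path)
  expect_equal(q$segment_length, 500L)
  expect_equal(q$unmatched_penalty, 80)
  expect_equal(q$coverage_cost_kind, "linear")
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("not_a_key = 5", bad)
  expect_error(read_params_file(bad), "unknown parameter key.*not_a_key")
  expect_error(scoring_params(coverage_exponent = 0.5))
  expect_error(scoring_params(segment_length = 0))
})
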