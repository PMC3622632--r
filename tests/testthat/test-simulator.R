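test_that("block libraries hit the pairwise identity target", {
  lib <- make_block_library(4, c(3000, 3000), 0.90, seed = 5)
  pid <- pairwise_identity(lib)
  expect_gte(pid, 0.87)
  expect_lte(pid, 0.93)
  # identity 1: all blocks equal the ancestor
  lib1 <- make_block_library(3, c(1000, 1000), 1.0, seed = 5)
  expect_true(all(lib1$blocks == lib1$ancestor))
  expect_error(make_block_library(3, identity = 0.4), "identity")
})

test_that("libraries and read sets are deterministic in the seed", {
  a <- make_block_library(3, c(2000, 2500), 0.9, seed = 77)
  b <- make_block_library(3, c(2000, 2500), 0.9, seed = 77)
  expect_identical(a$blocks, b$blocks)
  tpl <- render_haplotype(haplotype_architecture(c("B1", "B2"), 100), a)
  r1 <- simulate_reads(tpl, 4, seed = 9)
  r2 <- simulate_reads(tpl, 4, seed = 9)
  expect_identical(r1$end1, r2$end1)
  expect_identical(r1$pos, r2$pos)
  r3 <- simulate_reads(tpl, 4, seed = 10)
  expect_false(identical(r1$pos, r3$pos))
})

test_that("render_haplotype concatenates blocks and spacers exactly", {
  lib <- make_block_library(3, c(1500, 1500), 0.95, seed = 3)
  arch <- haplotype_architecture(c("B1", "B2"), spacers = 100)
  seq2 <- render_haplotype(arch, lib)
  expect_equal(nchar(seq2), 2 * 1500 + 3 * 100)
  # copy number: repeating a block lengthens by block + one spacer
  arch3 <- haplotype_architecture(c("B1", "B2", "B2"), spacers = 100)
  expect_equal(nchar(render_haplotype(arch3, lib)),
               nchar(seq2) + 1500 + 100)
  expect_error(render_haplotype(haplotype_architecture("Bx"), lib),
               "unknown block")
  # diploid use: concatenating two rendered haplotypes
  dip <- paste0(seq2, render_haplotype(arch3, lib))
  expect_equal(nchar(dip), nchar(seq2) + 3 * 1500 + 4 * 100)
})

test_that("simulate_reads emulates the paired-end protocol", {
  lib <- make_block_library(2, c(4000, 4000), 0.95, seed = 13)
  tpl <- render_haplotype(haplotype_architecture(c("B1", "B2"), 200), lib)
  # error-free ends are exact substrings at their recorded positions
  r0 <- simulate_reads(tpl, 5, seed = 2, error_rate = 0)
  expect_true(all(substring(tpl, r0$pos + 1, r0$pos + 100) == r0$end1))
  mate <- substring(tpl, r0$pos + r0$insert - 99, r0$pos + r0$insert)
  expect_true(all(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r0$end2))) == mate))
  # pair count is Poisson around coverage * len / (2 * read_length)
  r30 <- simulate_reads(tpl, 30, seed = 4)
  expected <- 30 * nchar(tpl) / 200
  expect_lt(abs(length(r30$read_ids) - expected), 5 * sqrt(expected))
  # measured error rate close to the requested one
  truth1 <- substring(tpl, r30$pos + 1, r30$pos + 100)
  nm <- mapply(function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]),
               r30$end1, truth1)
  rate <- sum(nm) / (100 * length(nm))
  expect_lt(abs(rate - 0.005), 4 * sqrt(0.005 / (100 * length(nm))))
  expect_error(simulate_reads(strrep("A", 150), 5), "shorter than")
})

test_that("exhaustive_map finds exactly the low-Hamming placements", {
  lib <- make_block_library(2, c(1500, 1500), 0.8, seed = 31)
  tpl <- render_haplotype(haplotype_architecture(c("B1", "B2"), 150), lib)
  r <- simulate_reads(tpl, 3, seed = 6, error_rate = 0)
  ps <- exhaustive_map(r, tpl)
  # error-free reads from a near-unique region: one cost-0 placement each
  bc <- best_costs(ps)
  expect_true(all(bc == 0))
  # duplicated block at identity 1: every block read gets >= 2 zero-cost
  # placements
  lib1 <- make_block_library(2, c(1500, 1500), 1.0, seed = 31)
  tpl2 <- render_haplotype(haplotype_architecture(c("B1", "B1"), 150), lib1)
  r2 <- simulate_reads(tpl2, 3, seed = 8, error_rate = 0)
  ps2 <- exhaustive_map(r2, tpl2)
  # pairs whose whole insert lies inside one block copy (period 1650,
  # block span [150, 1650) within each period)
  off <- r2$pos %% (1500 + 150)
  in_block <- off >= 150 & (off + r2$insert) <= 1650
  counts <- table(factor(ps2$placements$read[ps2$placements$cost == 0],
                         levels = seq_along(r2$read_ids)))
  expect_true(all(counts[in_block] >= 2))
})

test_that("planted mismatches cost mismatch_cost each at the true position", {
  lib <- make_block_library(1, c(2000, 2000), 1, seed = 17)
  tpl <- lib$blocks[["B1"]]
  r <- simulate_reads(tpl, 2, seed = 12, error_rate = 0)
  # plant 2 substitutions in the first read's first end
  ch <- strsplit(r$end1[1L], "")[[1L]]
  for (i in c(10, 50)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1L]
  r$end1[1L] <- paste(ch, collapse = "")
  ps <- exhaustive_map(r, tpl)
  own <- ps$placements[ps$placements$read == 1L &
                         ps$placements$pos == r$pos[1L], ]
  expect_equal(min(own$cost), 60)  # 2 * 30, concordant mate error-free
})

test_that("the seed-and-extend mapper agrees with a full Hamming scan", {
  set.seed(91)
  lib <- make_block_library(2, c(800, 800), 0.92, seed = 91)
  tpl <- render_haplotype(haplotype_architecture(c("B1", "B2"), 100), lib)
  r <- simulate_reads(tpl, 4, seed = 14, error_rate = 0.02)
  n <- min(25L, length(r$read_ids))
  hits <- sagescore:::hamming_hits(r$end1[seq_len(n)], tpl, 3L)
  for (i in seq_len(n)) {
    mine <- hits[hits$end == i, c("strand", "pos", "nmis")]
    rownames(mine) <- NULL
    ref <- scan_hamming(r$end1[i], tpl, 3L)
    rownames(ref) <- NULL
    expect_equal(mine, ref, info = paste("read", i))
  }
})

test_that("round trip at zero error: truth is recoverable", {
  # unique blocks (low identity), no errors: the optimal matching puts
  # nearly every read in its true segment
  lib <- make_block_library(3, c(2000, 2000), 0.75, seed = 55)
  tpl <- render_haplotype(haplotype_architecture(c("B1", "B2", "B3"), 150), lib)
  r <- simulate_reads(tpl, 8, seed = 16, error_rate = 0)
  ps <- exhaustive_map(r, tpl)
  expect_true(all(best_costs(ps) == 0))
  p <- scoring_params()
  seg <- segment_template(nchar(tpl), length(r$read_ids), p)
  sol <- solve_csm(build_instance(ps, seg, p))
  true_seg <- findInterval(r$pos, seg$starts)
  matched_seg <- match(sol$matching$y, sprintf("seg%05d", seq_along(seg$starts)))
  got <- matched_seg[match(r$read_ids, sol$matching$x)]
  expect_gte(mean(got == true_seg, na.rm = TRUE), 0.99)
  # the optimum can only improve on the truth's own coverage cost
  true_counts <- tabulate(true_seg, nbins = length(seg$starts))
  expect_lte(sol$cost, sum((seg$lambda - true_counts)^2) + 1e-9)
})

test_that("mapper placement costs respect the documented ranges", {
  # concordant pairs: 0..180 (two ends, <= 3 mismatches at 30 each);
  # discordant single ends: surcharge 90 plus 0..90
  fx <- sim_fixture(seed = 47, coverage = 10, error_rate = 0.01)
  ps <- exhaustive_map(fx$reads, fx$template)
  conc <- ps$placements[ps$placements$concordant, ]
  disc <- ps$placements[!ps$placements$concordant, ]
  expect_true(all(conc$cost >= 0 & conc$cost <= 180))
  expect_true(all(conc$cost %% 30 == 0))
  expect_true(all(disc$cost >= 90 & disc$cost <= 180))
  expect_true(all(ps$placements$pos >= 0 &
                    ps$placements$pos < nchar(fx$template)))
})

test_that("FASTA/FASTQ/truth outputs are well-formed", {
  lib <- make_block_library(2, c(1000, 1000), 0.9, seed = 61)
  tpl <- render_haplotype(haplotype_architecture(c("B1", "B2"), 100), lib)
  r <- simulate_reads(tpl, 2, seed = 18)
  dir <- withr::local_tempdir()
  write_fasta(c(tpl = tpl), file.path(dir, "t.fa"))
  back <- Biostrings::readDNAStringSet(file.path(dir, "t.fa"))
  expect_equal(as.character(back[[1L]]), tpl)
  write_fastq(r, file.path(dir, "reads"))
  fq1 <- readLines(file.path(dir, "reads_1.fastq"))
  fq2 <- readLines(file.path(dir, "reads_2.fastq"))
  expect_equal(length(fq1), 4 * length(r$read_ids))
  expect_equal(length(fq2), 4 * length(r$read_ids))
  expect_true(all(grepl("/1$", fq1[seq(1, length(fq1), 4)])))
  write_truth_tsv(r, file.path(dir, "truth.tsv"))
  tr <- read.delim(file.path(dir, "truth.tsv"), comment.char = "#")
  expect_equal(tr$read_id, r$read_ids)
  expect_equal(tr$true_pos, as.integer(r$pos))
})
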