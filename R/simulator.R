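DNA <- c("A", "C", "G", "T")

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

# substitute each position independently with probability `rate`, always
# to a different base
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit) > 0L) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    ch[hit] <- DNA[(match(ch[hit], DNA) - 1L + shift) %% 4L + 1L]
  }
  paste(ch, collapse = "")
}

#' Generate a library of mutually similar sequence blocks
#'
#' Emulates the multi-copy gene blocks of KIR-like regions: all blocks
#' are copies of a common random ancestor, independently mutated so
#' that the expected pairwise identity hits the target. For a per-copy
#' substitution rate `mu`, two copies agree at a site with probability
#' `(1 - mu)^2 + mu^2 / 3`; `mu` is solved from that relation.
#'
#' @param n_blocks Number of blocks.
#' @param length_range Block length range in bases (one length is drawn
#'   for the whole library so blocks stay alignable on the ancestor
#'   frame); default 4--16 kb.
#' @param identity Target pairwise identity in (0.5, 1].
#' @param seed RNG seed; the library is fully deterministic given it.
#' @return Object of class `block_library`: list with `blocks` (named
#'   character vector `B1..`), `ancestor`, `block_length`, `identity`,
#'   `mu`, `spacer_pool`, `seed`.
#' @export
make_block_library <- function(n_blocks, length_range = c(4000L, 16000L),
                               identity = 0.90, seed = 1L) {
  if (identity <= 0.5 || identity > 1)
    stop("target identity must be in (0.5, 1]")
  disc <- 4 - 16 * (1 - identity) / 3
  if (disc < 0) stop("infeasible identity target")
  mu <- (2 - sqrt(disc)) / (8 / 3)
  with_seed(seed, {
    len <- if (length_range[1L] == length_range[2L]) length_range[1L]
    else sample(length_range[1L]:length_range[2L], 1L)
    ancestor <- random_dna(len)
    blocks <- vapply(seq_len(n_blocks), function(i) mutate_seq(ancestor, mu),
                     character(1))
    names(blocks) <- paste0("B", seq_len(n_blocks))
    spacer_pool <- random_dna(20000L)
    structure(list(blocks = blocks, ancestor = ancestor, block_length = len,
                   identity = identity, mu = mu, spacer_pool = spacer_pool,
                   seed = seed),
              class = "block_library")
  })
}

#' @export
print.block_library <- function(x, ...) {
  cat("<block_library ", length(x$blocks), " blocks x ", x$block_length,
      " bp, target identity ", x$identity, ">\n", sep = "")
  invisible(x)
}

#' Mean pairwise identity of a block library
#'
#' Hamming identity on the shared ancestor frame, averaged over all
#' block pairs.
#'
#' @param lib A [make_block_library()] result.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(lib) {
  mats <- lapply(lib$blocks, function(s) strsplit(s, "")[[1L]])
  n <- length(mats)
  if (n < 2L) return(1)
  tot <- 0; k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + mean(mats[[i]] == mats[[j]]); k <- k + 1L
  }
  tot / k
}

#' Describe a haplotype as an ordered block architecture
#'
#' @param block_ids Ordered character vector of block ids (repeats
#'   allowed: copy number variation).
#' @param spacers Intergenic/flanking spacer lengths in bases: a vector
#'   of `length(block_ids) + 1` (leading flank, between blocks,
#'   trailing flank), or one value recycled.
#' @return Object of class `haplotype_architecture`.
#' @export
haplotype_architecture <- function(block_ids, spacers = 200L) {
  block_ids <- as.character(block_ids)
  spacers <- as.integer(rep_len(spacers, length(block_ids) + 1L))
  if (any(spacers < 0L)) stop("spacer lengths must be nonnegative")
  structure(list(block_ids = block_ids, spacers = spacers),
            class = "haplotype_architecture")
}

#' Render a haplotype sequence from an architecture and block library
#'
#' Deterministic concatenation: spacer sequences are cut from the
#' library's fixed spacer pool, so the same architecture and library
#' always render byte-identical sequence of length
#' `sum(block lengths) + sum(spacers)`.
#'
#' @param arch A [haplotype_architecture()].
#' @param lib A [make_block_library()] result.
#' @return A single character string.
#' @export
render_haplotype <- function(arch, lib) {
  unknown <- setdiff(arch$block_ids, names(lib$blocks))
  if (length(unknown) > 0L)
    stop("unknown block id(s): ", paste(unknown, collapse = ", "))
  pool <- lib$spacer_pool
  cut_spacer <- function(off, n) {
    if (n == 0L) return("")
    idx <- ((off + seq_len(n) - 1L) %% nchar(pool)) + 1L
    paste(substring(pool, idx, idx), collapse = "")
  }
  pieces <- character(2L * length(arch$block_ids) + 1L)
  off <- 0L
  for (k in seq_along(arch$block_ids)) {
    pieces[2L * k - 1L] <- cut_spacer(off, arch$spacers[k])
    off <- off + arch$spacers[k]
    pieces[2L * k] <- lib$blocks[[arch$block_ids[k]]]
  }
  pieces[2L * length(arch$block_ids) + 1L] <-
    cut_spacer(off, arch$spacers[length(arch$spacers)])
  paste(pieces, collapse = "")
}

#' Simulate paired-end reads with substitution errors
#'
#' Pair start positions are uniform over the template given the insert
#' size, insert sizes are normal (`insert_mean`, `insert_sd`) truncated
#' to `mean +/- 4 sd` and to what the template accommodates, the second
#' end is reverse-complemented, and each base is substituted
#' independently at `error_rate`. True positions are recorded for
#' later evaluation. The number of pairs is Poisson with mean
#' `coverage * length / (2 * read_length)`.
#'
#' @param template Template sequence (character string).
#' @param coverage Target mean base coverage.
#' @param seed RNG seed; output is deterministic given it.
#' @param params A [scoring_params()] (read length, insert
#'   distribution).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param template_id Recorded in the result.
#' @return Object of class `read_set`: list with `read_ids`, `end1`,
#'   `end2` (character vectors), `pos` (0-based true pair start),
#'   `insert`, plus the simulation settings.
#' @export
simulate_reads <- function(template, coverage, seed = 1L,
                           params = scoring_params(), error_rate = 0.005,
                           template_id = "template") {
  len <- nchar(template)
  rl <- params$read_length
  ins_lo <- max(2 * rl, round(params$insert_mean - 4 * params$insert_sd))
  ins_hi <- min(len, round(params$insert_mean + 4 * params$insert_sd))
  if (ins_lo > ins_hi || len < ins_lo)
    stop("template shorter than the minimum insert size")
  with_seed(seed, {
    n <- stats::rpois(1L, coverage * len / (2 * rl))
    insert <- if (n > 0L)
      pmin(pmax(round(stats::rnorm(n, params$insert_mean,
                                   params$insert_sd)), ins_lo), ins_hi)
    else integer(0)
    pos <- vapply(insert, function(i) sample.int(len - i + 1L, 1L) - 1L,
                  numeric(1))
    end1 <- if (n > 0L) substring(template, pos + 1, pos + rl) else character(0)
    mate <- if (n > 0L) substring(template, pos + insert - rl + 1, pos + insert)
            else character(0)
    end2 <- if (n > 0L) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(mate))) else character(0)
    if (error_rate > 0 && n > 0L) {
      end1 <- vapply(end1, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
      end2 <- vapply(end2, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
    }
    structure(list(read_ids = sprintf("read%06d", seq_len(n)),
                   end1 = end1, end2 = end2, pos = pos, insert = insert,
                   template_id = template_id, read_length = rl,
                   error_rate = error_rate, coverage = coverage, seed = seed),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set ", length(x$read_ids), " pairs of ", x$read_length,
      " bp from '", x$template_id, "'>\n", sep = "")
  invisible(x)
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# all template positions (either strand) where `ends` align with at most
# k mismatches: pigeonhole seed-and-extend. Splitting a read into k+1
# disjoint seeds guarantees one exact seed for any alignment with <= k
# mismatches; seed hits are verified by a vectorized mismatch count on
# character matrices. Returns a flat data.frame (end, strand, pos,
# nmis) with 0-based positions; strand +1 means the end matches the
# template forward, -1 its reverse complement.
hamming_hits <- function(ends, template, k) {
  subject <- Biostrings::DNAString(template)
  empty <- data.frame(end = integer(), strand = integer(),
                      pos = integer(), nmis = integer())
  npat <- length(ends)
  if (npat == 0L) return(empty)
  rl <- unique(nchar(ends))
  if (length(rl) != 1L) stop("reads must have a single length")
  w <- rl %/% (k + 1L)
  offs <- (0:k) * w
  pats <- c(Biostrings::DNAStringSet(ends),
            Biostrings::reverseComplement(Biostrings::DNAStringSet(ends)))
  seeds <- do.call(c, lapply(offs, function(o)
    Biostrings::subseq(pats, start = o + 1L, width = w)))
  st <- Biostrings::startIndex(Biostrings::matchPDict(
    Biostrings::PDict(seeds), subject))
  maxstart <- nchar(template) - rl + 1L
  hits <- unlist(st, use.names = FALSE)
  if (length(hits) == 0L) return(empty)
  sidx <- rep(seq_along(st), lengths(st))
  j <- (sidx - 1L) %% (2L * npat) + 1L
  cand <- hits - offs[(sidx - 1L) %/% (2L * npat) + 1L]
  ok <- cand >= 1L & cand <= maxstart
  j <- j[ok]; cand <- cand[ok]
  if (length(j) == 0L) return(empty)
  dup <- duplicated((as.numeric(j) - 1) * maxstart + cand)
  j <- j[!dup]; cand <- cand[!dup]
  # suppressWarnings: Biostrings warns about a long-changed as.matrix
  # behaviour for XStringViews; the char-matrix form is what we want
  m_t <- suppressWarnings(
    as.matrix(Biostrings::Views(subject, start = cand, width = rl)))
  m_p <- as.matrix(pats[j])
  nmis <- as.integer(rowSums(m_t != m_p))
  keep <- nmis <= k
  if (!any(keep)) return(empty)
  df <- data.frame(end = (j[keep] - 1L) %% npat + 1L,
                   strand = ifelse(j[keep] <= npat, 1L, -1L),
                   pos = cand[keep] - 1L, nmis = nmis[keep])
  df[order(df$end, -df$strand, df$pos), , drop = FALSE]
}

#' Exhaustively map simulated reads back to a template
#'
#' Stand-in for an all-alignments mapper: reports, for each end and
#' both strands, every template position with at most
#' `max_mismatches_per_end` mismatches, costing `mismatch_cost` per
#' mismatch. Opposite-orientation end hits whose implied insert lies
#' within `insert_mean +/- 4 * insert_sd` are combined into concordant
#' per-pair placements (position = leftmost aligned base of the first
#' mate, cost = sum of end costs); end hits in no concordant
#' combination become discordant placements at their own position with
#' the discordant penalty added. Reads with no hits at all are retained
#' with empty placements.
#'
#' @param reads A [simulate_reads()] result.
#' @param template Template sequence (character string).
#' @param params A [scoring_params()].
#' @param sam_path If non-`NULL`, also write the candidate alignments
#'   as SAM (per-end records, cost tag `XC`, `HI`-linked mates).
#' @param template_id Reference name used in the SAM output.
#' @return A [placement_set()].
#' @export
exhaustive_map <- function(reads, template, params = scoring_params(),
                           sam_path = NULL, template_id = "template") {
  n <- length(reads$read_ids)
  k <- params$max_mismatches_per_end
  if (k > 4L) stop("max_mismatches_per_end above 4 is intractable here")
  if (n == 0L) {
    ps <- placement_set(character(), NULL)
    if (!is.null(sam_path))
      write_sam(sam_path, template_id, nchar(template), reads,
                conc = NULL, d1 = NULL, d2 = NULL)
    return(ps)
  }
  h1 <- hamming_hits(reads$end1, template, k)
  h2 <- hamming_hits(reads$end2, template, k)
  rl <- reads$read_length
  lo <- params$insert_mean - 4 * params$insert_sd
  hi <- params$insert_mean + 4 * params$insert_sd

  # concordant combinations: all within-read hit pairs with opposing
  # orientation and an implied insert inside the window
  h1$rid <- seq_len(nrow(h1)); h2$rid <- seq_len(nrow(h2))
  cross <- merge(h1, h2, by = "end", suffixes = c("1", "2"))
  ins <- ifelse(cross$strand1 == 1L,
                cross$pos2 + rl - cross$pos1,
                cross$pos1 + rl - cross$pos2)
  ok <- cross$strand1 != cross$strand2 & ins >= lo & ins <= hi
  conc <- cross[ok, , drop = FALSE]
  used1 <- h1$rid %in% conc$rid1
  used2 <- h2$rid %in% conc$rid2
  d1 <- h1[!used1, , drop = FALSE]
  d2 <- h2[!used2, , drop = FALSE]

  placements <- rbind(
    if (nrow(conc) > 0L)
      data.frame(read = conc$end, pos = conc$pos1,
                 cost = params$mismatch_cost * (conc$nmis1 + conc$nmis2),
                 concordant = TRUE),
    if (nrow(d1) > 0L)
      data.frame(read = d1$end, pos = d1$pos,
                 cost = params$mismatch_cost * d1$nmis + params$discordant_penalty,
                 concordant = FALSE),
    if (nrow(d2) > 0L)
      data.frame(read = d2$end, pos = d2$pos,
                 cost = params$mismatch_cost * d2$nmis + params$discordant_penalty,
                 concordant = FALSE))
  if (is.null(placements))
    placements <- data.frame(read = integer(), pos = numeric(),
                             cost = numeric(), concordant = logical())
  rownames(placements) <- NULL
  if (!is.null(sam_path))
    write_sam(sam_path, template_id, nchar(template), reads,
              conc = conc, d1 = d1, d2 = d2,
              mismatch_cost = params$mismatch_cost, read_length = rl)
  placement_set(reads$read_ids, placements)
}

# SAM writer for the internal mapper's candidate alignments. Per-end
# records with the per-end cost in the XC tag; concordant candidates
# get the proper-pair flag and HI-linked mate records; leftover end
# hits become unpaired-in-pair records; fully unmapped pairs are kept
# as unmapped records so downstream readers see the whole read
# registry. `conc` has columns end/pos1/pos2/strand1/nmis1/nmis2,
# `d1`/`d2` columns end/pos/strand/nmis (0-based positions).
write_sam <- function(path, template_id, template_length, reads,
                      conc, d1, d2, mismatch_cost = 30, read_length = 100L) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", template_id, "\tLN:", template_length),
               "@PG\tID:sagescore\tPN:sagescore-exhaustive-map"), con)
  mk <- function(df) if (is.null(df) || nrow(df) == 0L) NULL else df
  conc <- mk(conc); d1 <- mk(d1); d2 <- mk(d2)
  ev_read <- c(conc$end, d1$end, d2$end)
  hi <- integer(length(ev_read))
  if (length(ev_read) > 0L) {
    o <- order(ev_read)
    hi[o] <- sequence(rle(ev_read[o])$lengths)
  }
  out <- character(0)
  nc <- NROW(conc)
  if (nc > 0L) {
    hic <- hi[seq_len(nc)]
    qn <- reads$read_ids[conc$end]
    f1 <- 1L + 2L + 64L + ifelse(conc$strand1 == -1L, 16L, 32L)
    f2 <- 1L + 2L + 128L + ifelse(conc$strand1 == -1L, 32L, 16L)
    out <- c(out,
      sprintf("%s\t%d\t%s\t%d\t0\t%dM\t=\t%d\t0\t*\t*\tXC:i:%d\tHI:i:%d",
              qn, f1, template_id, conc$pos1 + 1L, read_length,
              conc$pos2 + 1L, mismatch_cost * conc$nmis1, hic),
      sprintf("%s\t%d\t%s\t%d\t0\t%dM\t=\t%d\t0\t*\t*\tXC:i:%d\tHI:i:%d",
              qn, f2, template_id, conc$pos2 + 1L, read_length,
              conc$pos1 + 1L, mismatch_cost * conc$nmis2, hic))
  }
  emit_disc <- function(df, hvals, mate_flag) {
    if (is.null(df)) return(character(0))
    f <- 1L + mate_flag + ifelse(df$strand == -1L, 16L, 0L)
    sprintf("%s\t%d\t%s\t%d\t0\t%dM\t*\t0\t0\t*\t*\tXC:i:%d\tHI:i:%d",
            reads$read_ids[df$end], f, template_id, df$pos + 1L,
            read_length, mismatch_cost * df$nmis, hvals)
  }
  out <- c(out,
           emit_disc(d1, hi[nc + seq_len(NROW(d1))], 64L),
           emit_disc(d2, hi[nc + NROW(d1) + seq_len(NROW(d2))], 128L))
  unmapped <- setdiff(seq_along(reads$read_ids), ev_read)
  if (length(unmapped) > 0L) {
    qn <- reads$read_ids[unmapped]
    out <- c(out,
      sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*", qn, 1L + 4L + 8L + 64L),
      sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*", qn, 1L + 4L + 8L + 128L))
  }
  writeLines(out, con)
  invisible(path)
}

#' Write templates as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  xs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Write a read set as a FASTQ pair
#'
#' Files `<prefix>_1.fastq` / `<prefix>_2.fastq` with `/1` `/2` read
#' name suffixes and constant placeholder qualities.
#'
#' @param reads A [simulate_reads()] result.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (e in 1:2) {
    seqs <- if (e == 1L) reads$end1 else reads$end2
    con <- file(paths[e], "w")
    if (length(seqs) > 0L) {
      q <- strrep("I", nchar(seqs))
      writeLines(paste0("@", reads$read_ids, "/", e, "\n", seqs, "\n+\n", q),
                 con)
    }
    close(con)
  }
  invisible(paths)
}

#' Write the simulation truth table as TSV
#'
#' @param reads A [simulate_reads()] result.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# template: ", reads$template_id),
               paste0("# seed: ", reads$seed),
               "read_id\ttrue_pos\tinsert"), con)
  if (length(reads$read_ids) > 0L)
    writeLines(sprintf("%s\t%d\t%d", reads$read_ids,
                       as.integer(reads$pos), as.integer(reads$insert)), con)
  invisible(path)
}
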