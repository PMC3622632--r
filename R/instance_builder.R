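#' Scoring parameters
#'
#' Bundles every tunable of the read-to-template scoring pipeline with
#' the defaults used throughout: templates are cut into 1000 bp
#' segments, an unplaced read pays 100, a read end without a concordant
#' mate pays an extra 90 (the maximum cost of one 100 bp end at 3
#' mismatches x 30), and segment coverage deviations are charged
#' quadratically around the expected coverage.
#'
#' @param segment_length Segment size in bases (default 1000).
#' @param unmatched_penalty Cost of leaving a read unmatched
#'   (default 100).
#' @param discordant_penalty Extra cost for an end without a concordant
#'   mate (default 90).
#' @param coverage_cost_kind One of `"polynomial"`, `"linear"`,
#'   `"flat"`; `"flat"` (all-zero segment costs) exists as a test hook
#'   that reduces the score to the naive per-read limit.
#' @param coverage_exponent Exponent `p` of the polynomial kind,
#'   `f(i) = |lambda - i|^p` (default 2; must be >= 1 for convexity).
#' @param expected_coverage Optional per-segment expected-coverage
#'   override (vector recycled across segments); default derives
#'   `lambda = segment_length * n_reads / template_length`.
#' @param mismatch_cost Alignment cost per mismatch used by the internal
#'   mapper (default 30).
#' @param max_mismatches_per_end Mapper mismatch ceiling per 100 bp end
#'   (default 3, giving the 0--180 per-pair cost range).
#' @param read_length Read end length in bases (default 100).
#' @param insert_mean,insert_sd Insert size distribution; concordance
#'   requires opposing orientations and an implied insert within
#'   `insert_mean +/- 4 * insert_sd`.
#' @param cost_tag SAM tag holding the per-end alignment cost
#'   (default `"XC"`).
#' @return Object of class `scoring_params`.
#' @export
scoring_params <- function(segment_length = 1000L,
                           unmatched_penalty = 100,
                           discordant_penalty = 90,
                           coverage_cost_kind = c("polynomial", "linear", "flat"),
                           coverage_exponent = 2,
                           expected_coverage = NULL,
                           mismatch_cost = 30,
                           max_mismatches_per_end = 3L,
                           read_length = 100L,
                           insert_mean = 400,
                           insert_sd = 40,
                           cost_tag = "XC") {
  coverage_cost_kind <- match.arg(coverage_cost_kind)
  segment_length <- as.integer(segment_length)
  stopifnot(segment_length >= 1L, unmatched_penalty >= 0,
            discordant_penalty >= 0, coverage_exponent >= 1,
            mismatch_cost >= 0, max_mismatches_per_end >= 0L,
            read_length >= 1L, insert_mean > 0, insert_sd >= 0)
  structure(list(segment_length = segment_length,
                 unmatched_penalty = unmatched_penalty,
                 discordant_penalty = discordant_penalty,
                 coverage_cost_kind = coverage_cost_kind,
                 coverage_exponent = coverage_exponent,
                 expected_coverage = expected_coverage,
                 mismatch_cost = mismatch_cost,
                 max_mismatches_per_end = as.integer(max_mismatches_per_end),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 cost_tag = cost_tag),
            class = "scoring_params")
}

#' Partition a template into fixed-length segments
#'
#' Cuts `[0, template_length)` into consecutive `segment_length` bp
#' segments (the last may be shorter) and attaches to each its expected
#' coverage `lambda = width * n_reads / template_length`, so the
#' lambdas sum exactly to the number of reads.
#'
#' @param template_length Template length in bases.
#' @param n_reads Number of read (pairs) in the read set.
#' @param params A [scoring_params()].
#' @return Object of class `segmentation`: list with 0-based `starts`,
#'   `ends` (half-open) and `lambda`.
#' @export
segment_template <- function(template_length, n_reads, params = scoring_params()) {
  template_length <- as.numeric(template_length)
  if (length(template_length) != 1L || !is.finite(template_length) ||
      template_length < 1)
    stop("template_length must be a positive number of bases")
  if (n_reads < 0) stop("n_reads must be nonnegative")
  starts <- seq(0, template_length - 1, by = params$segment_length)
  ends <- pmin(starts + params$segment_length, template_length)
  lambda <- (ends - starts) * n_reads / template_length
  if (!is.null(params$expected_coverage))
    lambda <- rep_len(as.numeric(params$expected_coverage), length(starts))
  structure(list(template_length = template_length, starts = starts,
                 ends = ends, lambda = lambda),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation ", length(x$starts), " segments over ",
      x$template_length, " bp>\n", sep = "")
  invisible(x)
}

#' Combine per-end alignment costs into a per-pair placement cost
#'
#' Concordantly mapped mates simply add their end costs. An end whose
#' mate is absent (or not concordantly placeable) pays its own cost
#' plus the discordant penalty. A pair with neither end mapped has no
#' placement at all (`NA`); such a read can only contribute the
#' unmatched penalty.
#'
#' @param end1_cost,end2_cost Per-end costs; `NA` means the end did not
#'   map.
#' @param concordant Logical; whether the two ends form a concordant
#'   pair.
#' @param params A [scoring_params()].
#' @return Numeric cost, or `NA` if no end mapped.
#' @export
pair_cost <- function(end1_cost, end2_cost, concordant, params = scoring_params()) {
  has1 <- !is.na(end1_cost); has2 <- !is.na(end2_cost)
  if (concordant) {
    if (!has1 || !has2) stop("a concordant placement needs both end costs")
    return(end1_cost + end2_cost)
  }
  if (has1 && has2)
    stop("discordant placements are per end; call once per mapped end")
  if (!has1 && !has2) return(NA_real_)
  (if (has1) end1_cost else end2_cost) + params$discordant_penalty
}

#' Candidate placements of a read set
#'
#' Container pairing the full read registry (every read, mapped or not)
#' with a table of candidate placements. `pos` is the 0-based template
#' coordinate of the leftmost aligned base of the first mate (or of the
#' mapped end, for discordant single-end placements).
#'
#' @param read_ids Character vector: every read in the set.
#' @param placements `data.frame` with columns `read` (id or index into
#'   `read_ids`), `pos`, `cost`, `concordant`.
#' @return Object of class `placement_set`.
#' @export
placement_set <- function(read_ids, placements) {
  read_ids <- as.character(read_ids)
  if (anyDuplicated(read_ids)) stop("duplicate read ids")
  placements <- as.data.frame(placements)
  if (nrow(placements) == 0L) {
    placements <- data.frame(read = integer(), pos = numeric(),
                             cost = numeric(), concordant = logical())
  } else {
    ri <- if (is.character(placements$read) || is.factor(placements$read))
      match(as.character(placements$read), read_ids)
    else as.integer(placements$read)
    if (anyNA(ri) || any(ri < 1L) || any(ri > length(read_ids)))
      stop("placement references unknown read")
    if (any(placements$cost < 0) || any(placements$pos < 0))
      stop("placement positions and costs must be nonnegative")
    placements <- data.frame(read = ri, pos = as.numeric(placements$pos),
                             cost = as.numeric(placements$cost),
                             concordant = as.logical(placements$concordant))
  }
  structure(list(read_ids = read_ids, placements = placements),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat("<placement_set ", length(x$read_ids), " reads, ",
      nrow(x$placements), " candidate placements>\n", sep = "")
  invisible(x)
}

#' Best (minimum) placement cost per read
#'
#' @param ps A [placement_set()].
#' @return Numeric vector over `read_ids`; `Inf` for reads without any
#'   placement.
#' @export
best_costs <- function(ps) {
  out <- rep(Inf, length(ps$read_ids))
  if (nrow(ps$placements) > 0L) {
    agg <- tapply(ps$placements$cost, ps$placements$read, min)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Load candidate placements from SAM/BAM
#'
#' Reads an all-alignments mapping (one record per candidate placement
#' of each end, per-end cost in the `cost_tag` tag, candidates of one
#' read linked by the `HI` tag) and reconstructs per-pair placements:
#' proper-pair records contribute one concordant placement at the
#' first mate's position with the two end costs summed; mapped records
#' outside a proper pair each contribute one discordant placement with
#' the discordant penalty added. Unmapped reads are retained with no
#' placements. SAM input is converted on the fly via
#' [Rsamtools::asBam()]. With multiple references the records are
#' projected onto the concatenation of the reference sequences in
#' header order (used for diploid templates).
#'
#' @param path SAM or BAM file.
#' @param template_id Optional reference name to restrict to.
#' @param params A [scoring_params()].
#' @return A [placement_set()].
#' @export
load_placements <- function(path, template_id = NULL, params = scoring_params()) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
  if (!is.null(template_id)) {
    if (!template_id %in% names(hdr))
      stop("template '", template_id, "' not in SAM header")
    hdr <- hdr[template_id]
  }
  offsets <- c(0, cumsum(as.numeric(hdr)))[seq_along(hdr)]
  names(offsets) <- names(hdr)

  b <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos"),
      tag = c(params$cost_tag, "HI")))[[1L]]
  qname <- b$qname
  flag <- b$flag
  costs <- b$tag[[params$cost_tag]]
  if (is.null(costs)) costs <- rep(NA_real_, length(qname))
  hi <- b$tag[["HI"]]
  if (is.null(hi)) hi <- rep(1L, length(qname))
  read_ids <- sort(unique(qname))

  mapped <- bitwAnd(flag, 4L) == 0L
  if (!is.null(template_id))
    mapped <- mapped & as.character(b$rname) == template_id
  if (any(mapped & (is.na(costs) | is.null(costs))))
    stop("record without cost tag ", params$cost_tag, ": read '",
         qname[which(mapped & is.na(costs))[1L]], "'")
  gpos <- offsets[as.character(b$rname)] + b$pos - 1  # 0-based, concatenated

  proper <- mapped & bitwAnd(flag, 2L) == 2L
  first <- bitwAnd(flag, 64L) == 64L

  plc <- list()
  if (any(proper)) {
    key <- paste0(qname[proper], "\r", hi[proper])
    grp <- split(seq_len(sum(proper)), key)
    idx <- which(proper)
    rows <- lapply(grp, function(g) {
      gi <- idx[g]
      if (length(gi) != 2L)
        stop("proper pair group of read '", qname[gi[1L]],
             "' does not have exactly two records")
      p1 <- gi[first[gi]]
      if (length(p1) != 1L)
        stop("proper pair of read '", qname[gi[1L]],
             "' lacks a unique first mate")
      c(pos = unname(gpos[p1]), cost = sum(costs[gi]))
    })
    rows <- do.call(rbind, rows)
    plc$conc <- data.frame(
      read = vapply(strsplit(names(grp), "\r"), `[`, character(1), 1L),
      pos = rows[, "pos"], cost = rows[, "cost"], concordant = TRUE)
  }
  disc <- mapped & !proper
  if (any(disc)) {
    plc$disc <- data.frame(read = qname[disc], pos = unname(gpos[disc]),
                           cost = costs[disc] + params$discordant_penalty,
                           concordant = FALSE)
  }
  placements <- if (length(plc) > 0L) do.call(rbind, plc)
  else data.frame(read = character(), pos = numeric(), cost = numeric(),
                  concordant = logical())
  rownames(placements) <- NULL
  placement_set(read_ids, placements)
}

#' Build a CSM instance from placements and a segmentation
#'
#' `X` is the read set (unmapped reads included), `Y` the segments. The
#' matching cost of `(read, segment)` is the cheapest candidate
#' placement of the read whose position starts inside the segment;
#' reads get coverage costs `{0: unmatched_penalty, 1: 0, >=2: +Inf}`
#' and segments the convex deviation cost `f(i) = |lambda - i|^p`
#' (or linear / flat variants) tabulated at `i = 0 .. d_y`.
#'
#' @param ps A [placement_set()].
#' @param segmentation A [segment_template()] result.
#' @param params A [scoring_params()].
#' @return A [matching_instance()].
#' @export
build_instance <- function(ps, segmentation, params = scoring_params()) {
  nseg <- length(segmentation$starts)
  seg_ids <- sprintf("seg%05d", seq_len(nseg))
  x_ids <- ps$read_ids
  pl <- ps$placements
  if (nrow(pl) > 0L) {
    if (any(pl$pos >= segmentation$template_length))
      stop("placement position beyond template end")
    seg <- findInterval(pl$pos, segmentation$starts)
    o <- order(pl$read, seg, pl$cost)
    dup <- duplicated(paste0(pl$read[o], "\r", seg[o]))
    keep <- o[!dup]
    pairs <- data.frame(x = pl$read[keep], y = seg[keep], cost = pl$cost[keep])
  } else {
    pairs <- data.frame(x = integer(), y = integer(), cost = numeric())
  }
  d_y <- tabulate(pairs$y, nbins = nseg)
  f <- switch(params$coverage_cost_kind,
              polynomial = function(lam, i) abs(lam - i)^params$coverage_exponent,
              linear = function(lam, i) abs(lam - i),
              flat = function(lam, i) rep(0, length(i)))
  y_tables <- lapply(seq_len(nseg), function(j)
    f(segmentation$lambda[j], 0:d_y[j]))
  matching_instance(
    x_ids, seg_ids, pairs,
    x_tables = rep(list(c(params$unmatched_penalty, 0)), length(x_ids)),
    y_tables = y_tables)
}

#' Read a flat key = value parameter file
#'
#' Accepts exactly the [scoring_params()] field names; unknown keys are
#' an error. Lines starting with `#` and blank lines are ignored.
#'
#' @param path Parameter file.
#' @return A [scoring_params()].
#' @export
read_params_file <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (length(ln) == 0L) return(scoring_params())
  kv <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", ln))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed parameter line: '", ln[bad][1L], "'")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  known <- names(formals(scoring_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] %in% c("coverage_cost_kind", "cost_tag")) vals[i]
    else if (keys[i] == "expected_coverage")
      as.numeric(strsplit(vals[i], ",")[[1L]])
    else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(scoring_params, args)
}

#' Write scoring parameters as a flat key = value file
#'
#' @param params A [scoring_params()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_params_file <- function(params, path) {
  vals <- vapply(names(params), function(k) {
    v <- params[[k]]
    if (is.null(v)) "" else paste(format(v, scientific = FALSE), collapse = ",")
  }, character(1))
  keep <- vals != ""
  writeLines(c("# sagescore scoring parameters",
               paste(names(params)[keep], "=", vals[keep])), path)
  invisible(path)
}
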