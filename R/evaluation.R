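#' Score one template against a read set
#'
#' Full scoring pipeline: segment the template, build the
#' coverage-sensitive matching instance from the candidate placements,
#' solve it exactly, and record the optimal matching, the per-segment
#' coverage profile, and the naive baseline. Lower scores mean better
#' read support.
#'
#' @param ps A [placement_set()] of the read set on this template.
#' @param template_length Template length in bases (diploid templates
#'   are scored as the concatenation of their two haplotypes).
#' @param params A [scoring_params()].
#' @param template_id Identifier stored in the result.
#' @return Object of class `template_score`: list with `template_id`,
#'   `sage_score`, `naive_score`, `matching`, `coverage_profile`,
#'   `unmatched_count`, `segmentation`.
#' @export
score_template <- function(ps, template_length, params = scoring_params(),
                           template_id = "template") {
  segmentation <- segment_template(template_length, length(ps$read_ids), params)
  instance <- build_instance(ps, segmentation, params)
  sol <- solve_csm(instance)
  profile <- coverage_profile(sol$matching, segmentation)
  structure(list(template_id = template_id,
                 sage_score = sol$cost,
                 naive_score = naive_score(ps, params),
                 matching = sol$matching,
                 coverage_profile = profile,
                 unmatched_count = length(ps$read_ids) - nrow(sol$matching),
                 segmentation = segmentation),
            class = "template_score")
}

#' @export
print.template_score <- function(x, ...) {
  cat("<template_score '", x$template_id, "': sage = ",
      format(x$sage_score), ", naive = ", format(x$naive_score),
      ", unmatched = ", x$unmatched_count, ">\n", sep = "")
  invisible(x)
}

#' Naive best-alignment baseline score
#'
#' Sums the best (cheapest) candidate placement cost of every read,
#' ignoring coverage entirely; a read with no placement contributes the
#' unmatched penalty so the naive and coverage-sensitive scores share a
#' scale.
#'
#' @param ps A [placement_set()].
#' @param params A [scoring_params()].
#' @return A single number.
#' @export
naive_score <- function(ps, params = scoring_params()) {
  bc <- best_costs(ps)
  sum(ifelse(is.finite(bc), bc, params$unmatched_penalty))
}

#' Matching induced by naive best placements
#'
#' Assigns every mapped read to its single cheapest placement (ties
#' broken by the leftmost position), with no regard for coverage. Used
#' as the baseline whose coverage profile the coverage-sensitive
#' matching is compared against.
#'
#' @param ps A [placement_set()].
#' @param segmentation A [segment_template()] result.
#' @return A [csm_matching()] over the segmentation's segment ids.
#' @export
naive_matching <- function(ps, segmentation) {
  pl <- ps$placements
  if (nrow(pl) == 0L) return(csm_matching())
  o <- order(pl$read, pl$cost, pl$pos)
  keep <- o[!duplicated(pl$read[o])]
  seg <- findInterval(pl$pos[keep], segmentation$starts)
  csm_matching(ps$read_ids[pl$read[keep]], sprintf("seg%05d", seg))
}

#' Per-segment coverage profile of a matching
#'
#' @param m A [csm_matching()] whose `y` side are segment ids of
#'   `segmentation`.
#' @param segmentation A [segment_template()] result.
#' @return List with `counts` (matched reads per segment, in coordinate
#'   order), `lambda`, and `variance`, the mean squared deviation of
#'   the counts from the expected coverages.
#' @export
coverage_profile <- function(m, segmentation) {
  nseg <- length(segmentation$starts)
  seg_ids <- sprintf("seg%05d", seq_len(nseg))
  iy <- match(m$y, seg_ids)
  if (anyNA(iy)) stop("matching references segments outside the segmentation")
  counts <- tabulate(iy, nbins = nseg)
  list(counts = counts, lambda = segmentation$lambda,
       variance = mean((counts - segmentation$lambda)^2))
}

#' Rank templates by score
#'
#' @param scores List of `template_score` objects.
#' @return The list reordered ascending by `sage_score` (lower is
#'   better), ties broken by template id.
#' @export
rank_templates <- function(scores) {
  if (length(scores) < 1L) stop("need at least one template score")
  sage <- vapply(scores, `[[`, numeric(1), "sage_score")
  ids <- vapply(scores, `[[`, character(1), "template_id")
  scores[order(sage, ids)]
}

#' Second-best score normalization
#'
#' Affinely rescales a row of raw scores so the second-best
#' (second-smallest) score maps to 1 and the worst (largest) to 0; the
#' best score then lands at a value >= 1. This is the scale on which a
#' template would be judged if the truly best (and presumably correct)
#' template were absent from the database. Degenerate rows: with only
#' two distinct values the best maps to 1 and the worst to 0; if all
#' scores are equal everything maps to 1.
#'
#' @param scores Numeric vector of raw scores (lower is better).
#' @return Numeric vector of normalized scores.
#' @export
normalize_second_best <- function(scores) {
  s <- as.numeric(scores)
  if (length(s) == 0L) return(numeric())
  worst <- max(s)
  anchor <- if (length(s) >= 2L) sort(s)[2L] else min(s)
  if (worst == anchor) {
    distinct <- sort(unique(s))
    if (length(distinct) == 1L) return(rep(1, length(s)))
    # two-value degenerate row: best -> 1, worst -> 0
    anchor <- distinct[1L]
  }
  (worst - s) / (worst - anchor)
}

#' Percent-from-top transformation of a score row
#'
#' @param scores Numeric vector (lower is better).
#' @return `100 * (s - best) / best`; 0 marks the top-scoring template.
#' @export
percent_from_top <- function(scores) {
  best <- min(scores)
  if (best == 0) return(ifelse(scores == 0, 0, Inf))
  100 * (scores - best) / best
}

#' Write a coverage profile as TSV
#'
#' Columns: segment start, matched read count, expected coverage.
#'
#' @param score A `template_score`.
#' @param path Output path.
#' @param provenance Optional named character vector written as `#`
#'   header lines.
#' @return `path` invisibly.
#' @export
write_profile_tsv <- function(score, path, provenance = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  writeLines("segment_start\tcount\tlambda", con)
  writeLines(sprintf("%d\t%d\t%.6g",
                     as.integer(score$segmentation$starts),
                     score$coverage_profile$counts,
                     score$segmentation$lambda), con)
  invisible(path)
}
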