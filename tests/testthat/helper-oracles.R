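# Independent oracles, deliberately implemented with different
# algorithms than the package.

# maximum-cardinality bipartite matching by Kuhn's augmenting paths
max_bipartite_matching <- function(edges, x_ids, y_ids) {
  adj <- lapply(seq_along(x_ids), function(i)
    match(edges$y[edges$x == x_ids[i]], y_ids))
  match_y <- rep(0L, length(y_ids))
  try_augment <- function(u, seen) {
    for (v in adj[[u]]) {
      if (seen[v]) next
      seen[v] <- TRUE
      if (match_y[v] == 0L) {
        match_y[v] <<- u
        return(TRUE)
      }
      saved <- match_y[v]
      match_y[v] <<- 0L
      if (try_augment(saved, seen)) {
        match_y[v] <<- u
        return(TRUE)
      }
      match_y[v] <<- saved
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(x_ids)) {
    if (try_augment(u, rep(FALSE, length(y_ids)))) size <- size + 1L
  }
  size
}

# naive position-by-position Hamming scan of both strands; the mapper's
# correctness oracle on tiny inputs
scan_hamming <- function(end_seq, template, k) {
  rl <- nchar(end_seq)
  len <- nchar(template)
  tch <- strsplit(template, "")[[1L]]
  hits <- list()
  for (pat in list(c(strand = 1L, seq = end_seq),
                   c(strand = -1L, seq = as.character(
                     Biostrings::reverseComplement(
                       Biostrings::DNAString(end_seq)))))) {
    pch <- strsplit(pat[["seq"]], "")[[1L]]
    for (p in 0:(len - rl)) {
      nm <- sum(tch[(p + 1):(p + rl)] != pch)
      if (nm <= k)
        hits[[length(hits) + 1L]] <- data.frame(
          strand = as.integer(pat[["strand"]]), pos = p, nmis = nm)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(strand = integer(), pos = integer(), nmis = integer()))
  out <- do.call(rbind, hits)
  out[order(-out$strand, out$pos), , drop = FALSE]
}
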