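# Anchor estimation on a guide alignment and conversion of anchor boundaries
# into per-sequence barriers for walk synchronization.
#
# Anchors are gap-free, high-similarity windows of the guide MSA; similarity
# is measured by average normalized Hamming distance (ANHD) with indels
# counted as mismatches (gap-vs-gap included). Restricting candidates to
# fully gap-free windows guarantees that each anchor boundary maps to a
# single well-defined unaligned offset in every sequence.

# Per-column count of matching sequence pairs. A pair of cells matches only
# when both hold the same unambiguous residue; ambiguity codes count as
# mismatches unless ambig_match = TRUE, and gaps never match.
column_match_counts <- function(mat, ambig_match = FALSE) {
  matchable <- if (ambig_match) c(NUC_CHARS, AMBIG_CHARS) else NUC_CHARS
  out <- numeric(ncol(mat))
  for (ch in matchable) {
    cnt <- colSums(mat == ch)
    out <- out + cnt * (cnt - 1) / 2
  }
  out
}

#' Average normalized Hamming distance of an alignment window
#'
#' Mean, over all sequence pairs, of the fraction of mismatching columns in
#' the window `[start_col, start_col + length)`. Indels are treated as
#' mismatches (a gap never matches anything, including another gap).
#'
#' @param msa An `msa` with at least two rows.
#' @param start_col 0-based first column of the window.
#' @param length Window length in columns (default: full alignment width).
#' @param ambig_match Should identical ambiguity codes count as matches?
#'   Default `FALSE` (counted as mismatches).
#' @return Dissimilarity in `[0, 1]`.
#' @export
window_anhd <- function(msa, start_col = 0, length = msa_length(msa),
                        ambig_match = FALSE) {
  stopifnot(inherits(msa, "msa"))
  n <- msa_nseq(msa)
  if (n < 2) stop("ANHD requires at least two sequences", call. = FALSE)
  start_col <- as.integer(start_col); length <- as.integer(length)
  if (length < 1 || start_col < 0 || start_col + length > msa_length(msa))
    stop("window out of bounds", call. = FALSE)
  cols <- seq.int(start_col + 1L, start_col + length)
  matches <- column_match_counts(msa$matrix[, cols, drop = FALSE], ambig_match)
  npairs <- n * (n - 1) / 2
  1 - sum(matches) / (npairs * length)
}

#' Find high-similarity anchors on a guide alignment
#'
#' Scans every fully gap-free window of `anchor_len` columns, scores each by
#' ANHD, and selects anchors greedily in order of ascending ANHD (ties broken
#' by leftmost start column), skipping any window closer than `min_dist`
#' columns (nearest edges, in aligned coordinates) to an already selected
#' anchor. Selection stops at `num_anchors`; if fewer eligible windows exist
#' a warning is issued and the maximal feasible set is returned.
#'
#' @param guide Guide `msa`.
#' @param num_anchors Number of anchors requested; default
#'   `floor(k / 20)` where `k` is the guide length.
#' @param anchor_len Anchor length in columns (default 5).
#' @param min_dist Minimum separation between anchors in columns (default 25).
#' @param ambig_match Passed to [window_anhd()].
#' @return Data frame with columns `start_col`, `end_col` (half-open, 0-based)
#'   and `anhd`, sorted by `start_col`.
#' @export
find_anchors <- function(guide, num_anchors = NULL, anchor_len = 5,
                         min_dist = 25, ambig_match = FALSE) {
  stopifnot(inherits(guide, "msa"))
  k <- msa_length(guide)
  if (is.null(num_anchors)) num_anchors <- k %/% 20L
  num_anchors <- as.integer(num_anchors)
  anchor_len <- as.integer(anchor_len)
  min_dist <- as.integer(min_dist)
  if (anchor_len < 1) stop("anchor_len must be >= 1", call. = FALSE)
  if (num_anchors < 0) stop("num_anchors must be >= 0", call. = FALSE)
  empty <- data.frame(start_col = integer(), end_col = integer(),
                      anhd = numeric())
  if (num_anchors == 0 || anchor_len > k) return(empty)

  gapped <- colSums(guide$matrix == GAP_CHAR) > 0
  bad <- cumsum(c(0L, as.integer(gapped)))
  starts <- seq_len(k - anchor_len + 1L)       # 1-based window starts
  eligible <- (bad[starts + anchor_len] - bad[starts]) == 0L
  starts <- starts[eligible]
  if (length(starts) == 0) {
    warning("no gap-free windows available; no anchors selected")
    return(empty)
  }
  cm <- column_match_counts(guide$matrix, ambig_match)
  npairs <- msa_nseq(guide) * (msa_nseq(guide) - 1) / 2
  anhd <- vapply(starts, function(s)
    1 - sum(cm[seq.int(s, s + anchor_len - 1L)]) / (npairs * anchor_len),
    numeric(1))

  ord <- order(anhd, starts)
  sel_start <- integer(0); sel_anhd <- numeric(0)
  for (o in ord) {
    if (length(sel_start) >= num_anchors) break
    s0 <- starts[o] - 1L                        # 0-based
    e0 <- s0 + anchor_len
    ok <- TRUE
    for (t0 in sel_start) {
      te <- t0 + anchor_len
      gap <- if (s0 >= te) s0 - te else if (t0 >= e0) t0 - e0 else -1L
      if (gap < min_dist) { ok <- FALSE; break }
    }
    if (ok) { sel_start <- c(sel_start, s0); sel_anhd <- c(sel_anhd, anhd[o]) }
  }
  if (length(sel_start) < num_anchors)
    warning(sprintf("only %d of %d requested anchors could be placed",
                    length(sel_start), num_anchors))
  ord2 <- order(sel_start)
  data.frame(start_col = sel_start[ord2],
             end_col = sel_start[ord2] + anchor_len,
             anhd = sel_anhd[ord2])
}

#' Convert anchor boundaries into per-sequence barriers
#'
#' Each anchor contributes two barriers (at its start and end columns); the
#' barrier offset of sequence `s` at column `c` is the number of non-gap
#' cells of `s` in columns `[0, c)`, i.e. a 0-based cut point into the
#' unaligned sequence. Trivial barriers at the start (all zeros) and end
#' (the sequence lengths) are always included. Consecutive duplicate
#' barriers (empty segments for every sequence) are collapsed.
#'
#' @param guide Guide `msa`.
#' @param anchors Data frame from [find_anchors()]; must be sorted and
#'   non-overlapping.
#' @return A `barrier_set`: list with `offsets` (m x n integer matrix, one
#'   row per barrier, one column per sequence), `ids`, and `lengths`.
#' @export
anchors_to_barriers <- function(guide, anchors = NULL) {
  stopifnot(inherits(guide, "msa"))
  k <- msa_length(guide)
  if (is.null(anchors)) anchors <- data.frame(start_col = integer(),
                                              end_col = integer())
  if (nrow(anchors) > 1) {
    if (is.unsorted(anchors$start_col, strictly = TRUE) ||
        any(anchors$start_col[-1] < anchors$end_col[-nrow(anchors)]))
      stop("anchors must be sorted and non-overlapping", call. = FALSE)
  }
  ng <- guide$matrix != GAP_CHAR
  pref <- cbind(0L, t(apply(ng, 1, cumsum)))   # n x (k+1)
  cols <- sort(unique(c(0L, anchors$start_col, anchors$end_col, k)))
  off <- t(pref[, cols + 1L, drop = FALSE])
  if (nrow(off) > 1) {
    keep <- c(TRUE, rowSums(abs(off[-1, , drop = FALSE] -
                                off[-nrow(off), , drop = FALSE])) > 0)
    off <- off[keep, , drop = FALSE]
  }
  rownames(off) <- NULL
  colnames(off) <- msa_ids(guide)
  structure(list(offsets = off, ids = msa_ids(guide),
                 lengths = unname(pref[, k + 1L])),
            class = "barrier_set")
}

#' Trivial barriers for a set of unaligned sequences
#'
#' The minimal `barrier_set`: one barrier at the start of the sequences and
#' one at their ends.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @return A `barrier_set` with two barriers.
#' @export
trivial_barriers <- function(seqs) {
  seqs <- as_seqs(seqs)
  lens <- nchar(seqs)
  off <- rbind(rep(0L, length(seqs)), as.integer(lens))
  colnames(off) <- names(seqs)
  structure(list(offsets = off, ids = names(seqs), lengths = unname(lens)),
            class = "barrier_set")
}

#' @export
print.barrier_set <- function(x, ...) {
  cat(sprintf("<barrier_set> %d barriers over %d sequences\n",
              nrow(x$offsets), length(x$ids)))
  invisible(x)
}
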