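# SERES random walk on barrier space: resampling unaligned sequences.

#' Resample unaligned sequences by a SERES walk over barriers
#'
#' The walk lives on the barriers of a [anchors_to_barriers()] /
#' [trivial_barriers()] set. It starts at a barrier chosen uniformly at
#' random (direction uniform, forced inward at the trivial start/end
#' barriers) and repeatedly traverses to the neighboring barrier. During a
#' traversal, for every sequence the residues strictly between the two cut
#' points are appended to that sequence's replicate: in natural order when
#' moving right, in reversed order when moving left. Reversed appending on
#' leftward traversals is the only orientation that preserves residue
#' adjacency across traversal boundaries, and because the orientation flip
#' is global the sequences stay mutually synchronized. After each arrival
#' the walk terminates if the longest resampled sequence has reached
#' `length_factor` times the longest input sequence; otherwise the direction
#' reverses -- with certainty at a trivial barrier, else with probability
#' `gamma` -- and the walk continues. At least one traversal is always
#' performed.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @param barriers A `barrier_set` consistent with `seqs` (its last barrier
#'   must equal the sequence lengths). Default: trivial barriers only.
#' @param gamma Reversal probability in `[0, 1]`.
#' @param length_factor Positive multiple of the longest input sequence
#'   length that the longest resampled sequence must reach (default 1, so
#'   replicates are at least input-length, mirroring the aligned walk's
#'   length conservation).
#' @param start Optional 0-based index of the starting barrier.
#' @param direction Optional starting direction (`"L"`/`"R"` or `-1`/`1`);
#'   ignored (forced inward) at trivial barriers.
#' @return A `seres_replicate`: list with `sequences` (named character
#'   vector), `provenance` (named list; for each sequence the ordered
#'   0-based original indices of its resampled residues), and
#'   `segment_trace` (two-column integer matrix of 0-based
#'   `(barrier_from, barrier_to)` traversals, shared by all sequences).
#' @export
sample_unaligned_replicate <- function(seqs, barriers = NULL, gamma = 0.5,
                                       length_factor = 1, start = NULL,
                                       direction = NULL) {
  seqs <- as_seqs(seqs)
  if (is.null(barriers)) barriers <- trivial_barriers(seqs)
  stopifnot(inherits(barriers, "barrier_set"))
  if (!identical(barriers$ids, names(seqs)))
    stop("barrier set and sequences disagree on ids", call. = FALSE)
  off <- barriers$offsets
  m <- nrow(off); n <- ncol(off)
  lens <- nchar(seqs)
  if (any(off[1, ] != 0L) || any(off[m, ] != lens))
    stop("barriers inconsistent with sequence lengths", call. = FALSE)
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(length_factor) || length_factor <= 0)
    stop("length_factor must be > 0", call. = FALSE)
  if (all(lens == 0)) stop("all sequences are empty", call. = FALSE)

  chars <- strsplit(seqs, "", fixed = TRUE)
  target <- length_factor * max(lens)
  b <- if (is.null(start)) sample.int(m, 1L) else {
    s <- as.integer(start) + 1L
    if (s < 1L || s > m) stop("start barrier out of range", call. = FALSE)
    s
  }
  dir <- if (b == 1L) 1L else if (b == m) -1L else parse_direction(direction)

  acc <- lapply(seq_len(n), function(i) list())
  cur <- numeric(n)
  seg_from <- integer(0); seg_to <- integer(0)
  repeat {
    b2 <- b + dir
    lo_row <- min(b, b2); hi_row <- max(b, b2)
    for (s in seq_len(n)) {
      lo <- off[lo_row, s]; hi <- off[hi_row, s]
      if (hi > lo) {
        idx <- seq.int(lo, hi - 1L)
        if (dir < 0L) idx <- rev(idx)
        acc[[s]][[length(acc[[s]]) + 1L]] <- idx
        cur[s] <- cur[s] + (hi - lo)
      }
    }
    seg_from <- c(seg_from, b - 1L); seg_to <- c(seg_to, b2 - 1L)
    b <- b2
    if (max(cur) >= target) break
    if (b == 1L || b == m) dir <- -dir
    else if (runif(1) < gamma) dir <- -dir
  }

  prov <- lapply(acc, function(a)
    if (length(a)) as.integer(unlist(a, use.names = FALSE)) else integer(0))
  out <- vapply(seq_len(n), function(s)
    paste(chars[[s]][prov[[s]] + 1L], collapse = ""), character(1))
  structure(list(sequences = setNames(out, names(seqs)),
                 provenance = setNames(prov, names(seqs)),
                 segment_trace = cbind(from = seg_from, to = seg_to)),
            class = "seres_replicate")
}

#' @export
print.seres_replicate <- function(x, ...) {
  cat(sprintf("<seres_replicate> %d sequences, lengths %s\n",
              length(x$sequences),
              paste(range(nchar(x$sequences)), collapse = "-")))
  invisible(x)
}

#' Position-to-original-index map of a replicate
#'
#' Returns, for each sequence, the total map from resampled position to the
#' 0-based index of that residue in the original sequence, optionally
#' verifying residue-by-residue that the mapped characters agree.
#'
#' @param rep A `seres_replicate`.
#' @param seqs Optional original sequences to verify against.
#' @return Named list of 0-based integer vectors (element `p + 1` is the
#'   original index of resampled position `p`).
#' @export
replicate_provenance_map <- function(rep, seqs = NULL) {
  stopifnot(inherits(rep, "seres_replicate"))
  if (!is.null(seqs)) {
    seqs <- as_seqs(seqs)
    for (id in names(rep$sequences)) {
      orig <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
      got <- strsplit(rep$sequences[[id]], "", fixed = TRUE)[[1]]
      if (!identical(got, orig[rep$provenance[[id]] + 1L]))
        stop("provenance map does not reproduce original residues for ", id,
             call. = FALSE)
    }
  }
  rep$provenance
}
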