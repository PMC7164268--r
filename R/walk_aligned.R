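# SERES random walk over the sites of a fixed alignment.

parse_direction <- function(direction) {
  if (is.null(direction)) return(sample(c(-1L, 1L), 1L))
  if (is.character(direction)) {
    direction <- switch(toupper(direction), L = -1L, R = 1L,
                        stop("direction must be \"L\" or \"R\"", call. = FALSE))
  }
  direction <- as.integer(direction)
  if (!direction %in% c(-1L, 1L)) stop("direction must be -1 or 1", call. = FALSE)
  direction
}

#' Sample a SERES walk over alignment sites
#'
#' Performs a random walk on sites `0..k-1`. The start site and the starting
#' direction are drawn uniformly at random when unspecified. Each step emits
#' the current site, then the walk direction is updated -- at the first or
#' last site reversal is certain (the next move is inward), elsewhere the
#' direction reverses with probability `gamma` -- and the walk moves one
#' site. Emitting before the boundary reversal means each boundary site is
#' emitted exactly once per visit. The walk ends
#' when `target_length` sites have been emitted (default: the alignment
#' length, so replicates conserve length).
#'
#' With `gamma = 0` the walk degenerates to the two Heads-or-Tails readings:
#' started at site 0 moving right it reads the alignment left-to-right;
#' started at site `k-1` moving left it reads right-to-left.
#'
#' @param k Alignment length (number of sites), >= 1.
#' @param gamma Reversal probability in `[0, 1]`.
#' @param target_length Number of sites to emit (default `k`).
#' @param start Optional 0-based start site.
#' @param direction Optional start direction: `"L"`/`"R"` or `-1`/`1`.
#' @return Integer vector of 0-based sampled sites; consecutive entries
#'   differ by exactly 1 (neighbor preservation), except in the degenerate
#'   `k = 1` case where site 0 is emitted repeatedly.
#' @export
sample_aligned_trace <- function(k, gamma = 0.5, target_length = k,
                                 start = NULL, direction = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("alignment length must be >= 1", call. = FALSE)
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]", call. = FALSE)
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 1L)
    stop("target_length must be >= 1", call. = FALSE)
  if (is.null(start)) {
    start <- sample.int(k, 1L) - 1L
  } else {
    start <- as.integer(start)
    if (start < 0L || start >= k) stop("start site out of range", call. = FALSE)
  }
  if (k == 1L) return(integer(target_length))
  dir <- parse_direction(direction)
  u <- runif(target_length)
  trace <- integer(target_length)
  pos <- start
  for (t in seq_len(target_length)) {
    trace[t] <- pos
    if (pos == 0L) {
      dir <- 1L                 # reversal is certain at the ends: move inward
    } else if (pos == k - 1L) {
      dir <- -1L
    } else if (u[t] < gamma) {
      dir <- -dir
    }
    pos <- pos + dir
  }
  trace
}

#' Resample an alignment by a SERES walk over its columns
#'
#' Column `j` of the replicate equals column `trace[j]` of the input, where
#' the trace comes from [sample_aligned_trace()]; by default the replicate
#' therefore has exactly the input's dimensions.
#'
#' @param msa An `msa` object.
#' @inheritParams sample_aligned_trace
#' @return List with elements `alignment` (the resampled `msa`) and `trace`
#'   (the 0-based column trace).
#' @export
resample_alignment <- function(msa, gamma = 0.5, target_length = NULL,
                               start = NULL, direction = NULL) {
  stopifnot(inherits(msa, "msa"))
  k <- msa_length(msa)
  trace <- sample_aligned_trace(k, gamma, target_length %||% k, start, direction)
  mat <- msa$matrix[, trace + 1L, drop = FALSE]
  colnames(mat) <- NULL
  list(alignment = new_msa(mat), trace = trace)
}

#' Build an unaligned replicate from resampled alignment columns
#'
#' Shared plumbing for the aligned-walk and standard-bootstrap resampling
#' modes: the selected columns are degapped row-wise into unaligned replicate
#' sequences, and each resampled residue keeps a provenance pointer to its
#' 0-based index in the original unaligned sequence.
#'
#' @param msa An `msa` object.
#' @param cols0 Integer vector of 0-based column indices (may repeat).
#' @return A `seres_replicate`: list with `sequences` (named character
#'   vector; may contain empty strings if a row is all-gap in the sampled
#'   columns), `provenance` (named list of 0-based integer vectors), and
#'   `trace` (the column trace).
#' @export
replicate_from_columns <- function(msa, cols0) {
  stopifnot(inherits(msa, "msa"))
  cols0 <- as.integer(cols0)
  if (any(cols0 < 0L | cols0 >= msa_length(msa)))
    stop("column index out of range", call. = FALSE)
  mat <- msa$matrix[, cols0 + 1L, drop = FALSE]
  orig <- msa$provenance[, cols0 + 1L, drop = FALSE]
  ids <- msa_ids(msa)
  seqs <- character(length(ids))
  prov <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ng <- mat[i, ] != GAP_CHAR
    seqs[i] <- paste(mat[i, ng], collapse = "")
    prov[[i]] <- unname(orig[i, ng])
  }
  structure(list(sequences = setNames(seqs, ids),
                 provenance = setNames(prov, ids),
                 segment_trace = NULL, trace = cols0),
            class = "seres_replicate")
}
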