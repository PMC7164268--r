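# Replicate re-alignment: a deterministic builtin progressive aligner (so the
# whole pipeline runs with no external binary) and an external-command hook
# for tools such as MAFFT.

#' Pairwise global alignment
#'
#' Needleman-Wunsch with linear gap cost (defaults: match +1, mismatch -1,
#' gap -2) and fixed tie-breaking (diagonal > up > left), so the result is
#' deterministic. Either sequence may be empty.
#'
#' @param a,b Residue strings.
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `score` and integer vectors `ai`, `bi`: for each
#'   aligned column the 0-based index into `a` resp. `b`, with `-1` for a
#'   gap.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  nw_align_cpp(a, b, match, mismatch, gap)
}

#' Aligner specifications
#'
#' `aligner_builtin()` selects the package's deterministic star aligner
#' ([builtin_progressive_align()]); `aligner_external()` wraps a shell
#' command template containing `{in}` and `{out}` placeholders (e.g.
#' `"mafft --auto {in} > {out}"`). An external command must preserve the
#' residue order and content of every input sequence; this contract is
#' verified after every call.
#'
#' @param match,mismatch,gap Scoring parameters for the builtin aligner.
#' @param command Shell command template with `{in}` and `{out}`.
#' @return An `aligner_spec` object.
#' @export
aligner_builtin <- function(match = 1, mismatch = -1, gap = -2) {
  structure(list(mode = "builtin", match = match, mismatch = mismatch,
                 gap = gap), class = "aligner_spec")
}

#' @rdname aligner_builtin
#' @export
aligner_external <- function(command) {
  stopifnot(is.character(command), length(command) == 1)
  if (!grepl("{in}", command, fixed = TRUE) ||
      !grepl("{out}", command, fixed = TRUE))
    stop("command template must contain {in} and {out} placeholders",
         call. = FALSE)
  structure(list(mode = "external", command = command),
            class = "aligner_spec")
}

#' Deterministic star alignment around a centroid sequence
#'
#' Test-grade progressive aligner: every sequence is aligned pairwise
#' ([nw_align()]) to the centroid -- the sequence with the greatest total
#' pairwise alignment score, ties broken by smallest id -- and the pairwise
#' alignments are merged star-wise. Insertions relative to the centroid are
#' left-justified within per-slot blocks sized by the longest insertion, so
#' the result is independent of merge order, and permuting the input rows
#' changes only the row order of the output. Residues inserted by different
#' sequences in the same slot are not aligned to one another; this aligner
#' exists to make the pipeline self-contained, not to compete with real MSA
#' tools.
#'
#' @param seqs Named character vector of sequences (empty strings allowed).
#' @param match,mismatch,gap Scoring parameters.
#' @return An `msa` whose degapped rows equal `seqs`.
#' @export
builtin_progressive_align <- function(seqs, match = 1, mismatch = -1,
                                      gap = -2) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- setNames(normalise_residues(seqs), names(seqs))
  n <- length(seqs)
  ids <- names(seqs)
  if (n == 1) {
    mat <- matrix(strsplit(seqs, "", fixed = TRUE)[[1]], nrow = 1,
                  dimnames = list(ids, NULL))
    if (ncol(mat) == 0) stop("cannot align a single empty sequence", call. = FALSE)
    return(new_msa(mat))
  }
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- nw_align(seqs[[i]], seqs[[j]], match, mismatch, gap)$score
      scores[i, j] <- s; scores[j, i] <- s
    }
  }
  tot <- rowSums(scores)
  best <- which(tot == max(tot))
  ctr <- best[order(ids[best])][1]
  cchars <- strsplit(seqs[[ctr]], "", fixed = TRUE)[[1]]
  lc <- length(cchars)

  # Per non-centroid sequence: which residue (if any) is aligned to each
  # centroid residue, and which residues are inserted in each of the lc + 1
  # inter-residue slots.
  res_of <- vector("list", n)
  ins_of <- vector("list", n)
  ins_len <- matrix(0L, n, lc + 1L)
  for (i in seq_len(n)) {
    if (i == ctr) next
    al <- nw_align(seqs[[ctr]], seqs[[i]], match, mismatch, gap)
    ai <- al$ai; bi <- al$bi
    r <- rep(NA_integer_, lc)
    hit <- ai >= 0
    r[ai[hit] + 1L] <- ifelse(bi[hit] >= 0, bi[hit], NA_integer_)
    res_of[[i]] <- r
    slot <- cumsum(hit)[!hit]            # centroid residues consumed before
    ins <- split(bi[!hit], slot)
    ins_of[[i]] <- ins
    if (length(ins)) {
      sl <- as.integer(names(ins)) + 1L
      ins_len[i, sl] <- lengths(ins)
    }
  }
  widths <- apply(ins_len, 2, max)
  ktot <- sum(widths) + lc
  mat <- matrix(GAP_CHAR, n, ktot, dimnames = list(ids, NULL))
  # Column layout: slot 0 block, residue 1, slot 1 block, residue 2, ...
  res_cols <- cumsum(widths[seq_len(lc)] + 1L)       # columns of centroid residues
  slot_starts <- c(0L, res_cols) + 1L                # first column of each slot block
  mat[ctr, res_cols] <- cchars
  for (i in seq_len(n)) {
    if (i == ctr) next
    schars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    r <- res_of[[i]]
    hit <- !is.na(r)
    if (any(hit)) mat[i, res_cols[hit]] <- schars[r[hit] + 1L]
    for (sl in names(ins_of[[i]])) {
      g <- as.integer(sl) + 1L
      idx <- ins_of[[i]][[sl]]
      cols <- slot_starts[g] + seq_along(idx) - 1L
      mat[i, cols] <- schars[idx + 1L]
    }
  }
  # Drop columns that are entirely gaps (slots narrower than their width
  # never occur by construction, but an all-empty slot contributes none).
  keep <- colSums(mat != GAP_CHAR) > 0
  new_msa(mat[, keep, drop = FALSE])
}

run_external_aligner <- function(seqs, command) {
  tin <- tempfile(fileext = ".fasta")
  tout <- tempfile(fileext = ".fasta")
  terr <- tempfile(fileext = ".log")
  on.exit(unlink(c(tin, tout, terr)), add = TRUE)
  write_fasta(seqs, tin)
  cmd <- sub("{in}", shQuote(tin), command, fixed = TRUE)
  cmd <- sub("{out}", shQuote(tout), cmd, fixed = TRUE)
  status <- system(paste0("(", cmd, ") 2> ", shQuote(terr)))
  if (status != 0 || !file.exists(tout) || file.size(tout) == 0) {
    err <- if (file.exists(terr)) paste(readLines(terr, warn = FALSE),
                                        collapse = "\n") else ""
    stop("external aligner failed (exit ", status, "):\n", err, call. = FALSE)
  }
  out <- read_fasta(tout, aligned = TRUE)
  if (!setequal(msa_ids(out), names(seqs)))
    stop("external aligner changed the sequence ids", call. = FALSE)
  mat <- out$matrix[names(seqs), , drop = FALSE]
  new_msa(mat)
}

#' Align a set of sequences with a given aligner
#'
#' Dispatches on an [aligner_builtin()] / [aligner_external()] spec and
#' verifies the aligner contract: degapping the output rows must reproduce
#' the input sequences exactly.
#'
#' @param seqs Named character vector of sequences.
#' @param aligner An `aligner_spec` (default: builtin).
#' @return An `msa`.
#' @export
align_sequences <- function(seqs, aligner = aligner_builtin()) {
  stopifnot(inherits(aligner, "aligner_spec"))
  out <- switch(aligner$mode,
    builtin = builtin_progressive_align(seqs, aligner$match,
                                        aligner$mismatch, aligner$gap),
    external = run_external_aligner(seqs, aligner$command),
    stop("unknown aligner mode", call. = FALSE))
  got <- msa_sequences(out)[names(seqs)]
  want <- setNames(normalise_residues(seqs), names(seqs))
  if (!identical(unname(got), unname(want)))
    stop("aligner contract violation: degapped output differs from input",
         call. = FALSE)
  out
}

#' Re-align a resampled replicate
#'
#' Aligns the replicate's unaligned sequences and validates that the
#' degapped rows equal the replicate sequences, so the replicate's
#' provenance map composes through the new alignment.
#'
#' @param rep A `seres_replicate`.
#' @param aligner An `aligner_spec`.
#' @return An `msa` of the replicate sequences.
#' @export
realign_replicate <- function(rep, aligner = aligner_builtin()) {
  stopifnot(inherits(rep, "seres_replicate"))
  align_sequences(rep$sequences, aligner)
}
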