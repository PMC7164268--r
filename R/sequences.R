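# Sequence and alignment containers.
#
# Unaligned sequences are plain named character vectors (ids as names,
# uppercase residues, no gap characters). Alignments are `msa` objects: a
# character matrix plus a provenance matrix mapping every non-gap cell to the
# 0-based index of that residue within its own unaligned sequence.

GAP_CHAR <- "-"
NUC_CHARS <- c("A", "C", "G", "T", "U")
AMBIG_CHARS <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Residue alphabet
#'
#' The nucleotide alphabet accepted by the package: the four bases plus U,
#' IUPAC ambiguity codes, and the gap symbol `-`. The dot gap symbol `.`
#' (used by some rRNA alignment databases) is normalized to `-` on input, and
#' residues are stored uppercase.
#'
#' @return Character vector of allowed symbols.
#' @export
seq_alphabet <- function() c(NUC_CHARS, AMBIG_CHARS, GAP_CHAR)

normalise_residues <- function(x) {
  x <- toupper(x)
  gsub(".", GAP_CHAR, x, fixed = TRUE)
}

check_alphabet <- function(x, on_invalid = c("reject", "mask")) {
  on_invalid <- match.arg(on_invalid)
  pat <- sprintf("[^%s-]", paste(c(NUC_CHARS, AMBIG_CHARS), collapse = ""))
  if (any(grepl(pat, x))) {
    if (on_invalid == "reject") {
      stop("input contains characters outside the nucleotide alphabet; ",
           "use on_invalid = \"mask\" to replace them with N", call. = FALSE)
    }
    x <- gsub(pat, "N", x)
  }
  x
}

#' Validate unaligned sequences
#'
#' Normalizes case, checks names, and rejects gap characters and empty
#' sequences.
#'
#' @param x Named character vector (or list) of residue strings.
#' @return Named character vector of validated, uppercase sequences.
#' @export
as_seqs <- function(x) {
  if (is.list(x)) x <- unlist(x)
  stopifnot(is.character(x))
  if (length(x) == 0) stop("no sequences given", call. = FALSE)
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
    stop("sequences must have unique, non-empty names", call. = FALSE)
  x <- normalise_residues(x)
  if (any(grepl(GAP_CHAR, x, fixed = TRUE)))
    stop("unaligned sequences must not contain gap characters", call. = FALSE)
  if (any(!nzchar(x)))
    stop("sequences must have length >= 1", call. = FALSE)
  x
}

#' Construct an alignment object
#'
#' Builds an `msa` from a character matrix of residues and gaps. The
#' provenance matrix records, for every non-gap cell, the 0-based index of
#' that residue in its unaligned sequence, so degapping any row reproduces
#' the corresponding input sequence exactly.
#'
#' @param mat Character matrix (rows = sequences, columns = sites) with
#'   rownames giving sequence ids. Gap symbol `-`.
#' @return An object of class `msa`: list with elements `matrix` and
#'   `provenance` (integer matrix, `NA` at gap cells).
#' @export
new_msa <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat))
    stop("alignment must be a character matrix", call. = FALSE)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("alignment rows must have unique names", call. = FALSE)
  if (ncol(mat) < 1) stop("alignment must have at least one column", call. = FALSE)
  mat[] <- normalise_residues(mat)
  ng <- mat != GAP_CHAR
  prov <- matrix(NA_integer_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    r <- ng[i, ]
    if (any(r)) prov[i, r] <- seq_len(sum(r)) - 1L
  }
  structure(list(matrix = mat, provenance = prov), class = "msa")
}

#' @rdname new_msa
#' @param x Named character vector of equal-length gapped strings.
#' @export
msa_from_strings <- function(x) {
  stopifnot(is.character(x))
  if (length(unique(nchar(x))) != 1)
    stop("aligned records must all have the same length", call. = FALSE)
  mat <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(mat) <- names(x)
  new_msa(mat)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Alignment accessors
#'
#' @param x An `msa` object.
#' @return `msa_length()` the number of columns; `msa_nseq()` the number of
#'   rows; `msa_ids()` the sequence ids; `msa_sequences()` the degapped rows
#'   as a named character vector; `msa_strings()` the gapped rows.
#' @export
msa_length <- function(x) ncol(x$matrix)

#' @rdname msa_length
#' @export
msa_nseq <- function(x) nrow(x$matrix)

#' @rdname msa_length
#' @export
msa_ids <- function(x) rownames(x$matrix)

#' @rdname msa_length
#' @export
msa_sequences <- function(x) {
  out <- apply(x$matrix, 1, function(r) paste(r[r != GAP_CHAR], collapse = ""))
  setNames(as.character(out), rownames(x$matrix))
}

#' @rdname msa_length
#' @export
msa_strings <- function(x) {
  setNames(apply(x$matrix, 1, paste, collapse = ""), rownames(x$matrix))
}

#' Extract residue-pair homologies from an alignment
#'
#' Every column asserts homology among the residues it contains: each
#' unordered pair of sequences with non-gap cells in the same column yields
#' one residue-pair homology. Pairs are canonicalized so that
#' `seq_i < seq_j` lexicographically, making homology sets comparable across
#' alignments regardless of row order.
#'
#' @param msa An `msa` object.
#' @return Data frame with columns `seq_i`, `pos_i`, `seq_j`, `pos_j`
#'   (positions are 0-based indices into the unaligned sequences).
#' @export
extract_homologies <- function(msa) {
  ids <- msa_ids(msa)
  prov <- msa$provenance
  n <- length(ids)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        both <- !is.na(prov[i, ]) & !is.na(prov[j, ])
        if (!any(both)) next
        a <- ids[i]; b <- ids[j]
        pa <- prov[i, both]; pb <- prov[j, both]
        if (a > b) { tmp <- a; a <- b; b <- tmp; tp <- pa; pa <- pb; pb <- tp }
        out[[length(out) + 1L]] <- data.frame(
          seq_i = a, pos_i = unname(pa), seq_j = b, pos_j = unname(pb),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_i = character(), pos_i = integer(),
                      seq_j = character(), pos_j = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Canonical string keys for homology pairs
#'
#' @param h Data frame as returned by [extract_homologies()].
#' @return Character vector, one key per pair, usable for set operations.
#' @export
homology_keys <- function(h) {
  paste(h$seq_i, h$pos_i, h$seq_j, h$pos_j, sep = "\t")
}

# Resolve an msa / homology data frame / key vector into keys.
as_homology_keys <- function(x) {
  if (inherits(x, "msa")) return(homology_keys(extract_homologies(x)))
  if (is.data.frame(x)) return(homology_keys(x))
  if (is.character(x)) return(x)
  stop("cannot interpret object as a set of homologies", call. = FALSE)
}
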