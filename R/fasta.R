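# FASTA input/output (plain or gzip-compressed), via Biostrings.

#' Read sequences or an alignment from FASTA
#'
#' Headers are truncated at the first whitespace. Residues are uppercased and
#' `.` gaps are normalized to `-`. With `aligned = TRUE` all records must have
#' equal length and an [new_msa()] object is returned (with provenance); with
#' `aligned = FALSE` gap characters are stripped and a named character vector
#' of unaligned sequences is returned.
#'
#' @param path Path to a FASTA file (gzip transparently supported).
#' @param aligned Logical; interpret the records as an alignment?
#' @param on_invalid What to do with characters outside [seq_alphabet()]:
#'   `"reject"` (default, error) or `"mask"` (replace with `N`).
#' @return A named character vector of sequences, or an `msa`.
#' @export
read_fasta <- function(path, aligned = FALSE, on_invalid = c("reject", "mask")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
  x <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  x <- normalise_residues(x)
  x <- check_alphabet(x, on_invalid)
  if (aligned) {
    if (length(unique(nchar(x))) != 1)
      stop("aligned input has records of unequal length", call. = FALSE)
    msa_from_strings(x)
  } else {
    x <- gsub(GAP_CHAR, "", x, fixed = TRUE)
    as_seqs(x)
  }
}

#' Write sequences or an alignment to FASTA
#'
#' @param x Named character vector of sequences, or an `msa` (rows are
#'   written gapped).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (inherits(x, "msa")) x <- msa_strings(x)
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
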