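# GUIDANCE-style residue-pair support estimation from re-aligned replicates.

#' Score input-alignment homologies by replicate frequency
#'
#' For every residue-pair homology of the input alignment, a replicate
#' supports the pair if at least one column of the replicate's re-estimated
#' alignment contains an occurrence of both original residues (resampled
#' sequences can repeat residues; this binary rule reduces to classic
#' GUIDANCE scoring when every residue is sampled exactly once). The support
#' score is the number of supporting replicates divided by either the number
#' of replicates in which both residues were sampled at all
#' (`denominator = "cosampled"`, the default, which avoids deflating scores
#' of boundary-adjacent residues the walk visits less often) or the total
#' number of replicates (`"total"`).
#'
#' @param input_msa The `msa` being annotated.
#' @param replicates List of replicates, each a list with elements
#'   `alignment` (an `msa` of the resampled sequences) and `provenance`
#'   (named list mapping each resampled position to its 0-based original
#'   index, as produced by the walk functions).
#' @param denominator `"cosampled"` or `"total"`.
#' @return A `support_annotation`: data frame with the homology columns of
#'   [extract_homologies()] plus `support` (unit interval; `NA` when a pair
#'   was never co-sampled under the cosampled denominator), `n_supporting`
#'   and `n_cosampled`. Attributes `n_replicates` and `denominator`.
#' @export
pair_support <- function(input_msa, replicates,
                         denominator = c("cosampled", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(input_msa, "msa"))
  if (length(replicates) == 0)
    stop("at least one replicate is required", call. = FALSE)
  H <- extract_homologies(input_msa)
  keys <- homology_keys(H)
  ids <- msa_ids(input_msa)
  lens <- nchar(msa_sequences(input_msa))
  nH <- nrow(H)
  supp <- integer(nH)
  cosamp <- integer(nH)
  sids <- sort(ids)

  for (rep in replicates) {
    aln <- rep$alignment
    prov <- rep$provenance
    stopifnot(inherits(aln, "msa"))
    if (!setequal(msa_ids(aln), ids))
      stop("replicate alignment ids differ from input alignment ids",
           call. = FALSE)
    # Map every non-gap cell to its original residue index.
    omat <- aln$provenance
    for (id in ids) {
      rowv <- omat[id, ]
      nn <- !is.na(rowv)
      rowv[nn] <- prov[[id]][rowv[nn] + 1L]
      omat[id, ] <- rowv
    }
    # Homology keys realized in this replicate.
    rk <- vector("list", length(sids) * (length(sids) - 1) / 2)
    p <- 0L
    for (i in seq_len(length(sids) - 1)) {
      for (j in seq(i + 1, length(sids))) {
        a <- sids[i]; b <- sids[j]
        both <- !is.na(omat[a, ]) & !is.na(omat[b, ])
        p <- p + 1L
        if (any(both))
          rk[[p]] <- paste(a, omat[a, both], b, omat[b, both], sep = "\t")
      }
    }
    supp <- supp + (keys %in% unlist(rk, use.names = FALSE))
    # Which original residues were sampled at all in this replicate.
    samp <- lapply(ids, function(id) {
      v <- logical(lens[[id]]); v[prov[[id]] + 1L] <- TRUE; v
    })
    names(samp) <- ids
    ci <- logical(nH); cj <- logical(nH)
    for (id in ids) {
      w <- H$seq_i == id
      if (any(w)) ci[w] <- samp[[id]][H$pos_i[w] + 1L]
      w <- H$seq_j == id
      if (any(w)) cj[w] <- samp[[id]][H$pos_j[w] + 1L]
    }
    cosamp <- cosamp + (ci & cj)
  }

  denom <- if (denominator == "cosampled") cosamp else
    rep(length(replicates), nH)
  support <- ifelse(denom > 0, supp / denom, NA_real_)
  out <- cbind(H, support = support, n_supporting = supp,
               n_cosampled = cosamp)
  attr(out, "n_replicates") <- length(replicates)
  attr(out, "denominator") <- denominator
  class(out) <- c("support_annotation", "data.frame")
  out
}

#' Full SERES support-estimation pipeline
#'
#' Orchestrates resampling, re-alignment and scoring for an input alignment:
#' estimate anchors on the guide alignment, convert them to barriers, draw
#' `n_replicates` SERES walks over the unaligned sequences, re-align each
#' replicate, and score every input homology by its replicate frequency.
#' `method = "bootstrap"` replaces the walk by standard column resampling
#' with replacement (the site-i.i.d. baseline) and `method = "seres-aligned"`
#' by a SERES walk over the columns of the input alignment; in both cases
#' the resampled columns are degapped into unaligned replicate sequences and
#' re-aligned so that all three modes are directly comparable.
#'
#' Defaults follow the standard parameterization: `gamma = 0.5`,
#' 100 replicates, `floor(k/20)` anchors of 5 columns with minimum spacing
#' of 25 columns.
#'
#' To pool externally generated replicates (e.g. parametrically perturbed
#' alignments) with SERES replicates, call [pair_support()] directly on the
#' combined replicate list.
#'
#' @param input_msa The `msa` to annotate.
#' @param method `"seres"`, `"bootstrap"` or `"seres-aligned"`.
#' @param n_replicates Number of replicates (>= 1).
#' @param gamma Reversal probability.
#' @param length_factor Termination threshold of the unaligned walk.
#' @param num_anchors,anchor_len,min_anchor_dist Anchor parameters (see
#'   [find_anchors()]); `num_anchors = NULL` means `floor(k/20)`.
#' @param guide Guide `msa` for anchor estimation (default: the input).
#' @param aligner An `aligner_spec` used to re-align replicates.
#' @param seed Optional master seed; replicate `r` uses a child seed derived
#'   by a stable counter scheme, so the first replicates are identical
#'   regardless of `n_replicates`.
#' @param denominator Passed to [pair_support()].
#' @param na_support Value substituted for pairs never co-sampled under the
#'   cosampled denominator (default 0: no evidence, no support). Use `NA`
#'   to keep them undefined.
#' @param walk_start,walk_direction Optional fixed start barrier/site and
#'   direction for every walk (mainly for degenerate identity pipelines).
#' @return A `support_annotation` (see [pair_support()]).
#' @export
run_support_pipeline <- function(input_msa,
                                 method = c("seres", "bootstrap",
                                            "seres-aligned"),
                                 n_replicates = 100, gamma = 0.5,
                                 length_factor = 1, num_anchors = NULL,
                                 anchor_len = 5, min_anchor_dist = 25,
                                 guide = input_msa,
                                 aligner = aligner_builtin(), seed = NULL,
                                 denominator = "cosampled", na_support = 0,
                                 walk_start = NULL, walk_direction = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(input_msa, "msa"))
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("n_replicates must be >= 1", call. = FALSE)
  seqs <- msa_sequences(input_msa)
  k <- msa_length(input_msa)
  barriers <- NULL
  if (method == "seres") {
    anc <- find_anchors(guide, num_anchors = num_anchors,
                        anchor_len = anchor_len, min_dist = min_anchor_dist)
    barriers <- anchors_to_barriers(guide, anc)
  }
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, r))
    rep <- switch(method,
      seres = sample_unaligned_replicate(seqs, barriers, gamma = gamma,
                                         length_factor = length_factor,
                                         start = walk_start,
                                         direction = walk_direction),
      bootstrap = replicate_from_columns(
        input_msa, sample.int(k, k, replace = TRUE) - 1L),
      `seres-aligned` = replicate_from_columns(
        input_msa, sample_aligned_trace(k, gamma, start = walk_start,
                                        direction = walk_direction)))
    reps[[r]] <- list(alignment = realign_replicate(rep, aligner),
                      provenance = rep$provenance)
  }
  ann <- pair_support(input_msa, reps, denominator = denominator)
  if (!is.null(na_support) && !is.na(na_support))
    ann$support[is.na(ann$support)] <- na_support
  ann
}

#' Column-mean and residue-mean support summaries
#'
#' Convenience aggregations of a pair-level annotation: `column_support()`
#' averages the supports of the homologies asserted by each alignment
#' column; `residue_support()` averages, for each residue, the supports of
#' all pairs it participates in.
#'
#' @param annotation A `support_annotation` for `msa`.
#' @param msa The annotated `msa`.
#' @return A data frame.
#' @export
column_support <- function(annotation, msa) {
  stopifnot(inherits(msa, "msa"))
  prov <- msa$provenance
  # The column of a pair is the column where seq_i's residue pos_i sits.
  colof <- function(id, pos) {
    row <- prov[id, ]
    match(pos, row)
  }
  cols <- mapply(colof, annotation$seq_i, annotation$pos_i)
  agg <- tapply(annotation$support, cols, mean, na.rm = TRUE)
  data.frame(column = as.integer(names(agg)) - 1L,
             mean_support = as.numeric(agg))
}

#' @rdname column_support
#' @export
residue_support <- function(annotation, msa) {
  long <- rbind(
    data.frame(id = annotation$seq_i, pos = annotation$pos_i,
               support = annotation$support),
    data.frame(id = annotation$seq_j, pos = annotation$pos_j,
               support = annotation$support))
  agg <- stats::aggregate(support ~ id + pos, data = long, FUN = mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  agg[order(agg$id, agg$pos), , drop = FALSE]
}
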