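# Fixture generators and independent oracles used across the suite.

rand_seqs <- function(n, min_len = 10, max_len = 40, ids = NULL) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  x <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  setNames(x, ids %||% paste0("s", seq_len(n)))
}

rand_msa <- function(n, k, gap_prob = 0.2, ids = NULL) {
  repeat {
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), n * k, replace = TRUE,
                         prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
                  n, k)
    if (all(rowSums(mat != "-") > 0)) break
  }
  rownames(mat) <- ids %||% paste0("s", seq_len(n))
  new_msa(mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain dynamic-programming global alignment score (no traceback); written
# independently of the compiled implementation.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  S <- matrix(0, la + 1, lb + 1)
  S[, 1] <- (0:la) * gap
  S[1, ] <- (0:lb) * gap
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + if (av[i] == bv[j]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap)
    }
  }
  S[la + 1, lb + 1]
}

# Brute-force pairwise homology enumeration of an alignment: loop over every
# column and every pair of rows, no provenance machinery.
oracle_homologies <- function(msa) {
  mat <- msa$matrix
  ids <- rownames(mat)
  res <- character(0)
  pos <- matrix(0L, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) {
    c0 <- -1L
    for (j in seq_len(ncol(mat))) {
      if (mat[i, j] != "-") { c0 <- c0 + 1L; pos[i, j] <- c0 }
      else pos[i, j] <- NA
    }
  }
  for (j in seq_len(ncol(mat))) {
    rows <- which(!is.na(pos[, j]))
    if (length(rows) < 2) next
    for (a in seq_len(length(rows) - 1)) {
      for (b in seq(a + 1, length(rows))) {
        i1 <- rows[a]; i2 <- rows[b]
        id1 <- ids[i1]; id2 <- ids[i2]
        p1 <- pos[i1, j]; p2 <- pos[i2, j]
        if (id1 > id2) { t <- id1; id1 <- id2; id2 <- t
                         tp <- p1; p1 <- p2; p2 <- tp }
        res <- c(res, paste(id1, p1, id2, p2, sep = "\t"))
      }
    }
  }
  res
}

# Exhaustive support oracle: for every input homology and every replicate,
# scan all replicate-alignment columns for a co-occurrence of the two
# original residues (via the replicate provenance maps), and count
# co-sampling by direct membership tests.
oracle_pair_support <- function(input_msa, replicates,
                                denominator = "cosampled") {
  H <- extract_homologies(input_msa)
  n_sup <- integer(nrow(H)); n_cos <- integer(nrow(H))
  for (rep in replicates) {
    aln <- rep$alignment; prov <- rep$provenance
    mat <- aln$matrix
    rp <- aln$provenance
    for (h in seq_len(nrow(H))) {
      a <- H$seq_i[h]; b <- H$seq_j[h]
      pa <- H$pos_i[h]; pb <- H$pos_j[h]
      cos <- (pa %in% prov[[a]]) && (pb %in% prov[[b]])
      n_cos[h] <- n_cos[h] + cos
      if (!cos) next
      hit <- FALSE
      for (j in seq_len(ncol(mat))) {
        ra <- rp[a, j]; rb <- rp[b, j]
        if (!is.na(ra) && !is.na(rb) &&
            prov[[a]][ra + 1] == pa && prov[[b]][rb + 1] == pb) {
          hit <- TRUE; break
        }
      }
      n_sup[h] <- n_sup[h] + hit
    }
  }
  den <- if (denominator == "cosampled") n_cos
         else rep(length(replicates), nrow(H))
  ifelse(den > 0, n_sup / den, NA_real_)
}

# Mann-Whitney formulation of ROC-AUC: fraction of (positive, negative)
# score pairs ranked correctly, ties counting one half.
oracle_mw_auc <- function(scores, labels) {
  p <- scores[as.logical(labels)]
  n <- scores[!as.logical(labels)]
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force confusion counts by direct set definitions.
oracle_confusion <- function(true_keys, est_keys, supports, thr) {
  lab <- est_keys %in% true_keys
  pos <- supports >= thr
  list(tp = sum(lab & pos), fp = sum(!lab & pos),
       fn = sum(lab & !pos), tn = sum(!lab & !pos))
}

# Check the neighbor-preservation property of an unaligned replicate:
# within every barrier traversal, consecutive resampled residues of every
# sequence must be adjacent (and correctly ordered) in the original.
check_neighbor_preservation <- function(rep, barriers) {
  off <- barriers$offsets
  st <- rep$segment_trace
  for (s in seq_along(rep$provenance)) {
    p <- rep$provenance[[s]]
    at <- 0L
    for (tr in seq_len(nrow(st))) {
      b1 <- st[tr, 1] + 1L; b2 <- st[tr, 2] + 1L
      len <- abs(off[b2, s] - off[b1, s])
      if (len == 0) next
      seg <- p[(at + 1L):(at + len)]
      at <- at + len
      if (len > 1) {
        d <- diff(seg)
        expected <- if (b2 > b1) 1L else -1L
        if (!all(d == expected)) return(FALSE)
      }
    }
    if (at != length(p)) return(FALSE)
  }
  TRUE
}

# Brute-force anchor audit: every selected anchor is gap-free, spacing is
# respected, and under the greedy order each selection had minimal ANHD
# among windows compatible with the previously selected ones.
check_anchor_greedy <- function(guide, anchors, anchor_len, min_dist,
                                num_anchors) {
  k <- msa_length(guide)
  mat <- guide$matrix
  all_starts <- 0:(k - anchor_len)
  gapfree <- vapply(all_starts, function(s)
    all(mat[, (s + 1):(s + anchor_len)] != "-"), logical(1))
  anhd_all <- vapply(all_starts, function(s)
    window_anhd(guide, s, anchor_len), numeric(1))
  compatible <- function(s, chosen) {
    for (t in chosen) {
      gap <- if (s >= t + anchor_len) s - (t + anchor_len)
             else if (t >= s + anchor_len) t - (s + anchor_len) else -1L
      if (gap < min_dist) return(FALSE)
    }
    TRUE
  }
  # Re-run the greedy selection by brute force and compare.
  chosen <- integer(0)
  ord <- order(anhd_all, all_starts)
  for (o in ord) {
    if (length(chosen) >= num_anchors) break
    s <- all_starts[o]
    if (!gapfree[o]) next
    if (compatible(s, chosen)) chosen <- c(chosen, s)
  }
  identical(sort(chosen), sort(anchors$start_col))
}

make_tiny_msa <- function(strings) msa_from_strings(strings)

# A synthetic support annotation over explicit homology keys.
fake_scores <- function(keys, supports) {
  parts <- strsplit(keys, "\t", fixed = TRUE)
  d <- data.frame(seq_i = vapply(parts, `[`, "", 1),
                  pos_i = as.integer(vapply(parts, `[`, "", 2)),
                  seq_j = vapply(parts, `[`, "", 3),
                  pos_j = as.integer(vapply(parts, `[`, "", 4)),
                  support = supports, stringsAsFactors = FALSE)
  class(d) <- c("support_annotation", "data.frame")
  d
}

keyset <- function(...) paste("a", c(...), "b", c(...), sep = "\t")
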