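# Synthetic data generator: birth-death model trees, GTR substitutions, and
# an insertion/deletion process with homology bookkeeping, so that every
# stage of the support-estimation pipeline can be exercised against a known
# true alignment.

STATE_CHARS <- c("A", "C", "G", "T")

#' GTR substitution model
#'
#' Builds the rate matrix from six exchangeabilities (order AC, AG, AT, CG,
#' CT, GT) and four base frequencies, normalized to one expected
#' substitution per site per unit time, and precomputes the spectral
#' decomposition used for transition probabilities. The defaults are a
#' generic transition/transversion-biased nucleotide model; both parameters
#' are fully overridable.
#'
#' @param rates Six exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param freqs Four base frequencies (A, C, G, T); normalized to sum to 1.
#' @return A `gtr_model` with the rate matrix `Q`, `freqs`, and cached
#'   eigendecomposition.
#' @export
gtr_model <- function(rates = c(1, 3, 1, 1, 3, 1),
                      freqs = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)) {
  stopifnot(length(rates) == 6, length(freqs) == 4)
  if (any(rates <= 0) || any(freqs <= 0))
    stop("GTR rates and frequencies must be positive", call. = FALSE)
  freqs <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4, dimnames = list(STATE_CHARS, STATE_CHARS))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Q[i, j] <- rates[p] * freqs[j]
    Q[j, i] <- rates[p] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  # Reversibility makes D^{1/2} Q D^{-1/2} symmetric; eigendecompose once.
  sf <- sqrt(freqs)
  B <- outer(sf, 1 / sf) * Q
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(Q = Q, freqs = freqs, values = e$values, vectors = e$vectors,
                 sf = sf), class = "gtr_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A `gtr_model`.
#' @param t Elapsed time (branch length in expected substitutions per site).
#' @return 4x4 row-stochastic matrix.
#' @export
gtr_pmat <- function(model, t) {
  V <- model$vectors
  P <- (1 / model$sf) * (V %*% (exp(model$values * t) * t(V))) * rep(model$sf,
                                                                each = 4)
  P[P < 0] <- 0
  P / rowSums(P)
  }

#' Geometric gap-length distribution
#'
#' Indel lengths are drawn from a geometric distribution on `{1, 2, ...}`
#' with the given mean. The gap-length distribution is a pluggable
#' component: any function of `n` returning `n` positive integer lengths
#' can be supplied in its place.
#'
#' @param mean Mean indel length (> 1 allows multi-residue events).
#' @return A function `n -> n` lengths.
#' @export
gap_length_geometric <- function(mean = 4) {
  stopifnot(mean >= 1)
  p <- 1 / mean
  function(n) rgeom(n, p) + 1L
}

#' Simulation parameters
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param height Target tree height (root-to-furthest-leaf path length, in
#'   expected substitutions per site).
#' @param indel_prob Insertion/deletion event rate per site relative to the
#'   substitution rate (each of insertion and deletion occurs at this rate).
#' @param root_length Root sequence length in residues.
#' @param gtr A [gtr_model()].
#' @param gap_length Gap-length sampler, e.g. [gap_length_geometric()].
#' @param birth,death Birth-death rates for topology sampling (default is a
#'   pure-birth (Yule) process; the topology shape is largely irrelevant
#'   because branch lengths are redrawn uniformly afterwards).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_taxa = 10, height = 1, indel_prob = 0.06,
                       root_length = 1000, gtr = gtr_model(),
                       gap_length = gap_length_geometric(4),
                       birth = 1, death = 0) {
  stopifnot(n_taxa >= 2, height > 0, indel_prob >= 0, root_length >= 1)
  structure(list(n_taxa = as.integer(n_taxa), height = height,
                 indel_prob = indel_prob,
                 root_length = as.integer(root_length), gtr = gtr,
                 gap_length = gap_length, birth = birth, death = death),
            class = "sim_params")
}

#' Sample a model tree
#'
#' Topology from a birth-death process, branch lengths redrawn uniformly at
#' random from (0, 1), then all branches rescaled by `height / h0` so the
#' tree height equals `height` exactly.
#'
#' @param n_taxa Number of leaves.
#' @param height Target height.
#' @param birth,death Birth-death rates.
#' @return An [ape::rphylo()]-style `phylo` object.
#' @export
sample_tree <- function(n_taxa, height, birth = 1, death = 0) {
  if (n_taxa < 2) stop("need at least two taxa", call. = FALSE)
  tr <- ape::rphylo(n_taxa, birth = birth, death = death)
  tr$edge.length <- runif(nrow(tr$edge))
  h0 <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / h0)
  tr
}

rcat_rows <- function(pm) {
  # One categorical draw per row of a row-stochastic matrix.
  cp <- t(apply(pm, 1, cumsum))
  if (nrow(pm) == 1) cp <- matrix(cp, nrow = 1)
  u <- runif(nrow(pm))
  1L + rowSums(u > cp[, 1:3, drop = FALSE])
}

# Evolve one branch: indel events via a Gillespie process (insertion rate
# indel_prob * (L + 1) across slots, deletion rate indel_prob * L across
# sites), then substitutions applied analytically per site for its exposure
# time. Inserted residues draw their initial state from the stationary
# frequencies and are assigned fresh homology-column ids, spliced into the
# global column order next to their insertion anchor. Deletions truncate at
# the sequence end.
evolve_branch <- function(state, t, params, genv) {
  ids <- state$ids; st <- state$states
  btime <- numeric(length(ids))
  tau <- 0
  ri <- params$indel_prob
  if (ri > 0) {
    repeat {
      L <- length(ids)
      rate <- ri * (2 * L + 1)
      tau <- tau + rexp(1, rate)
      if (tau >= t) break
      if (runif(1) < (L + 1) / (2 * L + 1)) {
        pos <- sample.int(L + 1L, 1L) - 1L          # residues to the left
        len <- as.integer(params$gap_length(1))
        newids <- genv$counter + seq_len(len)
        genv$counter <- genv$counter + len
        newst <- sample.int(4L, len, replace = TRUE, prob = params$gtr$freqs)
        ids <- append(ids, newids, after = pos)
        st <- append(st, newst, after = pos)
        btime <- append(btime, rep(tau, len), after = pos)
        after <- if (pos > 0) match(ids[pos], genv$order)
                 else if (L > 0) match(ids[len + 1L], genv$order) - 1L
                 else length(genv$order)
        genv$order <- append(genv$order, newids, after = after)
      } else if (L > 0) {
        startp <- sample.int(L, 1L)
        len <- as.integer(params$gap_length(1))
        del <- seq.int(startp, min(L, startp + len - 1L))
        ids <- ids[-del]; st <- st[-del]; btime <- btime[-del]
      }
      if (length(ids) == 0 && ri == 0) break
    }
  }
  if (length(ids)) {
    for (bt in unique(btime)) {
      w <- which(btime == bt)
      P <- gtr_pmat(params$gtr, t - bt)
      st[w] <- rcat_rows(P[st[w], , drop = FALSE])
    }
  }
  list(ids = ids, states = st)
}

#' Evolve sequences down a model tree
#'
#' Runs the GTR substitution process and the indel process along every
#' branch, tracking residue homology through all insertions and deletions,
#' and assembles the true alignment: one column per homology class that
#' survives in at least one leaf.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param params A [sim_params()] object.
#' @return A `sim_bundle`: list with `tree`, `msa` (the true alignment),
#'   `sequences` (the degapped leaf sequences), and `params`. Degapping the
#'   true alignment reproduces `sequences` exactly.
#' @export
evolve_sequences <- function(tree, params) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "sim_params"))
  nt <- length(tree$tip.label)
  genv <- new.env()
  genv$order <- seq_len(params$root_length)
  genv$counter <- params$root_length
  root_states <- sample.int(4L, params$root_length, replace = TRUE,
                            prob = params$gtr$freqs)
  store <- vector("list", nt + tree$Nnode)
  store[[nt + 1L]] <- list(ids = seq_len(params$root_length),
                           states = root_states)
  tre <- ape::reorder.phylo(tree, "postorder")
  for (ei in rev(seq_len(nrow(tre$edge)))) {
    par <- tre$edge[ei, 1]; ch <- tre$edge[ei, 2]
    store[[ch]] <- evolve_branch(store[[par]], tre$edge.length[ei], params,
                                 genv)
  }
  leaves <- store[seq_len(nt)]
  alive <- unique(unlist(lapply(leaves, `[[`, "ids")))
  cols <- genv$order[genv$order %in% alive]
  mat <- matrix(GAP_CHAR, nt, length(cols),
                dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(nt)) {
    if (length(leaves[[i]]$ids) == 0)
      stop("a lineage lost its entire sequence; increase root_length or ",
           "decrease indel_prob", call. = FALSE)
    idx <- match(leaves[[i]]$ids, cols)
    mat[i, idx] <- STATE_CHARS[leaves[[i]]$states]
  }
  msa <- new_msa(mat)
  structure(list(tree = tree, msa = msa, sequences = msa_sequences(msa),
                 params = params), class = "sim_bundle")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: sample a model tree and evolve sequences down it.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional RNG seed.
#' @return A `sim_bundle`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- sample_tree(params$n_taxa, params$height, params$birth,
                      params$death)
  evolve_sequences(tree, params)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d taxa, true alignment %d columns\n",
              msa_nseq(x$msa), msa_length(x$msa)))
  invisible(x)
}

#' Summary statistics of a simulated dataset
#'
#' @param bundle A `sim_bundle`.
#' @return List with `anhd` (average normalized Hamming distance over the
#'   true alignment, indels as mismatches), `gappiness` (fraction of gap
#'   cells) and `true_align_length`.
#' @export
summary_stats <- function(bundle) {
  stopifnot(inherits(bundle, "sim_bundle"))
  m <- bundle$msa
  list(anhd = window_anhd(m),
       gappiness = mean(m$matrix == GAP_CHAR),
       true_align_length = msa_length(m))
}

#' Sum-of-pairs error rates between two alignments
#'
#' `sp_fn` is the proportion of reference-alignment homologies absent from
#' the estimated alignment; `sp_fp` the proportion of estimated-alignment
#' homologies absent from the reference. Both alignments must be over
#' identical sequences.
#'
#' @param true_msa,est_msa `msa` objects over the same sequences.
#' @return List with `sp_fn` and `sp_fp`.
#' @export
pair_error_rates <- function(true_msa, est_msa) {
  stopifnot(inherits(true_msa, "msa"), inherits(est_msa, "msa"))
  st <- msa_sequences(true_msa); se <- msa_sequences(est_msa)
  if (!setequal(names(st), names(se)) ||
      !identical(st[sort(names(st))], se[sort(names(se))]))
    stop("alignments are not over the same sequences", call. = FALSE)
  tk <- homology_keys(extract_homologies(true_msa))
  ek <- homology_keys(extract_homologies(est_msa))
  list(sp_fn = mean(!(tk %in% ek)), sp_fp = mean(!(ek %in% tk)))
}
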