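test_that("rescaled model trees hit the target height exactly", {
  set.seed(901)
  for (h in c(0.4, 1, 4.3)) {
    tr <- sample_tree(10, h)
    expect_equal(length(tr$tip.label), 10)
    expect_equal(max(ape::node.depth.edgelength(tr)), h, tolerance = 1e-9)
  }
  expect_error(sample_tree(1, 1), "two taxa")
})

test_that("without indels the true alignment is the gap-free root length", {
  p <- sim_params(n_taxa = 6, height = 0.8, indel_prob = 0,
                  root_length = 150)
  b <- simulate_dataset(p, seed = 902)
  st <- summary_stats(b)
  expect_equal(st$gappiness, 0)
  expect_equal(st$true_align_length, 150)
  expect_true(all(nchar(b$sequences) == 150))
})

test_that("a vanishing tree height leaves all sequences identical", {
  p <- sim_params(n_taxa = 5, height = 1e-9, indel_prob = 0,
                  root_length = 200)
  b <- simulate_dataset(p, seed = 903)
  expect_equal(length(unique(b$sequences)), 1)
  expect_equal(summary_stats(b)$anhd, 0)
})

test_that("degapping the true alignment reproduces the leaf sequences", {
  p <- sim_params(n_taxa = 8, height = 1, indel_prob = 0.08,
                  root_length = 120)
  set.seed(904)
  for (i in 1:5) {
    b <- simulate_dataset(p)
    expect_identical(msa_sequences(b$msa), b$sequences)
    # provenance indices strictly increasing along every row
    for (r in seq_len(msa_nseq(b$msa))) {
      pr <- b$msa$provenance[r, ]
      expect_true(all(diff(pr[!is.na(pr)]) == 1))
    }
  }
})

test_that("transition probabilities match the matrix exponential", {
  g <- gtr_model(rates = c(0.8, 2.5, 1.1, 0.9, 3.2, 1),
                 freqs = c(0.35, 0.18, 0.22, 0.25))
  for (t in c(0.01, 0.3, 1, 5)) {
    expect_equal(gtr_pmat(g, t), ape::matexpo(g$Q * t), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(rowSums(gtr_pmat(g, 2)), rep(1, 4), tolerance = 1e-12)
  # stationarity: pi P(t) = pi
  expect_equal(as.numeric(g$freqs %*% gtr_pmat(g, 0.7)),
               as.numeric(g$freqs), tolerance = 1e-10)
  expect_error(gtr_model(freqs = c(0, 0.4, 0.3, 0.3)), "positive")
})

test_that("pairwise divergence matches the substitution process", {
  # Two taxa at total path length t, no indels: the expected fraction of
  # mismatching sites has the closed form sum_a pi_a sum_b P_ab(t1) P_ab(t2)
  # computed here with the independent matrix-exponential oracle.
  g <- gtr_model()
  t1 <- 0.35; t2 <- 0.25
  P1 <- ape::matexpo(g$Q * t1); P2 <- ape::matexpo(g$Q * t2)
  p_same <- sum(g$freqs * rowSums(P1 * P2))
  p_mm <- 1 - p_same

  tr <- ape::read.tree(text = sprintf("(t1:%f,t2:%f);", t1, t2))
  p <- sim_params(n_taxa = 2, height = 1, indel_prob = 0, root_length = 1000)
  set.seed(905)
  mm <- replicate(10, {
    b <- evolve_sequences(tr, p)
    window_anhd(b$msa)
  })
  se <- sqrt(p_mm * (1 - p_mm) / (1000 * 10))
  expect_lt(abs(mean(mm) - p_mm), 3 * se + 1e-9)
})

test_that("simulation is seed-deterministic and height drives divergence", {
  p <- sim_params(n_taxa = 5, height = 1, indel_prob = 0.05,
                  root_length = 100)
  b1 <- simulate_dataset(p, seed = 906)
  b2 <- simulate_dataset(p, seed = 906)
  expect_identical(b1$sequences, b2$sequences)
  b3 <- simulate_dataset(p, seed = 907)
  expect_false(identical(b1$sequences, b3$sequences))

  anhd_at <- function(h) mean(vapply(1:3, function(s) {
    pp <- sim_params(n_taxa = 6, height = h, indel_prob = 0,
                     root_length = 150)
    summary_stats(simulate_dataset(pp, seed = 908 + s))$anhd
  }, numeric(1)))
  a <- anhd_at(0.1); bb <- anhd_at(0.7); cc <- anhd_at(3)
  expect_true(a < bb && bb < cc)
})

test_that("summary statistics implement the direct definitions", {
  m <- make_tiny_msa(c(a = "AC-T", b = "ACGT"))
  fake <- structure(list(msa = m), class = "sim_bundle")
  st <- summary_stats(fake)
  expect_equal(st$gappiness, 1 / 8)
  expect_equal(st$anhd, 0.25)
  expect_equal(st$true_align_length, 4)
})

test_that("sum-of-pairs error rates match set differences", {
  t <- make_tiny_msa(c(a = "ACGT", b = "ACGT"))
  expect_equal(pair_error_rates(t, t), list(sp_fn = 0, sp_fp = 0))

  # disjoint homology sets: both rates 1
  t2 <- make_tiny_msa(c(a = "AC", b = "CA"))
  e2 <- make_tiny_msa(c(a = "AC-", b = "-CA"))
  expect_equal(pair_error_rates(t2, e2), list(sp_fn = 1, sp_fp = 1))

  # 3-sequence toy vs exhaustive enumeration
  t3 <- make_tiny_msa(c(a = "AC-G", b = "ACTG", c = "AC-G"))
  e3 <- make_tiny_msa(c(a = "ACG-", b = "ACTG", c = "AC-G"))
  tk <- oracle_homologies(t3); ek <- oracle_homologies(e3)
  expect_equal(pair_error_rates(t3, e3),
               list(sp_fn = mean(!(tk %in% ek)), sp_fp = mean(!(ek %in% tk))))
  expect_error(pair_error_rates(t, t2), "same sequences")
})
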