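# Build a replicate list from explicit column choices of an input MSA,
# re-aligned with the builtin aligner.
column_replicates <- function(msa, col_lists, aligner = aligner_builtin()) {
  lapply(col_lists, function(cols) {
    rep <- replicate_from_columns(msa, cols)
    list(alignment = realign_replicate(rep, aligner),
         provenance = rep$provenance)
  })
}

test_that("identity replicates give support 1 for every homology", {
  m <- make_tiny_msa(c(a = "ACGTT", b = "AC-TT", c = "ACGT-"))
  k <- msa_length(m)
  reps <- lapply(1:3, function(i)
    list(alignment = m, provenance = setNames(
      lapply(msa_ids(m), function(id) 0:(nchar(msa_sequences(m)[[id]]) - 1)),
      msa_ids(m))))
  ann <- pair_support(m, reps)
  expect_true(all(ann$support == 1))
  expect_true(all(ann$n_cosampled == 3))
})

test_that("support equals supporting over co-sampling replicates", {
  # Two sequences, two columns; replicates alternate between sampling the
  # pair's column and not sampling it at all.
  m <- make_tiny_msa(c(a = "AC", b = "AC"))
  with_col0 <- column_replicates(m, list(c(0L, 0L), 0L))
  with_col1 <- column_replicates(m, list(1L))
  ann <- pair_support(m, c(with_col0, with_col1))
  df <- as.data.frame(ann)
  p0 <- df[df$pos_i == 0, ]
  expect_equal(p0$n_cosampled, 2)      # column 1 replicate never samples it
  expect_equal(p0$support, 1)
  annT <- pair_support(m, c(with_col0, with_col1), denominator = "total")
  expect_equal(as.data.frame(annT)[df$pos_i == 0, "support"], 2 / 3)
})

test_that("pair support equals the exhaustive column-scan oracle", {
  set.seed(701)
  for (i in 1:12) {
    n <- sample(3:5, 1)
    m <- rand_msa(n, sample(8:16, 1), gap_prob = 0.15)
    nrep <- sample(2:6, 1)
    k <- msa_length(m)
    reps <- column_replicates(m, replicate(nrep,
      sample.int(k, sample(4:k, 1), replace = TRUE) - 1L, simplify = FALSE))
    for (den in c("cosampled", "total")) {
      ann <- pair_support(m, reps, denominator = den)
      expect_equal(ann$support, oracle_pair_support(m, reps, den))
    }
  }
})

test_that("support scores are invariant to replicate order and grow with
           identity replicates under the total denominator", {
  set.seed(702)
  m <- rand_msa(3, 12, gap_prob = 0.1)
  k <- msa_length(m)
  reps <- column_replicates(m, replicate(4,
    sample.int(k, k, replace = TRUE) - 1L, simplify = FALSE))
  a1 <- pair_support(m, reps)
  a2 <- pair_support(m, rev(reps))
  expect_equal(a1$support, a2$support)

  before <- pair_support(m, reps, denominator = "total")$support
  idrep <- list(list(alignment = m, provenance = setNames(
    lapply(msa_ids(m), function(id) 0:(nchar(msa_sequences(m)[[id]]) - 1)),
    msa_ids(m))))
  after <- pair_support(m, c(reps, idrep), denominator = "total")$support
  expect_true(all(after >= before - 1e-12))
})

test_that("the pipeline validates inputs and is seed-reproducible", {
  m <- make_tiny_msa(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGAACGTAC"))
  expect_error(run_support_pipeline(m, n_replicates = 0), ">= 1")
  s1 <- run_support_pipeline(m, method = "seres", n_replicates = 5, seed = 9)
  s2 <- run_support_pipeline(m, method = "seres", n_replicates = 5, seed = 9)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # first replicates are stable when more are requested
  s3 <- run_support_pipeline(m, method = "seres", n_replicates = 8, seed = 9)
  expect_true(all(s3$n_cosampled >= s1$n_cosampled))
})

test_that("degenerate identity walks give support 1 end to end", {
  m <- make_tiny_msa(c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "ACGTACGAAA"))
  for (method in c("seres", "seres-aligned")) {
    ann <- run_support_pipeline(m, method = method, n_replicates = 3,
                                gamma = 0, walk_start = 0,
                                walk_direction = "R", seed = 1)
    expect_true(all(ann$support == 1))
  }
})

test_that("bootstrap mode resamples columns with replacement", {
  set.seed(703)
  m <- rand_msa(3, 20, gap_prob = 0.1)
  ann <- run_support_pipeline(m, method = "bootstrap", n_replicates = 6,
                              seed = 4)
  expect_true(all(ann$support >= 0 & ann$support <= 1))
  expect_equal(nrow(ann), nrow(extract_homologies(m)))
})

test_that("column and residue summaries aggregate pair scores", {
  m <- make_tiny_msa(c(a = "ACG", b = "ACG", c = "ACG"))
  reps <- column_replicates(m, list(0:2, 0:2))
  ann <- pair_support(m, reps)
  cs <- column_support(ann, m)
  expect_equal(nrow(cs), 3)
  expect_true(all(cs$mean_support == 1))
  rs <- residue_support(ann, m)
  expect_true(all(rs$support == 1))
  expect_equal(nrow(rs), 9)
})
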