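# Needleman-Wunsch alignment and its identity convention.

test_that("alignment identity matches the stated examples", {
  expect_equal(nw_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(nw_identity("ACGT", "AGGT"), 0.75)
  expect_error(nw_align("", "ACGT"), "non-empty")
})

test_that("score and identity agree exactly with the recursion oracle on short pairs", {
  set.seed(101)
  for (i in 1:60) {
    a <- rand_seq(sample(1:12, 1))
    b <- rand_seq(sample(1:12, 1))
    got <- nw_align(a, b)
    want <- nw_oracle(a, b)
    expect_identical(got$score, want$score)
    expect_identical(got$matches, want$matches)
    expect_identical(got$columns, want$columns)
    expect_identical(got$identity, want$identity)
  }
})

test_that("identity matrix is symmetric, unit-diagonal and matches scalar calls", {
  set.seed(5)
  seqs <- vapply(1:6, function(i) rand_seq(40), character(1))
  m <- nw_identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 6))
  expect_equal(m[2, 5], nw_identity(seqs[2], seqs[5]))
  x <- nw_identity_matrix(seqs[1:2], seqs[3:6])
  expect_equal(dim(x), c(2, 4))
  expect_equal(x[1, 1], nw_identity(seqs[1], seqs[3]))
})

test_that("a single substitution yields identity (L-1)/L", {
  set.seed(9)
  s <- rand_seq(100)
  # one substitution cannot be rescued by gaps at -2 per base
  expect_equal(nw_identity(s, sub_at(s, 50)), 0.99)
  s20 <- rand_seq(20)
  expect_equal(nw_identity(s20, sub_at(s20, 10)), 0.95)
})
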