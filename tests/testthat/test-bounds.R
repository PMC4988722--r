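test_that("four-gamete test recognises incompatible character pairs", {
  x <- square_sample()
  dat <- unclass(x)
  expect_true(four_gamete_incompatible(dat[, 1], dat[, 2]))
  expect_false(four_gamete_incompatible(dat[, 1], dat[, 3])) # only 00 and 11
  expect_false(four_gamete_incompatible(dat[, 2], dat[, 2]))
  expect_error(four_gamete_incompatible(dat[, 1], dat[1:3, 2]), "length")
})

test_that("compatible-character exclusion keeps incompatibility carriers", {
  expect_equal(exclude_compatible_characters(square_sample()), 1:3)
  expect_equal(exclude_compatible_characters(compatible_sample()), integer(0))
  # quartet: matches direct pairwise enumeration
  x <- quartet_sample()
  pairs <- which(outer(1:7, 1:7, Vectorize(function(i, j) {
    i < j && four_gamete_incompatible(unclass(x)[, i], unclass(x)[, j])
  })), arr.ind = TRUE)
  expect_equal(exclude_compatible_characters(x), sort(unique(as.integer(pairs))))
})

test_that("local haplotype bound maximises over admissible subsets", {
  f5 <- square_sample()
  expect_equal(local_haplotype_bound(f5, c(1L, 2L)), 1L) # 4 haps - 2 - 1
  # subset {5, 7} separates all four sequences: 4 - 2 - 1 = 1
  expect_equal(local_haplotype_bound(quartet_sample(), c(1L, 7L)), 1L)
  # negative values floor at zero (only two haplotypes on characters 1..4)
  expect_equal(local_haplotype_bound(quartet_sample(), c(1L, 4L)), 0L)
  expect_equal(local_haplotype_bound(f5, c(2L, 2L)), 0L)
  expect_error(local_haplotype_bound(f5, c(2L, 9L)), "invalid")
})

test_that("R_MG matches exhaustive decomposition on the worked examples", {
  f5 <- square_sample()
  rmg <- myers_griffiths_bound(f5, s = 3, w = 3)
  expect_equal(rmg$value, 2L)
  expect_equal(nrow(rmg$witness), 2L)

  expect_equal(myers_griffiths_bound(compatible_sample())$value, 0L)

  f7 <- myers_griffiths_bound(quartet_sample(), s = 7, w = 7)
  expect_lte(f7$value, 2L)
  expect_gte(f7$value, hudson_kaplan_rm(quartet_sample())$value)
})

test_that("Hudson-Kaplan R_m counts disjoint incompatible gaps", {
  expect_equal(hudson_kaplan_rm(square_sample())$value, 2L)
  expect_equal(hudson_kaplan_rm(compatible_sample())$value, 0L)
  one_pair <- character_matrix(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_equal(hudson_kaplan_rm(one_pair)$value, 1L)
})

test_that("bound chain and monotonicity hold on random matrices", {
  set.seed(17)
  for (rep in 1:25) {
    x <- random_binary_matrix(sample(4:9, 1), sample(2:6, 1))
    m <- ncol(x)
    rmg <- myers_griffiths_bound(x)$value
    rm_ <- hudson_kaplan_rm(x)$value
    hap <- max(0L, nrow(unique_haplotypes(x)$matrix) - m - 1L)
    expect_gte(rmg, rm_)
    expect_gte(rm_, 0L)
    expect_gte(rmg, hap)
    # (s, w) = (m, m) dominates any smaller search box
    if (m >= 3L) {
      s2 <- sample(2:m, 1); w2 <- sample(1:m, 1)
      expect_gte(rmg, myers_griffiths_bound(x, s = s2, w = w2)$value)
    }
  }
})
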