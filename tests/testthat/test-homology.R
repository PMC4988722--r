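test_that("rips filtration enumerates simplices in face order", {
  # three points, all pairwise distance 1: full triangle at scale 1
  d <- matrix(1L, 3, 3); diag(d) <- 0L
  f <- rips_filtration(d)
  expect_equal(sum(f$dim == 0L), 3L)
  expect_equal(sum(f$dim == 1L), 3L)
  expect_equal(sum(f$dim == 2L), 1L)
  expect_equal(f$value[f$dim == 2L], 1)

  # two points at distance 4
  d2 <- matrix(c(0L, 4L, 4L, 0L), 2, 2)
  f2 <- rips_filtration(d2)
  expect_equal(nrow(f2), 3L)
  expect_equal(f2$value[f2$dim == 1L], 4)

  # faces never appear after cofaces; values are max pairwise distances
  x <- square_sample()
  fs <- rips_filtration(hamming_matrix(x))
  expect_true(all(diff(fs$value) >= 0 | diff(fs$dim) >= 0))
  tri <- fs[fs$dim == 2L, ]
  expect_equal(unique(tri$value), 3)    # all triangles fill at scale 3
  e <- fs[fs$dim == 1L, ]
  expect_equal(sort(e$value), c(1, 1, 2, 2, 3, 3))
  expect_error(rips_filtration(matrix(c(0, 2, 1, 0), 2, 2)), "symmetric")
})

test_that("worked-example barcodes match the rank oracle", {
  d5 <- hamming_matrix(square_sample())
  bc <- h1_persistence(d5)
  expect_equal(nrow(bc), 1L)
  expect_equal(bc$birth, 2L)
  expect_equal(bc$death, 3L)
  expect_equal(betti1_at_scale(d5, 2L), 1L)
  expect_equal(betti1_at_scale(d5, 3L), 0L)
  expect_equal(betti1_at_scale(d5, 0L), 0L)

  # 4-cycle with unit sides and diagonal 2
  d <- matrix(c(0, 1, 2, 1,
                1, 0, 1, 2,
                2, 1, 0, 1,
                1, 2, 1, 0), 4, 4)
  storage.mode(d) <- "integer"
  bc2 <- h1_persistence(d)
  expect_equal(as.data.frame(bc2), data.frame(birth = 1L, death = 2L),
               ignore_attr = TRUE)

  # any 3-point sample: triangles fill instantly, no bars
  expect_equal(nrow(h1_persistence(hamming_matrix(
    random_binary_matrix(3, 5)))), 0L)
})

test_that("bars alive at every scale equal the GF(2)-rank Betti oracle", {
  set.seed(23)
  for (rep in 1:40) {
    x <- random_binary_matrix(sample(4:12, 1), sample(2:8, 1))
    d <- hamming_matrix(x)
    bc <- h1_persistence(d)
    for (t in 0:max(d)) {
      expect_equal(sum(bc$birth <= t & bc$death > t), betti1_at_scale(d, t),
                   info = sprintf("rep %d scale %d", rep, t))
    }
  }
})

test_that("barcodes are invariant under row permutation", {
  set.seed(31)
  for (rep in 1:10) {
    x <- random_binary_matrix(sample(4:9, 1), sample(3:7, 1))
    perm <- sample(nrow(x))
    xp <- character_matrix(unclass(x)[perm, , drop = FALSE])
    b1 <- as.data.frame(h1_persistence(hamming_matrix(x)))
    b2 <- as.data.frame(h1_persistence(hamming_matrix(xp)))
    srt <- function(b) b[order(b$birth, b$death), , drop = FALSE]
    expect_equal(srt(b1), srt(b2), ignore_attr = TRUE)
  }
})

test_that("four-gamete-compatible samples have no loops at any scale", {
  x <- compatible_sample()
  expect_equal(nrow(h1_persistence(hamming_matrix(x))), 0L)
  # tree-generated data (zero recombination) is always compatible
  for (seed in 1:5) {
    sim <- simulate_coalescent(sim_params(8L, rho = 0, segsites = 7L),
                               seed = seed)
    expect_equal(nrow(h1_persistence(hamming_matrix(sim$matrix))), 0L)
  }
})

test_that("representative cycles are closed walks alive at birth", {
  d <- hamming_matrix(square_sample())
  bc <- h1_persistence(d)
  rep1 <- attr(bc, "representatives")[[1L]]
  # every vertex appears an even number of times: a GF(2) cycle
  expect_true(all(table(as.integer(rep1)) %% 2L == 0L))
  expect_equal(max(d[rep1]), bc$birth)
})
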