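test_that("the three dialects parse and validate", {
  dir <- withr::local_tempdir()

  # plain matrix: the four-sequence sample prints back identically
  mp <- file.path(dir, "sample.txt")
  writeLines(c("1111001", "1111111", "0000110", "0000000"), mp)
  x <- read_alignment(mp, "matrix")
  expect_equal(dim(x), c(4L, 7L))
  expect_equal(unname(unclass(x)[1, ]), c(1L, 1L, 1L, 1L, 0L, 0L, 1L))

  # fasta with {0,1} alphabet
  fp <- file.path(dir, "sample.fa")
  writeLines(c(">a", "000", ">b", "010", ">c", "101", ">d", "111"), fp)
  xf <- read_alignment(fp, "fasta")
  expect_equal(rownames(xf), c("a", "b", "c", "d"))
  expect_equal(unname(unclass(xf)[2, ]), c(0L, 1L, 0L))

  # ms block: positions become coordinates
  mps <- file.path(dir, "sample.ms")
  writeLines(c("ms 4 1", "1 2 3", "", "//", "segsites: 3",
               "positions: 0.1 0.5 0.9", "000", "010", "101", "111"), mps)
  xm <- read_alignment(mps, "ms")
  expect_equal(dim(xm), c(4L, 3L))
  expect_equal(positions(xm), c(0.1, 0.5, 0.9))

  # auto-detection picks the right dialect for all three
  expect_equal(dim(read_alignment(mp)), c(4L, 7L))
  expect_equal(rownames(read_alignment(fp)), c("a", "b", "c", "d"))
  expect_equal(positions(read_alignment(mps)), c(0.1, 0.5, 0.9))
})

test_that("malformed input is rejected with located errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.txt")
  writeLines(c("0101", "0120"), bad)
  expect_error(read_alignment(bad, "matrix"), "non-binary symbol '2'")
  expect_error(read_alignment(bad, "matrix"), "line 2, column 3")

  ragged <- file.path(dir, "ragged.txt")
  writeLines(c("0101", "011"), ragged)
  expect_error(read_alignment(ragged, "matrix"), "ragged")

  empty <- file.path(dir, "empty.txt")
  writeLines(character(0), empty)
  expect_error(read_alignment(empty, "matrix"), "empty input")

  expect_error(character_matrix(matrix(c(0, 1, NA, 1), 2, 2)), "missing")
  expect_error(character_matrix(matrix(0:3, 2, 2)), "non-binary")
  expect_error(character_matrix(matrix(0:1, 2, 1), labels = c("a", "a")),
               "unique")
  expect_error(character_matrix(matrix(0:1, 1, 2), positions = c(5, 2)),
               "increasing")
})

test_that("read-write-read round-trips are the identity", {
  dir <- withr::local_tempdir()
  set.seed(7)
  for (rep in 1:5) {
    x <- random_binary_matrix(sample(2:8, 1), sample(1:9, 1))
    p <- file.path(dir, sprintf("rt%d.txt", rep))
    write_alignment(x, p)
    y <- read_alignment(p, "matrix")
    expect_equal(unclass(y), unclass(x), ignore_attr = TRUE)
    expect_equal(rownames(y), rownames(x))
  }
  # ms round trip through the simulator writer
  sim <- simulate_coalescent(sim_params(5L, rho = 2, segsites = 6L), seed = 3)
  p <- file.path(dir, "sim.ms")
  write_ms(sim, p)
  y <- read_alignment(p, "ms")
  expect_equal(unclass(y), unclass(sim$matrix), ignore_attr = TRUE)
  expect_equal(positions(y), positions(sim$matrix), tolerance = 1e-4)
})

test_that("constant characters are dropped with an index map", {
  base <- square_sample()
  with_const <- character_matrix(cbind(unclass(base)[, 1:2], 0L,
                                       unclass(base)[, 3, drop = FALSE]))
  out <- drop_constant_characters(with_const)
  expect_equal(out$removed, 3L)
  expect_equal(unclass(out$matrix), unclass(base), ignore_attr = TRUE)

  # identity on an all-segregating sample
  out2 <- drop_constant_characters(base)
  expect_equal(out2$removed, integer(0))

  allc <- character_matrix(matrix(1L, 3, 4))
  out3 <- drop_constant_characters(allc)
  expect_equal(ncol(out3$matrix), 0L)
  expect_equal(out3$removed, 1:4)
})

test_that("unique_haplotypes collapses duplicates consistently", {
  x <- quartet_sample()
  full <- unique_haplotypes(x, c(1L, 7L))
  expect_equal(nrow(full$matrix), 4L)

  # restricted to characters 1..4 only two haplotypes remain
  r14 <- unique_haplotypes(x, c(1L, 4L))
  expect_equal(nrow(r14$matrix), 2L)
  expect_equal(sort(r14$multiplicity), c(2L, 2L))
  expect_equal(sum(r14$multiplicity), nrow(x))
  expect_equal(r14$matrix[r14$row_map, , drop = FALSE],
               unclass(x)[, 1:4, drop = FALSE], ignore_attr = TRUE)

  expect_error(unique_haplotypes(x, c(8L, 9L)), "invalid character interval")

  # property: multiplicities sum to n, reduced rows pairwise distinct
  set.seed(11)
  for (rep in 1:10) {
    y <- random_binary_matrix(sample(3:9, 1), sample(2:7, 1))
    i <- sample(ncol(y), 1)
    k <- i + sample.int(ncol(y) - i + 1L, 1L) - 1L
    u <- unique_haplotypes(y, c(i, k))
    expect_equal(sum(u$multiplicity), nrow(y))
    expect_false(any(duplicated(apply(unclass(u$matrix), 1, paste,
                                      collapse = ""))))
  }
})
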