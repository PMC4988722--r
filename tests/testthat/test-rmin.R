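test_that("exact oracle reproduces the worked-example minima", {
  expect_equal(exact_rmin(square_sample()), 2L)
  expect_equal(exact_rmin(quartet_sample()), 2L)
  expect_equal(exact_rmin(compatible_sample()), 0L)
  big <- random_binary_matrix(12, 9)
  expect_error(exact_rmin(big), "too large")
  one_pair <- character_matrix(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_equal(exact_rmin(one_pair), 1L)
})

test_that("exact R_min dominates the classical bound chain", {
  set.seed(29)
  for (rep in 1:15) {
    x <- random_binary_matrix(sample(3:6, 1), sample(2:5, 1))
    r <- exact_rmin(x)
    rmg <- myers_griffiths_bound(x)$value
    rm_ <- hudson_kaplan_rm(x)$value
    hap <- max(0L, nrow(unique_haplotypes(x)$matrix) - ncol(x) - 1L)
    expect_gte(r, rmg)
    expect_gte(rmg, rm_)
    expect_gte(rmg, hap)
  }
})

test_that("b1_bar stays below R_min unless a character triple is saturated", {
  set.seed(37)
  for (rep in 1:15) {
    x <- random_binary_matrix(sample(4:6, 1), sample(2:5, 1))
    r <- exact_rmin(x)
    bb <- barcode_ensemble(x)$b1_bar
    # all eight gamete combinations on some triple allow b1_bar > R_min
    saturated <- FALSE
    m <- ncol(x)
    if (m >= 3L) {
      for (i in seq_len(m - 2L)) for (j in seq(i + 1L, m - 1L)) for (k in seq(j + 1L, m)) {
        g <- unique(apply(unclass(x)[, c(i, j, k)], 1L, paste, collapse = ""))
        if (length(g) == 8L) saturated <- TRUE
      }
    }
    if (!saturated) expect_lte(bb, r)
  }
})

test_that("ultra-minimal histories realise R_min with bounded local distances", {
  h5 <- ultra_minimal_cost(square_sample())
  expect_equal(h5$R, 2L)
  expect_equal(length(h5$parental_distances), 2L)
  expect_equal(h5$cost_D, sum(h5$parental_distances))

  h0 <- ultra_minimal_cost(compatible_sample())
  expect_equal(h0$R, 0L)
  expect_equal(h0$cost_D, 0L)

  # the example's ensemble deaths bound the interval-restricted parental
  # distances of the witness: one wide- and one narrow-scale event
  x <- quartet_sample()
  h7 <- ultra_minimal_cost(x)
  ens <- barcode_ensemble(x)
  restricted <- function(pair, i, k) {
    a <- strsplit(pair[1], "")[[1]][i:k]
    b <- strsplit(pair[2], "")[[1]][i:k]
    sum(a != b)
  }
  for (b in seq_len(nrow(ens$bars))) {
    i <- ens$bars$char_start[b]; k <- ens$bars$char_end[b]
    local_d <- vapply(h7$parents, restricted, 0, i = i, k = k)
    expect_true(any(local_d <= ens$bars$death[b]))
  }
})

test_that("condensed graphs obey the m + 2R / m + R + 1 / R counting laws", {
  for (x in list(square_sample(), quartet_sample(), compatible_sample())) {
    h <- ultra_minimal_cost(x)
    g <- condensed_graph(h)
    m_eff <- ncol(x)
    expect_equal(g$n_edges, m_eff + 2L * h$R)
    expect_equal(g$n_vertices, m_eff + h$R + 1L)
    expect_equal(g$n_loops, h$R)
  }
  set.seed(41)
  for (rep in 1:8) {
    x <- random_binary_matrix(sample(3:5, 1), sample(2:4, 1))
    x <- drop_constant_characters(x)$matrix
    if (ncol(x) == 0L) next
    h <- ultra_minimal_cost(x)
    g <- condensed_graph(h)
    expect_equal(g$n_edges, ncol(x) + 2L * h$R)
    expect_equal(g$n_vertices, ncol(x) + h$R + 1L)
    expect_equal(g$n_loops, h$R)
  }
})
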