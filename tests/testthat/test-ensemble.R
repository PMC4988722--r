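test_that("barcode ordering prefers count, then long-scale deaths", {
  one_bar <- data.frame(birth = 2L, death = 3L)
  two_bars <- data.frame(birth = c(1L, 1L), death = c(2L, 2L))
  expect_equal(barcode_order(one_bar, two_bars), two_bars)
  # equal count: the barcode reaching the larger death scale wins
  expect_equal(barcode_order(data.frame(birth = 1L, death = 2L),
                             data.frame(birth = 1L, death = 4L)),
               data.frame(birth = 1L, death = 4L))
  # identical barcodes: first argument
  expect_identical(barcode_order(one_bar, data.frame(birth = 2L, death = 3L)),
                   one_bar)
})

test_that("interval barcodes of the worked example match the printed scales", {
  x <- quartet_sample()
  b15 <- interval_barcode(x, 1L, 5L)
  expect_equal(nrow(b15), 1L)
  expect_equal(b15$death, 5L)
  b57 <- interval_barcode(x, 5L, 7L)
  expect_equal(nrow(b57), 1L)
  expect_equal(b57$birth, 2L)
  expect_equal(b57$death, 3L)
  # three or fewer unique haplotypes can never carry a loop
  expect_equal(nrow(interval_barcode(x, 1L, 4L)), 0L)
  expect_error(interval_barcode(x, 1L, 7L, s = 5L), "exceeding s")
  expect_error(interval_barcode(x, 1L, 7L, w = 4L), "exceeding w")
})

test_that("the ensemble recovers both recombination events of the example", {
  ens <- barcode_ensemble(quartet_sample(), s = 7, w = 7)
  expect_equal(ens$b1_bar, 2L)
  expect_equal(sort(ens$bars$death), c(3L, 5L))
  expect_equal(ens$partition, c(1L, 5L, 7L))
  expect_equal(ens$mean_eps_d, 2)        # (5 + 3) / 4 in eps units
  # the wide bar sits on characters 1..5, the narrow one within 5..7
  wide <- ens$bars[which.max(ens$bars$death), ]
  expect_equal(c(wide$char_start, wide$char_end), c(1L, 5L))
  narrow <- ens$bars[which.min(ens$bars$death), ]
  expect_true(narrow$char_start >= 5L && narrow$char_end <= 7L)

  ens5 <- barcode_ensemble(square_sample(), s = 3, w = 3)
  expect_equal(ens5$b1_bar, 2L)
  expect_equal(ens5$bars$birth, c(1L, 1L))
  expect_equal(ens5$bars$death, c(2L, 2L))

  expect_equal(barcode_ensemble(compatible_sample())$b1_bar, 0L)
})

test_that("ensemble DP equals brute-force maximisation over interval chains", {
  set.seed(13)
  for (rep in 1:20) {
    x <- random_binary_matrix(sample(4:8, 1), sample(2:6, 1))
    ens <- barcode_ensemble(x)
    bf <- brute_force_ensemble_bars(x)
    expect_equal(ens$b1_bar, nrow(bf))
    expect_equal(sort(ens$bars$death), sort(bf$death))
    expect_equal(sort(ens$bars$birth), sort(bf$birth))
  }
})

test_that("ensemble invariants: dominates b1, symmetric, vanishes when compatible", {
  set.seed(19)
  for (rep in 1:15) {
    x <- random_binary_matrix(sample(4:10, 1), sample(2:7, 1))
    ens <- barcode_ensemble(x)
    b1_full <- nrow(h1_persistence(hamming_matrix(x)))
    expect_gte(ens$b1_bar, b1_full)
    # row permutation leaves b1_bar unchanged
    xp <- character_matrix(unclass(x)[sample(nrow(x)), , drop = FALSE])
    expect_equal(barcode_ensemble(xp)$b1_bar, ens$b1_bar)
    # reversing character order leaves b1_bar unchanged
    xr <- character_matrix(unclass(x)[, rev(seq_len(ncol(x))), drop = FALSE])
    expect_equal(barcode_ensemble(xr)$b1_bar, ens$b1_bar)
    # the compatibility filter is the identity when every character is
    # already involved in an incompatibility
    if (length(exclude_compatible_characters(x)) == ncol(x)) {
      expect_equal(barcode_ensemble(x, exclude_compatible = TRUE)$b1_bar,
                   ens$b1_bar)
    }
  }
})

test_that("admissibility limits and degenerate inputs are handled", {
  x <- quartet_sample()
  # s = 2 allows no informative interval (two characters, <= 4 haplotypes,
  # but a 2-character interval can still hold a 4-cycle)
  ens_s2 <- barcode_ensemble(x, s = 2)
  expect_true(all(ens_s2$bars$char_end - ens_s2$bars$char_start <= 1L))
  ens_w2 <- barcode_ensemble(x, w = 2)
  expect_true(all(ens_w2$bars$char_end - ens_w2$bars$char_start <= 2L))
  # restricting the search space can only lose bars
  expect_lte(ens_w2$b1_bar, barcode_ensemble(x)$b1_bar)

  single <- character_matrix(matrix(c(0L, 1L), 2, 1))
  expect_equal(barcode_ensemble(single)$b1_bar, 0L)
  expect_warning(ens0 <- barcode_ensemble(compatible_sample(),
                                          exclude_compatible = TRUE),
                 "empty ensemble")
  expect_equal(ens0$b1_bar, 0L)
  expect_true(is.na(ens0$mean_eps_d))
})

test_that("breakpoint report and summaries expose bar locations", {
  x <- quartet_sample()
  ens <- barcode_ensemble(x)
  rep_ <- breakpoint_report(ens)
  expect_equal(nrow(rep_), 2L)
  expect_equal(rep_$pos_start, rep_$char_start) # default coordinates 1..m
  s <- ensemble_summary(ens)
  expect_equal(s$b1_bar, 2L)
  expect_equal(s$mean_eps_d, 2)
  expect_equal(sum(s$per_interval$bars), 2L)
  expect_equal(nrow(breakpoint_report(barcode_ensemble(compatible_sample()))),
               0L)
})
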