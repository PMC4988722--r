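test_that("parameter validation catches inconsistent models", {
  expect_error(sim_params(c(5, 5, 5)), "one or two demes")
  expect_error(sim_params(5, rho = -1, segsites = 3), "rho")
  expect_error(sim_params(5), "segsites or theta")
  expect_error(sim_params(5, segsites = 3, theta = 2), "segsites or theta")
  expect_error(sim_params(c(5, 5), segsites = 3), "join_time or migration")
  expect_silent(sim_params(c(5, 5), segsites = 3, join_time = 6))
  expect_silent(sim_params(c(5, 5), segsites = 3, migration = 0.5))
})

test_that("no recombination means one tree: compatible characters, b1_bar 0", {
  for (seed in 1:10) {
    sim <- simulate_coalescent(sim_params(12L, rho = 0, segsites = 10L),
                               seed = seed)
    expect_equal(sim$n_recombinations, 0L)
    expect_equal(length(exclude_compatible_characters(sim$matrix)), 0L)
    expect_equal(barcode_ensemble(sim$matrix)$b1_bar, 0L)
  }
})

test_that("pairwise coalescence time matches the ms-scaled expectation", {
  set.seed(101)
  tt <- replicate(4000, {
    simulate_coalescent(sim_params(2L, segsites = 0L))$events[[1L]]$time
  })
  # exponential with mean 0.5 in 4N0 units
  expect_equal(mean(tt), 0.5, tolerance = 0.05)
})

test_that("fixed-s conditioning yields exactly s segregating characters", {
  sim <- simulate_coalescent(sim_params(9L, rho = 3, segsites = 14L), seed = 5)
  expect_equal(ncol(sim$matrix), 14L)
  counts <- colSums(unclass(sim$matrix))
  expect_true(all(counts >= 1L & counts <= 8L)) # every column segregates
  expect_true(all(diff(positions(sim$matrix)) > 0))
  expect_true(all(positions(sim$matrix) >= 0 & positions(sim$matrix) < 1))
  s0 <- simulate_coalescent(sim_params(4L, segsites = 0L), seed = 2)
  expect_equal(ncol(s0$matrix), 0L)
})

test_that("two isolated demes share no ancestry before the join", {
  sim <- simulate_coalescent(sim_params(c(5L, 5L), segsites = 5L,
                                        migration = 0, join_time = 8,
                                        size_factors = c(1, 0.2)), seed = 9)
  # track deme membership of every lineage through the event log
  deme <- c(rep(1L, 5L), rep(2L, 5L))
  names(deme) <- as.character(1:10)
  for (e in sim$events) {
    if (e$type == "coal" && e$time < 8) {
      expect_equal(deme[[as.character(e$a)]], deme[[as.character(e$b)]])
      deme[[as.character(e$child)]] <- deme[[as.character(e$a)]]
    } else if (e$type == "coal") {
      deme[[as.character(e$child)]] <- 2L
    } else if (e$type == "rec") {
      deme[[as.character(e$left)]] <- deme[[as.character(e$lineage)]]
      deme[[as.character(e$right)]] <- deme[[as.character(e$lineage)]]
    }
  }
})

test_that("seeded runs are bit-reproducible", {
  a <- simulate_coalescent(sim_params(8L, rho = 4, segsites = 9L), seed = 77)
  b <- simulate_coalescent(sim_params(8L, rho = 4, segsites = 9L), seed = 77)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$breakpoints, b$breakpoints)
})

test_that("presets encode the study conditions", {
  set.seed(3)
  p <- sim_preset("bound_comparison")
  expect_equal(sum(p$sample_sizes), 40L)
  expect_equal(p$segsites, 12L)
  expect_true(p$rho >= 0 && p$rho <= 110)

  pm <- sim_preset("divergence_migration")
  expect_equal(pm$sample_sizes, c(250L, 50L))
  expect_equal(pm$segsites, 300L)
  expect_equal(pm$rho, 40)
  expect_equal(pm$migration, 0.5)
  expect_equal(pm$join_time, 6.0)
  expect_equal(pm$size_factors, c(1, 0.2))

  pn <- sim_preset("divergence_isolated")
  expect_equal(pn$migration, 0)
  expect_equal(pn$sample_sizes, c(250L, 50L))

  pb <- sim_preset("migration_response")
  expect_equal(pb$sample_sizes, c(125L, 25L))
  expect_true(pb$migration >= 0 && pb$migration <= 2)
  expect_error(sim_preset("no_such_scenario"), "arg")
})

test_that("theta mode produces segregating binary characters", {
  sim <- simulate_coalescent(sim_params(6L, rho = 1, theta = 8), seed = 13)
  if (ncol(sim$matrix) > 0L) {
    counts <- colSums(unclass(sim$matrix))
    expect_true(all(counts >= 1L & counts <= 5L))
  }
  expect_true(ncol(sim$matrix) >= 0L)
})
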