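# Hudson-style backward-in-time coalescent with recombination, one or two
# demes with (one-way) migration and a population-join event, infinite-sites
# mutations conditioned on a fixed number of segregating sites.
#
# Conventions follow ms: the locus is the unit interval; rho = 4*N0*r over
# the locus; times are reported in units of 4*N0 generations; -ej style
# join_time merges deme 1 into deme 2; size_factors are relative deme sizes;
# migration is the scaled backward rate M = 4*N0*m at which deme-1 lineages
# move to deme 2 (the -m 1 2 M command). Internally rates use the
# 2*N0-scaled clock (pair coalescence at rate 1/size, recombination at
# rho/2 per unit of ancestral breadth, migration at M/2 per lineage), which
# reproduces the ms expectations, e.g. mean pairwise coalescence time 0.5 in
# 4*N0 units.

#' Coalescent simulation parameters
#'
#' @param sample_sizes integer vector of per-deme sample counts (length 1
#'   or 2).
#' @param rho population-scaled recombination rate 4*N0*r over the locus.
#' @param segsites fixed number of segregating sites (ms \code{-s}
#'   semantics: mutations are placed on the realised genealogy until exactly
#'   this many segregating characters exist). Exactly one of
#'   \code{segsites}/\code{theta} must be given.
#' @param theta population-scaled mutation rate 4*N0*mu over the locus
#'   (Poisson number of mutations).
#' @param migration scaled backward migration rate M = 4*N0*m of deme-1
#'   lineages into deme 2; 0 for none.
#' @param join_time time (units of 4*N0 generations) at which deme 1 merges
#'   into deme 2 (\code{-ej} semantics); \code{Inf} for never. Two isolated
#'   demes with no migration must have a finite join time.
#' @param size_factors relative deme sizes (ms \code{-n}), one per deme.
#' @param locus_bp optional locus length in base pairs, for reporting only.
#' @return Object of class \code{"sim_params"}.
#' @export
sim_params <- function(sample_sizes, rho = 0, segsites = NULL, theta = NULL,
                       migration = 0, join_time = Inf, size_factors = NULL,
                       locus_bp = NULL) {
  sample_sizes <- as.integer(sample_sizes)
  nd <- length(sample_sizes)
  if (nd < 1L || nd > 2L) stop("one or two demes are supported")
  if (any(sample_sizes < 1L)) stop("sample sizes must be >= 1")
  if (rho < 0) stop("rho must be nonnegative")
  if (migration < 0) stop("migration must be nonnegative")
  if (is.null(size_factors)) size_factors <- rep(1, nd)
  if (length(size_factors) != nd || any(size_factors <= 0)) {
    stop("size_factors must be positive, one per deme")
  }
  if (is.null(segsites) == is.null(theta)) {
    stop("give exactly one of segsites or theta")
  }
  if (!is.null(segsites) && segsites < 0) stop("segsites must be >= 0")
  if (nd == 2L && migration == 0 && !is.finite(join_time)) {
    stop("two isolated demes never find a common ancestor; set join_time or migration")
  }
  structure(list(sample_sizes = sample_sizes, rho = rho, segsites = segsites,
                 theta = theta, migration = migration, join_time = join_time,
                 size_factors = size_factors, locus_bp = locus_bp),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("coalescent parameters: n = %s, rho = %g, %s\n",
              paste(x$sample_sizes, collapse = "+"), x$rho,
              if (!is.null(x$segsites)) sprintf("segsites = %d", x$segsites)
              else sprintf("theta = %g", x$theta)))
  if (length(x$sample_sizes) == 2L) {
    cat(sprintf("  two demes: sizes %s, migration M = %g, join at t = %g (4N0)\n",
                paste(x$size_factors, collapse = "/"), x$migration, x$join_time))
  }
  invisible(x)
}

# overlay-merge two piece lists; drop regions whose leaf set is complete.
# pieces within a lineage are disjoint and sorted, so coverage of each
# elementary interval reduces to findInterval on the start coordinates.
merge_pieces <- function(p1, p2, nfull) {
  a1 <- vapply(p1, `[[`, 0, "a"); b1 <- vapply(p1, `[[`, 0, "b")
  a2 <- vapply(p2, `[[`, 0, "a"); b2 <- vapply(p2, `[[`, 0, "b")
  bounds <- sort(unique(c(a1, b1, a2, b2)))
  lo <- bounds[-length(bounds)]
  i1 <- findInterval(lo, a1)
  i2 <- findInterval(lo, a2)
  out <- list()
  for (i in seq_along(lo)) {
    hi <- bounds[i + 1L]
    s1 <- if (i1[i] >= 1L && b1[i1[i]] >= hi) p1[[i1[i]]]$s else NULL
    s2 <- if (i2[i] >= 1L && b2[i2[i]] >= hi) p2[[i2[i]]]$s else NULL
    s <- if (is.null(s1)) s2 else if (is.null(s2)) s1 else sort(unique(c(s1, s2)))
    if (is.null(s) || length(s) == nfull) next
    k <- length(out)
    if (k > 0L && out[[k]]$b == lo[i] && identical(out[[k]]$s, s)) {
      out[[k]]$b <- hi
    } else {
      out[[k + 1L]] <- list(a = lo[i], b = hi, s = s)
    }
  }
  out
}

split_pieces <- function(pieces, u) {
  left <- list(); right <- list()
  for (p in pieces) {
    if (p$b <= u) left[[length(left) + 1L]] <- p
    else if (p$a >= u) right[[length(right) + 1L]] <- p
    else {
      left[[length(left) + 1L]] <- list(a = p$a, b = u, s = p$s)
      right[[length(right) + 1L]] <- list(a = u, b = p$b, s = p$s)
    }
  }
  list(left = left, right = right)
}

piece_breadth <- function(pieces) {
  if (length(pieces) == 0L) return(0)
  max(vapply(pieces, `[[`, 0, "b")) - min(vapply(pieces, `[[`, 0, "a"))
}

#' Simulate a sample under the coalescent with recombination
#'
#' Runs the backward-in-time process (coalescence, recombination, migration,
#' population join) until every position of the locus has reached its most
#' recent common ancestor, then places mutations on the realised genealogy
#' (fixed segregating-site count or Poisson theta mode).
#'
#' @param params a \code{sim_params} object.
#' @param seed optional integer seed (all randomness flows through R's RNG).
#' @return Object of class \code{"sim_result"}: list with
#'   \code{matrix} (a \code{character_matrix}; positions are the mutation
#'   coordinates in [0, 1)), \code{demes} (per-sequence deme of origin),
#'   \code{n_recombinations} (recombination events in the simulated ARG),
#'   \code{breakpoints} (their positions), \code{events} (the event log) and
#'   \code{params}.
#' @examples
#' sim <- simulate_coalescent(sim_params(8, rho = 5, segsites = 10), seed = 1)
#' sim$matrix
#' @export
simulate_coalescent <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(params$sample_sizes)
  nd <- length(params$sample_sizes)
  leaf_demes <- rep(seq_len(nd), params$sample_sizes)
  join_internal <- 2 * params$join_time # internal clock: 2*N0 units
  lin <- vector("list", n)
  for (i in seq_len(n)) {
    lin[[i]] <- list(id = i, deme = leaf_demes[i],
                     pieces = list(list(a = 0, b = 1, s = i)))
  }
  # demes/breadths are maintained incrementally alongside lin
  demes <- leaf_demes
  breadths <- rep(1, n)
  next_id <- n
  t <- 0
  joined <- nd == 1L
  events <- list()
  log_event <- function(e) events[[length(events) + 1L]] <<- e

  while (length(lin) > 1L) {
    k_by_deme <- tabulate(demes, nbins = nd)
    coal_rates <- k_by_deme * (k_by_deme - 1) / 2 / params$size_factors
    rec_rates <- params$rho / 2 * breadths
    mig_rates <- if (!joined && params$migration > 0) {
      ifelse(demes == 1L, params$migration / 2, 0)
    } else rep(0, length(lin))
    total <- sum(coal_rates) + sum(rec_rates) + sum(mig_rates)
    if (total <= 0) {
      if (!joined && is.finite(join_internal)) {
        t <- max(t, join_internal)
      } else stop("internal: stalled coalescent with zero total rate")
    } else {
      t_next <- t + stats::rexp(1L, total)
      if (!joined && t_next >= join_internal) {
        t <- join_internal
        for (i in seq_along(lin)) lin[[i]]$deme <- 2L
        demes[] <- 2L
        joined <- TRUE
        next
      }
      t <- t_next
    }
    if (!joined && t >= join_internal) {
      for (i in seq_along(lin)) lin[[i]]$deme <- 2L
      demes[] <- 2L
      joined <- TRUE
      next
    }
    u <- stats::runif(1L, 0, total)
    if (u < sum(coal_rates)) {
      d <- which(cumsum(coal_rates) > u)[1L]
      pair <- sample(which(demes == d), 2L)
      la <- lin[[pair[1L]]]; lb <- lin[[pair[2L]]]
      next_id <- next_id + 1L
      log_event(list(type = "coal", time = t, a = la$id, b = lb$id,
                     child = next_id, deme = d))
      merged <- merge_pieces(la$pieces, lb$pieces, n)
      lin <- lin[-pair]
      demes <- demes[-pair]
      breadths <- breadths[-pair]
      if (length(merged) > 0L) {
        lin[[length(lin) + 1L]] <- list(id = next_id, deme = d, pieces = merged)
        demes <- c(demes, d)
        breadths <- c(breadths, piece_breadth(merged))
      }
    } else if (u < sum(coal_rates) + sum(rec_rates)) {
      v <- u - sum(coal_rates)
      i <- which(cumsum(rec_rates) > v)[1L]
      li <- lin[[i]]
      lo <- min(vapply(li$pieces, `[[`, 0, "a"))
      hi <- max(vapply(li$pieces, `[[`, 0, "b"))
      bp <- stats::runif(1L, lo, hi)
      parts <- split_pieces(li$pieces, bp)
      if (length(parts$left) == 0L || length(parts$right) == 0L) next
      log_event(list(type = "rec", time = t, lineage = li$id, breakpoint = bp,
                     left = next_id + 1L, right = next_id + 2L))
      lin[[i]] <- list(id = next_id + 1L, deme = li$deme, pieces = parts$left)
      breadths[i] <- piece_breadth(parts$left)
      lin[[length(lin) + 1L]] <- list(id = next_id + 2L, deme = li$deme,
                                      pieces = parts$right)
      demes <- c(demes, li$deme)
      breadths <- c(breadths, piece_breadth(parts$right))
      next_id <- next_id + 2L
    } else {
      v <- u - sum(coal_rates) - sum(rec_rates)
      i <- which(cumsum(mig_rates) > v)[1L]
      log_event(list(type = "mig", time = t, lineage = lin[[i]]$id,
                     from = lin[[i]]$deme, to = 2L))
      lin[[i]]$deme <- 2L
      demes[i] <- 2L
    }
  }
  # event times are logged on the internal 2*N0 clock; report in 4*N0 units
  events <- lapply(events, function(e) { e$time <- e$time / 2; e })
  recs <- Filter(function(e) e$type == "rec", events)
  genealogy <- list(events = events, n = n, leaf_demes = leaf_demes)
  mat <- if (!is.null(params$segsites)) {
    place_mutations_fixed_s(genealogy, params$segsites)
  } else {
    place_mutations_theta(genealogy, params$theta)
  }
  structure(list(matrix = mat, demes = leaf_demes,
                 n_recombinations = length(recs),
                 breakpoints = vapply(recs, `[[`, 0, "breakpoint"),
                 events = events, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("coalescent sample: n = %d, m = %d segregating sites, %d ARG recombination%s\n",
              nrow(x$matrix), ncol(x$matrix), x$n_recombinations,
              if (x$n_recombinations == 1L) "" else "s"))
  invisible(x)
}

# marginal tree at position x from the event log: branches as
# (length, leaves) pairs, up to (excluding) the root
marginal_branches <- function(genealogy, x) {
  n <- genealogy$n
  carriers <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    assign(as.character(i), list(t0 = 0, leaves = i), envir = carriers)
  }
  n_carriers <- n
  branches_len <- numeric(0)
  branches_leaves <- list()
  if (n_carriers == 1L) return(list(len = branches_len, leaves = branches_leaves))
  for (e in genealogy$events) {
    if (e$type == "coal") {
      ca <- carriers[[as.character(e$a)]]
      cb <- carriers[[as.character(e$b)]]
      if (!is.null(ca) && !is.null(cb)) {
        branches_len <- c(branches_len, e$time - ca$t0, e$time - cb$t0)
        branches_leaves <- c(branches_leaves, list(ca$leaves), list(cb$leaves))
        lv <- sort(unique(c(ca$leaves, cb$leaves)))
        rm(list = c(as.character(e$a), as.character(e$b)), envir = carriers)
        n_carriers <- n_carriers - 1L
        if (length(lv) == n) break
        assign(as.character(e$child), list(t0 = e$time, leaves = lv),
               envir = carriers)
      } else if (!is.null(ca) || !is.null(cb)) {
        cc <- if (is.null(ca)) cb else ca
        rm(list = as.character(if (is.null(ca)) e$b else e$a), envir = carriers)
        assign(as.character(e$child), cc, envir = carriers)
      }
    } else if (e$type == "rec") {
      cl <- carriers[[as.character(e$lineage)]]
      if (!is.null(cl)) {
        rm(list = as.character(e$lineage), envir = carriers)
        assign(as.character(if (x < e$breakpoint) e$left else e$right), cl,
               envir = carriers)
      }
    }
  }
  list(len = branches_len, leaves = branches_leaves)
}

# encode the event log for the C++ tree-length sweep
encode_events <- function(events) {
  if (length(events) == 0L) return(matrix(0, 0L, 6L))
  do.call(rbind, lapply(events, function(e) {
    if (e$type == "coal") c(1, e$time, e$a, e$b, e$child, 0)
    else if (e$type == "rec") c(2, e$time, e$lineage, e$breakpoint,
                                e$left, e$right)
    else c(0, e$time, 0, 0, 0, 0)
  }))
}

# tree length is piecewise constant between recombination breakpoints:
# tabulate it once per genealogy
segment_table <- function(genealogy) {
  bps <- sort(unique(c(0, 1,
                       vapply(Filter(function(e) e$type == "rec",
                                     genealogy$events),
                              `[[`, 0, "breakpoint"))))
  mids <- (utils::head(bps, -1L) + utils::tail(bps, -1L)) / 2
  lens <- cpp_marginal_lengths(encode_events(genealogy$events),
                               genealogy$n, mids)
  list(bps = bps, widths = diff(bps), lens = lens)
}

place_one_mutation <- function(genealogy, x) {
  br <- marginal_branches(genealogy, x)
  tot <- sum(br$len)
  if (tot <= 0) return(NULL)
  u <- stats::runif(1L, 0, tot)
  b <- which(cumsum(br$len) > u)[1L]
  col <- integer(genealogy$n)
  col[br$leaves[[b]]] <- 1L
  col
}

#' Place a fixed number of mutations on a simulated genealogy
#'
#' Infinite-sites mutations with ms \code{-s} semantics: exactly \code{s}
#' mutations, each at a fresh position drawn with density proportional to
#' the local marginal-tree length (so diverse regions collect more sites,
#' exactly as when mutations rain uniformly on the realised graph), on a
#' branch of the marginal tree at that position chosen with probability
#' proportional to branch length; sequences descending from the branch carry
#' the derived allele 1.
#'
#' @param genealogy the \code{events}/\code{n}/\code{leaf_demes} list stored
#'   in a \code{sim_result}.
#' @param s number of segregating sites.
#' @return A \code{character_matrix} with \code{s} columns and positions in
#'   [0, 1).
#' @export
place_mutations_fixed_s <- function(genealogy, s) {
  if (s < 0) stop("s must be >= 0")
  n <- genealogy$n
  if (s == 0L) {
    return(character_matrix(matrix(integer(0), nrow = n, ncol = 0L)))
  }
  segs <- segment_table(genealogy)
  wt <- segs$lens * segs$widths
  if (sum(wt) <= 0) stop("cannot place mutations on a single-lineage genealogy")
  pick <- sample.int(length(wt), s, replace = TRUE, prob = wt)
  pos <- sort(stats::runif(s, segs$bps[pick], segs$bps[pick + 1L]))
  cols <- matrix(0L, n, s)
  for (j in seq_len(s)) {
    col <- place_one_mutation(genealogy, pos[j])
    if (is.null(col)) stop("cannot place mutations on a single-lineage genealogy")
    cols[, j] <- col
  }
  character_matrix(cols, positions = pos)
}

place_mutations_theta <- function(genealogy, theta) {
  segs <- segment_table(genealogy)
  # branch lengths are in 4*N0 units; mutations at rate theta/2 per unit
  wt <- segs$lens * segs$widths
  k <- stats::rpois(1L, theta / 2 * sum(wt))
  if (k == 0L) {
    return(character_matrix(matrix(integer(0), nrow = genealogy$n, ncol = 0L)))
  }
  seg <- sample.int(length(wt), k, replace = TRUE, prob = wt)
  pos <- sort(stats::runif(k, segs$bps[seg], segs$bps[seg + 1L]))
  cols <- matrix(0L, genealogy$n, k)
  for (j in seq_len(k)) cols[, j] <- place_one_mutation(genealogy, pos[j])
  character_matrix(cols, positions = pos)
}

#' Preset simulation setups
#'
#' Named parameter sets for the validation scenarios used throughout the
#' package (random parameters, such as a uniformly drawn recombination or
#' migration rate, are sampled from R's RNG when the preset is built):
#' \describe{
#'   \item{bound_comparison}{one deme, 40 sequences, 12 segregating sites, rho drawn
#'     uniformly on (0, 110) — the bound-comparison setup.}
#'   \item{divergence_migration}{two demes sampled 250/50, 300 segregating sites,
#'     rho = 40, deme-2 relative size 0.2, join at 6.0, migration M = 0.5.}
#'   \item{divergence_isolated}{as divergence_migration with no migration.}
#'   \item{rho_response}{one deme, 200 sequences, rho uniform on (0, 216), 30
#'     segregating sites — recombination-rate response.}
#'   \item{migration_response}{two demes sampled 125/25, rho = 60, join 6.0, size 0.2,
#'     migration drawn uniformly on (0, 2), 40 segregating sites —
#'     migration-rate response.}
#' }
#'
#' @param name preset name.
#' @return A \code{sim_params} object.
#' @export
sim_preset <- function(name = c("bound_comparison", "divergence_migration", "divergence_isolated",
                                "rho_response", "migration_response")) {
  name <- match.arg(name)
  switch(name,
    bound_comparison = sim_params(40L, rho = stats::runif(1L, 0, 110), segsites = 12L),
    divergence_migration = sim_params(c(250L, 50L), rho = 40, segsites = 300L,
                          migration = 0.5, join_time = 6.0,
                          size_factors = c(1, 0.2), locus_bp = 10000L),
    divergence_isolated = sim_params(c(250L, 50L), rho = 40, segsites = 300L,
                            migration = 0, join_time = 6.0,
                            size_factors = c(1, 0.2), locus_bp = 10000L),
    rho_response = sim_params(200L, rho = stats::runif(1L, 0, 216), segsites = 30L,
                        locus_bp = 30000L),
    migration_response = sim_params(c(125L, 25L), rho = 60, segsites = 40L,
                        migration = stats::runif(1L, 0, 2), join_time = 6.0,
                        size_factors = c(1, 0.2), locus_bp = 10000L))
}

#' Write simulated samples in ms dialect
#'
#' @param sims a \code{sim_result} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ms <- function(sims, path) {
  if (inherits(sims, "sim_result")) sims <- list(sims)
  n <- nrow(sims[[1L]]$matrix)
  lines <- c(sprintf("ms %d %d", n, length(sims)), "0 0 0", "")
  for (s in sims) {
    m <- s$matrix
    lines <- c(lines, "//", sprintf("segsites: %d", ncol(m)))
    if (ncol(m) > 0L) {
      lines <- c(lines,
                 paste("positions:", paste(sprintf("%.5f", positions(m)),
                                           collapse = " ")),
                 apply(unclass(m), 1L, paste, collapse = ""))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
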