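#' Four-gamete test for a pair of characters
#'
#' Two binary characters are incompatible (cannot both be placed on one tree
#' under infinite sites) iff all four gametes 00, 01, 10 and 11 occur across
#' them; an incompatible pair forces at least one recombination between the
#' two sites.
#'
#' @param col_a,col_b binary vectors of equal length (one entry per sequence).
#' @return \code{TRUE} iff the pair fails the test (all four gametes occur).
#' @export
four_gamete_incompatible <- function(col_a, col_b) {
  if (length(col_a) != length(col_b)) stop("columns must have the same length")
  g <- 2L * as.integer(col_a) + as.integer(col_b)
  length(unique(g)) == 4L
}

# all incompatible pairs (i < j), as a 2-column matrix
incompatible_pairs <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  m <- ncol(x)
  dat <- unclass(x)
  out <- list()
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (four_gamete_incompatible(dat[, i], dat[, j])) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) matrix(integer(0), ncol = 2L)
  else do.call(rbind, out)
}

#' Characters involved in at least one incompatibility
#'
#' Returns the indices of characters that fail the four-gamete test against
#' at least one other character. Characters compatible with everything carry
#' no recombination signal and can be excluded before computing barcodes
#' (the \code{-e} style reduction); original coordinates are preserved.
#'
#' @param x a \code{character_matrix}.
#' @return Integer vector of retained (incompatible) character indices,
#'   possibly empty.
#' @export
exclude_compatible_characters <- function(x) {
  pairs <- incompatible_pairs(x)
  sort(unique(as.integer(pairs)))
}

# per-subset haplotype-bound values for all admissible subsets within 1..m:
# |Q| <= s, max(Q) - min(Q) <= w. Returns best[a, b] = max over subsets with
# min = a, max = b of (#distinct haplotypes on Q - |Q| - 1), -Inf if none.
subset_bound_table <- function(x, s, w) {
  m <- ncol(x)
  dat <- unclass(x)
  best <- matrix(-Inf, m, m)
  if (m < 2L) return(best)
  # bit-encode rows when they fit an integer word: distinct-haplotype counts
  # on a subset reduce to unique() over masked row codes
  encode <- m <= 30L
  if (encode) rowcodes <- as.integer(dat %*% (2^(seq_len(m) - 1L)))
  # enumerate subsets anchored at their minimum a, others drawn from (a, a+w]
  for (a in seq_len(m - 1L)) {
    others <- seq(a + 1L, min(m, a + w))
    for (t in seq_len(min(s - 1L, length(others)))) {
      combos <- if (length(others) == 1L) list(others)
                else utils::combn(others, t, simplify = FALSE)
      for (sel in combos) {
        q <- c(a, sel)
        b <- max(q)
        h <- if (encode) {
          mask <- as.integer(sum(2^(q - 1L)))
          length(unique(bitwAnd(rowcodes, mask)))
        } else {
          length(unique(do.call(paste0, as.data.frame(dat[, q, drop = FALSE]))))
        }
        v <- h - length(q) - 1L
        if (v > best[a, b]) best[a, b] <- v
      }
    }
  }
  best
}

#' Local haplotype bound on a character interval
#'
#' The haplotype bound states that a sample with h distinct haplotypes on a
#' set Q of characters needs at least \code{h - |Q| - 1} recombinations with
#' breakpoints inside the span of Q. This maximises that bound over all
#' subsets Q of characters within \code{interval} with \code{|Q| <= s} and
#' index span \code{max(Q) - min(Q) <= w} (subsets need not be contiguous),
#' floored at zero.
#'
#' @param x a \code{character_matrix}.
#' @param interval integer pair \code{(i, k)}, 1-based inclusive.
#' @param s maximum subset size (default: interval width).
#' @param w maximum subset index span (default: interval width).
#' @return Nonnegative integer bound.
#' @export
local_haplotype_bound <- function(x, interval, s = NULL, w = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  ik <- check_interval(interval, ncol(x))
  sub <- cm_restrict(x, seq(ik[1L], ik[2L]))
  mm <- ncol(sub)
  if (is.null(s)) s <- mm
  if (is.null(w)) w <- mm
  best <- subset_bound_table(sub, s, w)
  v <- suppressWarnings(max(best))
  as.integer(max(0, if (is.finite(v)) v else 0))
}

#' Myers-Griffiths composite bound R_MG
#'
#' Composes local haplotype bounds over chains of character intervals by
#' dynamic programming: \code{R[k] = max over i < k of R[i] + b(i, k)}, where
#' \code{b(i, k)} is the best subset haplotype bound within characters
#' \code{i..k}. Consecutive intervals share their endpoint character, so the
#' recombinations counted by different links fall between distinct sites and
#' the bounds add. The result lower-bounds the minimum number of
#' single-crossover recombinations R_min.
#'
#' @param x a \code{character_matrix}.
#' @param s maximum subset size searched inside each interval (default m).
#' @param w maximum subset index span (default m).
#' @return List of class \code{"bound_result"} with \code{value} (R_MG),
#'   \code{kind = "RMG"} and \code{witness}: the optimal interval
#'   decomposition as a data frame of (start, end, bound).
#' @examples
#' m <- character_matrix(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1), c(1, 1, 1)))
#' myers_griffiths_bound(m)$value # 2
#' @export
myers_griffiths_bound <- function(x, s = NULL, w = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  m <- ncol(x)
  if (is.null(s)) s <- m
  if (is.null(w)) w <- m
  if (m < 2L) {
    return(structure(list(value = 0L, kind = "RMG",
                          witness = data.frame(start = integer(0),
                                               end = integer(0),
                                               bound = integer(0))),
                     class = "bound_result"))
  }
  best <- subset_bound_table(x, s, w)
  # b[i, k]: best subset bound using characters within i..k
  b <- matrix(0L, m, m)
  for (i in seq_len(m - 1L)) for (k in seq(i + 1L, m)) {
    block <- best[i:k, i:k]
    v <- suppressWarnings(max(block))
    b[i, k] <- as.integer(max(0, if (is.finite(v)) v else 0))
  }
  r <- numeric(m)
  back <- integer(m)
  for (k in seq(2L, m)) {
    cand <- r[seq_len(k - 1L)] + b[cbind(seq_len(k - 1L), k)]
    r[k] <- max(cand)
    back[k] <- which.max(cand)
  }
  # traceback
  wit <- list()
  k <- m
  while (k > 1L) {
    i <- back[k]
    wit[[length(wit) + 1L]] <- c(i, k, b[i, k])
    k <- i
  }
  wit <- do.call(rbind, rev(wit))
  structure(list(value = as.integer(r[m]), kind = "RMG",
                 witness = data.frame(start = wit[, 1L], end = wit[, 2L],
                                      bound = wit[, 3L])),
            class = "bound_result")
}

#' Hudson-Kaplan bound R_m
#'
#' Maximum number of disjoint character intervals each containing a
#' four-gamete-incompatible pair. An incompatible pair (a, b) occupies the
#' open breakpoint interval between sites a and b; two intervals sharing only
#' an endpoint site count as disjoint (their forced breakpoints lie in
#' non-overlapping gaps). Computed by the standard left-to-right greedy scan
#' over minimal incompatible intervals.
#'
#' @param x a \code{character_matrix}.
#' @return List of class \code{"bound_result"} with \code{value} (R_m),
#'   \code{kind = "Rm"} and \code{witness}: the selected disjoint intervals.
#' @export
hudson_kaplan_rm <- function(x) {
  pairs <- incompatible_pairs(x)
  if (nrow(pairs) == 0L) {
    return(structure(list(value = 0L, kind = "Rm",
                          witness = data.frame(start = integer(0),
                                               end = integer(0))),
                     class = "bound_result"))
  }
  ord <- order(pairs[, 2L], pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  chosen <- list()
  last_end <- -Inf
  for (r in seq_len(nrow(pairs))) {
    if (pairs[r, 1L] >= last_end) { # open intervals: endpoint sharing is fine
      chosen[[length(chosen) + 1L]] <- pairs[r, ]
      last_end <- pairs[r, 2L]
    }
  }
  wit <- do.call(rbind, chosen)
  structure(list(value = nrow(wit), kind = "Rm",
                 witness = data.frame(start = wit[, 1L], end = wit[, 2L])),
            class = "bound_result")
}

#' @export
print.bound_result <- function(x, ...) {
  cat(sprintf("%s lower bound on R_min: %d\n",
              switch(x$kind, RMG = "Myers-Griffiths (R_MG)",
                     Rm = "Hudson-Kaplan (R_m)", haplotype = "Haplotype"),
              x$value))
  if (!is.null(x$witness) && nrow(x$witness) > 0L) {
    cat("witness intervals:\n")
    print.data.frame(x$witness, row.names = FALSE)
  }
  invisible(x)
}
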