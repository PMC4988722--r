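#' Vietoris-Rips filtration of an integer distance matrix
#'
#' Enumerates all simplices of dimension at most \code{max_dim} whose
#' filtration value (the largest pairwise distance among their vertices) does
#' not exceed \code{max_scale}. The filtration scale is parameterised by
#' mutational distance \code{t = 2*eps}: a simplex enters when all its
#' pairwise Hamming distances are at most \code{t}.
#'
#' Simplices are ordered by (value, dimension, lexicographic vertex tuple), a
#' deterministic tie-break, so faces always precede cofaces.
#'
#' @param d symmetric nonnegative integer distance matrix.
#' @param max_dim maximum simplex dimension (2 is necessary and sufficient
#'   for first homology).
#' @param max_scale largest filtration value to include; defaults to the
#'   diameter of \code{d}, at which the complex is a full clique.
#' @return Data frame with columns \code{value}, \code{dim} and vertex
#'   columns \code{v1..v(max_dim+1)} (NA for absent vertices), one simplex
#'   per row, in filtration order.
#' @export
rips_filtration <- function(d, max_dim = 2L, max_scale = NULL) {
  check_distance_matrix(d)
  if (max_dim < 1L) stop("max_dim must be at least 1")
  if (max_dim > 2L) max_dim <- 2L
  p <- nrow(d)
  if (is.null(max_scale)) max_scale <- if (p > 1L) max(d) else 0L
  rows <- list()
  for (i in seq_len(p)) rows[[length(rows) + 1L]] <- c(0L, 0L, i, NA, NA)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
      if (d[i, j] <= max_scale) {
        rows[[length(rows) + 1L]] <- c(d[i, j], 1L, i, j, NA)
      }
    }
  }
  if (max_dim >= 2L && p > 2L) {
    for (i in seq_len(p - 2L)) for (j in seq(i + 1L, p - 1L)) for (k in seq(j + 1L, p)) {
      v <- max(d[i, j], d[i, k], d[j, k])
      if (v <= max_scale) rows[[length(rows) + 1L]] <- c(v, 2L, i, j, k)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("value", "dim", "v1", "v2", "v3")
  ord <- order(out$value, out$dim, out$v1, out$v2, out$v3, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First-persistent-homology barcode
#'
#' Computes the finite H1 bars of the Vietoris-Rips filtration of a distance
#' matrix, over GF(2), by boundary-matrix reduction. Bars are reported on the
#' mutational-distance scale \code{t = 2*eps}: a bar \code{(birth, death)}
#' spans scales \code{birth <= t < death} and \code{death} upper-bounds the
#' mutational distance between the recombining sequences behind the loop.
#' Each bar carries a representative cycle (the reduced chain alive at birth;
#' basis-dependent) as a two-column matrix of point indices.
#'
#' Points at mutual distance zero are collapsed before the filtration is
#' built; they would only add instantly-dead features. Zero-persistence pairs
#' are discarded.
#'
#' @param d symmetric nonnegative integer distance matrix (typically from
#'   [hamming_matrix()]).
#' @param max_scale cap on the filtration scale; defaults to the diameter, at
#'   which no infinite H1 bars exist.
#' @return Object of class \code{"h1_barcode"}: a data frame with columns
#'   \code{birth} and \code{death} (integer, \code{2*eps} units), with
#'   attribute \code{representatives} (list of edge matrices, indices into
#'   the rows of \code{d}).
#' @examples
#' m <- character_matrix(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1), c(1, 1, 1)))
#' h1_persistence(hamming_matrix(m)) # one bar, born 2, dead 3
#' @export
h1_persistence <- function(d, max_scale = NULL) {
  check_distance_matrix(d)
  storage.mode(d) <- "integer"
  p <- nrow(d)
  # collapse distance-zero duplicates, remembering original indices
  keep <- rep(TRUE, p)
  if (p > 1L) {
    for (j in seq(2L, p)) {
      if (any(d[seq_len(j - 1L), j] == 0L & keep[seq_len(j - 1L)])) keep[j] <- FALSE
    }
  }
  orig <- which(keep)
  dd <- d[orig, orig, drop = FALSE]
  res <- cpp_h1_persistence(dd, if (is.null(max_scale)) -1L else as.integer(max_scale))
  bars <- data.frame(birth = as.integer(res$birth), death = as.integer(res$death))
  reps <- lapply(res$representative, function(em) {
    em[] <- orig[em]
    em
  })
  structure(bars, representatives = reps, class = c("h1_barcode", "data.frame"))
}

#' @export
print.h1_barcode <- function(x, ...) {
  cat(sprintf("h1_barcode: %d bar%s (scales in 2*eps mutational-distance units)\n",
              nrow(x), if (nrow(x) == 1L) "" else "s"))
  if (nrow(x) > 0L) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# GF(2) rank by Gaussian elimination on a dense 0/1 matrix
gf2_rank <- function(a) {
  if (length(a) == 0L || nrow(a) == 0L || ncol(a) == 0L) return(0L)
  a <- a %% 2L
  nr <- nrow(a); nc <- ncol(a)
  rank <- 0L
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(a[row:nr, col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) a[c(row, piv), ] <- a[c(piv, row), ]
    hits <- which(a[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits) > 0L) {
      a[hits, ] <- (a[hits, , drop = FALSE] + matrix(a[row, ], length(hits),
                                                     nc, byrow = TRUE)) %% 2L
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

#' First Betti number of the Rips complex at a fixed scale
#'
#' Independent oracle: builds the boundary operators of the Rips complex at
#' scale \code{t} directly and computes
#' \code{beta_1 = dim ker(d1) - rank(d2)} by GF(2) Gaussian elimination,
#' without the persistence reduction algorithm. Used to cross-check
#' [h1_persistence()]: the number of bars alive at \code{t}
#' (\code{birth <= t < death}) must equal this value.
#'
#' @param d symmetric nonnegative integer distance matrix.
#' @param t integer scale (\code{2*eps} units), \code{t >= 0}.
#' @return Integer first Betti number.
#' @export
betti1_at_scale <- function(d, t) {
  check_distance_matrix(d)
  stopifnot(t >= 0)
  p <- nrow(d)
  edges <- NULL
  if (p > 1L) {
    idx <- which(upper.tri(d) & d <= t, arr.ind = TRUE)
    if (nrow(idx) > 0L) edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  }
  ne <- if (is.null(edges)) 0L else nrow(edges)
  if (ne == 0L) return(0L)
  d1 <- matrix(0L, p, ne)
  for (e in seq_len(ne)) d1[edges[e, ], e] <- 1L
  tri <- list()
  if (p > 2L) {
    for (i in seq_len(p - 2L)) for (j in seq(i + 1L, p - 1L)) for (k in seq(j + 1L, p)) {
      if (max(d[i, j], d[i, k], d[j, k]) <= t) tri[[length(tri) + 1L]] <- c(i, j, k)
    }
  }
  nt <- length(tri)
  r2 <- 0L
  if (nt > 0L) {
    ekey <- paste(edges[, 1L], edges[, 2L])
    d2 <- matrix(0L, ne, nt)
    for (s in seq_len(nt)) {
      v <- tri[[s]]
      d2[match(c(paste(v[1L], v[2L]), paste(v[1L], v[3L]), paste(v[2L], v[3L])),
               ekey), s] <- 1L
    }
    r2 <- gf2_rank(d2)
  }
  as.integer(ne - gf2_rank(d1) - r2)
}
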