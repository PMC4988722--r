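#' Hamming distance matrix of a haplotype sample
#'
#' Pairwise mutational distances: entry (a, b) counts the characters, within
#' the chosen interval (and \code{retained} subset, if any), at which
#' sequences a and b differ. Distances are raw integer counts; the bar scales
#' downstream are quoted in these units (a bar death \code{2*eps_d = 5} means
#' five mutations), so no length normalisation is applied.
#'
#' @param x a \code{character_matrix}.
#' @param interval optional integer pair \code{(i, k)}, 1-based inclusive.
#' @param retained optional character subset intersected with the interval.
#' @param metric distance to use; only \code{"hamming"} is implemented. The
#'   argument exists so alternative genetic distances can be slotted in later.
#' @return Symmetric integer matrix with zero diagonal, labelled by the
#'   sequence names.
#' @examples
#' m <- character_matrix(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1), c(1, 1, 1)))
#' hamming_matrix(m)
#' @export
hamming_matrix <- function(x, interval = NULL, retained = NULL,
                           metric = "hamming") {
  stopifnot(inherits(x, "character_matrix"))
  metric <- match.arg(metric, "hamming")
  m <- ncol(x)
  dat <- unclass(x)
  if (!is.null(interval) || !is.null(retained)) {
    if (is.null(interval)) interval <- c(1L, m)
    ik <- check_interval(interval, m)
    cols <- seq(ik[1L], ik[2L])
    if (!is.null(retained)) cols <- intersect(cols, as.integer(retained))
    dat <- dat[, cols, drop = FALSE]
  }
  n <- nrow(dat)
  if (ncol(dat) == 0L) {
    d <- matrix(0L, n, n)
  } else {
    # for 0/1 data: d(a,b) = sum a + sum b - 2 * <a,b>
    g <- tcrossprod(dat)
    s <- diag(g)
    d <- outer(s, s, "+") - 2L * g
    storage.mode(d) <- "integer"
  }
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  if (any(d != t(d))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  invisible(d)
}
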