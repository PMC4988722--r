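# ---- barcode ordering ----------------------------------------------------

# compare two bar tables (data frames with birth/death):
# > 0 if a is the greater barcode, 0 on exact tie.
# (1) larger bar count (L0); (2) elementwise larger sorted death sequence
# (ascending), so the least-informative bar is as long-scaled as possible;
# (3) larger total bar length (L1); (4) elementwise smaller sorted births.
compare_barcodes <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na != nb) return(sign(na - nb))
  if (na == 0L) return(0L)
  da <- sort(a$death); db <- sort(b$death)
  for (r in seq_len(na)) {
    if (da[r] != db[r]) return(sign(da[r] - db[r]))
  }
  l1a <- sum(a$death - a$birth); l1b <- sum(b$death - b$birth)
  if (l1a != l1b) return(sign(l1a - l1b))
  ba <- sort(a$birth); bb <- sort(b$birth)
  for (r in seq_len(na)) {
    if (ba[r] != bb[r]) return(sign(bb[r] - ba[r]))
  }
  0L
}

#' Ordering relation on barcodes
#'
#' Returns the greater of two barcodes under the ordering used by the
#' ensemble dynamic program: larger bar count (L0 norm) first; ties broken
#' by the elementwise larger sorted death-time sequence, then by larger
#' total bar length, then by elementwise smaller births; an exact tie
#' returns the first argument.
#'
#' @param bc1,bc2 barcodes: data frames with \code{birth} and \code{death}
#'   columns (e.g. from [h1_persistence()]).
#' @return Whichever barcode is greater (the first argument on an exact tie).
#' @export
barcode_order <- function(bc1, bc2) {
  if (compare_barcodes(bc2, bc1) > 0L) bc2 else bc1
}

# ---- interval barcodes ---------------------------------------------------

#' First-homology barcode of a character interval
#'
#' Computes the H1 barcode of the sample restricted to characters
#' \code{i..k} (intersected with \code{retained} if given): duplicate
#' restricted haplotypes are collapsed, the Hamming matrix of the unique rows
#' is built, and [h1_persistence()] is applied. Bars are annotated with the
#' source interval.
#'
#' @param x a \code{character_matrix}.
#' @param i,k interval bounds, 1-based inclusive.
#' @param retained optional character subset.
#' @param s,w admissibility limits: the interval must contain at most
#'   \code{s} retained characters and span at most \code{w} index steps;
#'   violating either is an error. Defaults impose no limit.
#' @return Data frame with columns \code{birth}, \code{death},
#'   \code{char_start}, \code{char_end}; attribute \code{representatives}
#'   holds one edge matrix per bar with indices into the unique-haplotype
#'   rows (attribute \code{haplotypes}).
#' @export
interval_barcode <- function(x, i, k, retained = NULL, s = NULL, w = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  ik <- check_interval(c(i, k), ncol(x))
  uh <- unique_haplotypes(x, interval = ik, retained = retained)
  nchar_used <- length(uh$columns)
  if (!is.null(s) && nchar_used > s) {
    stop(sprintf("interval (%d, %d) holds %d characters, exceeding s = %d",
                 ik[1L], ik[2L], nchar_used, s))
  }
  if (!is.null(w) && (ik[2L] - ik[1L]) > w) {
    stop(sprintf("interval (%d, %d) spans %d, exceeding w = %d",
                 ik[1L], ik[2L], ik[2L] - ik[1L], w))
  }
  bc <- h1_persistence(hamming_matrix(uh$matrix))
  out <- data.frame(birth = bc$birth, death = bc$death,
                    char_start = rep(ik[1L], nrow(bc)),
                    char_end = rep(ik[2L], nrow(bc)))
  structure(out,
            representatives = attr(bc, "representatives"),
            haplotypes = uh)
}

# ---- the ensemble dynamic program ---------------------------------------

#' Barcode ensemble of a haplotype sample
#'
#' The package's core computation. The alignment is partitioned into chains
#' of character intervals (consecutive intervals share their endpoint
#' character, so the breakpoints they witness fall between distinct sites);
#' each interval contributes its first-homology barcode; and the dynamic
#' program
#' \deqn{R_k = \max_{i < k} \; R_i \cup B_{ik}}
#' selects the partition whose disjoint union of bars is maximal under the
#' barcode ordering (bar count, then total length, then a deterministic
#' lexicographic rule). The resulting union is the barcode ensemble; its bar
#' count \code{b1_bar} lower-bounds the number of recombination events in
#' the topological ancestral recombination graph of the sample, and each
#' bar's death time (in \code{2*eps} mutational-distance units) upper-bounds
#' the local genetic distance between the sequences recombining in its
#' interval.
#'
#' Intervals holding more than \code{s} characters or spanning more than
#' \code{w} index steps contribute the empty barcode, which prunes the
#' search exactly as in interval-composition bound software. With
#' \code{exclude_compatible = TRUE} the chain runs over the characters that
#' fail the four-gamete test against at least one other character; reported
#' coordinates always refer to the original alignment.
#'
#' @param x a \code{character_matrix} (or an object [character_matrix()] can
#'   coerce).
#' @param s maximum number of (retained) characters per interval; default m.
#' @param w maximum interval index span \code{k - i} in retained-character
#'   indexing; default m.
#' @param exclude_compatible drop characters compatible with all others
#'   before partitioning (the \code{-e} style reduction).
#' @return Object of class \code{"barcode_ensemble"}: a list with
#'   \describe{
#'     \item{bars}{data frame of bars: \code{birth}, \code{death} (integer,
#'       \code{2*eps} units), \code{char_start}, \code{char_end} (original
#'       character indices), \code{pos_start}, \code{pos_end} (genomic
#'       coordinates).}
#'     \item{b1_bar}{total bar count.}
#'     \item{mean_eps_d}{mean death time in \code{eps} units (death / 2);
#'       \code{NA} for an empty ensemble.}
#'     \item{partition}{the winning chain of interval endpoints (original
#'       character indices).}
#'     \item{representatives}{per-bar representative cycles (edge matrices
#'       over the unique restricted haplotypes of the bar's interval).}
#'     \item{retained, s, w, exclude_compatible, input}{parameters and data
#'       for downstream reconstruction.}
#'   }
#' @examples
#' quartet <- character_matrix(rbind(
#'   c(1, 1, 1, 1, 0, 0, 1),
#'   c(1, 1, 1, 1, 1, 1, 1),
#'   c(0, 0, 0, 0, 1, 1, 0),
#'   c(0, 0, 0, 0, 0, 0, 0)))
#' ens <- barcode_ensemble(quartet)
#' ens            # two bars, deaths 5 and 3
#' summary(ens)
#' @export
barcode_ensemble <- function(x, s = NULL, w = NULL, exclude_compatible = FALSE) {
  if (!inherits(x, "character_matrix")) x <- character_matrix(x)
  m <- ncol(x)
  retained <- if (exclude_compatible) exclude_compatible_characters(x) else seq_len(m)
  if (is.null(s)) s <- max(length(retained), 1L)
  if (is.null(w)) w <- max(length(retained), 1L)
  if (s < 2L && length(retained) >= 2L) stop("s must be at least 2")
  if (w < 1L) stop("w must be at least 1")
  empty_bars <- data.frame(birth = integer(0), death = integer(0),
                           char_start = integer(0), char_end = integer(0))
  mk <- function(bars, reps, partition) {
    pos <- positions(x)
    bars$pos_start <- if (nrow(bars)) pos[bars$char_start] else numeric(0)
    bars$pos_end <- if (nrow(bars)) pos[bars$char_end] else numeric(0)
    structure(list(bars = bars,
                   b1_bar = nrow(bars),
                   mean_eps_d = if (nrow(bars)) mean(bars$death) / 2 else NA_real_,
                   partition = partition,
                   representatives = reps,
                   retained = retained,
                   s = s, w = w,
                   exclude_compatible = exclude_compatible,
                   input = x),
              class = "barcode_ensemble")
  }
  if (length(retained) == 0L || m == 0L) {
    warning("no characters left to partition; returning an empty ensemble")
    return(mk(empty_bars, list(), integer(0)))
  }
  mr <- length(retained)
  if (mr == 1L) return(mk(empty_bars, list(), retained))

  # DP over retained-character indexing 1..mr
  best_bars <- vector("list", mr)
  best_reps <- vector("list", mr)
  best_back <- integer(mr)
  best_bars[[1L]] <- empty_bars
  best_reps[[1L]] <- list()
  for (k in seq(2L, mr)) {
    cur_bars <- NULL
    for (i in seq_len(k - 1L)) {
      if ((k - i) <= w && (k - i + 1L) <= s) {
        ib <- interval_barcode(x, retained[i], retained[k], retained = retained)
        ib_reps <- attr(ib, "representatives")
      } else {
        ib <- empty_bars
        ib_reps <- list()
      }
      cand_bars <- rbind(best_bars[[i]], as.data.frame(ib))
      if (is.null(cur_bars) || compare_barcodes(cand_bars, cur_bars) > 0L) {
        cur_bars <- cand_bars
        cur_reps <- c(best_reps[[i]], ib_reps)
        best_back[k] <- i
      }
    }
    best_bars[[k]] <- cur_bars
    best_reps[[k]] <- cur_reps
  }
  chain <- mr
  k <- mr
  while (k > 1L) {
    k <- best_back[k]
    chain <- c(k, chain)
  }
  mk(best_bars[[mr]], best_reps[[mr]], retained[chain])
}

#' @export
print.barcode_ensemble <- function(x, ...) {
  cat(sprintf("barcode ensemble: b1_bar = %d bar%s (s = %d, w = %d%s)\n",
              x$b1_bar, if (x$b1_bar == 1L) "" else "s", x$s, x$w,
              if (x$exclude_compatible) ", compatible characters excluded" else ""))
  if (x$b1_bar > 0L) {
    cat(sprintf("mean death time <eps_d> = %g (mutational distance %g)\n",
                x$mean_eps_d, 2 * x$mean_eps_d))
    print.data.frame(x$bars, row.names = FALSE)
  }
  if (length(x$partition) > 1L) {
    cat("winning partition (character chain):",
        paste(x$partition, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.barcode_ensemble <- function(object, ...) {
  per_interval <- if (object$b1_bar > 0L) {
    stats::aggregate(list(bars = object$bars$birth),
                     by = list(char_start = object$bars$char_start,
                               char_end = object$bars$char_end),
                     FUN = length)
  } else {
    data.frame(char_start = integer(0), char_end = integer(0), bars = integer(0))
  }
  out <- list(b1_bar = object$b1_bar,
              mean_eps_d = object$mean_eps_d,
              per_interval = per_interval,
              s = object$s, w = object$w,
              n = nrow(object$input), m = ncol(object$input))
  class(out) <- "summary.barcode_ensemble"
  out
}

#' @export
print.summary.barcode_ensemble <- function(x, ...) {
  cat(sprintf("sample: n = %d sequences, m = %d characters\n", x$n, x$m))
  cat(sprintf("b1_bar = %d; <eps_d> = %s\n", x$b1_bar,
              if (is.na(x$mean_eps_d)) "undefined (no bars)"
              else format(x$mean_eps_d)))
  if (nrow(x$per_interval) > 0L) {
    cat("bars per interval:\n")
    print.data.frame(x$per_interval, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a barcode ensemble
#'
#' Draws each bar as a horizontal segment from birth to death on the
#' mutational-distance scale, labelled with its source character interval.
#'
#' @param x a \code{barcode_ensemble}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.barcode_ensemble <- function(x, ...) {
  b <- x$bars
  if (nrow(b) == 0L) {
    graphics::plot.new()
    graphics::title(main = "barcode ensemble (no bars)")
    return(invisible(x))
  }
  b <- b[order(b$death, b$birth), , drop = FALSE]
  graphics::plot(NA, xlim = c(0, max(b$death)), ylim = c(0.5, nrow(b) + 0.5),
                 xlab = "mutational distance (2*eps)", ylab = "bar",
                 yaxt = "n", ...)
  graphics::segments(b$birth, seq_len(nrow(b)), b$death, seq_len(nrow(b)),
                     lwd = 3)
  graphics::text(b$death, seq_len(nrow(b)),
                 labels = sprintf("chars %d-%d", b$char_start, b$char_end),
                 pos = 4, cex = 0.8)
  invisible(x)
}

#' Breakpoint location report
#'
#' Maps each ensemble bar to the genomic interval that must contain the
#' crossover breakpoint(s) it witnesses: the open interval between the
#' positions of its source characters. Per-character event counts for
#' histogram-style summaries follow directly by tabulating
#' \code{char_start..char_end}.
#'
#' @param ens a \code{barcode_ensemble}.
#' @return Data frame with one row per bar: \code{bar}, \code{birth},
#'   \code{death}, \code{char_start}, \code{char_end}, \code{pos_start},
#'   \code{pos_end}.
#' @export
breakpoint_report <- function(ens) {
  stopifnot(inherits(ens, "barcode_ensemble"))
  b <- ens$bars
  if (nrow(b) == 0L) {
    return(data.frame(bar = integer(0), birth = integer(0), death = integer(0),
                      char_start = integer(0), char_end = integer(0),
                      pos_start = numeric(0), pos_end = numeric(0)))
  }
  data.frame(bar = seq_len(nrow(b)), b, row.names = NULL)
}

#' Ensemble summary statistics
#'
#' Convenience accessor for the two headline statistics of a barcode
#' ensemble: the bar count \code{b1_bar} and the mean death time
#' \code{<eps_d>} (in \code{eps} units, i.e. death / 2), plus the per-interval
#' bar counts.
#'
#' @param ens a \code{barcode_ensemble}.
#' @return List with \code{b1_bar}, \code{mean_eps_d} (NA when the ensemble
#'   is empty) and \code{per_interval}.
#' @export
ensemble_summary <- function(ens) {
  s <- summary(ens)
  list(b1_bar = s$b1_bar, mean_eps_d = s$mean_eps_d,
       per_interval = s$per_interval)
}
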