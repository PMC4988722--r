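# Exact minimum-recombination oracle for tiny instances.
#
# Backward search over ancestral configurations: rows are partially specified
# sequences over {0, 1, *} ('*' = non-ancestral material). Safe moves applied
# greedily: clearing explained columns, removing singleton mutations, merging
# identical rows. Branching moves: coalescence of compatible rows and
# single-crossover splits (which cost one recombination). Iterative deepening
# on the recombination count gives R_min; exhaustive enumeration at that
# depth, with forward replay of node labels, gives the ultra-minimal history
# (minimum summed Hamming distance between recombining parents).

STAR <- "*"

rows_to_strings <- function(x) {
  apply(unclass(x), 1L, paste, collapse = "")
}

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

state_key <- function(rows) paste(sort(rows), collapse = "|")

# Hudson-Kaplan bound on a wildcard state: a valid lower bound on the
# recombinations still needed (incompatibilities among ancestral material
# cannot be resolved by mutation or coalescence).
state_hk_bound <- function(mat) {
  m <- ncol(mat)
  if (m < 2L || nrow(mat) < 4L) return(0L)
  pairs <- list()
  for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
    ok <- mat[, i] != STAR & mat[, j] != STAR
    if (sum(ok) < 4L) next
    g <- unique(paste0(mat[ok, i], mat[ok, j]))
    if (length(g) == 4L) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (length(pairs) == 0L) return(0L)
  p <- do.call(rbind, pairs)
  p <- p[order(p[, 2L], p[, 1L]), , drop = FALSE]
  cnt <- 0L; last <- -Inf
  for (r in seq_len(nrow(p))) {
    if (p[r, 1L] >= last) { cnt <- cnt + 1L; last <- p[r, 2L] }
  }
  cnt
}

# Apply all forced moves, recording events. rows: character matrix over
# {0,1,*} (n x m of single chars); ids: integer lineage ids.
oracle_clean <- function(mat, ids, events, counter) {
  repeat {
    changed <- FALSE
    if (nrow(mat) == 0L) break
    # explained / singleton-mutation columns
    for (c in seq_len(ncol(mat))) {
      col <- mat[, c]
      i0 <- which(col == "0"); i1 <- which(col == "1")
      n0 <- length(i0); n1 <- length(i1)
      if (n0 == 0L && n1 == 0L) next
      if (n0 == 0L || n1 == 0L) { # constant among ancestral material: clear
        mat[, c] <- STAR
        changed <- TRUE
        next
      }
      if (n0 == 1L && n1 > 1L) {
        events[[length(events) + 1L]] <- list(type = "mut", col = c,
                                              row = ids[i0], derived = "0",
                                              ancestral = "1")
        mat[, c] <- STAR
        changed <- TRUE
      } else if (n1 == 1L) { # includes the 1-vs-1 tie: derived allele is 1
        events[[length(events) + 1L]] <- list(type = "mut", col = c,
                                              row = ids[i1], derived = "1",
                                              ancestral = "0")
        mat[, c] <- STAR
        changed <- TRUE
      }
    }
    # drop lineages with no ancestral material left
    if (nrow(mat) > 0L) {
      alive <- rowSums(mat != STAR) > 0L
      if (!all(alive)) {
        for (i in which(!alive)) {
          events[[length(events) + 1L]] <- list(type = "drop", row = ids[i])
        }
        mat <- mat[alive, , drop = FALSE]
        ids <- ids[alive]
        changed <- TRUE
      }
    }
    # merge identical rows
    if (nrow(mat) > 1L) {
      keys <- apply(mat, 1L, paste, collapse = "")
      dup <- which(duplicated(keys))
      if (length(dup) > 0L) {
        i <- dup[1L]
        j <- which(keys == keys[i])[1L]
        counter <- counter + 1L
        events[[length(events) + 1L]] <- list(type = "coal", a = ids[j],
                                              b = ids[i], child = counter)
        ids[j] <- counter
        mat <- mat[-i, , drop = FALSE]
        ids <- ids[-i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(mat = mat, ids = ids, events = events, counter = counter)
}

rows_compatible <- function(a, b) {
  both <- a != STAR & b != STAR
  all(a[both] == b[both])
}

merge_rows <- function(a, b) {
  out <- a
  take <- a == STAR
  out[take] <- b[take]
  out
}

# successor states from branching moves; each: list(mat, ids, events, counter,
# cost). Duplicate successor matrices (up to row order) are pruned.
oracle_successors <- function(mat, ids, events, counter, allow_split) {
  succ <- list()
  seen <- character(0)
  n <- nrow(mat)
  add <- function(mat2, ids2, ev, counter2, cost) {
    key <- paste(sort(apply(mat2, 1L, paste, collapse = "")), collapse = "|")
    if (key %in% seen) return()
    seen[[length(seen) + 1L]] <<- key
    succ[[length(succ) + 1L]] <<- list(mat = mat2, ids = ids2,
                                       events = ev, counter = counter2,
                                       cost = cost)
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (rows_compatible(mat[i, ], mat[j, ])) {
        counter2 <- counter + 1L
        ev <- events
        ev[[length(ev) + 1L]] <- list(type = "coal", a = ids[i], b = ids[j],
                                      child = counter2)
        mat2 <- mat[-j, , drop = FALSE]
        ids2 <- ids[-j]
        mat2[i, ] <- merge_rows(mat[i, ], mat[j, ])
        ids2[i] <- counter2
        add(mat2, ids2, ev, counter2, 0L)
      }
    }
  }
  if (allow_split && ncol(mat) > 1L) {
    m <- ncol(mat)
    for (i in seq_len(n)) {
      anc <- which(mat[i, ] != STAR)
      if (length(anc) < 2L) next
      # only breakpoints separating ancestral material produce new states
      for (k in seq(min(anc), max(anc) - 1L)) {
        pre <- mat[i, ]; suf <- mat[i, ]
        pre[seq(k + 1L, m)] <- STAR
        suf[seq_len(k)] <- STAR
        if (all(pre == STAR) || all(suf == STAR)) next
        counter2 <- counter + 2L
        ev <- events
        ev[[length(ev) + 1L]] <- list(type = "split", row = ids[i], k = k,
                                      prefix = counter2 - 1L,
                                      suffix = counter2)
        mat2 <- rbind(mat[-i, , drop = FALSE], pre, suf)
        ids2 <- c(ids[-i], counter2 - 1L, counter2)
        rownames(mat2) <- NULL
        add(mat2, ids2, ev, counter2, 1L)
      }
    }
  }
  succ
}

# existence search with failure memoisation
oracle_feasible <- function(mat, ids, budget, memo) {
  cl <- oracle_clean(mat, ids, list(), 10000L)
  if (nrow(cl$mat) <= 1L) return(TRUE)
  key <- paste(sort(apply(cl$mat, 1L, paste, collapse = "")), collapse = "|")
  failed_at <- memo$failed[[key]]
  if (!is.null(failed_at) && budget <= failed_at) return(FALSE)
  if (state_hk_bound(cl$mat) > budget) {
    memo$failed[[key]] <- max(budget, failed_at %||% -1L)
    return(FALSE)
  }
  for (s in oracle_successors(cl$mat, cl$ids, list(), cl$counter, budget > 0L)) {
    if (oracle_feasible(s$mat, s$ids, budget - s$cost, memo)) return(TRUE)
  }
  memo$failed[[key]] <- max(budget, failed_at %||% -1L)
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_tiny <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  nd <- nrow(unique_haplotypes(x)$matrix)
  if (nd > 8L || ncol(x) > 8L) {
    stop(sprintf(paste("instance too large for the exact oracle",
                       "(%d distinct sequences, %d characters; both must be <= 8)"),
                 nd, ncol(x)))
  }
  invisible(x)
}

#' Exact minimum number of recombinations (tiny instances)
#'
#' Exhaustive backward search for the minimum number R_min of
#' single-crossover recombinations required to explain the sample under
#' infinite sites (no convergent evolution or back-mutation). Iterative
#' deepening on the recombination count; ancestral configurations are
#' memoised and pruned with the Hudson-Kaplan bound. Intended as a
#' ground-truth oracle for small examples and tests; the problem is NP-hard,
#' so instances are restricted to at most 8 distinct sequences and 8
#' characters.
#'
#' @param x a \code{character_matrix}.
#' @param max_r give up beyond this many recombinations.
#' @return R_min as an integer, or \code{NA} (with a warning) if it exceeds
#'   \code{max_r}.
#' @examples
#' square <- character_matrix(rbind(c(0,0,0), c(0,1,0), c(1,0,1), c(1,1,1)))
#' exact_rmin(square) # 2
#' @export
exact_rmin <- function(x, max_r = 6L) {
  check_tiny(x)
  mat <- matrix(as.character(unclass(x)), nrow(x), ncol(x))
  ids <- seq_len(nrow(x))
  memo <- new.env(parent = emptyenv())
  memo$failed <- list()
  for (r in 0:max_r) {
    if (oracle_feasible(mat, ids, r, memo)) return(as.integer(r))
  }
  warning("R_min exceeds max_r = ", max_r)
  NA_integer_
}

# ---- ultra-minimal histories --------------------------------------------

# forward replay: assign full sequences to every lineage, compute parental
# distances at each recombination, and collect condensed-graph edges.
replay_history <- function(events, x) {
  m <- ncol(x)
  dat <- matrix(as.character(unclass(x)), nrow(x), m)
  anc <- character(m)
  for (c in seq_len(m)) {
    vals <- unique(dat[, c])
    anc[c] <- if (length(vals) == 1L) vals else NA_character_
  }
  for (e in events) if (e$type == "mut") anc[e$col] <- e$ancestral
  if (anyNA(anc)) stop("internal: unexplained segregating character in history")
  seqs <- new.env(parent = emptyenv())
  getseq <- function(id) {
    s <- seqs[[as.character(id)]]
    if (is.null(s)) anc else s
  }
  setseq <- function(id, s) assign(as.character(id), s, envir = seqs)
  d_r <- integer(0)
  parents <- list()
  breakpoints <- integer(0)
  mut_edges <- list()
  rec_edges <- list()
  for (e in rev(events)) {
    if (e$type == "mut") {
      before <- getseq(e$row)
      after <- before
      after[e$col] <- e$derived
      mut_edges[[length(mut_edges) + 1L]] <-
        c(paste(before, collapse = ""), paste(after, collapse = ""),
          as.character(e$col))
      setseq(e$row, after)
    } else if (e$type == "coal") {
      s <- getseq(e$child)
      setseq(e$a, s)
      setseq(e$b, s)
    } else if (e$type == "split") {
      p <- getseq(e$prefix)
      q <- getseq(e$suffix)
      child <- c(p[seq_len(e$k)], q[seq(e$k + 1L, m)])
      d_r[[length(d_r) + 1L]] <- sum(p != q)
      parents[[length(parents) + 1L]] <- c(paste(p, collapse = ""),
                                           paste(q, collapse = ""))
      breakpoints[[length(breakpoints) + 1L]] <- e$k
      rec_edges[[length(rec_edges) + 1L]] <-
        c(paste(child, collapse = ""), paste(p, collapse = ""), "P")
      rec_edges[[length(rec_edges) + 1L]] <-
        c(paste(child, collapse = ""), paste(q, collapse = ""), "S")
      setseq(e$row, child)
    } # drop: nothing to do, lineage label defaults to the root sequence
  }
  leaf_seqs <- vapply(seq_len(nrow(x)),
                      function(i) paste(getseq(i), collapse = ""), character(1))
  observed <- apply(dat, 1L, paste, collapse = "")
  if (!identical(leaf_seqs, observed)) {
    stop("internal: history replay does not reproduce the sample")
  }
  list(d_r = rev(d_r), cost_D = sum(d_r),
       parents = rev(parents), breakpoints = rev(breakpoints),
       mut_edges = mut_edges, rec_edges = rec_edges,
       root = paste(anc, collapse = ""))
}

#' Ultra-minimal recombination history
#'
#' Among all backward histories with exactly R_min recombinations, finds one
#' minimising the total cost D = sum of d_r, where d_r is the Hamming
#' distance between the full sequences of the two parents of the r-th
#' recombination (node labels are propagated from the root once a history is
#' complete). Ultra-minimal histories are the parsimonious ARGs whose
#' recombining parents are as genetically close as possible; bar death times
#' in the barcode ensemble upper-bound these parental distances.
#'
#' @param x a \code{character_matrix} (tiny: at most 8 distinct sequences
#'   and 8 characters).
#' @param rmin the known R_min; computed via [exact_rmin()] when NULL.
#' @param max_histories safety cap on the number of complete histories
#'   enumerated.
#' @return Object of class \code{"minimal_history"}: list with \code{R},
#'   \code{parental_distances} (full-sequence Hamming distances d_r),
#'   \code{cost_D}, \code{parents} (per-recombination pair of full parental
#'   sequences), \code{breakpoints} (prefix lengths), \code{events} (the
#'   backward event sequence) and \code{root} (the inferred root sequence).
#' @export
ultra_minimal_cost <- function(x, rmin = NULL, max_histories = 200000L) {
  check_tiny(x)
  if (is.null(rmin)) rmin <- exact_rmin(x)
  if (is.na(rmin)) stop("R_min unknown; raise max_r in exact_rmin")
  mat <- matrix(as.character(unclass(x)), nrow(x), ncol(x))
  ids <- seq_len(nrow(x))
  memo <- new.env(parent = emptyenv())
  memo$failed <- list()
  best <- new.env(parent = emptyenv())
  best$D <- Inf
  best$hist <- NULL
  best$count <- 0L
  recurse <- function(mat, ids, events, counter, budget) {
    cl <- oracle_clean(mat, ids, events, counter)
    if (nrow(cl$mat) <= 1L) {
      if (budget > 0L) return(invisible()) # fewer recombinations than R_min
      best$count <- best$count + 1L
      if (best$count > max_histories) stop("history enumeration cap exceeded")
      rep <- replay_history(cl$events, x)
      if (rep$cost_D < best$D) {
        best$D <- rep$cost_D
        best$hist <- list(events = cl$events, replay = rep)
      }
      return(invisible())
    }
    if (!oracle_feasible(cl$mat, cl$ids, budget, memo)) return(invisible())
    for (s in oracle_successors(cl$mat, cl$ids, cl$events, cl$counter,
                                budget > 0L)) {
      recurse(s$mat, s$ids, s$events, s$counter, budget - s$cost)
    }
    invisible()
  }
  recurse(mat, ids, list(), 10000L, rmin)
  if (is.null(best$hist)) stop("no history found at R_min; internal error")
  rep <- best$hist$replay
  structure(list(R = as.integer(rmin),
                 parental_distances = as.integer(rep$d_r),
                 cost_D = as.integer(rep$cost_D),
                 parents = rep$parents,
                 breakpoints = as.integer(rep$breakpoints),
                 events = best$hist$events,
                 root = rep$root,
                 mut_edges = rep$mut_edges,
                 rec_edges = rep$rec_edges,
                 m = ncol(x)),
            class = "minimal_history")
}

#' @export
print.minimal_history <- function(x, ...) {
  cat(sprintf("ultra-minimal history: R_min = %d, cost D = %d\n", x$R, x$cost_D))
  if (x$R > 0L) {
    cat("parental Hamming distances d_r:",
        paste(x$parental_distances, collapse = " "), "\n")
  }
  cat(sprintf("root sequence: %s; %d backward events\n", x$root,
              length(x$events)))
  invisible(x)
}

#' Condensed graph of a minimal history
#'
#' Collapses all unlabelled (coalescence) edges of the history's ARG, leaving
#' only mutation edges (one per character) and recombination edges (two per
#' event, prefix and suffix parents). The resulting graph embeds in the
#' m-hypercube with diagonals and has m + 2R edges, m + R + 1 vertices and R
#' independent loops.
#'
#' @param h a \code{minimal_history}.
#' @return Object of class \code{"condensed_arg"}: list with \code{vertices}
#'   (sequence labels), \code{edges} (data frame from/to/label/type),
#'   \code{n_vertices}, \code{n_edges}, \code{n_loops} (cycle rank).
#' @export
condensed_graph <- function(h) {
  stopifnot(inherits(h, "minimal_history"))
  em <- do.call(rbind, c(h$mut_edges, h$rec_edges))
  edges <- data.frame(from = em[, 1L], to = em[, 2L], label = em[, 3L],
                      type = rep(c("mutation", "recombination"),
                                 c(length(h$mut_edges), length(h$rec_edges))),
                      stringsAsFactors = FALSE)
  verts <- unique(c(edges$from, edges$to))
  # connected components (union-find) for the cycle rank
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    ra <- find(match(edges$from[r], verts))
    rb <- find(match(edges$to[r], verts))
    if (ra != rb) parent[rb] <- ra
  }
  ncomp <- length(unique(vapply(seq_along(verts), find, integer(1))))
  loops <- nrow(edges) - length(verts) + ncomp
  structure(list(vertices = verts, edges = edges,
                 n_vertices = length(verts), n_edges = nrow(edges),
                 n_loops = as.integer(loops)),
            class = "condensed_arg")
}

#' @export
print.condensed_arg <- function(x, ...) {
  cat(sprintf("condensed ARG: %d vertices, %d labelled edges, %d independent loops\n",
              x$n_vertices, x$n_edges, x$n_loops))
  invisible(x)
}
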