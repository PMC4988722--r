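#' Partial reconstruction of the topological ARG
#'
#' Builds a graph whose loops are the representative cycles of the ensemble
#' bars, with the remaining sampled haplotypes attached by nearest-neighbour
#' Hamming distance. Representative cycles live on haplotypes restricted to a
#' bar's character interval; each restricted haplotype class is mapped back
#' to the sampled sequence (among its members) closest, over the full
#' alignment, to the members of the adjacent cycle classes — so sampled
#' internal nodes (e.g. one-mutation neighbours of a recombinant) are
#' preferred as loop vertices and distinct loops disentangle once such nodes
#' are present in the sample. Ties break to the lowest row index.
#'
#' Representatives are basis-dependent: the graph's topology (its loop
#' count and which samples sit on loops) is the contract, not the exact edge
#' geometry.
#'
#' @param x a \code{character_matrix}; defaults to the ensemble's input.
#' @param ens a \code{barcode_ensemble} computed on \code{x} (recomputed with
#'   default parameters when NULL).
#' @return Object of class \code{"targ_graph"}: list with
#'   \describe{
#'     \item{nodes}{data frame: \code{id}, \code{label}, \code{sequence} (one
#'       row per distinct haplotype).}
#'     \item{edges}{data frame: \code{from}, \code{to} (node ids),
#'       \code{length} (full Hamming distance), \code{kind} ("cycle" or
#'       "attachment").}
#'     \item{loops}{per-bar edge matrices (node ids).}
#'     \item{loop_count}{number of annotated loops (= the ensemble's
#'       \code{b1_bar}).}
#'   }
#' @examples
#' quartet <- character_matrix(rbind(
#'   c(1, 1, 1, 1, 0, 0, 1), c(1, 1, 1, 1, 1, 1, 1),
#'   c(0, 0, 0, 0, 1, 1, 0), c(0, 0, 0, 0, 0, 0, 0)))
#' g <- reconstruct_targ(quartet)
#' g$loop_count # 2 (both loops share the same four nodes)
#' @export
reconstruct_targ <- function(x, ens = NULL) {
  if (is.null(ens)) {
    stopifnot(inherits(x, "character_matrix"))
    ens <- barcode_ensemble(x)
  }
  stopifnot(inherits(ens, "barcode_ensemble"))
  if (missing(x) || is.null(x)) x <- ens$input
  n <- nrow(x)
  dfull <- hamming_matrix(x)
  uh_full <- unique_haplotypes(x)
  node_of_row <- uh_full$row_map # original row -> node id
  nodes <- data.frame(id = seq_len(nrow(uh_full$matrix)),
                      label = rownames(uh_full$matrix),
                      sequence = rows_to_strings(uh_full$matrix),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = integer(0), to = integer(0),
                      length = integer(0), kind = character(0))
  loops <- list()
  bars <- ens$bars
  for (b in seq_len(nrow(bars))) {
    ik <- c(bars$char_start[b], bars$char_end[b])
    uh <- unique_haplotypes(x, interval = ik, retained = ens$retained)
    rep_edges <- ens$representatives[[b]] # indices into uh$matrix rows
    classes <- sort(unique(as.integer(rep_edges)))
    members <- lapply(classes, function(cl) which(uh$row_map == cl))
    names(members) <- classes
    # adjacency among classes from the cycle edges
    adj <- lapply(classes, function(cl) {
      hit <- rep_edges[, 1L] == cl | rep_edges[, 2L] == cl
      setdiff(unique(as.integer(rep_edges[hit, , drop = FALSE])), cl)
    })
    names(adj) <- classes
    chosen <- integer(length(classes))
    for (ci in seq_along(classes)) {
      mem <- members[[ci]]
      if (length(mem) == 1L) { chosen[ci] <- mem; next }
      neigh_rows <- unlist(members[as.character(adj[[ci]])], use.names = FALSE)
      score <- vapply(mem, function(r) sum(dfull[r, neigh_rows]), numeric(1))
      chosen[ci] <- mem[which.min(score)] # which.min ties -> lowest index
    }
    names(chosen) <- classes
    loop_edges <- cbind(node_of_row[chosen[as.character(rep_edges[, 1L])]],
                        node_of_row[chosen[as.character(rep_edges[, 2L])]])
    loop_edges <- t(apply(loop_edges, 1L, sort))
    loops[[b]] <- loop_edges
    rows_from <- chosen[as.character(rep_edges[, 1L])]
    rows_to <- chosen[as.character(rep_edges[, 2L])]
    edges <- rbind(edges,
                   data.frame(from = pmin(loop_edges[, 1L], loop_edges[, 2L]),
                              to = pmax(loop_edges[, 1L], loop_edges[, 2L]),
                              length = dfull[cbind(rows_from, rows_to)],
                              kind = "cycle"))
  }
  edges <- unique(edges)
  # attach nodes not on any cycle by nearest-neighbour full Hamming distance
  on_cycle <- sort(unique(c(edges$from, edges$to)))
  in_graph <- on_cycle
  if (length(in_graph) == 0L) in_graph <- 1L
  duniq <- hamming_matrix(uh_full$matrix)
  for (v in nodes$id) {
    if (v %in% in_graph) next
    cand <- in_graph
    dv <- duniq[v, cand]
    u <- cand[which.min(dv)] # ties -> lowest node index (cand is sorted)
    edges <- rbind(edges, data.frame(from = min(v, u), to = max(v, u),
                                     length = duniq[v, u],
                                     kind = "attachment"))
    in_graph <- sort(c(in_graph, v))
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, loops = loops,
                 loop_count = length(loops)),
            class = "targ_graph")
}

#' @export
print.targ_graph <- function(x, ...) {
  cat(sprintf("topological ARG: %d nodes, %d edges, %d annotated loop%s\n",
              nrow(x$nodes), nrow(x$edges), x$loop_count,
              if (x$loop_count == 1L) "" else "s"))
  for (b in seq_along(x$loops)) {
    ids <- sort(unique(as.integer(x$loops[[b]])))
    cat(sprintf("  loop %d: nodes {%s}\n", b,
                paste(x$nodes$label[ids], collapse = ", ")))
  }
  invisible(x)
}

#' Edge list of a reconstructed tARG
#'
#' @param g a \code{targ_graph}.
#' @return Data frame with \code{from}, \code{to} (node labels),
#'   \code{length} and \code{kind}, suitable for writing as TSV.
#' @export
targ_edges <- function(g) {
  stopifnot(inherits(g, "targ_graph"))
  data.frame(from = g$nodes$label[g$edges$from],
             to = g$nodes$label[g$edges$to],
             length = g$edges$length,
             kind = g$edges$kind,
             stringsAsFactors = FALSE)
}

#' Convert a tARG to an igraph object
#'
#' @param g a \code{targ_graph}.
#' @return An undirected \code{igraph} graph with node attribute
#'   \code{sequence} and edge attributes \code{length} and \code{kind}.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "targ_graph"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for graph conversion")
  }
  ig <- igraph::graph_from_data_frame(targ_edges(g), directed = FALSE,
                                      vertices = data.frame(
                                        name = g$nodes$label,
                                        sequence = g$nodes$sequence))
  ig
}

#' Write a tARG as GraphML
#'
#' @param g a \code{targ_graph}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(g, path) {
  ig <- as_igraph(g)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Plot a reconstructed tARG
#'
#' Simple base-graphics layout: cycle nodes on a circle per loop, attached
#' nodes radiating from their anchor. For presentation-quality figures
#' convert with [as_igraph()] and use igraph's layouts.
#'
#' @param x a \code{targ_graph}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.targ_graph <- function(x, ...) {
  nn <- nrow(x$nodes)
  theta <- seq(0, 2 * pi, length.out = nn + 1L)[seq_len(nn)]
  xy <- cbind(cos(theta), sin(theta))
  graphics::plot(xy, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), pch = 19,
                 xlab = "", ylab = "", axes = FALSE, ...)
  graphics::segments(xy[x$edges$from, 1L], xy[x$edges$from, 2L],
                     xy[x$edges$to, 1L], xy[x$edges$to, 2L],
                     lty = ifelse(x$edges$kind == "cycle", 1L, 3L))
  graphics::text(xy[, 1L] * 1.18, xy[, 2L] * 1.18, labels = x$nodes$label,
                 cex = 0.8)
  invisible(x)
}
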