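# In-code fixtures used across the suite.

# four sequences, seven characters: two nested recombination loops
quartet_sample <- function() {
  character_matrix(rbind(c(1, 1, 1, 1, 0, 0, 1),
                         c(1, 1, 1, 1, 1, 1, 1),
                         c(0, 0, 0, 0, 1, 1, 0),
                         c(0, 0, 0, 0, 0, 0, 0)),
                   labels = c("A", "B", "C", "D"))
}

# the square sample {000, 010, 101, 111}: one visible loop, R_min = 2
square_sample <- function() {
  character_matrix(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1), c(1, 1, 1)))
}

# quartet plus the two internal nodes that disentangle the loop generators
quartet_extended <- function() {
  character_matrix(rbind(c(1, 1, 1, 1, 0, 0, 1),
                         c(1, 1, 1, 1, 1, 1, 1),
                         c(0, 0, 0, 0, 1, 1, 0),
                         c(0, 0, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 1, 0, 0, 0),
                         c(1, 1, 1, 1, 1, 1, 0)),
                   labels = c("A", "B", "C", "D", "E", "F"))
}

# a pairwise four-gamete-compatible sample (perfect phylogeny, no loops)
compatible_sample <- function() {
  character_matrix(rbind(c(0, 0, 0, 0),
                         c(1, 0, 0, 0),
                         c(1, 1, 0, 0),
                         c(0, 0, 1, 0),
                         c(0, 0, 1, 1)))
}

random_binary_matrix <- function(n, m, p = 0.5) {
  character_matrix(matrix(stats::rbinom(n * m, 1L, p), n, m))
}

# brute-force ensemble: enumerate every interval chain and take the maximum
# under the barcode ordering (oracle for the dynamic program)
brute_force_ensemble_bars <- function(x) {
  m <- ncol(x)
  best <- data.frame(birth = integer(0), death = integer(0))
  chains <- function(chain) {
    last <- chain[length(chain)]
    if (last == m) {
      bars <- do.call(rbind, lapply(seq_len(length(chain) - 1L), function(q) {
        ib <- interval_barcode(x, chain[q], chain[q + 1L])
        data.frame(birth = ib$birth, death = ib$death)
      }))
      if (is.null(bars)) bars <- data.frame(birth = integer(0), death = integer(0))
      if (tdarec:::compare_barcodes(bars, best) > 0L) best <<- bars
      return(invisible())
    }
    for (nxt in seq(last + 1L, m)) chains(c(chain, nxt))
  }
  if (m >= 2L) chains(1L)
  best
}
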