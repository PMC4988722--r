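#' Binary haplotype alignment
#'
#' Container for a sample of \code{n} haplotype sequences scored at \code{m}
#' biallelic segregating characters. Entries are 0/1, rows are sequences,
#' columns are characters. Each character carries a genomic coordinate;
#' coordinates default to the character index \code{1..m}.
#'
#' Duplicate sequences are permitted (real phased data contains them) and are
#' collapsed internally before any homology computation; duplicated labels are
#' not.
#'
#' @param data integer/numeric matrix (or coercible) with entries in
#'   \{0, 1\}; no missing values.
#' @param labels character vector of unique sequence identifiers; defaults to
#'   \code{seq1..seqn}.
#' @param positions strictly increasing numeric vector of genomic coordinates,
#'   one per character; defaults to \code{1..m}.
#' @return An object of class \code{"character_matrix"}: the 0/1 integer
#'   matrix with \code{dimnames} set from \code{labels}, and attribute
#'   \code{positions}.
#' @examples
#' m <- character_matrix(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1), c(1, 1, 1)))
#' m
#' @export
character_matrix <- function(data, labels = NULL, positions = NULL) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "integer"
  n <- nrow(data)
  m <- ncol(data)
  if (n < 1L) stop("character matrix needs at least one sequence")
  if (anyNA(data)) stop("missing values are not allowed in a character matrix")
  if (m > 0L && !all(data == 0L | data == 1L)) {
    bad <- which(data != 0L & data != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary allele at row %d, column %d", bad[1L], bad[2L]))
  }
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must equal the number of sequences")
  if (anyDuplicated(labels)) stop("sequence labels must be unique")
  if (is.null(positions)) positions <- seq_len(m)
  positions <- as.numeric(positions)
  if (length(positions) != m) stop("positions length must equal the number of characters")
  if (m > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  dimnames(data) <- list(labels, NULL)
  structure(data, positions = positions, class = c("character_matrix", "matrix"))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d sequences x %d segregating characters\n",
              nrow(x), ncol(x)))
  if (ncol(x) > 0L) {
    pos <- positions(x)
    cat(sprintf("positions: %s%s\n",
                paste(utils::head(pos, 6L), collapse = " "),
                if (length(pos) > 6L) " ..." else ""))
  }
  show <- utils::head(seq_len(nrow(x)), 10L)
  for (i in show) {
    cat(sprintf("  %-12s %s\n", rownames(x)[i],
                paste(x[i, ], collapse = "")))
  }
  if (nrow(x) > 10L) cat(sprintf("  ... (%d more)\n", nrow(x) - 10L))
  invisible(x)
}

#' Genomic coordinates of the characters
#'
#' @param x a \code{character_matrix}.
#' @return Numeric vector of length \code{ncol(x)}.
#' @export
positions <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  attr(x, "positions")
}

# subset columns, keeping positions in step
cm_restrict <- function(x, cols) {
  character_matrix(unclass(x)[, cols, drop = FALSE],
                   labels = rownames(x),
                   positions = positions(x)[cols])
}

check_interval <- function(interval, m) {
  if (length(interval) != 2L) stop("interval must be a pair (i, k)")
  i <- as.integer(interval[1L]); k <- as.integer(interval[2L])
  if (is.na(i) || is.na(k) || i < 1L || k > m || i > k) {
    stop(sprintf("invalid character interval (%s, %s) for m = %d",
                 interval[1L], interval[2L], m))
  }
  c(i, k)
}

#' Read a haplotype alignment
#'
#' Reads an n x m binary alignment in one of three dialects:
#' \describe{
#'   \item{\code{matrix}}{one haplotype per line as a run of 0/1 characters,
#'     optionally preceded by \code{"name<TAB>"}.}
#'   \item{\code{fasta}}{standard FASTA headers, sequences over \{0, 1\}.}
#'   \item{\code{ms}}{Hudson's ms output. A replicate starts at a line
#'     beginning \code{"//"}; only \code{segsites:}, \code{positions:} and the
#'     haplotype rows are parsed. \code{positions:} values become character
#'     coordinates.}
#' }
#' With \code{format = "auto"} the dialect is guessed from the first
#' non-blank line (\code{>} for FASTA, \code{ms}/\code{//}/\code{segsites:}
#' for ms, otherwise plain matrix).
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"matrix"}, \code{"fasta"},
#'   \code{"ms"}.
#' @return A \code{character_matrix}, or a list of them when an ms file
#'   contains several replicate blocks.
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, format = c("auto", "matrix", "fasta", "ms")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty input: ", path)
  if (format == "auto") {
    first <- trimws(nonblank[1L])
    format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "//") || startsWith(first, "segsites:") ||
               startsWith(first, "ms ")) "ms"
      else "matrix"
  }
  switch(format,
         matrix = parse_matrix_dialect(lines),
         fasta  = parse_fasta_dialect(lines),
         ms     = parse_ms_dialect(lines))
}

parse_binary_row <- function(s, line_no) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("0", "1"))
  if (length(bad) > 0L) {
    stop(sprintf("non-binary symbol '%s' at line %d, column %d",
                 chars[bad[1L]], line_no, bad[1L]))
  }
  as.integer(chars)
}

parse_matrix_dialect <- function(lines) {
  keep <- which(nzchar(trimws(lines)))
  labels <- character(0)
  rows <- list()
  for (idx in seq_along(keep)) {
    ln <- keep[idx]
    fields <- strsplit(trimws(lines[ln]), "\t", fixed = TRUE)[[1L]]
    if (length(fields) == 2L) {
      labels[idx] <- fields[1L]
      seqstr <- gsub("[[:space:]]", "", fields[2L])
    } else {
      labels[idx] <- NA_character_
      seqstr <- gsub("[[:space:]]", "", fields[1L])
    }
    rows[[idx]] <- parse_binary_row(seqstr, ln)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) {
    stop(sprintf("ragged rows: line %d has %d characters, expected %d",
                 keep[which(lens != lens[1L])[1L]],
                 lens[lens != lens[1L]][1L], lens[1L]))
  }
  if (all(is.na(labels))) labels <- NULL
  else labels[is.na(labels)] <- paste0("seq", which(is.na(labels)))
  character_matrix(do.call(rbind, rows), labels = labels)
}

parse_fasta_dialect <- function(lines) {
  hdr <- which(startsWith(trimws(lines), ">"))
  if (length(hdr) == 0L) stop("no FASTA headers found")
  labels <- sub("^>\\s*", "", trimws(lines[hdr]))
  labels <- sub("\\s.*$", "", labels)
  bounds <- c(hdr, length(lines) + 1L)
  rows <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!startsWith(trimws(body), ">")]
    seqstr <- gsub("[[:space:]]", "", paste(body, collapse = ""))
    if (!nzchar(seqstr)) stop("empty sequence for FASTA record ", labels[i])
    rows[[i]] <- parse_binary_row(seqstr, hdr[i] + 1L)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) stop("ragged rows: FASTA sequences differ in length")
  character_matrix(do.call(rbind, rows), labels = labels)
}

parse_ms_dialect <- function(lines) {
  trimmed <- trimws(lines)
  starts <- which(startsWith(trimmed, "//"))
  if (length(starts) == 0L) {
    # tolerate a bare block without the // separator
    if (any(startsWith(trimmed, "segsites:"))) starts <- 0L
    else stop("no ms replicate block ('//' or 'segsites:') found")
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  reps <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- trimmed[seq(starts[b] + 1L, ends[b])]
    segline <- block[startsWith(block, "segsites:")]
    if (length(segline) == 0L) stop("ms block without a 'segsites:' line")
    segsites <- as.integer(sub("^segsites:\\s*", "", segline[1L]))
    pos <- NULL
    posline <- block[startsWith(block, "positions:")]
    if (length(posline) > 0L) {
      pos <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "", posline[1L])),
                                 "\\s+")[[1L]])
    }
    if (segsites == 0L) {
      reps[[b]] <- character_matrix(matrix(integer(0), nrow = 1L, ncol = 0L))
      next
    }
    hap <- block[grepl("^[01]+$", block)]
    if (length(hap) == 0L) stop("ms block with segsites > 0 but no haplotype rows")
    rows <- lapply(seq_along(hap), function(i) parse_binary_row(hap[i], i))
    lens <- lengths(rows)
    if (any(lens != segsites)) {
      stop(sprintf("ragged rows: ms haplotype has %d characters, segsites: %d",
                   lens[lens != segsites][1L], segsites))
    }
    if (!is.null(pos) && length(pos) != segsites) {
      stop("ms 'positions:' length does not match segsites")
    }
    reps[[b]] <- character_matrix(do.call(rbind, rows), positions = pos)
  }
  if (length(reps) == 1L) reps[[1L]] else reps
}

#' Write a haplotype alignment
#'
#' Emits the plain matrix dialect (one \code{name<TAB>sequence} line per
#' haplotype) read back by [read_alignment()].
#'
#' @param x a \code{character_matrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  lines <- vapply(seq_len(nrow(x)),
                  function(i) paste0(rownames(x)[i], "\t",
                                     paste(unclass(x)[i, ], collapse = "")),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Drop non-segregating characters
#'
#' Removes columns where only one allele is present. The method's premise is
#' that every character segregates; constant columns carry no information
#' about recombination.
#'
#' @param x a \code{character_matrix}.
#' @return List with \code{matrix} (the reduced \code{character_matrix},
#'   possibly with zero columns) and \code{removed} (original indices of the
#'   dropped columns).
#' @export
drop_constant_characters <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  m <- ncol(x)
  if (m == 0L) return(list(matrix = x, removed = integer(0)))
  counts <- colSums(unclass(x))
  keep <- which(counts > 0L & counts < nrow(x))
  list(matrix = cm_restrict(x, keep), removed = setdiff(seq_len(m), keep))
}

#' Collapse duplicate haplotypes on a character interval
#'
#' Restricts the alignment to characters \code{interval[1]..interval[2]}
#' (1-based, inclusive; intersected with \code{retained} if given) and
#' de-duplicates the rows. Distance-zero duplicates are topologically
#' redundant in a Rips filtration, so every homology computation works on the
#' reduced set.
#'
#' @param x a \code{character_matrix}.
#' @param interval integer pair \code{(i, k)}; default spans all characters.
#' @param retained optional integer vector of character indices to intersect
#'   with the interval (used by the compatible-character filter).
#' @return List with \code{matrix} (unique rows restricted to the chosen
#'   characters), \code{multiplicity} (count of input rows per unique row;
#'   sums to \code{nrow(x)}), \code{row_map} (for each input row, the index
#'   of its unique representative) and \code{columns} (original indices of
#'   the characters used).
#' @export
unique_haplotypes <- function(x, interval = NULL, retained = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  m <- ncol(x)
  if (is.null(interval)) interval <- c(1L, max(m, 1L))
  if (m == 0L) {
    return(list(matrix = x, multiplicity = nrow(x),
                row_map = rep(1L, nrow(x)), columns = integer(0)))
  }
  ik <- check_interval(interval, m)
  cols <- seq(ik[1L], ik[2L])
  if (!is.null(retained)) cols <- intersect(cols, as.integer(retained))
  sub <- unclass(x)[, cols, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "")
  first <- !duplicated(key)
  uniq_keys <- key[first]
  row_map <- match(key, uniq_keys)
  red <- character_matrix(sub[first, , drop = FALSE],
                          labels = rownames(x)[first],
                          positions = positions(x)[cols])
  list(matrix = red,
       multiplicity = as.integer(tabulate(row_map, nbins = length(uniq_keys))),
       row_map = row_map,
       columns = as.integer(cols))
}
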