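#' Parse ms-family coalescent output
#'
#' Reads the plain-text output of Hudson's ms and its descendants (msHOT,
#' msms): a command line, seed line(s), then replicates delimited by `//`,
#' each carrying `segsites: <k>`, `positions: <p1> ... <pk>` and one 0/1
#' haplotype string per sampled chromosome. Header chatter between the
#' load-bearing lines (seeds, blank lines, msms `prob:`/`time:` lines) is
#' skipped permissively, since the three programs differ in what they print.
#'
#' `segsites: 0` blocks are legal and yield an empty matrix; its row count is
#' taken from the sample-size token of the command line when one is present.
#' When the command line carries a sample size, a replicate whose row count
#' disagrees raises a warning (not an error).
#'
#' @param stream path to an ms output file, or a character vector of its
#'   lines.
#' @return a [replicate_set()] of [haplotype_matrix()] objects with
#'   fractional positions.
#' @examples
#' txt <- c("ms 4 1 -t 5", "123 456 789", "", "//", "segsites: 3",
#'          "positions: 0.1 0.5 0.9", "010", "110", "001", "111")
#' reps <- parse_ms(txt)
#' reps$replicates[[1]]$alleles
#' @export
parse_ms <- function(stream) {
  lines <- read_input_lines(stream)
  if (length(lines) == 0L) stop("empty ms input")
  src <- lines[[1L]]
  nsam <- ms_sample_size(src)

  starts <- which(startsWith(trimws(lines), "//"))
  if (length(starts) == 0L) stop("no replicate delimiter '//' found in ms input")
  ends <- c(starts[-1L] - 1L, length(lines))

  reps <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- seq.int(starts[b] + 1L, length.out = max(0L, ends[b] - starts[b]))
    reps[[b]] <- parse_ms_block(lines, block, nsam, unit = "fraction")
    n_rows <- nrow(reps[[b]]$alleles)
    if (!is.na(nsam) && ncol(reps[[b]]$alleles) > 0L && n_rows != nsam) {
      warning(sprintf(
        "replicate %d has %d haplotype row(s) but the command line's sample-size token is %d",
        b, n_rows, nsam))
    }
  }
  replicate_set(reps, source_command = src)
}

# Parse one replicate block. `block` holds the line numbers (into `lines`)
# after the `//` delimiter; line numbers are reported in errors.
parse_ms_block <- function(lines, block, nsam, unit) {
  seg_at <- block[grepl("^\\s*segsites:", lines[block])]
  if (length(seg_at) == 0L) {
    stop(sprintf("replicate block starting near line %d lacks a 'segsites:' line",
                 if (length(block)) block[1L] else length(lines)))
  }
  seg_at <- seg_at[1L]
  k <- suppressWarnings(as.integer(sub("^\\s*segsites:\\s*", "", lines[seg_at])))
  if (is.na(k) || k < 0L) {
    stop(sprintf("line %d: malformed segsites count", seg_at))
  }

  if (k == 0L) {
    n_rows <- if (is.na(nsam)) 0L else nsam
    return(haplotype_matrix(matrix(0L, n_rows, 0L), numeric(0),
                            position_unit = unit))
  }

  pos_at <- block[block > seg_at & grepl("^\\s*positions:", lines[block])]
  if (length(pos_at) == 0L) {
    stop(sprintf("line %d: 'segsites: %d' without a 'positions:' line", seg_at, k))
  }
  pos_at <- pos_at[1L]
  positions <- suppressWarnings(as.numeric(
    strsplit(trimws(sub("^\\s*positions:\\s*", "", lines[pos_at])), "\\s+")[[1L]]
  ))
  if (anyNA(positions) || length(positions) != k) {
    stop(sprintf("line %d: expected %d numeric positions, found %d",
                 pos_at, k, length(positions)))
  }

  rows <- collect_haplotype_rows(lines, block[block > pos_at], k)
  resorted <- handle_unsorted(rows$mat, positions)
  haplotype_matrix(resorted$mat, resorted$positions, position_unit = unit)
}

# Gather consecutive 0/1 haplotype rows, validating length and alphabet.
# Digit-bearing lines that are not pure 0/1 are parse errors (bad allele
# characters); anything else is treated as header chatter and skipped.
collect_haplotype_rows <- function(lines, candidates, k) {
  rows <- list()
  for (ln in candidates) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    if (grepl("^[01]+$", txt)) {
      if (nchar(txt) != k) {
        stop(sprintf("line %d: haplotype row has %d characters, expected %d",
                     ln, nchar(txt), k))
      }
      rows[[length(rows) + 1L]] <- as.integer(strsplit(txt, "")[[1L]])
    } else if (grepl("^[0-9]+$", txt)) {
      stop(sprintf("line %d: haplotype row contains characters other than 0/1", ln))
    }
    # non-numeric chatter: skip
  }
  if (length(rows) == 0L) {
    stop("replicate block contains no haplotype rows")
  }
  list(mat = do.call(rbind, rows))
}

handle_unsorted <- function(mat, positions) {
  if (is.unsorted(positions)) {
    warning("site positions are not non-decreasing; columns re-sorted by position")
    o <- order(positions)
    mat <- mat[, o, drop = FALSE]
    positions <- positions[o]
  }
  list(mat = mat, positions = positions)
}

# Sample-size token of an ms-style command line ("ms nsam nreps ..."); NA
# when the line does not carry one (msms flag syntax, generated data).
ms_sample_size <- function(cmd) {
  toks <- strsplit(trimws(cmd), "\\s+")[[1L]]
  if (length(toks) >= 2L && grepl("^[0-9]+$", toks[2L])) {
    as.integer(toks[2L])
  } else {
    NA_integer_
  }
}

read_input_lines <- function(stream) {
  if (is.character(stream) && length(stream) == 1L && file.exists(stream)) {
    readLines(stream, warn = FALSE)
  } else if (is.character(stream)) {
    stream
  } else {
    stop("`stream` must be a file path or a character vector of lines")
  }
}

#' Parse GENOME-style haplotype output
#'
#' Reads a base-pair-position haplotype dialect: optional `#` comment lines,
#' a `positions:` header of integer base-pair coordinates, then one 0/1 row
#' per chromosome (whitespace inside rows is ignored). Multiple replicates
#' are delimited by `//` lines, as in ms. Non-monotone positions are
#' re-sorted with a warning rather than rejected, to tolerate third-party
#' output; a header with no haplotype rows is an error.
#'
#' @inheritParams parse_ms
#' @return a [replicate_set()] with positions in base pairs.
#' @examples
#' txt <- c("positions: 100 250", "01", "11")
#' parse_genome(txt)$replicates[[1]]$positions
#' @export
parse_genome <- function(stream) {
  lines <- read_input_lines(stream)
  if (length(lines) == 0L) stop("empty GENOME-style input")
  src <- lines[[1L]]

  body <- which(!grepl("^\\s*#", lines))
  starts <- body[startsWith(trimws(lines[body]), "//")]
  if (length(starts) == 0L) {
    blocks <- list(body)
  } else {
    bounds <- c(starts, length(lines) + 1L)
    blocks <- lapply(seq_along(starts), function(b) {
      body[body > starts[b] & body < bounds[b + 1L]]
    })
  }

  reps <- lapply(blocks, function(block) parse_genome_block(lines, block))
  replicate_set(reps, source_command = src)
}

parse_genome_block <- function(lines, block) {
  pos_at <- block[grepl("^\\s*positions:", lines[block], ignore.case = TRUE)]
  if (length(pos_at) == 0L) {
    stop("GENOME-style block lacks a 'positions:' header line")
  }
  pos_at <- pos_at[1L]
  positions <- suppressWarnings(as.numeric(
    strsplit(trimws(sub("^\\s*positions:\\s*", "", lines[pos_at],
                        ignore.case = TRUE)), "\\s+")[[1L]]
  ))
  if (length(positions) == 0L || anyNA(positions)) {
    stop(sprintf("line %d: malformed base-pair positions", pos_at))
  }

  cand <- block[block > pos_at]
  # rows may contain internal whitespace; strip it before validation
  squeezed <- lines
  squeezed[cand] <- gsub("\\s+", "", lines[cand])
  rows <- tryCatch(
    collect_haplotype_rows(squeezed, cand, length(positions)),
    error = function(e) {
      if (grepl("no haplotype rows", conditionMessage(e))) {
        stop("GENOME-style block has a position header but no haplotype rows")
      }
      stop(e)
    }
  )
  resorted <- handle_unsorted(rows$mat, positions)
  haplotype_matrix(resorted$mat, resorted$positions, position_unit = "bp")
}

#' Generate a synthetic haplotype fixture
#'
#' Draws a haplotype matrix directly from per-site derived-allele
#' probabilities: column \eqn{j} is i.i.d. Bernoulli(`freq_spectrum[j]`)
#' across chromosomes, and positions are sorted uniform draws on \[0, 1\].
#' Sites are mutually independent (no linkage disequilibrium), which is the
#' intended test-bed behaviour: it stands in for a coalescent simulator when
#' none is available, not for real genealogical structure.
#'
#' @param n_chromosomes positive integer number of rows.
#' @param n_sites number of segregating sites (0 gives an empty matrix).
#' @param freq_spectrum per-site target derived-allele probability, strictly
#'   inside (0, 1); a scalar is recycled. Default: independent uniform draws
#'   on \[0.2, 0.8\] (common variants, the regime of the bundled power
#'   analyses).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return a [haplotype_matrix()] with fractional positions.
#' @examples
#' m <- generate_fixture(100, 10, freq_spectrum = 0.4, seed = 1)
#' colMeans(m$alleles)
#' @export
generate_fixture <- function(n_chromosomes, n_sites, freq_spectrum = NULL,
                             seed) {
  stopifnot(n_chromosomes >= 1, n_sites >= 0)
  n_chromosomes <- as.integer(n_chromosomes)
  n_sites <- as.integer(n_sites)
  if (n_sites == 0L) {
    return(haplotype_matrix(matrix(0L, n_chromosomes, 0L), numeric(0)))
  }
  with_seed(seed, {
    p <- if (is.null(freq_spectrum)) {
      stats::runif(n_sites, 0.2, 0.8)
    } else {
      rep_len(as.numeric(freq_spectrum), n_sites)
    }
    if (any(p <= 0 | p >= 1)) {
      stop("freq_spectrum probabilities must lie strictly inside (0, 1)")
    }
    positions <- sort(stats::runif(n_sites))
    alleles <- matrix(
      stats::rbinom(n_chromosomes * n_sites, 1L, rep(p, each = n_chromosomes)),
      nrow = n_chromosomes, ncol = n_sites
    )
    haplotype_matrix(alleles, positions)
  })
}

#' Serialize replicates back to ms-format text
#'
#' Inverse of [parse_ms()]: `parse_ms(to_ms_text(r))` reproduces `r` exactly
#' in alleles and to printed precision (6 decimals) in positions. Replicates
#' with base-pair positions are converted to locus fractions first, which
#' requires `locus_length_bp` to be set on each matrix.
#'
#' @param rep a [replicate_set()] or a single [haplotype_matrix()].
#' @return a character vector of ms-format lines.
#' @export
to_ms_text <- function(rep) {
  if (inherits(rep, "haplotype_matrix")) {
    rep <- replicate_set(list(rep), source_command = "coalpheno export")
  }
  stopifnot(inherits(rep, "replicate_set"))
  out <- c(if (nzchar(rep$source_command)) rep$source_command else "coalpheno export",
           "0 0 0")
  for (m in rep$replicates) {
    pos <- m$positions
    if (m$position_unit == "bp") {
      if (is.null(m$locus_length_bp)) {
        stop("cannot write bp positions as ms fractions: locus_length_bp not set")
      }
      pos <- pos / m$locus_length_bp
    }
    out <- c(out, "", "//", sprintf("segsites: %d", ncol(m$alleles)))
    if (ncol(m$alleles) > 0L) {
      out <- c(out,
               paste("positions:", paste(sprintf("%.6f", pos), collapse = " ")),
               apply(m$alleles, 1L, paste, collapse = ""))
    }
  }
  out
}

#' Convert fractional site positions to integer base pairs
#'
#' Maps fractions of the locus to `round(f * locus_length_bp)` with ties
#' rounded half up. Collisions (two sites mapping to the same base pair,
#' inevitable on short loci) are resolved by bumping the later site one base
#' pair to the right, with a warning, so that map files carry strictly
#' increasing coordinates.
#'
#' @param positions numeric fractions in \[0, 1\], non-decreasing.
#' @param locus_length_bp positive integer locus length.
#' @return strictly increasing integer base-pair positions.
#' @export
positions_to_bp <- function(positions, locus_length_bp) {
  stopifnot(locus_length_bp >= 1)
  if (length(positions) == 0L) return(integer(0))
  if (any(positions < 0 | positions > 1)) {
    stop("fractional positions must lie in [0, 1]")
  }
  bp <- floor(positions * as.numeric(locus_length_bp) + 0.5)  # half up
  bumped <- FALSE
  if (length(bp) > 1L) {
    for (i in 2:length(bp)) {
      if (bp[i] <= bp[i - 1L]) {
        bp[i] <- bp[i - 1L] + 1
        bumped <- TRUE
      }
    }
  }
  if (bumped) {
    warning("position collisions after bp conversion; later sites bumped +1 bp")
  }
  as.integer(bp)
}
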