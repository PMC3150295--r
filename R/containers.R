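#' Haplotype matrix
#'
#' The central container for coalescent output: a binary matrix with one row
#' per sampled chromosome and one column per segregating site (0 = ancestral
#' allele, 1 = derived allele), together with per-site positions. Positions
#' are either fractions of the simulated locus in \[0, 1\] (the ms family) or
#' integer base pairs.
#'
#' @param alleles integer/numeric matrix of 0s and 1s, chromosomes in rows,
#'   segregating sites in columns.
#' @param positions numeric vector of per-site coordinates, non-decreasing,
#'   one per column.
#' @param position_unit `"fraction"` (of the locus, in \[0, 1\]) or `"bp"`.
#' @param locus_length_bp optional positive integer length of the simulated
#'   locus, used to convert fractional positions to base pairs.
#' @return an object of class `haplotype_matrix` with fields `alleles`,
#'   `positions`, `position_unit`, `locus_length_bp`.
#' @examples
#' m <- haplotype_matrix(rbind(c(0, 1), c(1, 1)), positions = c(0.2, 0.7))
#' allele_frequency(m, 2)
#' @export
haplotype_matrix <- function(alleles, positions,
                             position_unit = c("fraction", "bp"),
                             locus_length_bp = NULL) {
  position_unit <- match.arg(position_unit)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) > 0L && nrow(alleles) < 1L) {
    stop("a haplotype matrix with sites must have at least one chromosome")
  }
  if (length(alleles) > 0L && !all(alleles %in% c(0L, 1L))) {
    stop("allele values must be 0 (ancestral) or 1 (derived)")
  }
  positions <- as.numeric(positions)
  if (length(positions) != ncol(alleles)) {
    stop("length(positions) must equal the number of sites (columns)")
  }
  if (is.unsorted(positions)) {
    stop("positions must be non-decreasing")
  }
  if (position_unit == "fraction" && length(positions) &&
      (min(positions) < 0 || max(positions) > 1)) {
    stop("fractional positions must lie in [0, 1]")
  }
  if (!is.null(locus_length_bp)) {
    stopifnot(length(locus_length_bp) == 1L, locus_length_bp >= 1)
    locus_length_bp <- as.integer(locus_length_bp)
  }
  structure(
    list(alleles = alleles, positions = positions,
         position_unit = position_unit, locus_length_bp = locus_length_bp),
    class = "haplotype_matrix"
  )
}

#' Diploid genotype matrix
#'
#' Diploid genotypes coded -1 (homozygous ancestral), 0 (heterozygous),
#' +1 (homozygous derived), one row per individual. Usually produced by
#' [pair_diploids()] from an even number of chromosomes.
#'
#' @param codes matrix over \{-1, 0, +1\}, individuals in rows, sites in
#'   columns.
#' @inheritParams haplotype_matrix
#' @return an object of class `genotype_matrix`.
#' @seealso [pair_diploids()]
#' @export
genotype_matrix <- function(codes, positions,
                            position_unit = c("fraction", "bp"),
                            locus_length_bp = NULL) {
  position_unit <- match.arg(position_unit)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (length(codes) > 0L && !all(codes %in% c(-1L, 0L, 1L))) {
    stop("genotype codes must be -1, 0 or +1")
  }
  positions <- as.numeric(positions)
  if (length(positions) != ncol(codes)) {
    stop("length(positions) must equal the number of sites (columns)")
  }
  if (is.unsorted(positions)) stop("positions must be non-decreasing")
  if (!is.null(locus_length_bp)) {
    stopifnot(length(locus_length_bp) == 1L, locus_length_bp >= 1)
    locus_length_bp <- as.integer(locus_length_bp)
  }
  structure(
    list(codes = codes, positions = positions,
         position_unit = position_unit, locus_length_bp = locus_length_bp),
    class = "genotype_matrix"
  )
}

#' Ordered set of simulation replicates
#'
#' Wraps the haplotype matrices of one simulator run (ms emits several
#' replicates per invocation, delimited by `//`). All replicates share one
#' position unit.
#'
#' @param replicates list of [haplotype_matrix()] objects.
#' @param source_command verbatim first line of the parsed file, kept for
#'   provenance (or a descriptive string for generated data).
#' @return an object of class `replicate_set`.
#' @export
replicate_set <- function(replicates, source_command = "") {
  stopifnot(is.list(replicates),
            all(vapply(replicates, inherits, logical(1), "haplotype_matrix")))
  units <- unique(vapply(replicates, `[[`, character(1), "position_unit"))
  if (length(units) > 1L) {
    stop("all replicates in a set must share one position unit")
  }
  structure(list(replicates = replicates,
                 source_command = as.character(source_command)[1L]),
            class = "replicate_set")
}

#' Phenotype vector
#'
#' Per-individual trait values: real numbers for a quantitative trait or
#' 0/1 affection status for a case/control trait. Quantitative vectors
#' produced by [generate_quantitative()] carry the genetic values (phenotype
#' minus environmental noise) as attribute `"genetic"`.
#'
#' @param values numeric vector, one entry per individual.
#' @param kind `"quantitative"` or `"case_control"`.
#' @return an object of class `phenotype_vector` (a numeric vector with a
#'   `kind` attribute).
#' @export
phenotype_vector <- function(values, kind = c("quantitative", "case_control")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("phenotype values must be finite")
  if (kind == "case_control" && length(values) &&
      !all(values %in% c(0, 1))) {
    stop("case/control phenotypes must be 0 (control) or 1 (case)")
  }
  structure(values, kind = kind, class = "phenotype_vector")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d chromosomes x %d sites (positions in %s)\n",
              nrow(x$alleles), ncol(x$alleles), x$position_unit))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d diploid individuals x %d sites (positions in %s)\n",
              nrow(x$codes), ncol(x$codes), x$position_unit))
  invisible(x)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d replicate(s); source: %s\n",
              length(x$replicates), x$source_command))
  invisible(x)
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("<phenotype_vector> %s, n = %d\n", attr(x, "kind"), length(x)))
  print(utils::head(as.numeric(x)))
  invisible(x)
}

# ---- internal shared accessors -------------------------------------------

# Number of sites (columns) of either matrix kind.
site_count <- function(m) ncol(geno_matrix(m))

# Number of statistical units: chromosomes (haploid) or individuals (diploid).
unit_count <- function(m) nrow(geno_matrix(m))

is_diploid <- function(m) inherits(m, "genotype_matrix")

# The underlying numeric matrix (alleles or codes).
geno_matrix <- function(m) {
  if (is_diploid(m)) m$codes else m$alleles
}

# Rebuild the same container around a new matrix / positions.
rebuild_geno <- function(m, mat, positions) {
  if (is_diploid(m)) {
    genotype_matrix(mat, positions, m$position_unit, m$locus_length_bp)
  } else {
    haplotype_matrix(mat, positions, m$position_unit, m$locus_length_bp)
  }
}

check_site_index <- function(m, site) {
  k <- site_count(m)
  if (any(site < 1L | site > k)) {
    stop(sprintf("site index out of range [1, %d]", k))
  }
  as.integer(site)
}
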