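#' Four-gamete compatibility of two sites
#'
#' Two biallelic sites are compatible with a single genealogical tree without
#' recombination iff at most three of the four possible two-site gametes
#' (00, 01, 10, 11) are observed across the sampled chromosomes.
#'
#' @param m a [haplotype_matrix()].
#' @param site_a,site_b 1-based column indices.
#' @return `TRUE` iff fewer than four distinct gametes are observed.
#' @examples
#' m <- haplotype_matrix(rbind(c(0, 0), c(0, 1), c(1, 0)),
#'                       positions = c(0.1, 0.9))
#' four_gamete_compatible(m, 1, 2)
#' @export
four_gamete_compatible <- function(m, site_a, site_b) {
  stopifnot(inherits(m, "haplotype_matrix"))
  site_a <- check_site_index(m, site_a)
  site_b <- check_site_index(m, site_b)
  gametes <- m$alleles[, site_a] * 2L + m$alleles[, site_b]
  length(unique(gametes)) < 4L
}

#' Partition sites into haploblocks by the four-gamete test
#'
#' Scans sites left to right, extending the current block while the
#' candidate site is four-gamete compatible with every site already in the
#' block, and starting a new block at the first incompatibility. The result
#' is a deterministic, order-stable tiling of all sites into maximal
#' recombination-free runs; within every returned block, all site pairs pass
#' the four-gamete test. Used to constrain a pair of causal variants to a
#' single block, emulating a causal haplotype or allelic heterogeneity
#' within one gene.
#'
#' @param m a [haplotype_matrix()].
#' @return a data.frame with integer columns `start_site`, `end_site`
#'   (1-based, inclusive); the rows tile `[1, n_sites]` without gap or
#'   overlap. Zero rows for an empty matrix.
#' @examples
#' m <- generate_fixture(20, 12, seed = 7)
#' find_haploblocks(m)
#' @export
find_haploblocks <- function(m) {
  stopifnot(inherits(m, "haplotype_matrix"))
  k <- ncol(m$alleles)
  if (k == 0L) {
    return(data.frame(start_site = integer(0), end_site = integer(0)))
  }
  starts <- 1L
  block_start <- 1L
  for (j in seq_len(k)[-1L]) {
    ok <- TRUE
    for (s in block_start:(j - 1L)) {
      if (!four_gamete_compatible(m, s, j)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) {
      block_start <- j
      starts <- c(starts, j)
    }
  }
  data.frame(start_site = starts, end_site = c(starts[-1L] - 1L, k))
}

# Block index (into find_haploblocks(m) rows) of each site.
site_block_ids <- function(blocks, n_sites) {
  rep.int(seq_len(nrow(blocks)), blocks$end_site - blocks$start_site + 1L)
}
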