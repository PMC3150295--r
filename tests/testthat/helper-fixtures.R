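# Shared fixtures and independent oracles for the suite.

# ms output for the canonical 4-chromosome, two-replicate example.
ms_example_lines <- function() {
  c("ms 4 2 -t 5.0",
    "27473 20949 21476",
    "",
    "//",
    "segsites: 3",
    "positions: 0.1 0.5 0.9",
    "010",
    "110",
    "001",
    "111",
    "",
    "//",
    "segsites: 2",
    "positions: 0.25 0.75",
    "00",
    "01",
    "11",
    "10")
}

# 4-site matrix where sites 1-2 form one haploblock and 3-4 another:
# columns 1 and 2 are identical (compatible), column 3 shows all four
# gametes against them, and column 4 equals column 3.
blocky_matrix <- function() {
  haplotype_matrix(
    rbind(c(0, 0, 0, 0),
          c(1, 1, 0, 0),
          c(1, 1, 1, 1),
          c(0, 0, 1, 1)),
    positions = c(0.1, 0.3, 0.6, 0.9)
  )
}

# Independent haploblock oracle: precompute the full pairwise four-gamete
# compatibility matrix by direct gamete enumeration, then partition sites by
# the same greedy all-pairs rule expressed against that matrix.
oracle_compat_matrix <- function(A) {
  k <- ncol(A)
  C <- matrix(TRUE, k, k)
  if (k < 2L) return(C)
  for (i in 1:(k - 1L)) {
    for (j in (i + 1L):k) {
      seen <- unique(paste0(A[, i], A[, j]))
      C[i, j] <- C[j, i] <- length(seen) < 4L
    }
  }
  C
}

oracle_blocks <- function(A) {
  k <- ncol(A)
  if (k == 0L) return(data.frame(start_site = integer(0), end_site = integer(0)))
  C <- oracle_compat_matrix(A)
  starts <- 1L
  cur <- 1L
  for (j in seq_len(k)[-1L]) {
    if (!all(C[cur:(j - 1L), j])) {
      cur <- j
      starts <- c(starts, j)
    }
  }
  data.frame(start_site = starts, end_site = c(starts[-1L] - 1L, k))
}

# Haplotype matrix with hand-set derived-allele counts per column
# (n chromosomes; counts[j] ones in column j, positions equally spaced).
counted_matrix <- function(n, counts) {
  A <- vapply(counts, function(ct) c(rep(1L, ct), rep(0L, n - ct)),
              integer(n))
  haplotype_matrix(A, positions = seq(0.05, 0.95, length.out = length(counts)))
}

# Memoised scaled-down rerun of the additive two-QTN study (model with two
# effects of 0.05): 50 replicates of 20,000 haploids at 200 sites.
.acceptance_cache <- new.env(parent = emptyenv())

additive_study <- function() {
  if (!is.null(.acceptance_cache$additive)) return(.acceptance_cache$additive)
  res <- variance_study(effects = c(0.05, 0.05), epistatic_effect = 0,
                        n_reps = 50, seed = 20260929)
  .acceptance_cache$additive <- res
  res
}

epistatic_study <- function() {
  if (!is.null(.acceptance_cache$epistatic)) return(.acceptance_cache$epistatic)
  res <- variance_study(effects = c(0.01, 0.01), epistatic_effect = 0.08,
                        n_reps = 50, seed = 20260930)
  .acceptance_cache$epistatic <- res
  res
}

# One row per replicate: total R2, the two QTN incremental R2s, the
# epistatic incremental R2 and fictive-allele frequency (NA when absent).
variance_study <- function(effects, epistatic_effect, n_reps, seed,
                           n_chromosomes = 20000, n_sites = 200) {
  rows <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, r)
    m <- generate_fixture(n_chromosomes, n_sites, seed = derive_seed(rep_seed, 1))
    q <- select_qtns(m, length(effects), effects, seed = derive_seed(rep_seed, 2))
    model <- quant_trait_model(q, epistatic_effect = epistatic_effect)
    y <- generate_quantitative(m, model, seed = derive_seed(rep_seed, 3))
    rv <- recovered_variance(m, model, y)
    data.frame(total_r2 = rv$total_r2,
               qtn1 = rv$partial_r2[[1]],
               qtn2 = rv$partial_r2[[2]],
               epistatic = if (epistatic_effect > 0) rv$partial_r2[["epistatic"]] else NA_real_,
               epistatic_freq = rv$epistatic_freq)
  })
  do.call(rbind, rows)
}
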