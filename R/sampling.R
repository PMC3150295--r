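#' Subsampling / ascertainment plan
#'
#' Describes how the full simulated population is reduced to a study sample:
#' an optional cap on markers and on individuals, optional removal of the
#' causal marker(s) (frequently the causal mutation itself is not
#' genotyped), and, for case/control traits, a minimum number of cases plus
#' an optional number of controls to ascertain.
#'
#' @param n_markers optional positive integer number of markers to retain.
#' @param n_individuals optional positive integer number of individuals.
#' @param remove_causal logical; delete the causal columns before marker
#'   sampling.
#' @param min_cases optional positive integer number of cases to ascertain.
#' @param n_controls optional positive integer number of controls; when
#'   unset, all remaining non-case individuals are kept as controls.
#' @param seed integer seed for the sampling draws.
#' @return an object of class `sample_plan`.
#' @export
sample_plan <- function(n_markers = NULL, n_individuals = NULL,
                        remove_causal = FALSE, min_cases = NULL,
                        n_controls = NULL, seed = 1L) {
  for (v in list(n_markers, n_individuals, min_cases, n_controls)) {
    if (!is.null(v)) stopifnot(length(v) == 1L, v >= 1)
  }
  structure(list(n_markers = n_markers, n_individuals = n_individuals,
                 remove_causal = isTRUE(remove_causal),
                 min_cases = min_cases, n_controls = n_controls,
                 seed = seed),
            class = "sample_plan")
}

#' Pair chromosomes into diploid individuals
#'
#' Coalescent output is haploid; diploid trait models require genotypes.
#' Individual \eqn{i} is formed from chromosomes \eqn{2i-1} and \eqn{2i}
#' (file order), which under coalescent exchangeability amounts to random
#' union of gametes (Hardy-Weinberg proportions). Codes are
#' `allele1 + allele2 - 1`, i.e. -1/0/+1.
#'
#' @param m a [haplotype_matrix()] with an even number of rows.
#' @return a [genotype_matrix()] with half as many rows.
#' @export
pair_diploids <- function(m) {
  stopifnot(inherits(m, "haplotype_matrix"))
  n <- nrow(m$alleles)
  if (n %% 2L != 0L) {
    stop(sprintf("cannot pair %d chromosomes into diploids: odd row count", n))
  }
  odd <- seq(1L, n, by = 2L)
  codes <- m$alleles[odd, , drop = FALSE] + m$alleles[odd + 1L, , drop = FALSE] - 1L
  genotype_matrix(codes, m$positions, m$position_unit, m$locus_length_bp)
}

#' Ascertain cases and controls from a simulated population
#'
#' Mirrors the sampling of real case/control studies: from a (large)
#' simulated population, draw `min_cases` affected individuals uniformly
#' without replacement, plus `n_controls` unaffected ones (all remaining
#' controls when `n_controls` is unset, capped by `n_individuals` when that
#' is set). When fewer cases exist than requested, the error reports the
#' available count — the remedy is to simulate a larger population.
#'
#' @param statuses a [phenotype_vector()] of kind `"case_control"`.
#' @param plan a [sample_plan()] with `min_cases` set.
#' @return sorted integer indices of the selected individuals.
#' @export
ascertain_case_control <- function(statuses, plan) {
  stopifnot(inherits(statuses, "phenotype_vector"),
            attr(statuses, "kind") == "case_control",
            inherits(plan, "sample_plan"))
  if (is.null(plan$min_cases)) stop("plan$min_cases must be set for ascertainment")
  cases <- which(as.numeric(statuses) == 1)
  controls <- which(as.numeric(statuses) == 0)
  if (length(cases) < plan$min_cases) {
    stop(sprintf(paste("only %d case(s) available but min_cases = %d;",
                       "simulate a larger population"),
                 length(cases), plan$min_cases))
  }
  n_ctrl <- plan$n_controls
  if (is.null(n_ctrl) && !is.null(plan$n_individuals)) {
    n_ctrl <- max(0L, plan$n_individuals - plan$min_cases)
  }
  if (!is.null(n_ctrl) && length(controls) < n_ctrl) {
    stop(sprintf(paste("only %d control(s) available but %d requested;",
                       "simulate a larger population"),
                 length(controls), n_ctrl))
  }
  with_seed(derive_seed(plan$seed, 3), {
    picked_cases <- if (length(cases) == plan$min_cases) cases else {
      cases[sample.int(length(cases), plan$min_cases)]
    }
    picked_controls <- if (is.null(n_ctrl)) controls else if (n_ctrl == 0L) {
      integer(0)
    } else controls[sample.int(length(controls), n_ctrl)]
    sort(c(picked_cases, picked_controls))
  })
}

#' Subsample markers and individuals
#'
#' Reduces a phenotyped population to a study sample in a fixed order:
#' causal columns are deleted first when `plan$remove_causal` (the causal
#' mutation is frequently not genotyped), then markers are drawn uniformly
#' without replacement and re-sorted by position, then individuals are drawn
#' uniformly (or taken from `individual_indices` when ascertainment already
#' chose them), preserving the genotype-phenotype pairing throughout.
#'
#' @param m a [haplotype_matrix()] or [genotype_matrix()].
#' @param phen a [phenotype_vector()] aligned with the rows of `m`.
#' @param qtns data.frame of causal sites (as from [select_qtns()]), or
#'   `NULL`.
#' @param plan a [sample_plan()].
#' @param individual_indices optional pre-chosen row indices (e.g. from
#'   [ascertain_case_control()]); overrides `plan$n_individuals`.
#' @return a list with elements `genotypes` (same class as `m`),
#'   `phenotypes`, and `qtn_sites` — the column indices of retained causal
#'   sites in the subsampled matrix (empty when removed or not retained by
#'   the marker draw).
#' @export
subsample <- function(m, phen, qtns = NULL, plan = sample_plan(),
                      individual_indices = NULL) {
  stopifnot(inherits(plan, "sample_plan"))
  mat <- geno_matrix(m)
  if (length(phen) != nrow(mat)) {
    stop("phenotype length must equal the number of rows of the matrix")
  }
  qtn_sites <- if (is.null(qtns)) integer(0) else as.integer(qtns$site)

  keep_cols <- seq_len(ncol(mat))
  if (plan$remove_causal && length(qtn_sites)) {
    keep_cols <- setdiff(keep_cols, qtn_sites)
  }
  if (!is.null(plan$n_markers)) {
    if (plan$n_markers > length(keep_cols)) {
      stop(sprintf("n_markers = %d exceeds the %d available marker(s)",
                   plan$n_markers, length(keep_cols)))
    }
    keep_cols <- with_seed(derive_seed(plan$seed, 4),
                           keep_cols[sample.int(length(keep_cols), plan$n_markers)])
  }
  keep_cols <- keep_cols[order(m$positions[keep_cols], keep_cols)]

  if (!is.null(individual_indices)) {
    keep_rows <- sort(as.integer(individual_indices))
    if (any(keep_rows < 1L | keep_rows > nrow(mat))) {
      stop("individual_indices out of range")
    }
  } else if (!is.null(plan$n_individuals)) {
    if (plan$n_individuals > nrow(mat)) {
      stop(sprintf("n_individuals = %d exceeds the %d available individual(s)",
                   plan$n_individuals, nrow(mat)))
    }
    keep_rows <- with_seed(derive_seed(plan$seed, 5),
                           sort(sample.int(nrow(mat), plan$n_individuals)))
  } else {
    keep_rows <- seq_len(nrow(mat))
  }

  out_m <- rebuild_geno(m, mat[keep_rows, keep_cols, drop = FALSE],
                        m$positions[keep_cols])
  out_phen <- phenotype_vector(as.numeric(phen)[keep_rows], attr(phen, "kind"))
  list(genotypes = out_m,
       phenotypes = out_phen,
       qtn_sites = match(intersect(qtn_sites, keep_cols), keep_cols))
}
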