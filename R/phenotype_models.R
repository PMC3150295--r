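#' Derived-allele frequency at a site
#'
#' @param m a [haplotype_matrix()] or [genotype_matrix()].
#' @param site 1-based column index (vectorized).
#' @return frequency of the derived allele among sampled chromosomes, in
#'   \[0, 1\]. For diploids this counts alleles, not carriers:
#'   `(codes + 1) / 2` averaged over individuals.
#' @examples
#' m <- haplotype_matrix(cbind(c(0, 1, 1, 0)), positions = 0.5)
#' allele_frequency(m, 1)
#' @export
allele_frequency <- function(m, site) {
  site <- check_site_index(m, site)
  if (is_diploid(m)) {
    colMeans((m$codes[, site, drop = FALSE] + 1L) / 2)
  } else {
    colMeans(m$alleles[, site, drop = FALSE])
  }
}

#' Quantitative trait model
#'
#' Bundles the causal architecture of a quantitative trait: the causal sites
#' (QTNs) with their variance proportions \eqn{\pi_j}, an optional positive
#' epistatic variance proportion \eqn{\pi_E} between exactly two QTNs, a
#' dominance flag (diploids only), and the ploidy. The trait heritability is
#' \eqn{h^2 = \sum_j \pi_j + \pi_E} and must be below 1, since environmental
#' noise has unit variance.
#'
#' @param qtns data.frame as returned by [select_qtns()], with columns
#'   `site`, `effect`, `derived_freq`.
#' @param epistatic_effect optional \eqn{\pi_E \ge 0}; requires exactly two
#'   QTNs.
#' @param dominance logical; recode diploid genotypes so that carrying at
#'   least one derived allele is equivalent to homozygous derived.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return an object of class `quant_trait_model`.
#' @export
quant_trait_model <- function(qtns, epistatic_effect = 0,
                              dominance = FALSE,
                              ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.data.frame(qtns),
            all(c("site", "effect", "derived_freq") %in% names(qtns)))
  if (any(qtns$effect < 0)) stop("QTN effects must be non-negative")
  if (any(qtns$derived_freq <= 0 | qtns$derived_freq >= 1)) {
    stop("QTNs must be polymorphic: derived frequencies strictly in (0, 1)")
  }
  if (anyDuplicated(qtns$site)) stop("QTN sites must be distinct")
  epistatic_effect <- as.numeric(epistatic_effect)
  stopifnot(length(epistatic_effect) == 1L, epistatic_effect >= 0)
  if (epistatic_effect > 0 && nrow(qtns) != 2L) {
    stop("an epistatic effect requires exactly two QTNs")
  }
  if (dominance && ploidy != "diploid") {
    stop("dominance applies to diploid individuals only")
  }
  h2 <- sum(qtns$effect) + epistatic_effect
  if (h2 >= 1) {
    stop(sprintf("heritability sum(effects) + epistatic_effect = %.3f must be < 1", h2))
  }
  structure(list(qtns = qtns, epistatic_effect = epistatic_effect,
                 dominance = dominance, ploidy = ploidy, h2 = h2),
            class = "quant_trait_model")
}

#' Penetrance model for a qualitative trait
#'
#' Defines the probability of being affected for every genotype at one or
#' two causal loci. Table shapes by ploidy and locus count:
#' haploid one-locus, length 2 (ancestral, derived); diploid one-locus,
#' length 3 (hom. ancestral, het., hom. derived); haploid two-locus, 2 x 2;
#' diploid two-locus, 3 x 3 (rows = first locus, columns = second). The
#' two-locus table admits arbitrary interactions between the loci.
#'
#' @param table numeric vector or matrix of affection probabilities in
#'   \[0, 1\], shaped as above.
#' @param loci 1 or 2 site indices (1-based).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return an object of class `penetrance_model`.
#' @examples
#' # fully recessive single diploid locus
#' penetrance_model(c(0, 0, 1), loci = 5, ploidy = "diploid")
#' @export
penetrance_model <- function(table, loci, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  loci <- as.integer(loci)
  if (!length(loci) %in% 1:2) stop("a penetrance model has 1 or 2 loci")
  if (anyDuplicated(loci)) stop("penetrance loci must be distinct")
  table <- if (length(loci) == 2L) as.matrix(table) else as.numeric(table)
  if (any(table < 0 | table > 1)) {
    stop("penetrance entries are probabilities and must lie in [0, 1]")
  }
  g <- if (ploidy == "haploid") 2L else 3L
  if (length(loci) == 1L) {
    if (length(table) != g) {
      stop(sprintf("one-locus %s penetrance table must have %d entries", ploidy, g))
    }
  } else {
    if (!is.matrix(table) || !all(dim(table) == c(g, g))) {
      stop(sprintf("two-locus %s penetrance table must be %d x %d", ploidy, g, g))
    }
  }
  structure(list(table = table, loci = loci, ploidy = ploidy),
            class = "penetrance_model")
}

#' Select causal sites (QTNs) under constraints
#'
#' By default causal sites are drawn uniformly at random from all eligible
#' sites; eligibility requires polymorphism and, when `freq_range` is given,
#' a derived-allele frequency inside the range (inclusive). Individual sites
#' can be pinned with `fixed_sites`, which are honoured verbatim (after a
#' polymorphism/frequency check) and complemented by random draws. With
#' `require_common_haploblock`, both members of a QTN pair are drawn
#' uniformly from all eligible site pairs lying in one four-gamete
#' haploblock (see [find_haploblocks()]).
#'
#' Eligible sites are scanned in column order before sampling, so selection
#' is reproducible across platforms for a given seed.
#'
#' @param m a [haplotype_matrix()].
#' @param n_qtns number of causal sites.
#' @param effects numeric vector of variance proportions \eqn{\pi_j}, one
#'   per QTN.
#' @param freq_range optional `c(f_min, f_max)` on the derived-allele
#'   frequency.
#' @param fixed_sites optional site indices to use verbatim.
#' @param require_common_haploblock logical; both QTNs on one haploblock
#'   (pairs only).
#' @param seed integer seed for the selection draw.
#' @return a data.frame with one row per QTN: `site`, `effect`,
#'   `derived_freq`, ordered by site index.
#' @export
select_qtns <- function(m, n_qtns, effects, freq_range = NULL,
                        fixed_sites = NULL, require_common_haploblock = FALSE,
                        seed = 1L) {
  stopifnot(inherits(m, "haplotype_matrix"), n_qtns >= 1)
  n_qtns <- as.integer(n_qtns)
  if (length(effects) != n_qtns) {
    stop("length(effects) must equal n_qtns")
  }
  if (require_common_haploblock && n_qtns != 2L) {
    stop("the common-haploblock constraint applies to exactly two QTNs")
  }

  freq <- allele_frequency(m, seq_len(site_count(m)))
  eligible <- freq > 0 & freq < 1
  if (!is.null(freq_range)) {
    stopifnot(length(freq_range) == 2L, freq_range[1] <= freq_range[2])
    eligible <- eligible & freq >= freq_range[1] & freq <= freq_range[2]
  }

  fixed_sites <- as.integer(fixed_sites)
  if (length(fixed_sites)) {
    check_site_index(m, fixed_sites)
    if (length(fixed_sites) > n_qtns) stop("more fixed sites than QTNs")
    bad <- fixed_sites[freq[fixed_sites] <= 0 | freq[fixed_sites] >= 1]
    if (length(bad)) {
      stop(sprintf("fixed site(s) %s are monomorphic and cannot be QTNs",
                   paste(bad, collapse = ", ")))
    }
  }

  if (require_common_haploblock) {
    if (length(fixed_sites)) {
      stop("fixed sites and the common-haploblock constraint cannot be combined")
    }
    blocks <- find_haploblocks(m)
    block_of <- site_block_ids(blocks, site_count(m))
    elig_sites <- which(eligible)
    pairs <- list()
    for (b in unique(block_of[elig_sites])) {
      s <- elig_sites[block_of[elig_sites] == b]
      if (length(s) >= 2L) {
        pairs[[length(pairs) + 1L]] <- t(utils::combn(s, 2L))
      }
    }
    if (length(pairs) == 0L) {
      stop(paste("no haploblock contains two eligible sites;",
                 "relax freq_range or simulate a longer locus"))
    }
    pairs <- do.call(rbind, pairs)
    pick <- with_seed(seed, sample.int(nrow(pairs), 1L))
    chosen <- sort(pairs[pick, ])
  } else {
    pool <- setdiff(which(eligible), fixed_sites)
    n_draw <- n_qtns - length(fixed_sites)
    if (length(pool) < n_draw) {
      stop(sprintf(paste("only %d eligible site(s) available for %d QTN(s);",
                         "constraint that failed: %s"),
                   length(pool), n_draw,
                   if (is.null(freq_range)) "polymorphism"
                   else sprintf("freq_range [%g, %g]", freq_range[1], freq_range[2])))
    }
    drawn <- if (n_draw > 0L) {
      with_seed(seed, pool[sample.int(length(pool), n_draw)])
    } else integer(0)
    chosen <- sort(c(fixed_sites, drawn))
  }

  data.frame(site = chosen, effect = as.numeric(effects),
             derived_freq = freq[chosen])
}

#' Additive effect coefficient for a QTN
#'
#' The coefficient \eqn{\beta_j} applied to QTN \eqn{j}'s genotype coding so
#' that the QTN explains proportion \eqn{\pi_j} of total phenotypic variance
#' when the environmental noise is standard normal and QTNs are independent:
#' \deqn{\beta_j = \sqrt{\pi_j / (v_j (1 - h^2))}}
#' where \eqn{v_j} is the variance of the genotype coding —
#' \eqn{f_j(1-f_j)} for 0/1 haploid (or dominant-carrier) coding and
#' \eqn{2 f_j (1-f_j)} for the diploid \{-1, 0, +1\} coding under
#' Hardy-Weinberg proportions. With this scaling the genetic variance totals
#' \eqn{h^2/(1-h^2)} and the phenotypic variance \eqn{1/(1-h^2)}, so each
#' QTN's share is exactly \eqn{\pi_j} and the QTNs' joint share is
#' \eqn{h^2}.
#'
#' @param pi_j variance proportion of the QTN, in \[0, 1).
#' @param f_j derived-allele frequency, strictly in (0, 1).
#' @param h2 trait heritability \eqn{\sum_j \pi_j + \pi_E}, in \[0, 1).
#' @param coding_variance variance \eqn{v_j} of the genotype coding;
#'   defaults to `f_j * (1 - f_j)` (0/1 coding).
#' @return the non-negative coefficient \eqn{\beta_j}.
#' @examples
#' effect_coefficient(0.05, 0.5, h2 = 0.1)                        # haploid
#' effect_coefficient(0.05, 0.5, h2 = 0.1, coding_variance = 0.5) # diploid
#' @export
effect_coefficient <- function(pi_j, f_j, h2, coding_variance = f_j * (1 - f_j)) {
  stopifnot(pi_j >= 0, f_j > 0, f_j < 1, coding_variance > 0)
  if (h2 >= 1 || h2 < 0) stop("heritability h2 must lie in [0, 1)")
  sqrt(pi_j / (coding_variance * (1 - h2)))
}

#' Allelic state of the fictive epistatic QTN
#'
#' Epistasis between two QTNs is modelled as a fictive third QTN whose
#' allelic state is 1 iff the individual carries at least one derived allele
#' at both basal QTNs, and 0 otherwise.
#'
#' @param g1,g2 genotype codes at the two basal QTNs: 0/1 alleles for
#'   haploids, \{-1, 0, +1\} codes for diploids. Vectorized.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return integer vector of 0/1 fictive-allele states.
#' @examples
#' epistatic_state(0, 0, "diploid")  # double heterozygote carries both: 1
#' epistatic_state(1, 0, "haploid")  # derived at one locus only: 0
#' @export
epistatic_state <- function(g1, g2, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (ploidy == "haploid") {
    stopifnot(all(g1 %in% 0:1), all(g2 %in% 0:1))
    as.integer(g1 == 1L & g2 == 1L)
  } else {
    stopifnot(all(g1 %in% -1:1), all(g2 %in% -1:1))
    as.integer(g1 >= 0L & g2 >= 0L)
  }
}

# Genotype coding columns for the QTNs of a model: 0/1 alleles (haploid),
# {-1,0,+1} codes (diploid additive) or 0/1 carrier indicator (dominant).
qtn_design <- function(m, model) {
  g <- geno_matrix(m)[, model$qtns$site, drop = FALSE]
  if (model$ploidy == "diploid" && model$dominance) {
    g <- matrix(as.integer(g >= 0L), nrow(g), ncol(g))
  }
  storage.mode(g) <- "double"
  g
}

# Realized coding variance of one design column given the coding convention.
coding_variance_of <- function(x, ploidy, dominance) {
  if (ploidy == "diploid" && !dominance) {
    f <- mean((x + 1) / 2)
    2 * f * (1 - f)
  } else {
    q <- mean(x)          # 0/1 coding: allele or carrier frequency
    q * (1 - q)
  }
}

#' Generate quantitative phenotypes
#'
#' Computes \eqn{Y_i = \sum_j \beta_j g_{ij} + \beta_E e_i + \epsilon_i}
#' with \eqn{\epsilon_i} i.i.d. standard normal. The genotype coding
#' \eqn{g_{ij}} is the 0/1 allele for haploids, the \{-1, 0, +1\} code for
#' diploids under the additive model, or the 0/1 carrier indicator under
#' dominance (heterozygous and homozygous-derived individuals are then
#' interchangeable). Coefficients come from [effect_coefficient()] with the
#' realized frequency of each QTN.
#'
#' When the model carries an epistatic effect \eqn{\pi_E}, the fictive
#' third-QTN indicator (see [epistatic_state()]) is first residualized by
#' least squares against the two basal QTN coding columns; the residual is
#' scaled by \eqn{\beta_E = \sqrt{\pi_E / (v_r (1-h^2))}} with \eqn{v_r} its
#' realized variance. The fictive indicator is a deterministic function of
#' the basal genotypes and therefore partially collinear with them;
#' residualizing makes \eqn{\pi_E} the variance explained by epistasis
#' *beyond* the main effects, which keeps the variance partition exact:
#' each QTN contributes \eqn{\pi_j}, the interaction \eqn{\pi_E}, and the
#' total \eqn{h^2}.
#'
#' @param m a [haplotype_matrix()] (haploid models) or [genotype_matrix()]
#'   (diploid models); must match `model$ploidy`.
#' @param model a [quant_trait_model()].
#' @param seed integer seed for the environmental noise.
#' @return a [phenotype_vector()] of kind `"quantitative"` with attributes
#'   `"genetic"` (the genetic values \eqn{Y_i - \epsilon_i}) and `"h2"`.
#' @examples
#' m <- generate_fixture(500, 20, seed = 1)
#' q <- select_qtns(m, 2, effects = c(0.05, 0.05), seed = 2)
#' y <- generate_quantitative(m, quant_trait_model(q), seed = 3)
#' var(as.numeric(y))  # close to 1/(1 - 0.1)
#' @export
generate_quantitative <- function(m, model, seed) {
  stopifnot(inherits(model, "quant_trait_model"))
  if (is_diploid(m) != (model$ploidy == "diploid")) {
    stop(sprintf("model ploidy is %s but the matrix is %s", model$ploidy,
                 if (is_diploid(m)) "diploid" else "haploid"))
  }
  n <- unit_count(m)
  check_site_index(m, model$qtns$site)
  X <- qtn_design(m, model)

  genetic <- numeric(n)
  for (j in seq_len(ncol(X))) {
    v <- coding_variance_of(X[, j], model$ploidy, model$dominance)
    if (v <= 0) {
      stop(sprintf("QTN at site %d is monomorphic in this sample", model$qtns$site[j]))
    }
    f <- if (model$ploidy == "diploid") mean((geno_matrix(m)[, model$qtns$site[j]] + 1) / 2) else mean(X[, j])
    beta <- effect_coefficient(model$qtns$effect[j], f, model$h2, coding_variance = v)
    genetic <- genetic + beta * X[, j]
  }

  if (model$epistatic_effect > 0) {
    raw <- geno_matrix(m)[, model$qtns$site, drop = FALSE]
    e <- epistatic_state(raw[, 1L], raw[, 2L], model$ploidy)
    if (all(e == e[1L])) {
      stop(paste("the fictive epistatic allele is monomorphic in this sample;",
                 "re-select QTNs (e.g. with a higher frequency range)"))
    }
    fit <- stats::lm.fit(cbind(1, X), e)
    r <- fit$residuals
    v_r <- mean(r^2)
    if (v_r < sqrt(.Machine$double.eps)) {
      stop(paste("the fictive epistatic indicator is collinear with the QTN",
                 "codings; re-select QTNs"))
    }
    beta_e <- sqrt(model$epistatic_effect / (v_r * (1 - model$h2)))
    genetic <- genetic + beta_e * r
  }

  eps <- with_seed(seed, stats::rnorm(n))
  out <- phenotype_vector(genetic + eps, kind = "quantitative")
  attr(out, "genetic") <- genetic
  attr(out, "h2") <- model$h2
  out
}

# Map genotypes at the model's loci to penetrance probabilities.
penetrance_probs <- function(m, model) {
  check_site_index(m, model$loci)
  g <- geno_matrix(m)[, model$loci, drop = FALSE]
  idx <- if (model$ploidy == "haploid") g + 1L else g + 2L
  if (length(model$loci) == 1L) {
    model$table[idx[, 1L]]
  } else {
    model$table[cbind(idx[, 1L], idx[, 2L])]
  }
}

#' Assign case/control status from a penetrance model
#'
#' Each individual is affected with the probability their genotype at the
#' model's locus (or two-locus genotype combination) is assigned in the
#' penetrance table, as an independent Bernoulli draw.
#'
#' @param m a [haplotype_matrix()] (haploid) or [genotype_matrix()]
#'   (diploid), matching the model's ploidy.
#' @param model a [penetrance_model()].
#' @param seed integer seed for the Bernoulli draws.
#' @return a [phenotype_vector()] of kind `"case_control"` (1 = case).
#' @export
assign_case_control <- function(m, model, seed) {
  stopifnot(inherits(model, "penetrance_model"))
  if (is_diploid(m) != (model$ploidy == "diploid")) {
    stop(sprintf("model ploidy is %s but the matrix is %s", model$ploidy,
                 if (is_diploid(m)) "diploid" else "haploid"))
  }
  p <- penetrance_probs(m, model)
  status <- with_seed(seed, as.numeric(stats::runif(length(p)) < p))
  phenotype_vector(status, kind = "case_control")
}

#' Expected disease prevalence under a penetrance model
#'
#' Closed form \eqn{\sum_g P(g)\,\mathrm{penetrance}(g)} over all
#' multi-locus genotypes; the population mean of [assign_case_control()].
#'
#' @param model a [penetrance_model()].
#' @param genotype_frequencies probabilities per genotype, in the same shape
#'   as the model's table (vector for one locus, matrix for two); must sum
#'   to 1 within `1e-9`.
#' @return the expected case fraction.
#' @examples
#' pm <- penetrance_model(c(0, 0, 1), loci = 1, ploidy = "diploid")
#' expected_prevalence(pm, c(0.25, 0.5, 0.25))
#' @export
expected_prevalence <- function(model, genotype_frequencies) {
  stopifnot(inherits(model, "penetrance_model"))
  freq <- if (length(model$loci) == 2L) as.matrix(genotype_frequencies)
          else as.numeric(genotype_frequencies)
  if (!identical(dim(freq), dim(model$table)) ||
      length(freq) != length(model$table)) {
    stop("genotype_frequencies must match the penetrance table's shape")
  }
  if (abs(sum(freq) - 1) > 1e-9) {
    stop("genotype frequencies must sum to 1 (within 1e-9)")
  }
  sum(freq * model$table)
}

#' Realized variance decomposition of a simulated trait
#'
#' Quality-control companion to [generate_quantitative()]: regresses the
#' simulated phenotype on the raw causal design columns (the QTN genotype
#' codings plus, for epistatic models, the fictive-indicator column) and
#' reports the total R-squared together with each column's incremental
#' R-squared (the drop in R-squared when that column is removed). Under the
#' package's scaling these converge, as the sample grows, to \eqn{h^2} and
#' to the per-effect variance proportions \eqn{\pi_j}, \eqn{\pi_E}.
#'
#' @param m the matrix the phenotype was generated from.
#' @param model the [quant_trait_model()] used.
#' @param phen the resulting [phenotype_vector()].
#' @return a list with `total_r2`, `partial_r2` (named per QTN site, plus
#'   `"epistatic"` when applicable) and `epistatic_freq` (frequency of the
#'   fictive allele, or `NA`).
#' @export
recovered_variance <- function(m, model, phen) {
  stopifnot(inherits(model, "quant_trait_model"))
  y <- as.numeric(phen)
  X <- qtn_design(m, model)
  labels <- sprintf("site%d", model$qtns$site)
  e_freq <- NA_real_
  if (model$epistatic_effect > 0) {
    raw <- geno_matrix(m)[, model$qtns$site, drop = FALSE]
    e <- epistatic_state(raw[, 1L], raw[, 2L], model$ploidy)
    e_freq <- mean(e)
    X <- cbind(X, e)
    labels <- c(labels, "epistatic")
  }
  r2_of <- function(M) {
    if (is.null(M) || ncol(M) == 0L) return(0)
    fit <- stats::lm.fit(cbind(1, M), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  total <- r2_of(X)
  partial <- vapply(seq_len(ncol(X)), function(j) {
    total - r2_of(X[, -j, drop = FALSE])
  }, numeric(1))
  list(total_r2 = total,
       partial_r2 = stats::setNames(partial, labels),
       epistatic_freq = e_freq)
}
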