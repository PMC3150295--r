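test_that("allele frequencies count derived alleles over chromosomes", {
  m <- counted_matrix(4, c(2, 0, 3))
  expect_equal(allele_frequency(m, 1), 0.5)
  expect_equal(allele_frequency(m, 2), 0)
  expect_equal(allele_frequency(m, 3), 0.75)

  # diploid: codes count alleles, not carriers
  d <- genotype_matrix(cbind(c(1L, -1L, 0L, 0L)), 0.5)
  expect_equal(allele_frequency(d, 1), 0.5)
})

test_that("select_qtns honours forced choices, fixed sites and frequency ranges", {
  # 10 chromosomes; only site 3 has frequency inside [0.4, 0.6]
  m <- counted_matrix(10, c(1, 9, 5, 10, 0, 2))
  q <- select_qtns(m, 1, effects = 0.05, freq_range = c(0.4, 0.6), seed = 1)
  expect_identical(q$site, 3L)
  expect_equal(q$derived_freq, 0.5)

  # manual override is honoured verbatim with realized frequencies
  q2 <- select_qtns(m, 2, effects = c(0.02, 0.03), fixed_sites = c(3, 6),
                    seed = 9)
  expect_identical(q2$site, c(3L, 6L))
  expect_equal(q2$derived_freq, c(0.5, 0.2))
  expect_error(select_qtns(m, 1, 0.05, fixed_sites = 4), "monomorphic")

  # exhaustive eligibility: with exactly two qualifying sites of twenty,
  # every seed returns that pair
  counts <- rep(1L, 20); counts[c(7, 13)] <- 10L
  m20 <- counted_matrix(20, counts)  # freq 0.05 except 0.5 at sites 7, 13
  for (s in 1:200) {
    q3 <- select_qtns(m20, 2, effects = c(0.05, 0.05),
                      freq_range = c(0.4, 0.6), seed = s)
    expect_identical(q3$site, c(7L, 13L))
  }

  expect_error(select_qtns(m, 1, 0.05, freq_range = c(0.98, 0.99)),
               "freq_range")
})

test_that("the common-haploblock constraint keeps QTN pairs inside one block", {
  m <- blocky_matrix()  # blocks {1,2} and {3,4}, all sites polymorphic
  blocks <- find_haploblocks(m)
  for (s in 1:25) {
    q <- select_qtns(m, 2, effects = c(0.01, 0.01),
                     require_common_haploblock = TRUE, seed = s)
    in_block <- vapply(seq_len(nrow(blocks)), function(b) {
      all(q$site >= blocks$start_site[b] & q$site <= blocks$end_site[b])
    }, logical(1))
    expect_true(any(in_block))
  }

  # no block holds two eligible sites -> eligibility error
  m_bad <- haplotype_matrix(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                            c(0.2, 0.8))
  expect_error(select_qtns(m_bad, 2, c(0.01, 0.01),
                           require_common_haploblock = TRUE, seed = 1),
               "no haploblock")
})

test_that("effect coefficients realize the stated variance proportions", {
  # closed forms frozen from beta = sqrt(pi / (v (1 - h2)))
  expect_equal(effect_coefficient(0.05, 0.5, h2 = 0.1), 0.4714045,
               tolerance = 1e-6)
  expect_equal(effect_coefficient(0.05, 0.5, h2 = 0.1, coding_variance = 0.5),
               0.3333333, tolerance = 1e-6)
  expect_equal(effect_coefficient(0, 0.3, h2 = 0.1), 0)
  expect_error(effect_coefficient(0.05, 0.5, h2 = 1), "h2")

  # empirical oracle: two independent QTNs at 100,000 haploids; each
  # explains ~0.05 of the variance and jointly ~0.10
  m <- generate_fixture(1e5, 2, freq_spectrum = 0.5, seed = 5)
  q <- select_qtns(m, 2, effects = c(0.05, 0.05), fixed_sites = c(1, 2),
                   seed = 1)
  model <- quant_trait_model(q)
  y <- generate_quantitative(m, model, seed = 6)
  rv <- recovered_variance(m, model, y)
  expect_lt(abs(rv$total_r2 - 0.10), 0.01)
  expect_lt(max(abs(rv$partial_r2 - 0.05)), 0.01)
})

test_that("the fictive epistatic state requires a derived allele at both loci", {
  # diploid double heterozygote carries one derived allele at each locus
  expect_identical(epistatic_state(0, 0, "diploid"), 1L)
  expect_identical(epistatic_state(1, -1, "diploid"), 0L)
  expect_identical(epistatic_state(c(1, 1, 0), c(1, 0, 1), "haploid"),
                   c(1L, 0L, 0L))
})

test_that("quantitative phenotypes decompose into genetic value plus unit noise", {
  # no QTNs: pure standard-normal noise
  none <- quant_trait_model(data.frame(site = integer(0), effect = numeric(0),
                                       derived_freq = numeric(0)))
  m <- generate_fixture(5000, 3, seed = 21)
  y0 <- generate_quantitative(m, none, seed = 22)
  expect_lt(abs(var(as.numeric(y0)) - 1), 0.06)
  expect_identical(attr(y0, "genetic"), rep(0, 5000))

  # additive haploid: individuals ancestral at every QTN have genetic value 0
  q <- select_qtns(m, 2, effects = c(0.05, 0.05), fixed_sites = c(1, 2),
                   seed = 1)
  y <- generate_quantitative(m, quant_trait_model(q), seed = 23)
  anc <- rowSums(m$alleles[, q$site]) == 0
  expect_true(any(anc))
  expect_identical(attr(y, "genetic")[anc], rep(0, sum(anc)))

  # bit-reproducible under a fixed seed
  y2 <- generate_quantitative(m, quant_trait_model(q), seed = 23)
  expect_identical(as.numeric(y), as.numeric(y2))
  expect_false(identical(as.numeric(y),
                         as.numeric(generate_quantitative(m, quant_trait_model(q),
                                                          seed = 24))))
})

test_that("dominance makes heterozygotes and derived homozygotes equivalent", {
  d <- genotype_matrix(cbind(c(-1L, 0L, 1L, 0L, -1L, 1L)), 0.5)
  q <- data.frame(site = 1L, effect = 0.2,
                  derived_freq = allele_frequency(d, 1))
  y <- generate_quantitative(d, quant_trait_model(q, dominance = TRUE,
                                                  ploidy = "diploid"),
                             seed = 3)
  g <- attr(y, "genetic")
  expect_identical(g[d$codes[, 1] == -1L], rep(0, 2))
  expect_equal(length(unique(g[d$codes[, 1] >= 0L])), 1L)
  expect_gt(g[2], 0)
})

test_that("degenerate causal configurations are rejected with guidance", {
  mono <- haplotype_matrix(cbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 0L, 1L)),
                           c(0.2, 0.8))
  bad_q <- data.frame(site = 1L, effect = 0.05, derived_freq = 0.5)
  expect_error(
    generate_quantitative(mono, quant_trait_model(bad_q), seed = 1),
    "monomorphic"
  )

  # derived alleles never co-occur: the fictive allele is monomorphic
  apart <- haplotype_matrix(cbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)),
                            c(0.2, 0.8))
  q2 <- data.frame(site = 1:2, effect = c(0.01, 0.01),
                   derived_freq = c(0.5, 0.5))
  expect_error(
    generate_quantitative(apart, quant_trait_model(q2, epistatic_effect = 0.08),
                          seed = 1),
    "re-select"
  )

  expect_error(quant_trait_model(data.frame(site = 1:2, effect = c(0.5, 0.3),
                                            derived_freq = c(0.5, 0.5)),
                                 epistatic_effect = 0.3),
               "< 1")
})

test_that("case/control assignment follows the penetrance table", {
  m <- generate_fixture(200, 2, freq_spectrum = 0.5, seed = 31)
  never <- penetrance_model(c(0, 0), loci = 1, ploidy = "haploid")
  expect_identical(sum(assign_case_control(m, never, seed = 1)), 0)
  always <- penetrance_model(c(1, 1), loci = 1, ploidy = "haploid")
  expect_identical(sum(assign_case_control(m, always, seed = 1)), 200)

  # reproducible draws
  table <- penetrance_model(c(0.1, 0.8), loci = 2, ploidy = "haploid")
  s1 <- assign_case_control(m, table, seed = 5)
  expect_identical(as.numeric(s1),
                   as.numeric(assign_case_control(m, table, seed = 5)))

  # recessive diploid locus near f = 0.5: prevalence ~ f^2 ~ 0.25
  big <- pair_diploids(generate_fixture(80000, 1, freq_spectrum = 0.5,
                                        seed = 32))
  rec <- penetrance_model(c(0, 0, 1), loci = 1, ploidy = "diploid")
  status <- assign_case_control(big, rec, seed = 33)
  geno_freq <- tabulate(big$codes[, 1] + 2L, 3L) / nrow(big$codes)
  expect_lt(abs(mean(status) - expected_prevalence(rec, geno_freq)), 0.01)
  expect_lt(abs(mean(status) - 0.25), 0.01)
})

test_that("expected prevalence is the penetrance-weighted genotype mixture", {
  uniform <- penetrance_model(c(0.3, 0.3, 0.3), loci = 1, ploidy = "diploid")
  expect_equal(expected_prevalence(uniform, c(0.25, 0.5, 0.25)), 0.3)

  rec <- penetrance_model(c(0, 0, 1), loci = 1, ploidy = "diploid")
  expect_equal(expected_prevalence(rec, c(0.25, 0.5, 0.25)), 0.25)

  # two independent haploid loci at f = 0.5, affected only when both derived
  both <- penetrance_model(rbind(c(0, 0), c(0, 1)), loci = c(1, 2),
                           ploidy = "haploid")
  expect_equal(expected_prevalence(both, matrix(0.25, 2, 2)), 0.25)

  expect_error(expected_prevalence(rec, c(0.3, 0.3, 0.3)), "sum to 1")
  expect_error(expected_prevalence(rec, c(0.5, 0.5)), "shape")
})
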