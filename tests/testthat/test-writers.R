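# 2 individuals x 2 markers, diploid, quantitative trait
tiny_dataset <- function(phen = phenotype_vector(c(1.5, -0.2))) {
  g <- genotype_matrix(rbind(c(1L, -1L), c(0L, 0L)), c(100, 250),
                       position_unit = "bp")
  gwas_dataset(g, phen)
}

test_that("PED/MAP output matches the PLINK conventions byte for byte", {
  d <- tiny_dataset()
  prefix <- file.path(withr::local_tempdir(), "x")
  write_plink_ped_map(d, prefix)
  expect_identical(readLines(paste0(prefix, ".map")),
                   c("1\tsnp1\t0\t100", "1\tsnp2\t0\t250"))
  expect_identical(readLines(paste0(prefix, ".ped")),
                   c("ind1\tind1\t0\t0\t0\t1.5\tT\tT\tA\tA",
                     "ind2\tind2\t0\t0\t0\t-0.2\tA\tT\tA\tT"))
})

test_that("case/control phenotypes use the 1 = control / 2 = case coding", {
  d <- tiny_dataset(phenotype_vector(c(0, 1), kind = "case_control"))
  prefix <- file.path(withr::local_tempdir(), "cc")
  write_plink_ped_map(d, prefix)
  ped <- readLines(paste0(prefix, ".ped"))
  expect_identical(vapply(strsplit(ped, "\t"), `[`, character(1), 6L),
                   c("1", "2"))
})

test_that("an empty marker set still yields valid six-column PED lines", {
  g <- genotype_matrix(matrix(0L, 2, 0), numeric(0), position_unit = "bp")
  d <- gwas_dataset(g, phenotype_vector(c(0.3, 0.4)))
  prefix <- file.path(withr::local_tempdir(), "empty")
  write_plink_ped_map(d, prefix)
  expect_identical(readLines(paste0(prefix, ".map")), character(0))
  expect_identical(length(strsplit(readLines(paste0(prefix, ".ped"))[1],
                                   "\t")[[1]]), 6L)
})

test_that("TPED/TFAM transpose the PED/MAP layout exactly", {
  d <- tiny_dataset()
  prefix <- file.path(withr::local_tempdir(), "t")
  write_tped_tfam(d, prefix)
  tped <- readLines(paste0(prefix, ".tped"))
  expect_identical(tped,
                   c("1\tsnp1\t0\t100\tT\tT\tA\tT",
                     "1\tsnp2\t0\t250\tA\tA\tA\tT"))
  expect_identical(readLines(paste0(prefix, ".tfam")),
                   c("ind1\tind1\t0\t0\t0\t1.5",
                     "ind2\tind2\t0\t0\t0\t-0.2"))

  # structural transpose identity against ped/map on a larger fixture
  m <- pair_diploids(generate_fixture(40, 15, seed = 81))
  d2 <- gwas_dataset(m, phenotype_vector(rnorm(20)))
  p2 <- file.path(withr::local_tempdir(), "big")
  write_plink_ped_map(d2, p2)
  write_tped_tfam(d2, p2)
  expect_identical(length(readLines(paste0(p2, ".tped"))),
                   length(readLines(paste0(p2, ".map"))))
  expect_identical(length(readLines(paste0(p2, ".tfam"))),
                   length(readLines(paste0(p2, ".ped"))))

  # round trip: recover genotype codes from our own tped
  rows <- strsplit(readLines(paste0(p2, ".tped")), "\t")
  codes <- vapply(rows, function(r) {
    al <- matrix(r[-(1:4)], nrow = 2)
    as.integer(colSums(al == "T") - 1L)
  }, integer(20))  # individuals x markers
  expect_identical(codes, unname(m$codes))
})

test_that("EMMA matrices use dosage fractions with markers in rows", {
  d <- tiny_dataset()
  prefix <- file.path(withr::local_tempdir(), "e")
  write_emma(d, prefix)
  expect_identical(readLines(paste0(prefix, ".geno")),
                   c("1\t0.5", "0\t0.5"))
  expect_identical(readLines(paste0(prefix, ".pheno")), "1.5\t-0.2")

  # haploid alleles pass through unchanged
  h <- haplotype_matrix(cbind(c(0L, 1L, 1L, 0L)), 0.5)
  dh <- gwas_dataset(h, phenotype_vector(c(1, 2, 3, 4)))
  write_emma(dh, prefix)
  expect_identical(readLines(paste0(prefix, ".geno")), "0\t1\t1\t0")
})

test_that("TSV output round-trips the dataset and rejects non-finite traits", {
  m <- pair_diploids(generate_fixture(30, 8, seed = 91))
  d <- gwas_dataset(m, phenotype_vector(round(rnorm(15), 6)))
  prefix <- file.path(withr::local_tempdir(), "r")
  write_tsv(d, prefix)
  back <- read_tsv_dataset(prefix)
  expect_identical(geno_codes <- back$genotypes$codes, unname(m$codes))
  expect_identical(back$positions_bp, d$positions_bp)
  expect_identical(back$marker_ids, d$marker_ids)
  expect_equal(as.numeric(back$phenotypes), as.numeric(d$phenotypes),
               tolerance = 1e-12)

  expect_error(phenotype_vector(c(1, NaN)), "finite")
  expect_error(phenotype_vector(c(1, Inf)), "finite")
})

test_that("all writers are byte-deterministic and conserve allele counts", {
  m <- pair_diploids(generate_fixture(60, 12, seed = 101))
  d <- gwas_dataset(m, phenotype_vector(rnorm(30)))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  for (dir in c(dir1, dir2)) {
    write_plink_ped_map(d, file.path(dir, "o"))
    write_tped_tfam(d, file.path(dir, "o"))
    write_emma(d, file.path(dir, "o"))
    write_tsv(d, file.path(dir, "o"))
  }
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }

  # derived-allele counts per marker agree across every format
  truth <- colSums(m$codes + 1L)
  ped <- do.call(rbind, strsplit(readLines(file.path(dir1, "o.ped")), "\t"))
  ped_counts <- vapply(seq_len(ncol(m$codes)), function(j) {
    sum(ped[, 6 + 2 * j - 1] == "T") + sum(ped[, 6 + 2 * j] == "T")
  }, numeric(1))
  tped <- strsplit(readLines(file.path(dir1, "o.tped")), "\t")
  tped_counts <- vapply(tped, function(r) sum(r[-(1:4)] == "T"), numeric(1))
  emma <- strsplit(readLines(file.path(dir1, "o.geno")), "\t")
  emma_counts <- vapply(emma, function(r) 2 * sum(as.numeric(r)), numeric(1))
  tsv <- read_tsv_dataset(file.path(dir1, "o"))
  tsv_counts <- colSums(tsv$genotypes$codes + 1L)
  expect_equal(ped_counts, truth)
  expect_equal(tped_counts, truth)
  expect_equal(emma_counts, truth)
  expect_equal(unname(tsv_counts), unname(truth))
})

test_that("haploid genotypes are exported as homozygous diploids with a warning", {
  h <- haplotype_matrix(rbind(c(0L, 1L), c(1L, 1L)), c(0.1, 0.9))
  d <- gwas_dataset(h, phenotype_vector(c(0.1, 0.2)))
  prefix <- file.path(withr::local_tempdir(), "h")
  expect_warning(write_plink_ped_map(d, prefix), "homozygous")
  ped <- strsplit(readLines(paste0(prefix, ".ped")), "\t")[[1]]
  expect_identical(ped[7:10], c("A", "A", "T", "T"))
})
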