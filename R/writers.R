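#' Export-ready dataset
#'
#' Binds genotypes, phenotypes, marker metadata and individual identifiers
#' for the file writers. Fractional site positions are converted to strictly
#' increasing integer base pairs via [positions_to_bp()] (default locus
#' length 1 Mbp); base-pair positions are used as-is (collisions bumped).
#'
#' @param genotypes a [haplotype_matrix()] or [genotype_matrix()].
#' @param phenotypes a [phenotype_vector()] aligned with the rows.
#' @param locus_length_bp locus length used for the fraction-to-bp
#'   conversion; ignored when positions are already in bp. Defaults to the
#'   matrix's own `locus_length_bp`, else 1e6.
#' @param marker_ids,individual_ids optional character identifiers;
#'   defaults `snp<j>` and `ind<i>`.
#' @return an object of class `gwas_dataset`.
#' @export
gwas_dataset <- function(genotypes, phenotypes, locus_length_bp = NULL,
                         marker_ids = NULL, individual_ids = NULL) {
  stopifnot(inherits(phenotypes, "phenotype_vector"))
  n_ind <- unit_count(genotypes)
  n_mrk <- site_count(genotypes)
  if (length(phenotypes) != n_ind) {
    stop("phenotype length must equal the number of individuals")
  }
  if (genotypes$position_unit == "fraction") {
    len <- locus_length_bp %||% genotypes$locus_length_bp %||% 1e6
    positions_bp <- positions_to_bp(genotypes$positions, len)
  } else {
    positions_bp <- as.integer(round(genotypes$positions))
    if (n_mrk > 1L && any(diff(positions_bp) <= 0L)) {
      for (i in 2:n_mrk) {
        if (positions_bp[i] <= positions_bp[i - 1L]) {
          positions_bp[i] <- positions_bp[i - 1L] + 1L
        }
      }
      warning("non-increasing bp positions bumped to strictly increasing")
    }
  }
  marker_ids <- marker_ids %||% sprintf("snp%d", seq_len(n_mrk))
  individual_ids <- individual_ids %||% sprintf("ind%d", seq_len(n_ind))
  if (length(marker_ids) != n_mrk) stop("marker_ids length mismatch")
  if (length(individual_ids) != n_ind) stop("individual_ids length mismatch")
  if (anyDuplicated(marker_ids) || anyDuplicated(individual_ids)) {
    stop("marker and individual identifiers must be unique")
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 positions_bp = positions_bp,
                 marker_ids = as.character(marker_ids),
                 individual_ids = as.character(individual_ids)),
            class = "gwas_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One number, deterministic, locale-free, no scientific notation.
fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE),
         character(1))
}

# PLINK phenotype column: 1 = control, 2 = case; quantitative as decimal.
plink_phenotype <- function(phen) {
  if (attr(phen, "kind") == "case_control") {
    as.character(as.integer(phen) + 1L)
  } else {
    fmt_num(as.numeric(phen))
  }
}

# Per-individual diploid codes for export; haploids become homozygous
# diploids with a warning (PLINK has no haploid autosomal representation).
export_codes <- function(d, warn_haploid = TRUE) {
  if (is_diploid(d$genotypes)) {
    d$genotypes$codes
  } else {
    if (warn_haploid) {
      warning("haploid genotypes written as homozygous diploids")
    }
    d$genotypes$alleles * 2L - 1L
  }
}

# Two allele letters per genotype code: A = ancestral, T = derived
# (arbitrary fixed letters; coalescent output carries no nucleotides).
allele_pair <- function(code) {
  c(`-1` = "A\tA", `0` = "A\tT", `1` = "T\tT")[as.character(code)]
}

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write PLINK PED/MAP files
#'
#' `<prefix>.map`: one marker per line — chromosome (fixed to 1: one
#' simulated locus), marker id, genetic distance 0, base-pair position.
#' `<prefix>.ped`: one individual per line — family id, individual id,
#' paternal id 0, maternal id 0, sex 0, phenotype (1 = control / 2 = case,
#' or decimal trait value), then two allele letters per marker (A =
#' ancestral, T = derived). All fields tab-separated; haploid input is
#' written as homozygous diploid with a warning.
#'
#' @param d a [gwas_dataset()].
#' @param out_prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_plink_ped_map <- function(d, out_prefix) {
  stopifnot(inherits(d, "gwas_dataset"))
  map <- sprintf("1\t%s\t0\t%d", d$marker_ids, d$positions_bp)
  codes <- export_codes(d)
  phen <- plink_phenotype(d$phenotypes)
  ped <- vapply(seq_along(d$individual_ids), function(i) {
    geno <- if (ncol(codes) > 0L) {
      paste(allele_pair(codes[i, ]), collapse = "\t")
    } else NULL
    paste(c(d$individual_ids[i], d$individual_ids[i], "0", "0", "0",
            phen[i], geno), collapse = "\t")
  }, character(1))
  paths <- paste0(out_prefix, c(".ped", ".map"))
  write_lf(ped, paths[1]); write_lf(map, paths[2])
  invisible(paths)
}

#' Write transposed PLINK TPED/TFAM files
#'
#' The transposed layout consumed by EMMAX and other mixed-model tools:
#' `<prefix>.tped` has one marker per line (chromosome 1, marker id,
#' genetic distance 0, bp, then two allele letters per individual) and
#' `<prefix>.tfam` one individual per line (family id, individual id,
#' 0, 0, 0, phenotype).
#'
#' @inheritParams write_plink_ped_map
#' @return invisibly, the two file paths.
#' @export
write_tped_tfam <- function(d, out_prefix) {
  stopifnot(inherits(d, "gwas_dataset"))
  codes <- export_codes(d)
  tped <- vapply(seq_along(d$marker_ids), function(j) {
    paste(c("1", d$marker_ids[j], "0", d$positions_bp[j],
            allele_pair(codes[, j])), collapse = "\t")
  }, character(1))
  phen <- plink_phenotype(d$phenotypes)
  tfam <- sprintf("%s\t%s\t0\t0\t0\t%s", d$individual_ids, d$individual_ids, phen)
  paths <- paste0(out_prefix, c(".tped", ".tfam"))
  write_lf(tped, paths[1]); write_lf(tfam, paths[2])
  invisible(paths)
}

#' Write EMMA matrix files
#'
#' `<prefix>.geno`: a markers x individuals matrix of numeric genotypes —
#' derived-allele dosage fractions 0 / 0.5 / 1 for diploids (homozygous
#' ancestral / heterozygous / homozygous derived) or 0 / 1 for haploids —
#' tab-separated, no header. `<prefix>.pheno`: one tab-separated row of
#' trait values.
#'
#' @inheritParams write_plink_ped_map
#' @return invisibly, the two file paths.
#' @export
write_emma <- function(d, out_prefix) {
  stopifnot(inherits(d, "gwas_dataset"))
  if (is_diploid(d$genotypes)) {
    num <- (t(d$genotypes$codes) + 1) / 2     # markers x individuals
  } else {
    num <- t(d$genotypes$alleles)
  }
  geno <- apply(num, 1L, function(row) paste(fmt_num(row), collapse = "\t"))
  if (length(geno) == 0L) geno <- character(0)
  pheno <- paste(fmt_num(as.numeric(d$phenotypes)), collapse = "\t")
  paths <- paste0(out_prefix, c(".geno", ".pheno"))
  write_lf(as.character(geno), paths[1]); write_lf(pheno, paths[2])
  invisible(paths)
}

#' Write generic TSV files
#'
#' `<prefix>.geno.tsv`: header `individual_id` followed by one column per
#' marker named `<marker_id>_<bp>`, then one row of genotype codes per
#' individual (0/1 alleles for haploids, -1/0/+1 codes for diploids).
#' `<prefix>.pheno.tsv`: columns `individual_id`, `phenotype`. Output is
#' byte-deterministic: LF line endings, no timestamps.
#'
#' @inheritParams write_plink_ped_map
#' @return invisibly, the two file paths.
#' @export
write_tsv <- function(d, out_prefix) {
  stopifnot(inherits(d, "gwas_dataset"))
  codes <- geno_matrix(d$genotypes)
  header <- paste(c("individual_id",
                    sprintf("%s_%d", d$marker_ids, d$positions_bp)),
                  collapse = "\t")
  body <- vapply(seq_along(d$individual_ids), function(i) {
    paste(c(d$individual_ids[i], codes[i, ]), collapse = "\t")
  }, character(1))
  pheno <- c("individual_id\tphenotype",
             sprintf("%s\t%s", d$individual_ids,
                     fmt_num(as.numeric(d$phenotypes))))
  paths <- paste0(out_prefix, c(".geno.tsv", ".pheno.tsv"))
  write_lf(c(header, body), paths[1]); write_lf(pheno, paths[2])
  invisible(paths)
}

#' Read back a TSV genotype/phenotype pair
#'
#' Inverse of [write_tsv()] for round-trip checks and downstream analysis in
#' R: reconstructs the genotype matrix (class inferred from the codes),
#' base-pair positions, identifiers and phenotypes.
#'
#' @param prefix the prefix passed to [write_tsv()].
#' @param kind phenotype kind of the stored trait.
#' @return a [gwas_dataset()].
#' @export
read_tsv_dataset <- function(prefix, kind = c("quantitative", "case_control")) {
  kind <- match.arg(kind)
  g <- utils::read.delim(paste0(prefix, ".geno.tsv"), check.names = FALSE)
  p <- utils::read.delim(paste0(prefix, ".pheno.tsv"))
  ids <- g$individual_id
  codes <- as.matrix(g[, -1L, drop = FALSE])
  cols <- colnames(codes)
  bp <- as.integer(sub(".*_", "", cols))
  marker_ids <- sub("_[0-9]+$", "", cols)
  dimnames(codes) <- NULL
  geno <- if (length(codes) && any(codes == -1L)) {
    genotype_matrix(codes, bp, position_unit = "bp")
  } else if (all(codes %in% 0:1)) {
    haplotype_matrix(codes, bp, position_unit = "bp")
  } else {
    genotype_matrix(codes, bp, position_unit = "bp")
  }
  gwas_dataset(geno, phenotype_vector(p$phenotype, kind),
               marker_ids = marker_ids, individual_ids = ids)
}
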