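#' Simulation run configuration
#'
#' Declarative description of one end-to-end run: where the genotypes come
#' from, which trait model to attach, how to subsample, and what to write.
#' Validation enforces the model's mutual exclusivity (a quantitative trait
#' has `effects`, a case/control trait has a `penetrance` table) and the
#' heritability bound `sum(effects) + epistatic_effect < 1`.
#'
#' @param input_path path to the genotype file (`ms` or `genome` dialects);
#'   ignored for `input_dialect = "fixture"`.
#' @param input_dialect `"ms"`, `"genome"`, or `"fixture"` (generate
#'   genotypes internally with [generate_fixture()]).
#' @param trait_kind `"quantitative"` or `"case_control"`.
#' @param ploidy `"haploid"` or `"diploid"` (diploids are formed by pairing
#'   consecutive chromosomes).
#' @param effects numeric vector of QTN variance proportions (quantitative
#'   traits); its length sets the number of QTNs.
#' @param epistatic_effect epistatic variance proportion between exactly two
#'   QTNs (quantitative traits), default 0.
#' @param dominance logical dominance flag (diploid quantitative traits).
#' @param penetrance penetrance table (case/control traits); shape as in
#'   [penetrance_model()], which also sets the number of causal loci.
#' @param freq_range optional allele-frequency range for causal-site
#'   selection.
#' @param fixed_sites optional causal site indices to use verbatim.
#' @param haploblock_constraint logical; place the two QTNs on a common
#'   four-gamete haploblock.
#' @param min_cases,n_controls case/control ascertainment (see
#'   [ascertain_case_control()]).
#' @param n_markers,n_individuals,remove_causal subsampling (see
#'   [subsample()]).
#' @param locus_length_bp locus length for bp conversion of fractional
#'   positions (default 1e6).
#' @param fixture_chromosomes,fixture_sites,fixture_freq fixture-generator
#'   settings when `input_dialect = "fixture"`.
#' @param formats subset of `c("ped", "tped", "emma", "tsv")`.
#' @param out_prefix output path prefix; replicate `r` writes
#'   `<out_prefix>_rep<r>.*`.
#' @param seed root seed; all stage streams derive from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_path = NULL,
                       input_dialect = c("ms", "genome", "fixture"),
                       trait_kind = c("quantitative", "case_control"),
                       ploidy = c("haploid", "diploid"),
                       effects = NULL, epistatic_effect = 0,
                       dominance = FALSE, penetrance = NULL,
                       freq_range = NULL, fixed_sites = NULL,
                       haploblock_constraint = FALSE,
                       min_cases = NULL, n_controls = NULL,
                       n_markers = NULL, n_individuals = NULL,
                       remove_causal = FALSE, locus_length_bp = 1e6,
                       fixture_chromosomes = 400, fixture_sites = 200,
                       fixture_freq = NULL,
                       formats = "tsv", out_prefix = "coalpheno_out",
                       seed = 1L) {
  input_dialect <- match.arg(input_dialect)
  trait_kind <- match.arg(trait_kind)
  ploidy <- match.arg(ploidy)
  formats <- match.arg(formats, c("ped", "tped", "emma", "tsv"),
                       several.ok = TRUE)
  if (trait_kind == "quantitative") {
    if (is.null(effects) || length(effects) < 1L) {
      stop("a quantitative trait requires `effects` (one entry per QTN)")
    }
    if (!is.null(penetrance)) {
      stop("`penetrance` is for case/control traits; use `effects` here")
    }
    if (sum(effects) + epistatic_effect >= 1) {
      stop("sum(effects) + epistatic_effect must be < 1 (heritability bound)")
    }
    if (epistatic_effect > 0 && length(effects) != 2L) {
      stop("an epistatic effect requires exactly two QTNs")
    }
  } else {
    if (is.null(penetrance)) {
      stop("a case/control trait requires a `penetrance` table")
    }
    if (!is.null(effects)) {
      stop("`effects` is for quantitative traits; use `penetrance` here")
    }
  }
  if (input_dialect != "fixture" && is.null(input_path)) {
    stop("input_path is required unless input_dialect = 'fixture'")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a key-value text file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Comma-separated values become vectors; penetrance tables are given
#' row-wise as a comma list (its length determines the shape). Keys mirror
#' the arguments of [run_config()]. Values given in `overrides` (e.g. from
#' command-line flags) win over the file.
#'
#' @param path config file path.
#' @param overrides named list of values overriding the file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) {
    stop(sprintf("malformed config line: %s", bad[1L]))
  }
  args <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
  args <- lapply(args, parse_config_value)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  if (!is.null(args$penetrance)) {
    args$penetrance <- shape_penetrance(args$penetrance,
                                        args$ploidy %||% "haploid")
  }
  unknown <- setdiff(names(args), names(formals(run_config)))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, args)
}

parse_config_value <- function(v) {
  parts <- trimws(strsplit(v, ",")[[1L]])
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  low <- tolower(parts)
  if (all(low %in% c("true", "false"))) return(low == "true")
  parts
}

# A flat comma list read from a config file becomes a penetrance table:
# length 2/3 stays a vector; length 4/9 becomes a row-wise square matrix.
shape_penetrance <- function(flat, ploidy) {
  g <- if (identical(ploidy, "diploid")) 3L else 2L
  if (length(flat) == g) return(flat)
  if (length(flat) == g * g) {
    return(matrix(flat, g, g, byrow = TRUE))
  }
  stop(sprintf("penetrance table for %s must have %d (one-locus) or %d (two-locus) entries",
               ploidy, g, g * g))
}

#' Run the simulation pipeline
#'
#' Executes, per replicate of the input: parse (or generate) haplotypes,
#' pair diploids if required, select causal sites, generate the phenotype on
#' the full population, subsample markers and individuals (with optional
#' causal-marker removal and case/control ascertainment), and write every
#' requested output format as `<out_prefix>_rep<r>.*`. A run manifest
#' (`<out_prefix>_manifest.json`) records the seed, realized causal
#' positions and frequencies, case counts and MD5 checksums of every output
#' file; identical configuration and seed reproduce identical checksums.
#'
#' A stage failure aborts that replicate with a stage-named diagnostic; the
#' run fails only when every replicate fails.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the manifest (also written as JSON).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  reps <- switch(cfg$input_dialect,
    ms = parse_ms(cfg$input_path)$replicates,
    genome = parse_genome(cfg$input_path)$replicates,
    fixture = list(generate_fixture(cfg$fixture_chromosomes, cfg$fixture_sites,
                                    cfg$fixture_freq,
                                    seed = derive_seed(cfg$seed, 1)))
  )

  manifest <- list(seed = cfg$seed, trait_kind = cfg$trait_kind,
                   ploidy = cfg$ploidy, n_replicates = length(reps),
                   replicates = list())
  failures <- character(0)

  for (r in seq_along(reps)) {
    rep_seed <- derive_seed(cfg$seed, 10 + r)
    entry <- tryCatch(
      run_one_replicate(cfg, reps[[r]], r, rep_seed),
      error = function(e) {
        msg <- sprintf("replicate %d: %s", r, conditionMessage(e))
        message(msg)
        structure(list(error = msg), class = "replicate_failure")
      }
    )
    if (inherits(entry, "replicate_failure")) {
      failures <- c(failures, entry$error)
      manifest$replicates[[r]] <- list(replicate = r, error = entry$error)
    } else {
      manifest$replicates[[r]] <- entry
    }
  }

  if (length(failures) == length(reps)) {
    stop(sprintf("all %d replicate(s) failed; first failure: %s",
                 length(reps), failures[1L]))
  }
  manifest_path <- paste0(cfg$out_prefix, "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

run_one_replicate <- function(cfg, hap, r, rep_seed) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  m <- if (cfg$ploidy == "diploid") {
    stage("pair_diploids", pair_diploids(hap))
  } else hap

  n_causal <- if (cfg$trait_kind == "quantitative") {
    length(cfg$effects)
  } else {
    if (is.matrix(cfg$penetrance)) 2L else 1L
  }
  qtns <- stage("select_qtns", select_qtns(
    hap, n_causal,
    effects = if (cfg$trait_kind == "quantitative") cfg$effects else rep(0, n_causal),
    freq_range = cfg$freq_range, fixed_sites = cfg$fixed_sites,
    require_common_haploblock = cfg$haploblock_constraint,
    seed = derive_seed(rep_seed, 1)
  ))

  phen <- stage("phenotype", {
    if (cfg$trait_kind == "quantitative") {
      model <- quant_trait_model(qtns, cfg$epistatic_effect, cfg$dominance,
                                 cfg$ploidy)
      generate_quantitative(m, model, seed = derive_seed(rep_seed, 2))
    } else {
      model <- penetrance_model(cfg$penetrance, qtns$site, cfg$ploidy)
      assign_case_control(m, model, seed = derive_seed(rep_seed, 2))
    }
  })

  plan <- sample_plan(n_markers = cfg$n_markers,
                      n_individuals = cfg$n_individuals,
                      remove_causal = cfg$remove_causal,
                      min_cases = cfg$min_cases, n_controls = cfg$n_controls,
                      seed = derive_seed(rep_seed, 3))
  idx <- if (cfg$trait_kind == "case_control" && !is.null(cfg$min_cases)) {
    stage("ascertainment", ascertain_case_control(phen, plan))
  } else NULL
  sub <- stage("subsample", subsample(m, phen, qtns, plan,
                                      individual_indices = idx))

  d <- stage("dataset", gwas_dataset(sub$genotypes, sub$phenotypes,
                                     locus_length_bp = cfg$locus_length_bp))
  prefix <- sprintf("%s_rep%d", cfg$out_prefix, r)
  files <- character(0)
  for (fmt in cfg$formats) {
    files <- c(files, stage(paste0("write_", fmt), switch(fmt,
      ped = write_plink_ped_map(d, prefix),
      tped = write_tped_tfam(d, prefix),
      emma = write_emma(d, prefix),
      tsv = write_tsv(d, prefix)
    )))
  }

  list(
    replicate = r,
    seed = rep_seed,
    causal_sites = qtns$site,
    causal_positions_bp = positions_to_bp_safe(hap, qtns$site, cfg$locus_length_bp),
    causal_frequencies = qtns$derived_freq,
    n_individuals = length(sub$phenotypes),
    n_markers = site_count(sub$genotypes),
    n_cases = if (cfg$trait_kind == "case_control") {
      sum(as.numeric(sub$phenotypes))
    } else NULL,
    retained_causal_columns = sub$qtn_sites,
    files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  )
}

positions_to_bp_safe <- function(hap, sites, locus_length_bp) {
  pos <- hap$positions[sites]
  if (hap$position_unit == "bp") {
    as.integer(round(pos))
  } else {
    as.integer(floor(pos * as.numeric(locus_length_bp) + 0.5))
  }
}
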