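# End-to-end orchestration on simulated (or pre-simulated) data: generate ->
# phase -> syntelogs/Ks -> fractionation -> tandem/enrichment -> B chromosome
# -> ploidy -> diversity, collated into one report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a simulated allopolyploid
#'
#' Simulates a genome, B chromosome and observations from `config`, then runs
#' every analysis stage in dependency order and collates a single report:
#' subgenome assignment, Ks modes and a dated divergence, retention counts
#' and loss-bias tests, tandem arrays and term enrichment (against a seeded
#' toy term map), B copy ratio and origin fraction, the MAF ploidy call, and
#' the piN/piS summary. Every quantity in the report is a pure function of
#' (config, seed); the report records both plus a config hash.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, the report is written as
#'   JSON and Markdown and the simulated inputs as FASTA/GFF3/BED/TSV.
#' @param k,min_total,min_fold phasing parameters (see
#'   [select_differential_kmers()]).
#' @param min_block syntelog block threshold.
#' @param window_genes,step_genes retention-profile window (desk-scale
#'   defaults; field data would use 100/10).
#' @param max_gap tandem-array gap threshold.
#' @param coverage_window B copy-number window width (bp).
#' @param calibration_ks,calibration_t calibration anchor: a Ks peak of known
#'   age (defaults: the grass rho duplication, Ks 0.453 at 70 My, which dates
#'   a Ks of 0.2 to ~30.9 My).
#' @param maf_min_total,maf_max_total,maf_min_minor,maf_min_sites MAF filter
#'   settings (see [filter_sites()]; `maf_min_sites` is lowered to suit
#'   desk-scale site counts).
#' @param n_terms toy term-map size for the enrichment demonstration.
#' @return report list (class `pipeline_report`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         k = 13L, min_total = 100, min_fold = 2,
                         min_block = 5L,
                         window_genes = 20L, step_genes = 5L,
                         max_gap = 10L, coverage_window = 1000L,
                         calibration_ks = 0.453, calibration_t = 70e6,
                         maf_min_total = 20L, maf_max_total = 200L,
                         maf_min_minor = 8L, maf_min_sites = 50L,
                         n_terms = 15L) {
  stopifnot(inherits(config, "sim_config"))

  sim <- .stage("simulate", simulate_allopolyploid(config))
  genome <- sim$genome
  truth <- sim$truth
  bsim <- .stage("simulate_b", simulate_b_chromosome(genome, config))
  genome <- bsim$genome
  obs <- .stage("simulate_observations", simulate_observations(genome, config))

  # --- phasing ----------------------------------------------------------
  phasing <- .stage("phase", {
    main <- genome$chromosomes[setdiff(names(genome$chromosomes), bsim$truth$b_name)]
    km <- count_kmers(main, k = k)
    diff_km <- select_differential_kmers(km, truth$pairing,
                                         min_total = min_total, min_fold = min_fold)
    assign_subgenomes(diff_km, truth$pairing)
  })
  true_labels <- stats::setNames(
    c(truth$pairing$label1, truth$pairing$label2),
    c(truth$pairing$member1, truth$pairing$member2)
  )

  # --- syntelogs and Ks dating -----------------------------------------
  genes_a <- genome$genes[genome$genes$subgenome == "A", ]
  genes_d <- genome$genes[genome$genes$subgenome == "D", ]
  pairs <- .stage("syntelogs", find_syntelogs(genes_a, genes_d, min_block = min_block))
  pairs <- .stage("ks", syntelog_ks(pairs, genome))
  ksd <- .stage("ks_modes", ks_modes(pairs$ks))
  clock <- calibrate(calibration_ks, calibration_t)
  age <- date_divergence(clock, primary_mode(ksd))

  # --- fractionation ----------------------------------------------------
  fract <- .stage("fractionation", {
    anc <- truth$syntelogs[, c("ancestor", "chrom_pair")]
    names(anc) <- c("id", "chrom")
    nontandem <- genome$genes[!genome$genes$tandem, ]
    retained_a <- nontandem$ancestor[nontandem$subgenome == "A"]
    retained_d <- nontandem$ancestor[nontandem$subgenome == "D"]
    ret <- build_retention(anc$id, retained_a, retained_d)
    test <- loss_bias_test(ret$aggregates$a_only, ret$aggregates$d_only,
                           both = ret$aggregates$both)
    prof <- retention_windows(ret, anc, window = window_genes, step = step_genes)
    list(retention = ret, test = test, profile = prof)
  })

  # --- tandem duplication and enrichment -------------------------------
  dup <- .stage("duplication", {
    arrays <- find_tandem_arrays(genome$genes, max_gap = max_gap)
    tandem_genes <- unique(unlist(strsplit(arrays$members, ",")))
    population <- genome$genes$id
    set.seed(config$seed + 3L)
    fams <- unique(genome$genes$family)
    term_map <- lapply(seq_len(n_terms), function(i) {
      f <- sample(fams, max(2L, round(length(fams) / n_terms)))
      genome$genes$id[genome$genes$family %in% f]
    })
    names(term_map) <- sprintf("TERM%03d", seq_len(n_terms))
    enr <- if (length(tandem_genes) >= 2L) {
      go_enrichment(tandem_genes, population, term_map)
    } else NULL
    list(arrays = arrays, tandem_genes = tandem_genes, enrichment = enr)
  })

  # --- B chromosome -----------------------------------------------------
  bchrom <- .stage("bchrom", {
    track <- window_coverage(obs$coverage, genome$masks, window = coverage_window)
    ratio <- b_copy_ratio(track, bsim$truth$b_name)
    trace <- trace_origins(genome$chromosomes[[bsim$truth$b_name]],
                           genome, b_name = bsim$truth$b_name)
    list(track = track, ratio = ratio, trace = trace)
  })

  # --- ploidy -----------------------------------------------------------
  ploidy <- .stage("ploidy", {
    flt <- filter_sites(obs$allele_depth, min_total = maf_min_total,
                        max_total = maf_max_total, min_minor = maf_min_minor)
    maf_profile(flt, min_sites = maf_min_sites)
  })

  # --- diversity --------------------------------------------------------
  div <- .stage("diversity", {
    eff <- annotate_effects(obs$allele_depth, genome)
    pi_by_class(eff, genome)
  })

  report <- structure(list(
    seed = config$seed,
    config_hash = .config_hash(config),
    phasing = list(
      assignment = phasing$assignment,
      n_diagnostic_kmers = nrow(phasing$diagnostic_kmers),
      matches_truth = assignment_matches_truth(phasing, true_labels)
    ),
    ks = list(
      n_pairs = nrow(pairs),
      modes = ksd$modes,
      primary_mode = primary_mode(ksd),
      calibration = list(ks = calibration_ks, t_years = calibration_t,
                         rate = clock$rate),
      divergence_years = age
    ),
    fractionation = list(
      aggregates = fract$retention$aggregates,
      chi2 = fract$test$chi2, p = fract$test$p,
      mean_window_frac_a = mean(fract$profile$frac_a),
      mean_window_frac_d = mean(fract$profile$frac_d)
    ),
    duplication = list(
      n_arrays = nrow(dup$arrays),
      n_tandem_genes = length(dup$tandem_genes),
      top_terms = if (!is.null(dup$enrichment)) {
        utils::head(dup$enrichment[, c("term", "p", "p_fdr")], 3L)
      } else NULL
    ),
    bchrom = list(
      copy_ratio = bchrom$ratio$ratio,
      interpretation = bchrom$ratio$interpretation,
      origin_fraction = bchrom$trace$fraction,
      n_fragments = bchrom$trace$n_fragments
    ),
    ploidy = list(
      mode = ploidy$mode, call = ploidy$call, n_sites = ploidy$n_sites
    ),
    diversity = list(
      pi_nonsyn = div$pi_nonsyn, pi_syn = div$pi_syn, ratio = div$ratio
    )
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_genome(genome, out_dir)
    write_allele_depth(obs$allele_depth, file.path(out_dir, "allele_depth.tsv"))
    write_coverage(obs$coverage, file.path(out_dir, "coverage.tsv"))
    jsonlite::write_json(.report_json(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    writeLines(format(report), file.path(out_dir, "report.md"))
  }
  report
}

.report_json <- function(report) {
  r <- unclass(report)
  r$phasing$assignment <- as.list(r$phasing$assignment)
  r
}

#' @export
format.pipeline_report <- function(x, ...) {
  c(
    "# Allopolyploid pipeline report",
    "",
    sprintf("- seed: %d, config hash: %s", x$seed, x$config_hash),
    sprintf("- phasing: %d chromosomes, matches truth: %s",
            nrow(x$phasing$assignment), x$phasing$matches_truth),
    sprintf("- Ks: %d syntelog pairs, primary mode %.3f, dated %.3g My",
            x$ks$n_pairs, x$ks$primary_mode, x$ks$divergence_years / 1e6),
    sprintf("- fractionation: both %d / A-only %d / D-only %d / neither %d; chi2 = %.2f (p = %.3g)",
            x$fractionation$aggregates$both, x$fractionation$aggregates$a_only,
            x$fractionation$aggregates$d_only, x$fractionation$aggregates$neither,
            x$fractionation$chi2, x$fractionation$p),
    sprintf("- tandem: %d arrays, %d duplicate genes",
            x$duplication$n_arrays, x$duplication$n_tandem_genes),
    sprintf("- B chromosome: coverage ratio %.2f; origin fraction %.3f (%d fragments)",
            x$bchrom$copy_ratio, x$bchrom$origin_fraction, x$bchrom$n_fragments),
    sprintf("- ploidy: MAF mode %.3f -> %s (%d sites)",
            x$ploidy$mode, x$ploidy$call, x$ploidy$n_sites),
    sprintf("- diversity: piN %.5f / piS %.5f = %.2f",
            x$diversity$pi_nonsyn, x$diversity$pi_syn, x$diversity$ratio)
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
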