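#' Pipeline configuration
#'
#' Single validated configuration block for the end-to-end synthetic run.
#' Unknown keys are rejected; the fully resolved configuration is echoed
#' into the run manifest. The default genome is a desk-scale stand-in for a
#' 12-Mb yeast genome: twelve chromosomes of 0.12-0.42 Mb (3.6 Mb total) at
#' 0.7\% marker density, with the smallest chromosome carrying the
#' subtelomeric structural locus, as in the organism.
#'
#' @param ... overrides of the defaults listed below.
#' @return a validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    chrom_lengths = c(chrI = 120000, chrII = 320000, chrIII = 280000,
                      chrIV = 360000, chrV = 300000, chrVI = 260000,
                      chrVII = 340000, chrVIII = 220000, chrIX = 420000,
                      chrX = 380000, chrXI = 300000, chrXII = 300000),
    snv_density = 0.007,
    motif = "TCGA",
    n_mutants = 30,
    events_per_mutant = 4,
    selection_threshold = 0.2,
    mean_depth = 50,
    dispersion = 1,
    junction_support_rate = 0.3,
    false_junction_rate = 0.5,
    window_size = 10000,
    aggregation_cutoff = 0.9,
    alpha = 0.05,
    n_decoy_genes = 30,
    passage_cycles = 20,
    passage_pop = 100,
    passage_clones = 18,
    seed = 1)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_taqmap("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  assert_scalar_number(cfg$snv_density, "snv_density", 0, 0.05,
                       strict_upper = TRUE)
  assert_scalar_number(cfg$mean_depth, "mean_depth", 0, Inf,
                       strict_lower = TRUE)
  assert_scalar_number(cfg$alpha, "alpha", 0, 1, strict_lower = TRUE)
  assert_scalar_number(cfg$window_size, "window_size", 1000, Inf)
  if (cfg$n_mutants < 1)
    stop_taqmap("n_mutants must be >= 1 (got %s)", cfg$n_mutants)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full synthetic mapping experiment
#'
#' Executes simulate -> call -> map -> phenotype on synthetic data: builds
#' the hybrid genome, draws the selected mutant cohort, simulates evidence,
#' calls and classifies events per mutant, aggregates windowed homozygosity
#' into a hotspot report with candidate genes, tabulates aneuploidy
#' frequencies, runs the serial-passage arm, and (when \code{out} is given)
#' writes every artifact plus a provenance manifest. Identical config and
#' seed give identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out optional output directory; when NULL nothing is written.
#' @param quiet suppress stage messages.
#' @return list of class \code{taq_run}: genome, cohort, calls (per
#'   mutant), hotspots (\code{hotspot_report}), candidates, aneuploidy,
#'   passage, annotation, config.
#' @export
run_all <- function(config = pipeline_config(), out = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  seed <- config$seed

  say("[1/6] genome: %d chromosome(s)", length(config$chrom_lengths))
  genome <- build_hybrid_genome(config$chrom_lengths, config$snv_density,
                                config$motif, seed = derive_seed(seed, 1))
  model <- default_phenotype_model(genome)

  say("[2/6] cohort: selecting %d mutants", config$n_mutants)
  cohort <- simulate_taq_cohort(
    genome, model, n_mutants = config$n_mutants,
    events_per_mutant = config$events_per_mutant,
    selection_threshold = config$selection_threshold,
    seed = derive_seed(seed, 2))

  say("[3/6] evidence + caller: %d mutants", config$n_mutants)
  evidence <- simulate_cohort_evidence(
    cohort, seed = derive_seed(seed, 3), mean_depth = config$mean_depth,
    dispersion = config$dispersion,
    junction_support_rate = config$junction_support_rate,
    false_junction_rate = config$false_junction_rate,
    window_size = config$window_size)
  calls <- lapply(evidence, call_events, sites = genome$sites)

  say("[4/6] hotspot mapping")
  wstats <- lapply(calls, function(cl)
    window_homozygosity(cl$marker_calls, genome$chromosomes,
                        config$window_size))
  segs <- lapply(calls, `[[`, "segments")
  agg <- aggregate_cohort(wstats, config$aggregation_cutoff, segments = segs)
  hotspots <- test_hotspots(agg, alpha = config$alpha)
  annotation <- model_gene_annotation(genome, model, config$n_decoy_genes,
                                      seed = derive_seed(seed, 4))
  candidates <- candidate_genes(hotspots, annotation)
  aneu <- aneuploidy_frequency(lapply(calls, `[[`, "events"),
                               genome$chromosomes)

  say("[5/6] serial-passage arm: %d cycles", config$passage_cycles)
  passage <- simulate_serial_passage(
    cycles = config$passage_cycles, n_pop = config$passage_pop,
    n_clones = config$passage_clones, seed = derive_seed(seed, 5))

  res <- structure(list(genome = genome, model = model, cohort = cohort,
                        calls = calls, window_stats = wstats,
                        aggregate = agg, hotspots = hotspots,
                        candidates = candidates, aneuploidy = aneu,
                        passage = passage, annotation = annotation,
                        config = config),
                   class = "taq_run")

  if (!is.null(out)) {
    say("[6/6] writing report to %s", out)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_genome(genome, file.path(out, "genome"))
    for (i in seq_along(evidence))
      write_evidence(evidence[[i]], file.path(out, sprintf("m%03d", i)))
    for (i in seq_along(calls))
      write_events(calls[[i]]$events, file.path(out, sprintf("m%03d_events", i)))
    truth_all <- do.call(rbind, lapply(seq_along(cohort$mutants), function(i)
      cbind(mutant = i, truth_events_df(cohort$mutants[[i]]))))
    write.table(truth_all, file.path(out, "truth_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(hotspots$windows, file.path(out, "hotspot_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(hotspots$hotspots, file.path(out, "hotspots.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(candidates, file.path(out, "candidate_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(aneu, file.path(out, "aneuploidy_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mutation_table(passage), file.path(out, "passage_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("rtracklayer", quietly = TRUE))
      write_genes_gff3(annotation, file.path(out, "genes.gff3"))
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          "manifest.json"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("taqmap")),
      seed = seed,
      config = unclass(config),
      checksums = as.list(tools::md5sum(file.path(out, files))))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.taq_run <- function(x, ...) {
  cat("taq_run\n")
  print(x$cohort)
  cat(sprintf("  hotspot intervals: %d; candidate genes: %d\n",
              nrow(x$hotspots$hotspots), nrow(x$candidates)))
  causal <- x$candidates$gene[x$candidates$gene %in%
                                x$annotation$gene[x$annotation$causal]]
  cat(sprintf("  causal genes recovered: %s\n",
              if (length(causal)) paste(causal, collapse = ", ") else "none"))
  invisible(x)
}
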