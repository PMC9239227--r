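# End-to-end pipeline orchestration: synthetic data -> gas calculus ->
# community statistics -> regime scan, with fail-fast configuration
# validation and a machine-readable summary.

#' Load and validate a pipeline configuration
#'
#' The configuration is a JSON document (or an equivalent R list) with
#' optional stage blocks `synth`, `gas`, `community` and `regime`; each block
#' carries the stage's parameters (including a `seed` where the stage is
#' stochastic). Validation is fail-fast: every error is reported before any
#' stage runs, and referenced input files must exist at load time.
#'
#' @param config path to a JSON file, or a list.
#' @return The validated configuration (class `PipelineConfig`).
#' @export
loadPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a list or a JSON file path")

  errors <- character(0)
  addErr <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  known <- c("synth", "gas", "community", "regime", "seed", "verbosity")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    addErr("unknown config blocks: %s", paste(unknown, collapse = ", "))

  if (!is.null(config$community)) {
    cm <- config$community
    for (p in c("counts_path", "meta_path", "ddpcr_path")) {
      if (!is.null(cm[[p]]) && !file.exists(cm[[p]]))
        addErr("community$%s does not exist: %s", p, cm[[p]])
    }
    needs_ddpcr <- is.null(config$synth) && is.null(cm$ddpcr_path)
    if (needs_ddpcr)
      addErr(paste0("community stage needs ddPCR totals: provide ",
                    "community$ddpcr_path or enable the synth stage"))
    if (is.null(config$synth) && is.null(cm$counts_path))
      addErr("community stage needs counts: provide community$counts_path or enable synth")
    thr <- cm$threshold_high %||% 2
    if (!is.numeric(thr)) addErr("community$threshold_high must be numeric")
  }
  if (!is.null(config$regime)) {
    rg <- config$regime
    if (!is.null(rg$ratios) && (!is.numeric(rg$ratios) || any(rg$ratios <= 0)))
      addErr("regime$ratios must be positive numbers")
  }
  if (!is.null(config$synth)) {
    sp <- config$synth
    bad <- setdiff(names(sp), c(names(formals(communitySpec)), "enabled"))
    if (length(bad) > 0)
      addErr("unknown synth parameters: %s", paste(bad, collapse = ", "))
  }
  if (!is.null(config$gas)) {
    gs <- config$gas
    bad <- setdiff(names(gs), c(names(formals(gasSimSpec)), "gas_path",
                                "initial_N_oxyanions", "recovery_fractions",
                                "enabled"))
    if (length(bad) > 0)
      addErr("unknown gas parameters: %s", paste(bad, collapse = ", "))
    if (!is.null(gs$gas_path) && !file.exists(gs$gas_path))
      addErr("gas$gas_path does not exist: %s", gs$gas_path)
  }

  if (length(errors) > 0)
    stopf("invalid pipeline config:\n  - %s", paste(errors, collapse = "\n  - "))
  structure(config, class = c("PipelineConfig", "list"))
}

logMsg <- function(verbosity, fmt, ...) {
  if (verbosity > 0) message(sprintf(paste0("[dualenrich] ", fmt), ...))
}

#' Run the configured pipeline
#'
#' Executes the enabled stages in dependency order (synth -> gas ->
#' community -> regime), writes per-stage TSV outputs into `out_dir` and a
#' JSON summary (`summary.json`) containing the key quantities of each stage
#' plus the fully resolved configuration for provenance.
#'
#' @param config a configuration accepted by [loadPipelineConfig()].
#' @param out_dir output directory, created if needed.
#' @return The summary list, invisibly; side effect: files under `out_dir`.
#' @export
runPipeline <- function(config, out_dir) {
  config <- loadPipelineConfig(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verb <- config$verbosity %||% 1
  summary <- list(config = unclass(config))
  experiment <- NULL

  if (!is.null(config$synth)) {
    logMsg(verb, "stage synth: generating enrichment dataset")
    args <- config$synth[names(config$synth) %in% names(formals(communitySpec))]
    spec <- do.call(communitySpec, args)
    ds <- generateEnrichmentDataset(spec)
    experiment <- ds$experiment
    writeOTUTableTSV(experiment,
                     file.path(out_dir, "otu_counts.tsv"),
                     file.path(out_dir, "sample_meta.tsv"),
                     file.path(out_dir, "ddpcr_totals.tsv"))
    utils::write.table(ds$truth, file.path(out_dir, "truth_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$synth <- list(n_otus = nrow(experiment),
                          n_samples = ncol(experiment),
                          truth_census = as.list(table(ds$truth$category)))
  }

  if (!is.null(config$gas)) {
    logMsg(verb, "stage gas: kinetics calculus")
    gs <- config$gas
    if (!is.null(gs$gas_path)) {
      series <- readGasSeriesTSV(gs$gas_path)
      vial <- vialSpec()
    } else {
      args <- gs[names(gs) %in% names(formals(gasSimSpec))]
      gspec <- do.call(gasSimSpec, args)
      sim <- generateGasSeries(gspec)
      series <- sim$series
      vial <- gspec$vial
      writeGasSeriesTSV(series, file.path(out_dir, "gas_raw.tsv"))
    }
    corr <- correctSeries(series, vial)
    rates <- data.frame(time_h = corr@times[-1], t(corr@rates),
                        check.names = FALSE)
    utils::write.table(rates, file.path(out_dir, "gas_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- tryCatch(twoPopulationFit(corr@times[-1], corr@rates["N2-N", ]),
                    error = function(e) NULL)
    summary$gas <- list(
      cumulative_N2 = unname(corr@cumulative_production["N2-N", ncol(corr@cumulative_production)]),
      two_population_fit = if (!is.null(fit)) list(
        rate_decline = fit@rate_decline, rate_growth = fit@rate_growth,
        amplitude_decline = fit@amplitude_decline,
        amplitude_growth = fit@amplitude_growth) else NULL)
    if (!is.null(gs$initial_N_oxyanions)) {
      fracs <- gs$recovery_fractions %||% c(0.40, 1.00)
      summary$gas$I_N2O <- lapply(setNames(fracs, paste0("recovery_", 100 * fracs)),
                                  function(fr) tryCatch(
                                    iN2O(corr, gs$initial_N_oxyanions, fr),
                                    error = function(e) NA_real_))
    }
  }

  if (!is.null(config$community)) {
    logMsg(verb, "stage community: OTU statistics")
    cm <- config$community
    if (!is.null(cm$counts_path)) {
      experiment <- readOTUTableTSV(cm$counts_path, cm$meta_path, cm$ddpcr_path)
    }
    if (is.null(experiment))
      stopf("community stage has no input (no synth stage and no counts_path)")
    rare <- rarefySamples(experiment, depth = cm$depth %||% 9000,
                          seed = cm$seed %||% 1L)
    ratios <- enrichmentRatios(rare, f = cm$transfer_fraction %||% 0.1)
    niche <- classifyNiche(ratios, threshold_high = cm$threshold_high %||% 2,
                           threshold_low = cm$threshold_low %||% 0)
    clades <- clusterClades(rare, top_n = cm$top_n %||% 500,
                            n_clades = cm$n_clades %||% 6)
    utils::write.table(niche, file.path(out_dir, "niche_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clade_df <- data.frame(otu_id = names(cladeAssignments(clades)),
                           clade = as.character(cladeAssignments(clades)))
    utils::write.table(clade_df, file.path(out_dir, "clades.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$community <- list(
      n_samples_rarefied = ncol(rare),
      dropped_samples = attr(rare, "dropped"),
      niche_census = as.list(table(niche$category)),
      clade_sizes = as.list(table(cladeAssignments(clades))))
  }

  if (!is.null(config$regime)) {
    logMsg(verb, "stage regime: competition-outcome scan")
    rg <- config$regime
    ratios <- rg$ratios %||% seq(0.2, 0.6, by = 0.1)
    prot <- defaultProtocol(n_passages = as.integer(rg$n_passages %||% 25L))
    res <- regimeScan(prot, defaultTraitsTemplate(), ratios)
    regime_df <- data.frame(ratio = res@ratio_grid, outcome = res@outcome,
                            passages = res@passages_to_dominance)
    utils::write.table(regime_df, file.path(out_dir, "regime.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$regime <- list(critical_ratio = res@critical_ratio,
                           outcomes = as.list(table(res@outcome)))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  logMsg(verb, "done: %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}
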