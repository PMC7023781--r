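#' Read a pipeline configuration file
#'
#' YAML with top-level keys `seed`, `outdir`, `stages`, and optional blocks
#' `design`, `hmm`, `filters`, `windows`, `crossovers_csv`, `te_bed`.
#' Omitted fields fall back to package defaults.
#'
#' @param path YAML path.
#' @return Config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a raw config list.
#' @export
as_pipeline_config <- function(cfg) {
  defaults <- list(seed = 1L, outdir = "dysrec_out",
                   stages = c("simulate", "genotype", "call", "map",
                              "clusters", "fit"),
                   windows = list(map_window = 500e3, cluster_window = 100e3,
                                  min_progeny = 4L))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$windows <- utils::modifyList(defaults$windows, as.list(cfg$windows))
  num_vec <- function(x) {  # YAML floats like "2.0e7" arrive as strings
    v <- unlist(x)
    stats::setNames(as.numeric(v), names(v))
  }
  if (!inherits(cfg$design, "study_design")) {
    dargs <- if (is.null(cfg$design)) list() else cfg$design
    for (k in c("chromosomes", "n_mothers", "alpha", "beta", "mode_weights"))
      if (!is.null(dargs[[k]])) dargs[[k]] <- num_vec(dargs[[k]])
    if (is.null(dargs$seed)) dargs$seed <- cfg$seed
    cfg$design <- do.call(study_design, dargs)
  }
  if (!inherits(cfg$hmm, "hmm_params"))
    cfg$hmm <- do.call(hmm_params, if (is.null(cfg$hmm)) list() else cfg$hmm)
  if (!inherits(cfg$filters, "filter_config")) {
    fargs <- if (is.null(cfg$filters)) list() else cfg$filters
    for (k in c("telomere_excl", "proximal_excl"))
      if (!is.null(fargs[[k]])) fargs[[k]] <- num_vec(fargs[[k]])
    if (is.null(fargs$min_reads) && "simulate" %in% cfg$stages) {
      # scale the published 10,000-read floor (~1/30 of mean sample reads)
      # to the simulated coverage
      expected <- cfg$design$coverage * cfg$design$n_markers *
        length(cfg$design$chromosomes)
      fargs$min_reads <- floor(expected / 30)
    }
    cfg$filters <- do.call(filter_config, fargs)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, genotype = 211L, call = 307L, map = 401L,
               clusters = 503L, fit = 601L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the analysis pipeline end to end
#'
#' Stages (in order): `simulate` (cohort simulation), `genotype` (ancestry
#' HMM), `call` (crossover calling + filters), `map` (genetic map and
#' windowed rates), `clusters` (sibling-cluster detection), `fit`
#' (mitotic-rate likelihood model with nested comparisons). Every stage
#' reads and writes plain-text files under `outdir`; reruns with the same
#' config are bit-identical. When `crossovers_csv` is set, the simulate /
#' genotype / call stages are skipped and the table is read instead.
#'
#' @param config a `pipeline_config`, a raw config list, or a YAML path.
#' @return Report list (also written to `report.json` / `report.md`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  report <- list(config_seed = config$seed, stages = stages)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  chrom_lengths <- config$design$chromosomes
  records <- samples <- posteriors <- study <- NULL
  n_gametes <- NULL

  if (!is.null(config$crossovers_csv)) {
    tab <- tryCatch(read_crossover_table(config$crossovers_csv),
                    error = function(e) fail("read", e))
    records <- tab$records; samples <- tab$samples
    n_gametes <- length(unique(samples$sample))
    stages <- setdiff(stages, c("simulate", "genotype", "call"))
    chroms_here <- sort(unique(tab$gametes$chrom))
  } else {
    chroms_here <- names(chrom_lengths)
  }

  if ("simulate" %in% stages) {
    study <- tryCatch(
      simulate_dataset(config$design, seed = stage_seed(config$seed, "simulate")),
      error = function(e) fail("simulate", e))
    samples <- study$samples
    data.table::fwrite(samples, file.path(outdir, "samples.csv"))
    write_marker_map(study$map, file.path(outdir, "marker_map.tsv"))
    cdt <- data.table::copy(study$counts)[, pos := round(pos) + 1]
    data.table::fwrite(cdt, file.path(outdir, "allele_counts.csv"))
    report$simulate <- list(n_samples = nrow(samples),
                            n_mothers = length(unique(samples$mother)),
                            n_true_mitotic = nrow(study$truth$mitotic))
  }

  if ("genotype" %in% stages) {
    if (is.null(study)) stop("genotype stage needs the simulate stage")
    posteriors <- tryCatch(
      ancestry_posteriors(study$counts, study$map, config$hmm,
                          samples = samples),
      error = function(e) fail("genotype", e))
    pout <- data.table::copy(posteriors)[, pos := round(pos) + 1]
    data.table::fwrite(pout, file.path(outdir, "posteriors.csv"))
    report$genotype <- list(n_tracks = nrow(unique(posteriors[, .(sample, chrom)])))
  }

  if ("call" %in% stages) {
    if (is.null(posteriors)) stop("call stage needs the genotype stage")
    kept_samples <- tryCatch(filter_samples(samples, config$filters),
                             error = function(e) fail("call", e))
    n_removed <- attr(kept_samples, "n_removed")
    raw <- call_all_crossovers(posteriors[sample %in% kept_samples$sample],
                               config$hmm)
    records <- filter_crossovers(raw, config$filters, chrom_lengths)
    samples <- kept_samples
    n_gametes <- nrow(samples)
    data.table::fwrite(
      data.table::copy(records)[, `:=`(start = round(start) + 1,
                                       end = round(end) + 1,
                                       mid = round(mid) + 1)],
      file.path(outdir, "crossover_intervals.csv"))
    write_crossover_table(records, samples,
                          file.path(outdir, "crossovers.csv"),
                          chromosomes = chroms_here)
    report$call <- list(samples_removed_reads = n_removed,
                        samples_kept = nrow(samples),
                        co_total = nrow(records),
                        co_kept = nrow(kept(records)),
                        removed_by_rule = as.list(table(records$status)))
  }

  if (is.null(n_gametes) && !is.null(samples))
    n_gametes <- length(unique(samples$sample))

  if ("map" %in% stages) {
    gl <- tryCatch({
      ml <- map_lengths(records, n_gametes, chromosomes = chroms_here)
      wr <- window_rates(records, n_gametes,
                         chrom_lengths[names(chrom_lengths) %in% chroms_here],
                         config$windows$map_window)
      list(ml = ml, wr = wr)
    }, error = function(e) fail("map", e))
    data.table::fwrite(gl$ml, file.path(outdir, "map.csv"))
    data.table::fwrite(gl$wr, file.path(outdir, "window_rates.csv"))
    dist <- co_count_distribution(records, samples, chromosomes = chroms_here,
                                  seed = stage_seed(config$seed, "map"))
    data.table::fwrite(dist, file.path(outdir, "co_count_distribution.csv"))
    report$map <- list(total_cM = attr(gl$ml, "total_cM"),
                       per_chrom = stats::setNames(gl$ml$cM, gl$ml$chrom))
  }

  clusters <- NULL
  if ("clusters" %in% stages) {
    clusters <- tryCatch(
      detect_clusters(records, samples, config$windows$cluster_window,
                      config$windows$min_progeny),
      error = function(e) fail("clusters", e))
    cl_out <- data.table::copy(clusters)
    if (nrow(cl_out)) {
      cl_out[, carriers := vapply(carriers, paste, "", collapse = ";")]
      cl_out[, `:=`(start = round(start) + 1, end = round(end) + 1)]
    }
    data.table::fwrite(cl_out, file.path(outdir, "clusters.csv"))
    report$clusters <- list(n = nrow(clusters),
                            by_condition = as.list(table(clusters$condition)))
  }

  if ("fit" %in% stages) {
    if (is.null(clusters)) stop("fit stage needs the clusters stage")
    est_chroms <- intersect(c("X", "3"), chroms_here)
    if (!length(est_chroms)) est_chroms <- chroms_here
    obs <- build_cohort_observations(clusters, samples, est_chroms)
    fits <- tryCatch(list(
      m2 = fit_mitotic(obs, model_spec("shared", "shared")),
      m3b = fit_mitotic(obs, model_spec("shared", "split")),
      m3a = fit_mitotic(obs, model_spec("split", "shared")),
      m4 = fit_mitotic(obs, model_spec("split", "split"))),
      error = function(e) fail("fit", e))
    comp <- list(beta_split_vs_shared = compare_models(fits$m2, fits$m3b),
                 alpha_split_vs_shared = compare_models(fits$m2, fits$m3a),
                 full_vs_beta_split = compare_models(fits$m3b, fits$m4))
    cis <- lapply(stats::setNames(nm = names(fits$m3b$estimates)),
                  function(p) profile_ci(fits$m3b, p))
    write_fit_json(fits$m3b, file.path(outdir, "fit.json"),
                   comparisons = comp, cis = cis)
    report$fit <- list(estimates = as.list(fits$m3b$estimates),
                       loglik = fits$m3b$loglik,
                       transmission = as.list(transmission_rate(fits$m3b)),
                       comparisons = comp)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(outdir, "report.md"))
  invisible(report)
}

render_report_md <- function(report) {
  ln <- c("# dysrec pipeline report", "",
          sprintf("- seed: %s", report$config_seed),
          sprintf("- stages: %s", paste(report$stages, collapse = ", ")))
  if (!is.null(report$call))
    ln <- c(ln, sprintf("- samples kept: %d (removed below read floor: %d)",
                        report$call$samples_kept,
                        report$call$samples_removed_reads),
            sprintf("- crossovers kept: %d of %d called",
                    report$call$co_kept, report$call$co_total))
  if (!is.null(report$map))
    ln <- c(ln, sprintf("- total map length: %.1f cM", report$map$total_cM))
  if (!is.null(report$clusters))
    ln <- c(ln, sprintf("- recombination clusters: %d", report$clusters$n))
  if (!is.null(report$fit))
    ln <- c(ln, sprintf("- mitotic model (3-parameter, split beta): %s",
                        paste(sprintf("%s=%.3f", names(report$fit$estimates),
                                      unlist(report$fit$estimates)),
                              collapse = ", ")))
  ln
}
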