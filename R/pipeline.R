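#' Default pipeline configuration
#'
#' Collects the tunable thresholds of the pipeline with their standard
#' values: 30/20 nt motif window, 50 nt positional-equivalence rule,
#' 20/10 nt cluster extension, top-10 consensus, summed-pattern-count null
#' on 50-mers.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_up = 30, window_down = 20,
    equivalence_max_gap = 50,
    extend_up = 20, extend_down = 10,
    n_top = 10, trim_fraction = 0.025,
    null_mode = "summed_pattern_counts",
    null_window_len = 50,
    anchor = "five_prime",
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis stages behind a single entry point, reading
#' standard-format inputs and writing deterministic TSV/JSON artifacts to
#' `out_dir`. Stages:
#'
#' * `simulate` — write a synthetic iCLIP cohort, probe library and
#'   titration series to `out_dir`.
#' * `rnacompete` — probe TSV (`probes`) -> Z-score tables, scatter table,
#'   consensus motif (TSV + MEME block).
#' * `clip` — cluster TSVs (`fl`, `nhl`) + genome FASTA (`genome`) +
#'   optional blocklist rules -> per-gene summary TSV, window BED, cohort
#'   report JSON.
#' * `motifs` — no input: analytic null frequencies for the configured
#'   window, both counting modes.
#' * `fit` — titration TSV (`titration`) -> JSON fit report + fitted-curve
#'   TSV.
#'
#' @param stage one of `"simulate"`, `"rnacompete"`, `"clip"`, `"motifs"`,
#'   `"fit"`.
#' @param inputs named list of input file paths (stage-dependent, see
#'   Details).
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config()].
#' @param rules a [filter_rules()] for the `clip` stage.
#' @return invisibly, a named list of the artifact paths written, plus the
#'   stage's in-memory result in `$result`.
#' @export
run_stage <- function(stage = c("simulate", "rnacompete", "clip", "motifs", "fit"),
                      inputs = list(), out_dir = ".",
                      config = pipeline_config(), rules = filter_rules()) {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need_inputs <- function(keys) {
    miss <- setdiff(keys, names(inputs))
    if (length(miss)) stop("stage '", stage, "' needs input(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    bad <- keys[!vapply(inputs[keys], file.exists, logical(1))]
    if (length(bad)) stop("missing input file(s): ",
                          paste(unlist(inputs[bad]), collapse = ", "),
                          call. = FALSE)
  }
  paths <- list()
  result <- NULL
  if (stage == "simulate") {
    sim <- simulate_clip_cohort(seed = config$seed, dir = out_dir)
    probes <- simulate_rnacompete(seed = config$seed)
    paths$probes <- file.path(out_dir, "probes.tsv")
    write_probe_table(probes, paths$probes)
    titr <- simulate_titration(Kd = 1.7, seed = config$seed, n_replicates = 3)
    paths$titration <- file.path(out_dir, "titration.tsv")
    write_titration(titr, paths$titration)
    paths <- c(paths, sim$paths)
    result <- sim
  } else if (stage == "rnacompete") {
    need_inputs("probes")
    probes <- read_probe_table(inputs$probes)
    res <- rnacompete_analysis(probes, trim_fraction = config$trim_fraction,
                               n_top = config$n_top)
    for (s in names(res$tables)) {
      paths[[paste0("scores_", s)]] <- file.path(out_dir,
                                                 paste0("kmer_scores_", s, ".tsv"))
      utils::write.table(res$tables[[s]], paths[[paste0("scores_", s)]],
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    paths$scatter <- file.path(out_dir, "zscore_scatter.tsv")
    utils::write.table(res$concordance$table, paths$scatter, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$consensus <- file.path(out_dir, "consensus.meme")
    write_meme_motif(res$consensus, paths$consensus)
    result <- res
  } else if (stage == "clip") {
    need_inputs(c("fl", "nhl", "genome"))
    fl <- read_cluster_table(inputs$fl, bait = "FL")
    nhl <- read_cluster_table(inputs$nhl, bait = "NHL")
    genome <- read_genome(inputs$genome)
    res <- clip_target_analysis(
      fl, nhl, genome, rules = rules,
      max_gap = config$equivalence_max_gap,
      up = config$window_up, down = config$window_down,
      anchor = config$anchor,
      null_mode = config$null_mode,
      null_window_len = config$null_window_len)
    paths$summary <- file.path(out_dir, "gene_summary.tsv")
    genes <- res$overlap$summary
    if (!is.null(res$motifs)) {
      genes <- merge(genes, res$motifs$genes, by = "gene_id", all.x = TRUE)
    }
    excluded <- res$filtered$excluded
    genes$excluded_reason <- excluded$reason[match(genes$gene_id, excluded$gene_id)]
    utils::write.table(genes, paths$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$windows_bed <- file.path(out_dir, "windows.bed")
    write_bed(res$windows, paths$windows_bed)
    paths$report <- file.path(out_dir, "cohort_report.json")
    jsonlite::write_json(c(list(config = config), res$report), paths$report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result <- res
  } else if (stage == "motifs") {
    res <- list(
      summed = null_window_probability(config$null_window_len,
                                       "summed_pattern_counts"),
      distinct_exact = null_window_probability(config$null_window_len,
                                               "distinct_words"))
    paths$null <- file.path(out_dir, "null_model.json")
    jsonlite::write_json(
      list(window_len = config$null_window_len,
           summed_pattern_counts = res$summed$probability,
           distinct_words_exact = res$distinct_exact$probability),
      paths$null, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result <- res
  } else if (stage == "fit") {
    need_inputs("titration")
    titr <- read_titration(inputs$titration)
    fit <- fit_hill(titr)
    paths$fit <- file.path(out_dir, "hill_fit.json")
    rep <- if (inherits(fit, "hill_fit_set")) {
      list(Kd_mean = fit$Kd_mean, Kd_sd = fit$Kd_sd,
           n_replicates = fit$n_replicates, n_converged = fit$n_converged,
           replicates = lapply(fit$fits, function(f)
             c(as.list(f$coefficients), converged = f$converged)))
    } else {
      c(as.list(fit$coefficients), converged = fit$converged,
        flags = list(fit$flags))
    }
    jsonlite::write_json(rep, paths$fit, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths$curve <- file.path(out_dir, "fitted_curve.tsv")
    one <- if (inherits(fit, "hill_fit_set")) fit$fits[[1]] else fit
    if (one$converged) {
      cg <- exp(seq(log(min(titr$concentration)), log(max(titr$concentration)),
                    length.out = 100))
      utils::write.table(
        data.frame(concentration = cg,
                   fraction_bound = predict(one, data.frame(concentration = cg))),
        paths$curve, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    result <- fit
  }
  invisible(c(paths, list(result = result)))
}
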