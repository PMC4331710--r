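# End-to-end pipeline: inputs -> gold standard -> features -> fit -> tiered
# predictions -> network modules -> enrichment, with a machine-readable run
# report. Each stage is also available as a standalone function so the
# pipeline stays independently testable.

#' Pipeline configuration
#'
#' @param input_dir directory laid out as by [world_to_files()] (`catalog.tsv`,
#'   `ppi.tsv`, `ddi.tsv`, `localization.tsv`, `annotation.tsv`,
#'   `expression/*.tsv`).
#' @param out_dir output directory for artifacts.
#' @param thresholds named numeric, elements `high` and `low`
#'   (defaults 2.575 / 1.692, the package's stock operating points).
#' @param module_params named list/vector: `min` (3), `max` (30),
#'   `density` (0.7).
#' @param alpha enrichment significance level on BH-adjusted p (0.05).
#' @param cutoff gold-standard split date (default `"2012-01-01"`).
#' @param seed integer seed for the randomized-module null.
#' @return Validated list of class `iii_config`.
#' @export
iii_pipeline_config <- function(input_dir, out_dir,
                                thresholds = c(high = 2.575, low = 1.692),
                                module_params = list(min = 3L, max = 30L,
                                                     density = 0.7),
                                alpha = 0.05,
                                cutoff = "2012-01-01",
                                seed = 1L) {
  if (!all(c("high", "low") %in% names(thresholds)) ||
      thresholds[["high"]] < thresholds[["low"]])
    validation_error("config: thresholds must satisfy high >= low")
  if (module_params$min > module_params$max)
    validation_error("config: module min size exceeds max size")
  if (alpha <= 0 || alpha >= 1)
    validation_error("config: alpha must lie in (0, 1)")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 thresholds = thresholds, module_params = module_params,
                 alpha = alpha, cutoff = as.Date(cutoff),
                 seed = as.integer(seed)),
            class = "iii_config")
}

#' Run the full prediction pipeline
#'
#' Stages, in order: read and validate inputs; build the gold standard
#' (positives from isoform-specified records + the single-isoform rule, split
#' at the cutoff date; negatives from membrane x nucleus localization);
#' compute features and fit the logistic model on the training gold standard;
#' evaluate on the test positives vs the negatives; score all candidate pairs
#' (isoform cross products of gene-level PPIs) into high/low/rescued tiers;
#' build the interaction network from the low-confidence set; discover
#' overlapping dense modules; compare their GO/pathway enrichment rates with
#' size-matched random modules.
#'
#' Artifacts written to `config$out_dir`: `gold_standard.tsv`,
#' `predictions.tsv`, `modules.tsv`, `enrichment.tsv`, `report.json`.
#'
#' @param config an `iii_config`.
#' @return The run report (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "iii_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  inputs <- stage("read_inputs", read_world_files(config$input_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  gold <- stage("gold_standard",
                build_gold_standard(inputs$ppi, inputs$catalog,
                                    inputs$localization, config$cutoff))
  write_gold_standard(gold, file.path(config$out_dir, "gold_standard.tsv"))

  gold_pairs <- rbind(gold$positives_train[, c("isoform_a", "isoform_b")],
                      gold$positives_test[, c("isoform_a", "isoform_b")],
                      gold$negatives)
  gold_feats <- stage("features_gold",
                      build_feature_vectors(gold_pairs, inputs$datasets,
                                            inputs$catalog, inputs$ddi))
  n_train_pos <- nrow(gold$positives_train)
  n_test_pos <- nrow(gold$positives_test)
  n_neg <- nrow(gold$negatives)
  train_idx <- c(seq_len(n_train_pos),
                 n_train_pos + n_test_pos + seq_len(n_neg))
  train_labels <- c(rep(1L, n_train_pos), rep(0L, n_neg))
  fit <- stage("fit", fit_logistic(gold_feats[train_idx, , drop = FALSE],
                                   train_labels))

  evaluation <- stage("evaluate", if (n_test_pos > 0 && n_neg > 0)
    evaluate_on_test(fit, gold_feats, gold, config$thresholds) else NULL)

  cand <- stage("candidates", candidate_pairs(inputs$ppi, inputs$catalog))
  cand_feats <- stage("features_candidates",
                      build_feature_vectors(cand, inputs$datasets,
                                            inputs$catalog, inputs$ddi))
  preds <- stage("predict", predict_iii(cand_feats, fit, inputs$ppi,
                                        inputs$catalog, config$thresholds))
  write_predictions(preds, file.path(config$out_dir, "predictions.tsv"))

  network <- stage("network", network_from_predictions(preds))
  modules <- stage("modules",
                   discover_modules(network,
                                    min_size = config$module_params$min,
                                    max_size = config$module_params$max,
                                    min_density = config$module_params$density))

  enr <- stage("enrichment", enrich_modules(modules, inputs$annotation,
                                            network$nodes))
  write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
  sig <- enr[!is.na(enr$adjusted_p) & enr$adjusted_p < config$alpha, ,
             drop = FALSE]
  top_terms <- lapply(split(sig$term_id, sig$module_id), unique)
  write_modules(modules, file.path(config$out_dir, "modules.tsv"), top_terms)

  rates <- list(GO = NA_real_, pathway = NA_real_,
                random_GO = NA_real_, random_pathway = NA_real_)
  if (length(modules) > 0) {
    rates$GO <- enrichment_rate(modules, inputs$annotation, network$nodes,
                                config$alpha, "GO")
    rates$pathway <- enrichment_rate(modules, inputs$annotation,
                                     network$nodes, config$alpha, "pathway")
    rand <- randomize_modules(modules, network$nodes, config$seed, network)
    rates$random_GO <- enrichment_rate(rand, inputs$annotation,
                                       network$nodes, config$alpha, "GO")
    rates$random_pathway <- enrichment_rate(rand, inputs$annotation,
                                            network$nodes, config$alpha,
                                            "pathway")
  }

  report <- list(
    counts = list(
      isoforms = nrow(inputs$catalog$isoforms),
      genes = length(unique(inputs$catalog$isoforms$gene_id)),
      ppi_records = nrow(inputs$ppi),
      gsp_train = n_train_pos, gsp_test = n_test_pos, gsn = n_neg,
      candidates = nrow(cand),
      predictions_total = nrow(preds),
      high = sum(preds$tier == "high"),
      low = sum(preds$tier == "low"),
      rescued = sum(preds$tier == "rescued"),
      network_nodes = length(network$nodes),
      network_edges = nrow(network$edges),
      modules = length(modules)
    ),
    coefficients = as.list(fit$coefficients),
    thresholds = as.list(config$thresholds),
    operating_points = if (!is.null(evaluation))
      evaluation$operating_points else NULL,
    enrichment_rates = rates,
    seed = config$seed
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher used by the `inst/cli/iii.R` script:
#' `iii_main(c("simulate", "--out", DIR, "--seed", N))` or
#' `iii_main(c("run-all", "--input", DIR, "--out", DIR, "--seed", N))`.
#' Flags for `run-all`: `--high-threshold`, `--low-threshold`, `--min-size`,
#' `--max-size`, `--density`, `--alpha`, `--cutoff`, plus `--config FILE`
#' pointing to a JSON object whose keys mirror the flag names (explicit flags
#' override config values).
#'
#' @param args character vector of command-line arguments.
#' @return Exit status: 0 on success, 2 on validation/usage error, 3 on
#'   runtime error.
#' @export
iii_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: iii <simulate|run-all> [--flags]",
    "  simulate --out DIR --seed N",
    "  run-all  --input DIR --out DIR [--seed N] [--high-threshold X]",
    "           [--low-threshold X] [--min-size N] [--max-size N]",
    "           [--density X] [--alpha X] [--cutoff YYYY-MM-DD]",
    sep = "\n")
  if (length(args) == 0) { message(usage); return(2L) }
  cmd <- args[1]
  flags <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("malformed flag: ", rest[i]); return(2L)
    }
    flags[[substring(rest[i], 3)]] <- rest[i + 1L]
    i <- i + 2L
  }
  file_cfg <- list()
  if (!is.null(flags[["config"]])) {
    if (!file.exists(flags[["config"]])) {
      message("config file not found: ", flags[["config"]]); return(2L)
    }
    file_cfg <- jsonlite::read_json(flags[["config"]], simplifyVector = TRUE)
  }
  get_flag <- function(name, default = NULL) {
    if (!is.null(flags[[name]])) flags[[name]]
    else if (!is.null(file_cfg[[name]])) file_cfg[[name]]
    else default
  }
  tryCatch({
    if (cmd == "simulate") {
      out <- get_flag("out"); seed <- get_flag("seed")
      if (is.null(out) || is.null(seed)) { message(usage); return(2L) }
      world <- generate_world(synthetic_world_config(seed =
                                                       as.integer(seed)))
      world_to_files(world, out)
      message(sprintf("wrote synthetic world to %s", out))
      0L
    } else if (cmd == "run-all") {
      input <- get_flag("input"); out <- get_flag("out")
      if (is.null(input) || is.null(out)) { message(usage); return(2L) }
      cfg <- iii_pipeline_config(
        input_dir = input, out_dir = out,
        thresholds = c(high = as.numeric(get_flag("high-threshold", 2.575)),
                       low = as.numeric(get_flag("low-threshold", 1.692))),
        module_params = list(min = as.integer(get_flag("min-size", 3)),
                             max = as.integer(get_flag("max-size", 30)),
                             density = as.numeric(get_flag("density", 0.7))),
        alpha = as.numeric(get_flag("alpha", 0.05)),
        cutoff = get_flag("cutoff", "2012-01-01"),
        seed = as.integer(get_flag("seed", 1)))
      report <- run_pipeline(cfg)
      message(sprintf(
        "pipeline done: %d candidates, %d high / %d low / %d rescued, %d modules",
        report$counts$candidates, report$counts$high, report$counts$low,
        report$counts$rescued, report$counts$modules))
      0L
    } else {
      message(usage); 2L
    }
  }, iii_validation_error = function(e) { message(conditionMessage(e)); 2L },
     error = function(e) { message(conditionMessage(e)); 3L })
}
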