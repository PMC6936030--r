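# Command-line surface: thin orchestration over the other modules.
# Subcommands: simulate, encode, cv, train, evaluate, predict, logo.
# All numerical work is delegated; every artifact directory gets a
# run_config.json recording the resolved configuration and seed.

psi_log <- function(...) message("[psiforest] ", sprintf(...))

resolve_window <- function(config) {
  if (!is.null(config$species_tag) && config$species_tag %in% c("H", "M", "S")) {
    wl <- species_profile(config$species_tag)$window_length
    if (!is.null(config$window_length) && config$window_length != wl) {
      stop("window_length ", config$window_length, " conflicts with species ",
           config$species_tag, " (profile window ", wl, ")")
    }
    return(wl)
  }
  if (is.null(config$window_length)) stop("either species_tag or window_length is required")
  as.integer(config$window_length)
}

write_run_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

default_config <- function() {
  list(encoder = "NCP", seed = 1L, out_dir = ".", species_tag = NULL,
       window_length = NULL, n_trees = 200L, threshold = 0.5, alpha = 0.05,
       n_positive = 200L, n_negative = 200L, folds = 5L,
       max_depth = 6L, fraction = 0.5, edge_policy = "skip")
}

merge_config <- function(...) {
  out <- default_config()
  for (cfg in list(...)) {
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    out <- utils::modifyList(out, cfg)
  }
  out
}

load_input_dataset <- function(config) {
  if (!is.null(config$manifest)) {
    load_manifest_dataset(config$manifest)
  } else if (!is.null(config$positives) && !is.null(config$negatives)) {
    load_fragment_dataset(config$positives, config$negatives,
                          species_tag = config$species_tag %||% "custom")
  } else {
    stop("supply either --manifest or both --positives and --negatives")
  }
}

#' Simulate a synthetic benchmark on disk
#'
#' Writes a positive/negative FASTA pair and JSON manifest under
#' `config$out_dir`. `config$biases` may be a data.frame
#' (position/nt/prob) or the path of a JSON array of such records.
#'
#' @param config named list; relevant keys: `window_length` or
#'   `species_tag`, `n_positive`, `n_negative`, `biases`, `seed`,
#'   `out_dir`.
#' @return the manifest path, invisibly.
#' @export
run_simulate <- function(config) {
  config <- merge_config(config)
  wl <- resolve_window(config)
  biases <- config$biases
  if (is.character(biases)) {
    biases <- as.data.frame(jsonlite::read_json(biases, simplifyVector = TRUE))
  }
  spec <- signal_spec(window_length = wl, n_positive = config$n_positive,
                      n_negative = config$n_negative, biases = biases,
                      seed = config$seed)
  ds <- simulate_dataset(spec)
  write_run_config(config, config$out_dir)
  manifest <- write_fragment_dataset(ds, config$out_dir,
                                     config$basename %||% "synthetic")
  psi_log("simulated %d+%d fragments of length %d (seed %d) -> %s",
          spec$n_positive, spec$n_negative, wl, spec$seed, manifest)
  invisible(manifest)
}

#' Encode a dataset to a feature-matrix TSV
#'
#' @param config keys: input (`manifest` or `positives`/`negatives`),
#'   `encoder`, encoder parameters (`k_max`, `k`, `lambda`, `w`),
#'   `out_dir`.
#' @return the TSV path, invisibly.
#' @export
run_encode <- function(config) {
  config <- merge_config(config)
  ds <- load_input_dataset(config)
  params <- config[names(config) %in% c("k_max", "k", "lambda", "w")]
  fm <- do.call(encode_dataset, c(list(ds, config$encoder), params))
  write_run_config(config, config$out_dir)
  path <- file.path(config$out_dir, paste0("features_", tolower(config$encoder), ".tsv"))
  write_feature_matrix(fm, path)
  psi_log("encoded %d fragments -> %d features (%s) -> %s",
          nrow(fm), ncol(fm), config$encoder, path)
  invisible(path)
}

#' Grid-search cross-validation from the command line
#'
#' Writes the accuracy heatmap TSV (rows depth, columns fraction), a
#' best-parameters JSON, and the per-fold metrics TSV.
#'
#' @param config keys: input, `encoder`, `folds`, `n_trees`, `seed`,
#'   grid overrides `depth_values` / `fraction_values`, `out_dir`.
#' @return the `psi_cv` object, invisibly.
#' @export
run_cv <- function(config) {
  config <- merge_config(config)
  ds <- load_input_dataset(config)
  grid <- grid_spec(
    depth_values = config$depth_values %||% 2:6,
    fraction_values = config$fraction_values %||% seq(0.20, 0.80, by = 0.05),
    folds = config$folds, n_trees = config$n_trees, seed = config$seed)
  psi_log("grid search: %d combinations x %d folds (seed %d)",
          length(grid$depth_values) * length(grid$fraction_values),
          grid$folds, grid$seed)
  cv <- grid_search_cv(ds, config$encoder, list(), grid)
  write_run_config(config, config$out_dir)
  write_cv_heatmap(cv, file.path(config$out_dir, "cv_heatmap.tsv"))
  write.table(cv$fold_metrics, file.path(config$out_dir, "cv_fold_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(cv$best, list(seed = grid$seed, encoder = config$encoder)),
    file.path(config$out_dir, "cv_best.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  psi_log("best: max_depth=%d fraction=%.2f score=%.4f",
          cv$best$max_depth, cv$best$fraction, cv$best$score)
  invisible(cv)
}

#' Train and save a final model
#'
#' @param config keys: input, `encoder`, `n_trees`, `max_depth`,
#'   `fraction`, `seed`, `out_dir`.
#' @return the model path, invisibly.
#' @export
run_train <- function(config) {
  config <- merge_config(config)
  ds <- load_input_dataset(config)
  cfg <- forest_config(n_trees = config$n_trees, max_depth = config$max_depth,
                       max_features_fraction = config$fraction, seed = config$seed)
  model <- train_final(ds, config$encoder, list(), cfg)
  write_run_config(config, config$out_dir)
  path <- file.path(config$out_dir, "model.rds")
  save_model(model, path)
  psi_log("trained %s model on %d fragments -> %s", config$encoder, length(ds), path)
  invisible(path)
}

#' Evaluate a saved model on a labeled test set
#'
#' @param config keys: input, `model`, `threshold`, `out_dir`.
#' @return the `psi_eval`, invisibly.
#' @export
run_evaluate <- function(config) {
  config <- merge_config(config)
  if (is.null(config$model)) stop("--model is required")
  model <- load_model(config$model)
  ds <- load_input_dataset(config)
  ev <- evaluate_model(model, ds, threshold = config$threshold)
  write_run_config(config, config$out_dir)
  write_eval_result(ev, file.path(config$out_dir, "evaluation"))
  psi_log("ACC=%.4f SN=%.4f SP=%.4f MCC=%.4f", ev$acc, ev$sn, ev$sp, ev$mcc)
  invisible(ev)
}

#' Scan RNA sequences for candidate pseudouridine sites
#'
#' For every uridine in every input sequence a window is placed with
#' the U at its center, encoded with the model's encoder, and scored;
#' sites called positive are reported with 1-based positions.
#' Sequences without uridines (or, under the skip edge policy, shorter
#' than the window) yield an empty record, not an error.
#'
#' @param config keys: `fasta` (input sequences), `model`,
#'   `edge_policy`, `threshold`, `out_dir`.
#' @return data.frame of candidate sites, invisibly.
#' @export
run_predict <- function(config) {
  config <- merge_config(config)
  if (is.null(config$model)) stop("--model is required")
  if (is.null(config$fasta)) stop("--fasta is required")
  model <- load_model(config$model)
  seqs <- read_fasta(config$fasta, alphabet_policy = "dna_ok")
  psi_log("scanning %d sequence(s) with window %d, edge policy '%s'",
          nrow(seqs), model$window_length, config$edge_policy)
  all_sites <- list()
  for (i in seq_len(nrow(seqs))) {
    frags <- extract_u_windows(seqs[i, ], model$window_length,
                               edge_policy = config$edge_policy)
    if (length(frags) == 0L) {
      if (nchar(seqs$residues[i]) < model$window_length &&
          config$edge_policy == "skip" && grepl("U", seqs$residues[i])) {
        warning("sequence '", seqs$id[i], "' is shorter than the window (",
                model$window_length, "); no site can be scored under the skip policy")
      }
      next
    }
    pred <- predict(model, frags, threshold = config$threshold)
    keep <- pred$call == "positive"
    if (any(keep)) {
      all_sites[[length(all_sites) + 1L]] <- data.frame(
        sequence_id = seqs$id[i], position = frags$origin_pos[keep],
        score = pred$score[keep], stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites)
           else data.frame(sequence_id = character(0), position = integer(0),
                           score = numeric(0))
  write_run_config(config, config$out_dir)
  path <- file.path(config$out_dir, "predicted_sites.tsv")
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  psi_log("%d candidate site(s) -> %s", nrow(sites), path)
  invisible(sites)
}

#' Two-sample logo from the command line
#'
#' @param config keys: input (manifest or positives/negatives),
#'   `alpha`, `out_dir`.
#' @return the `psi_logo` stats, invisibly.
#' @export
run_logo <- function(config) {
  config <- merge_config(config)
  ds <- load_input_dataset(config)
  pos <- subset_dataset(ds, which(ds$label == "positive"))
  neg <- subset_dataset(ds, which(ds$label == "negative"))
  stats <- two_sample_logo(pos, neg, alpha = config$alpha)
  write_run_config(config, config$out_dir)
  paths <- render_logo(stats, file.path(config$out_dir, "two_sample_logo"))
  psi_log("%d significant cell(s) -> %s", sum(stats$call != "none"), paths[["tsv"]])
  invisible(stats)
}

cli_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON config file (flags override it)"),
    optparse::make_option("--manifest", type = "character", default = NULL),
    optparse::make_option("--positives", type = "character", default = NULL),
    optparse::make_option("--negatives", type = "character", default = NULL),
    optparse::make_option("--fasta", type = "character", default = NULL),
    optparse::make_option("--model", type = "character", default = NULL),
    optparse::make_option("--encoder", type = "character", default = NULL),
    optparse::make_option("--species-tag", dest = "species_tag",
                          type = "character", default = NULL),
    optparse::make_option("--window-length", dest = "window_length",
                          type = "integer", default = NULL),
    optparse::make_option("--n-positive", dest = "n_positive",
                          type = "integer", default = NULL),
    optparse::make_option("--n-negative", dest = "n_negative",
                          type = "integer", default = NULL),
    optparse::make_option("--biases", type = "character", default = NULL,
                          help = "JSON file of {position, nt, prob} records"),
    optparse::make_option("--folds", type = "integer", default = NULL),
    optparse::make_option("--n-trees", dest = "n_trees", type = "integer",
                          default = NULL),
    optparse::make_option("--max-depth", dest = "max_depth", type = "integer",
                          default = NULL),
    optparse::make_option("--fraction", type = "double", default = NULL),
    optparse::make_option("--threshold", type = "double", default = NULL),
    optparse::make_option("--alpha", type = "double", default = NULL),
    optparse::make_option("--edge-policy", dest = "edge_policy",
                          type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = NULL)
  )
}

#' Command-line entry point
#'
#' Dispatches `psiforest <simulate|encode|cv|train|evaluate|predict|logo>
#' [options]`. Configuration precedence: command-line flags over a
#' `--config` JSON file over package defaults. Logs go to standard
#' error; machine-readable artifacts are files only.
#'
#' @param args character vector of arguments (defaults to the process
#'   command line).
#' @return integer exit status (0 on success).
#' @export
psiforest_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  commands <- c(simulate = "run_simulate", encode = "run_encode", cv = "run_cv",
                train = "run_train", evaluate = "run_evaluate",
                predict = "run_predict", logo = "run_logo")
  if (length(args) == 0L || !args[1] %in% names(commands)) {
    message("usage: psiforest <", paste(names(commands), collapse = "|"), "> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = cli_options(),
                                   usage = paste("psiforest", cmd, "[options]"))
  status <- tryCatch({
    opts <- optparse::parse_args(parser, args = args[-1])
    opts$help <- NULL
    file_cfg <- if (!is.null(opts$config)) {
      jsonlite::read_json(opts$config, simplifyVector = TRUE)
    } else list()
    opts$config <- NULL
    config <- merge_config(file_cfg, opts)
    do.call(commands[[cmd]], list(config))
    0L
  }, error = function(e) {
    message("[psiforest] error in '", cmd, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}
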