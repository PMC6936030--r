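# The run_* functions are the command surface; the Rscript wrapper at
# inst/scripts/psiforest only dispatches to them.

test_that("run_simulate writes the FASTA pair, manifest, and config provenance", {
  dir <- withr::local_tempdir()
  manifest <- run_simulate(list(window_length = 9, n_positive = 12, n_negative = 12,
                                seed = 5, out_dir = dir))
  expect_true(file.exists(manifest))
  ds <- load_manifest_dataset(manifest)
  expect_equal(unname(dataset_counts(ds)[c("n_positive", "n_negative")]), c(12L, 12L))
  cfg <- jsonlite::read_json(file.path(dir, "run_config.json"), simplifyVector = TRUE)
  expect_equal(cfg$seed, 5)
})

test_that("run_encode produces a feature TSV of the expected width", {
  dir <- withr::local_tempdir()
  manifest <- run_simulate(list(species_tag = "H", n_positive = 10, n_negative = 10,
                                seed = 2, out_dir = dir))
  tsv <- run_encode(list(manifest = manifest, encoder = "NCP",
                         out_dir = file.path(dir, "enc")))
  feat <- read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(feat), 20L)
  expect_equal(ncol(feat), 2L + 63L)  # id + label + 3*21 features
})

test_that("run_cv writes a heatmap shaped by the grid plus best-params JSON", {
  dir <- withr::local_tempdir()
  manifest <- run_simulate(list(window_length = 9, n_positive = 20, n_negative = 20,
                                seed = 3, out_dir = dir))
  out <- file.path(dir, "cv")
  cv <- run_cv(list(manifest = manifest, folds = 3, n_trees = 40, seed = 9,
                    depth_values = c(2, 3), fraction_values = c(0.3, 0.5, 0.7),
                    out_dir = out))
  hm <- read.delim(file.path(out, "cv_heatmap.tsv"), check.names = FALSE)
  expect_equal(dim(hm), c(2L, 4L))
  best <- jsonlite::read_json(file.path(out, "cv_best.json"), simplifyVector = TRUE)
  expect_true(best$max_depth %in% c(2, 3))
  expect_equal(best$seed, 9)
  expect_true(file.exists(file.path(out, "cv_fold_metrics.tsv")))
})

test_that("identical config and seed reproduce byte-identical CV artifacts", {
  dir <- withr::local_tempdir()
  manifest <- run_simulate(list(window_length = 9, n_positive = 15, n_negative = 15,
                                seed = 4, out_dir = dir))
  cfg <- list(manifest = manifest, folds = 3, n_trees = 30, seed = 21,
              depth_values = c(2, 4), fraction_values = c(0.4, 0.6))
  run_cv(c(cfg, list(out_dir = file.path(dir, "a"))))
  run_cv(c(cfg, list(out_dir = file.path(dir, "b"))))
  for (f in c("cv_heatmap.tsv", "cv_fold_metrics.tsv", "cv_best.json")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)))
  }
})

test_that("train/evaluate/predict chain end-to-end through saved artifacts", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(strong_signal_spec(n_positive = 60, n_negative = 60, seed = 8))
  manifest <- write_fragment_dataset(ds, dir, "train")
  model_path <- run_train(list(manifest = manifest, n_trees = 80, max_depth = 6,
                               fraction = 0.5, seed = 2,
                               out_dir = file.path(dir, "model")))
  expect_true(file.exists(model_path))

  test_ds <- simulate_dataset(strong_signal_spec(n_positive = 40, n_negative = 40, seed = 80))
  test_manifest <- write_fragment_dataset(test_ds, dir, "test")
  ev <- run_evaluate(list(manifest = test_manifest, model = model_path,
                          out_dir = file.path(dir, "eval")))
  expect_gt(ev$acc, 0.7)
  expect_true(file.exists(file.path(dir, "eval", "evaluation.json")))

  # scanning: every reported site must sit on a U
  fa <- file.path(dir, "query.fa")
  withr::with_seed(12, {
    seqs <- replicate(3, paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
                               collapse = ""))
  })
  writeLines(c(rbind(paste0(">q", 1:3), seqs)), fa)
  sites <- run_predict(list(fasta = fa, model = model_path,
                            out_dir = file.path(dir, "pred")))
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      s <- seqs[match(sites$sequence_id[i], paste0("q", 1:3))]
      expect_equal(substr(s, sites$position[i], sites$position[i]), "U")
    }
  }
  expect_true(file.exists(file.path(dir, "pred", "predicted_sites.tsv")))
})

test_that("scanning handles U-free and too-short sequences gracefully", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(strong_signal_spec(n_positive = 30, n_negative = 30, seed = 1))
  model_path <- file.path(dir, "m.rds")
  save_model(train_final(ds, config = forest_config(n_trees = 30, seed = 1)), model_path)

  no_u <- tmp_fasta(c(">nou", "ACGCAGCGACGCAGCAGCAGCAGCA"), "nou.fa")
  sites <- run_predict(list(fasta = no_u, model = model_path, out_dir = dir))
  expect_equal(nrow(sites), 0L)

  short <- tmp_fasta(c(">short", "ACGUA"), "short.fa")
  expect_warning(
    sites2 <- run_predict(list(fasta = short, model = model_path, out_dir = dir)),
    "shorter than the window")
  expect_equal(nrow(sites2), 0L)
})

test_that("run_logo writes the cell table and plot", {
  dir <- withr::local_tempdir()
  spec <- signal_spec(window_length = 9, n_positive = 100, n_negative = 100,
                      biases = data.frame(position = 2, nt = "G", prob = 0.9),
                      seed = 6)
  manifest <- write_fragment_dataset(simulate_dataset(spec), dir, "logo")
  st <- run_logo(list(manifest = manifest, out_dir = file.path(dir, "logo")))
  expect_true(file.exists(file.path(dir, "logo", "two_sample_logo.tsv")))
  expect_true(any(st$call == "enriched"))
})

test_that("usage errors exit non-zero through the CLI dispatcher, success exits zero", {
  expect_equal(suppressMessages(psiforest_cli(character(0))), 1L)
  expect_equal(suppressMessages(psiforest_cli("cv")), 1L)  # missing inputs
  dir <- withr::local_tempdir()
  status <- suppressMessages(psiforest_cli(c(
    "simulate", "--window-length", "9", "--n-positive", "5",
    "--n-negative", "5", "--seed", "3", "--out-dir", dir)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "synthetic_manifest.json")))
})

test_that("species/window conflicts are rejected and profiles resolve", {
  expect_error(resolve_window <- run_simulate(
    list(species_tag = "H", window_length = 31, n_positive = 2, n_negative = 2,
         out_dir = withr::local_tempdir())), "conflicts")
})
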