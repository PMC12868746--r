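test_that("cohort bundles round-trip exactly", {
  co <- generate_cohort(tiny_cohort_config(seed = 3))
  dir <- withr::local_tempdir()
  write_eeg_bundle(co, dir)
  back <- read_eeg_bundle(dir)
  expect_setequal(names(back$recordings), names(co$recordings))
  for (id in names(co$recordings)) {
    expect_identical(back$recordings[[id]]$data, co$recordings[[id]]$data)
    expect_equal(back$recordings[[id]]$fs, co$recordings[[id]]$fs)
    expect_equal(back$recordings[[id]]$label, co$recordings[[id]]$label)
  }
  expect_equal(back$clinical$panss_total, co$clinical$panss_total)
  expect_error(read_eeg_bundle(withr::local_tempdir()), "no recordings")
})

test_that("PI archives round-trip with metadata", {
  seqs <- simulate_pi_sequences(2, 3, resolution = 6, seed = 2)
  attr(seqs, "ranges") <- list(synthetic = list(birth_range = c(0, 1),
                                                pers_range = c(0, 2)))
  path <- withr::local_tempfile(fileext = ".rds")
  write_pi_archive(seqs, path)
  back <- read_pi_archive(path)
  expect_equal(length(back), length(seqs))
  expect_identical(back[[1]]$pis, seqs[[1]]$pis)
  expect_equal(attr(back, "ranges")$synthetic$pers_range, c(0, 2))
  expect_error(read_pi_archive(file.path(tempdir(), "nope.rds")),
               "no such archive")
})

test_that("checkpoints restore generators bit-for-bit", {
  gen <- generator_state(5, seed = 4)
  disc <- discriminator_state(5, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(gen, disc, training_config(seed = 1), path)
  ck <- load_checkpoint(path)
  probe <- matrix(runif(25), 5, 5)
  expect_identical(generator_forward(ck$gen, probe),
                   generator_forward(gen, probe))
  expect_identical(discriminator_forward(ck$disc, probe),
                   discriminator_forward(disc, probe))
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")),
               "no such checkpoint")
})

test_that("run configs round-trip JSON and reject unknown keys", {
  cfg <- run_config(seed = 7, bands = c("Theta", "Gamma"),
                    tda = list(resolution = 20, max_points = 40),
                    training = list(batch_size = 16))
  expect_equal(cfg$tda$resolution, 20)
  expect_equal(cfg$training$batch_size, 16)
  expect_equal(cfg$training$lr_pretrain, 0.01)   # defaults preserved

  path <- withr::local_tempfile(fileext = ".json")
  save_run_config(cfg, path)
  back <- load_run_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 0)

  expect_error(run_config(typo_key = 1), "unknown config key.*typo_key")
  expect_error(run_config(tda = list(resolutionn = 10)),
               "tda.resolutionn")
})

test_that("the full pipeline runs end-to-end at desk scale", {
  dir <- withr::local_tempdir()
  cfg <- run_config(
    seed = 11, out_dir = dir, bands = "Alpha", window_s = 2,
    cohort = list(n_subjects_per_class = 3, duration_s = 12, fs = 100,
                  n_channels = 2),
    tda = list(resolution = 8, max_points = 30, max_hom_dim = 1,
               hom_dims = 1, delay = 2),
    training = list(batch_size = 8, epochs_pretrain = 2, epochs_joint = 2))
  res <- full_run(cfg, clinical_epochs = 10)
  expect_true(file.exists(file.path(dir, "config.json")))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(dir, "pi_archive.rds")))
  expect_s3_class(res$report, "evaluation_report")
  expect_gte(res$report$mae, 0)
  rep_json <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep_json$mae, res$report$mae, tolerance = 1e-12)
})

test_that("the command-line entry point parses and simulates", {
  cli <- system.file("cli", "topoforecast", package = "topoforecast")
  expect_true(nzchar(cli) && file.exists(cli))
  dir <- file.path(withr::local_tempdir(), "run")
  cfg_path <- withr::local_tempfile(fileext = ".json")
  save_run_config(run_config(
    seed = 2, out_dir = dir,
    cohort = list(n_subjects_per_class = 2, duration_s = 8, fs = 100,
                  n_channels = 2)), cfg_path)
  out <- system2("Rscript", c(cli, "simulate", "--config", cfg_path),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status") %||% 0, 0)
  expect_true(file.exists(file.path(dir, "cohort", "clinical.csv")))
})
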