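#' End-to-end pipeline run
#'
#' Chains every stage from one validated [run_config()]: simulate the
#' cohort, extract per-band persistence-image sequences, split subjects,
#' pretrain and adversarially train the forecaster on the training
#' patients, evaluate next-window prediction on the held-out patients, and
#' correlate image-quality coefficients with the planted clinical scores.
#' All artifacts (resolved config, per-epoch losses, evaluation report,
#' checkpoint) are written under `config$out_dir`.
#'
#' @param config a `run_config`.
#' @param epochs_pretrain,epochs_joint,clinical_epochs optional overrides
#'   of the configured epoch counts (handy for smoke runs).
#' @return list with `cohort`, `pi_seqs`, `split`, `gen`, `disc`,
#'   `report`, `clinical_cor`, `out_dir`, invisibly.
#' @export
full_run <- function(config = run_config(), epochs_pretrain = NULL,
                     epochs_joint = NULL, clinical_epochs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_run_config(config, file.path(config$out_dir, "config.json"))

  cc <- config$cohort
  cohort <- generate_cohort(cohort_config(
    n_subjects_per_class = cc$n_subjects_per_class,
    duration_s = cc$duration_s, fs = cc$fs, n_channels = cc$n_channels,
    class_effect = unlist(cc$class_effect), amp_jitter_sd = cc$amp_jitter_sd,
    noise_sd = cc$noise_sd, am_depth = cc$am_depth,
    clinical_slope = cc$clinical_slope,
    clinical_noise_sd = cc$clinical_noise_sd, window_s = config$window_s,
    seed = substream_seed(config$seed, "cohort")))

  td <- config$tda
  pi_seqs <- extract_pi_sequences(
    cohort, bands = config$bands, window_s = config$window_s,
    tda = tda_config(embed_dim = td$embed_dim, delay = td$delay,
                     max_points = td$max_points,
                     max_hom_dim = td$max_hom_dim, hom_dims = td$hom_dims,
                     resolution = td$resolution, sigma = td$sigma),
    seed = substream_seed(config$seed, "tda"))
  write_pi_archive(pi_seqs, file.path(config$out_dir, "pi_archive.rds"))

  tc <- config$training
  tconf <- training_config(
    lr_pretrain = tc$lr_pretrain, lr_joint = tc$lr_joint,
    batch_size = tc$batch_size,
    classification_threshold = tc$classification_threshold,
    gat_dropout = tc$gat_dropout, epochs_pretrain = tc$epochs_pretrain,
    epochs_joint = tc$epochs_joint, train_frac = tc$train_frac,
    val_frac = tc$val_frac, recon_weight = tc$recon_weight,
    seed = substream_seed(config$seed, "train"))

  labels <- vapply(pi_seqs, function(e) e$label, character(1))
  ids <- vapply(pi_seqs, function(e) e$subject_id, character(1))
  pat_ids <- unique(ids[labels == "patient"])
  split <- split_subjects(pat_ids, tconf$train_frac, tconf$val_frac,
                          tconf$seed)
  train_pairs <- make_pairs(pi_seqs[ids %in% split$train])
  test_pairs <- make_pairs(pi_seqs[ids %in% split$test])

  gen <- generator_state(td$resolution, dropout = tconf$gat_dropout,
                         seed = substream_seed(config$seed, "gen"))
  pre <- pretrain_generator(gen, train_pairs, tconf,
                            epochs = epochs_pretrain)
  disc <- discriminator_state(td$resolution,
                              seed = substream_seed(config$seed, "disc"))
  adv <- adversarial_train(pre$gen, disc, train_pairs, tconf,
                           epochs = epochs_joint)

  report <- evaluate_prediction(adv$gen, test_pairs, tconf)
  utils::write.csv(
    data.frame(epoch = seq_along(adv$gen_losses),
               gen_loss = adv$gen_losses, disc_loss = adv$disc_losses),
    file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(band = report$band, n_pairs = report$n_pairs, auc = report$auc,
         map = report$map, mae = report$mae),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  save_checkpoint(adv$gen, adv$disc, tconf,
                  path = file.path(config$out_dir, "checkpoint.rds"))

  clinical_cor <- NULL
  if (!is.null(cohort$clinical) && nrow(cohort$clinical) >= 5) {
    clinical_cor <- clinical_correlations(
      pi_seqs, cohort$clinical, epochs = clinical_epochs %||%
        config$clinical$epochs,
      seed = substream_seed(config$seed, "clinical"))
    utils::write.csv(clinical_cor,
                     file.path(config$out_dir, "clinical_correlations.csv"),
                     row.names = FALSE)
  }

  invisible(list(cohort = cohort, pi_seqs = pi_seqs, split = split,
                 gen = adv$gen, disc = adv$disc, report = report,
                 pretrain_losses = pre$losses, gen_losses = adv$gen_losses,
                 disc_losses = adv$disc_losses, clinical_cor = clinical_cor,
                 out_dir = config$out_dir))
}
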