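# Serialization of cohorts, PI archives, checkpoints and run configs.
# Recordings are stored as a numeric-array bundle: one .rds matrix
# (channels x samples) plus a .json sidecar per subject, and a clinical.csv.

#' Write a cohort as a numeric-array bundle
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eeg_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    saveRDS(rec$data, file.path(dir, paste0(rec$subject_id, ".rds")))
    meta <- list(subject_id = rec$subject_id, fs = rec$fs,
                 label = rec$label,
                 band_amplitudes = as.list(rec$band_amplitudes))
    jsonlite::write_json(meta, file.path(dir, paste0(rec$subject_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cohort$clinical) && nrow(cohort$clinical)) {
    utils::write.csv(
      cohort$clinical[, c("subject_id", "panss_total", "panss_positive",
                          "panss_negative")],
      file.path(dir, "clinical.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_eeg_bundle()]
#'
#' @param dir bundle directory.
#' @return an `eeg_cohort` (without the generating config).
#' @export
read_eeg_bundle <- function(dir) {
  metas <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(metas)) stop("no recordings found in ", dir)
  recs <- list()
  for (mf in metas) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    rds <- sub("\\.json$", ".rds", mf)
    if (!file.exists(rds)) stop("missing data file for ", meta$subject_id)
    amps <- unlist(meta$band_amplitudes)
    recs[[meta$subject_id]] <- new_eeg_recording(
      meta$subject_id, readRDS(rds), meta$fs, meta$label,
      if (length(amps)) amps else NULL)
  }
  clin_file <- file.path(dir, "clinical.csv")
  clinical <- if (file.exists(clin_file)) {
    tibble::as_tibble(utils::read.csv(clin_file, stringsAsFactors = FALSE))
  } else NULL
  structure(list(recordings = recs, clinical = clinical, config = NULL),
            class = "eeg_cohort")
}

#' Write / read a persistence-image archive
#'
#' The images are stored as an RDS payload with a JSON metadata sidecar
#' (axis ranges and TDA settings).
#'
#' @param pi_seqs a `pi_sequences` object.
#' @param path archive path (`.rds`; the sidecar gets `.json`).
#' @return `path`, invisibly.
#' @export
write_pi_archive <- function(pi_seqs, path) {
  stopifnot(inherits(pi_seqs, "pi_sequences"))
  saveRDS(unclass(pi_seqs), path)
  tda <- attr(pi_seqs, "tda")
  meta <- list(ranges = attr(pi_seqs, "ranges"),
               tda = if (!is.null(tda)) unclass(tda))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pi_archive
#' @export
read_pi_archive <- function(path) {
  if (!file.exists(path)) stop("no such archive: ", path)
  seqs <- readRDS(path)
  meta_file <- paste0(path, ".json")
  out <- structure(seqs, class = "pi_sequences")
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    attr(out, "ranges") <- meta$ranges
    attr(out, "tda") <- meta$tda
  }
  out
}

#' Save / load a model checkpoint
#'
#' Stores generator and discriminator parameter states with their
#' structural settings; loading validates shapes against the requested
#' resolution.
#'
#' @param gen a `generator_state`.
#' @param disc optional `discriminator_state`.
#' @param config optional `training_config`, stored alongside.
#' @param path checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(gen, disc = NULL, config = NULL, path) {
  saveRDS(list(gen = gen, disc = disc, config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  ck <- readRDS(path)
  if (!inherits(ck$gen, "generator_state")) {
    stop("corrupted checkpoint: no generator state in ", path)
  }
  with(ck$gen, stopifnot(n_pixels == resolution^2,
                         ncol(params$fc$W) == n_pixels))
  ck
}

# ---- run configuration ----------------------------------------------------

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "topoforecast-run",
    bands = "Alpha",
    window_s = 4,
    cohort = list(n_subjects_per_class = 10L, duration_s = 160, fs = 250,
                  n_channels = 8L, noise_sd = 2, amp_jitter_sd = 0.2,
                  am_depth = 0.5, clinical_slope = 1, clinical_noise_sd = 1,
                  class_effect = list(Delta = 0, Theta = 0, Alpha = 0,
                                      Beta = 0, Gamma = 0)),
    tda = list(embed_dim = 3L, delay = 4L, max_points = 200L,
               max_hom_dim = 2L, hom_dims = c(1L, 2L), resolution = 100L),
    training = list(lr_pretrain = 0.01, lr_joint = 0.001, batch_size = 32L,
                    classification_threshold = 0.4, gat_dropout = 0.6,
                    epochs_pretrain = 100L, epochs_joint = 800L,
                    train_frac = 0.8, val_frac = 0.1, recon_weight = 1,
                    disc_loss_floor = 0.35),
    clinical = list(epochs = 500L)
  )
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(defaults)) return(override)
  extra <- setdiff(names(override), names(defaults))
  if (length(extra)) {
    stop("unknown config key", if (length(extra) > 1) "s" else "", ": ",
         paste0(path, extra, collapse = ", "))
  }
  for (nm in names(override)) {
    defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                   paste0(path, nm, "."))
  }
  defaults
}

#' Build a validated run configuration
#'
#' Merges user overrides into the package defaults; unknown keys are
#' rejected by name. The result serializes losslessly to and from JSON.
#'
#' @param ... named overrides matching the default structure (see
#'   `topoforecast:::run_config_defaults()`), e.g.
#'   `run_config(seed = 7, tda = list(resolution = 20))`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  structure(merge_config(run_config_defaults(), list(...)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return [load_run_config()] returns the validated `run_config`.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}
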