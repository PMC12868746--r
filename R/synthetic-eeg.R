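#' Configuration for a synthetic EEG cohort
#'
#' Describes a two-class (patient/control) cohort of multi-channel EEG
#' recordings built from amplitude-modulated band-limited oscillations.
#' Each recording is the sum, over the five classical bands, of a sinusoid
#' at band-centre frequency with slow random amplitude modulation plus
#' band-passed Gaussian noise, plus broadband white noise. Patients differ
#' from controls by additive shifts (`class_effect`) of the per-band
#' amplitudes, and every subject carries a lognormal amplitude jitter so
#' per-subject summaries (used to plant clinical relations) vary across the
#' cohort.
#'
#' @param n_subjects_per_class subjects per class.
#' @param duration_s recording length in seconds (default 160, divisible by
#'   `window_s`).
#' @param fs sampling rate in Hz (default 250).
#' @param n_channels channels per recording (default 8).
#' @param band_amplitude named 5-vector of mean band amplitudes (arbitrary
#'   microvolt-scale units) for Delta/Theta/Alpha/Beta/Gamma.
#' @param class_effect named 5-vector of additive patient-class amplitude
#'   shifts per band.
#' @param amp_jitter_sd sd of the per-subject lognormal amplitude jitter.
#' @param noise_sd sd of broadband white noise added per channel.
#' @param am_depth depth of the slow amplitude modulation in `[0, 1)`.
#' @param clinical_slope slope of the planted linear relation between a
#'   patient's mean Theta amplitude and the PANSS-like total score.
#' @param clinical_noise_sd sd of the noise on the planted score.
#' @param window_s analysis window length the duration must tile.
#' @param seed integer seed; fully determines the cohort.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_class = 10L, duration_s = 160,
                          fs = 250, n_channels = 8L,
                          band_amplitude = c(Delta = 20, Theta = 10,
                                             Alpha = 15, Beta = 5, Gamma = 3),
                          class_effect = c(Delta = 0, Theta = 0, Alpha = 0,
                                           Beta = 0, Gamma = 0),
                          amp_jitter_sd = 0.2, noise_sd = 2, am_depth = 0.5,
                          clinical_slope = 1, clinical_noise_sd = 1,
                          window_s = 4, seed = 1L) {
  if (fs <= 0 || duration_s <= 0) {
    stop("invalid config: fs and duration_s must be positive")
  }
  if (n_subjects_per_class < 1 || n_channels < 1) {
    stop("invalid config: need at least one subject and one channel")
  }
  if (abs(duration_s / window_s - round(duration_s / window_s)) > 1e-9) {
    stop("invalid config: duration_s must be divisible by window_s")
  }
  band_names <- names(eeg_bands())
  band_amplitude <- band_amplitude[band_names]
  class_effect <- class_effect[band_names]
  if (anyNA(band_amplitude) || anyNA(class_effect) ||
      !all(is.finite(c(band_amplitude, class_effect)))) {
    stop("invalid config: band_amplitude and class_effect must be finite ",
         "and named over ", paste(band_names, collapse = "/"))
  }
  structure(list(
    n_subjects_per_class = as.integer(n_subjects_per_class),
    duration_s = duration_s, fs = fs, n_channels = as.integer(n_channels),
    band_amplitude = band_amplitude, class_effect = class_effect,
    amp_jitter_sd = amp_jitter_sd, noise_sd = noise_sd, am_depth = am_depth,
    clinical_slope = clinical_slope, clinical_noise_sd = clinical_noise_sd,
    window_s = window_s, seed = as.integer(seed)
  ), class = "cohort_config")
}

new_eeg_recording <- function(subject_id, data, fs, label,
                              band_amplitudes = NULL) {
  stopifnot(is.matrix(data), nrow(data) >= 1, all(is.finite(data)),
            fs > 0, label %in% c("patient", "control", "unknown"))
  structure(list(subject_id = subject_id, data = data, fs = fs,
                 label = label, band_amplitudes = band_amplitudes),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

simulate_recording <- function(config, subject_id, label) {
  bands <- eeg_bands()
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  is_patient <- label == "patient"
  amps <- pmax(config$band_amplitude +
                 if (is_patient) config$class_effect else 0, 0)
  amps <- amps * exp(stats::rnorm(length(amps), 0, config$amp_jitter_sd))
  names(amps) <- names(bands)
  data <- matrix(0, config$n_channels, n)
  # one coherent source per band, projected to every channel with a small
  # per-channel gain and phase perturbation (volume-conduction-like), so
  # band rhythms survive channel averaging as they do in scalp EEG
  for (b in names(bands)) {
    if (amps[[b]] == 0) next
    f0 <- mean(bands[[b]])
    am_f <- stats::runif(1, 0.05, 0.3)
    am_ph <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    am <- 1 + config$am_depth * sin(2 * pi * am_f * t + am_ph)
    bn <- band_noise(n, config$fs, bands[[b]])
    for (ch in seq_len(config$n_channels)) {
      gain <- exp(stats::rnorm(1, 0, 0.1))
      jit <- stats::rnorm(1, 0, 0.2)
      carrier <- sin(2 * pi * f0 * t + ph + jit) * am
      data[ch, ] <- data[ch, ] + amps[[b]] * gain * (carrier + 0.3 * bn)
    }
  }
  for (ch in seq_len(config$n_channels)) {
    data[ch, ] <- data[ch, ] + stats::rnorm(n, 0, config$noise_sd)
  }
  new_eeg_recording(subject_id, data, config$fs, label, amps)
}

# Unit-variance Gaussian noise band-passed into [low, high] Hz.
band_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  y <- bandpass_series(w, fs, band[1], band[2])
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate a labelled synthetic EEG cohort with clinical scores
#'
#' Simulates `2 * n_subjects_per_class` recordings (classes `patient` and
#' `control`) from a [cohort_config()], then plants a PANSS-like clinical
#' score for each patient via [plant_clinical_relation()] using the config's
#' `clinical_slope` and `clinical_noise_sd`. The config seed fully
#' determines the output.
#'
#' @param config a [cohort_config()].
#' @return list with `recordings` (list of `eeg_recording`) and `clinical`
#'   (tibble of per-patient scores), class `eeg_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- with_seed(substream_seed(config$seed, "cohort"), {
    out <- list()
    for (cls in c("patient", "control")) {
      for (i in seq_len(config$n_subjects_per_class)) {
        id <- sprintf("%s%02d", if (cls == "patient") "P" else "C", i)
        out[[id]] <- simulate_recording(config, id, cls)
      }
    }
    out
  })
  cohort <- structure(list(recordings = recs, config = config),
                      class = "eeg_cohort")
  cohort$clinical <- plant_clinical_relation(
    cohort, slope = config$clinical_slope,
    noise_sd = config$clinical_noise_sd,
    seed = substream_seed(config$seed, "clinical"))
  cohort
}

#' @export
print.eeg_cohort <- function(x, ...) {
  labs <- vapply(x$recordings, `[[`, "", "label")
  cat(sprintf("<eeg_cohort> %d recordings (%d patient / %d control), %g s @ %g Hz\n",
              length(labs), sum(labs == "patient"), sum(labs == "control"),
              x$config$duration_s, x$config$fs))
  invisible(x)
}

#' Plant a linear clinical-score relation in a cohort
#'
#' Assigns each patient-class subject PANSS-like scores linearly related to
#' a declared, topologically relevant signal property: the subject's
#' realized mean Theta-band amplitude (which drives the scale of loops in
#' the delay-embedded Theta windows). `panss_total = 50 + slope * property
#' + N(0, noise_sd)`; positive and negative subscores are fixed fractions
#' of the total plus the same noise model. With `noise_sd = 0` and
#' `slope = 1` the total score is an exact affine map of the property.
#'
#' @param cohort an `eeg_cohort` (or bare list of `eeg_recording`s).
#' @param slope linear slope on the planted property.
#' @param noise_sd Gaussian noise sd on each score.
#' @param seed integer seed for the noise.
#' @return tibble with `subject_id`, `panss_total`, `panss_positive`,
#'   `panss_negative` and the planted `property` (one row per patient).
#' @export
plant_clinical_relation <- function(cohort, slope, noise_sd, seed = 1L) {
  recs <- if (inherits(cohort, "eeg_cohort")) cohort$recordings else cohort
  stopifnot(length(recs) > 0)
  pats <- Filter(function(r) r$label == "patient", recs)
  if (!length(pats)) {
    return(tibble::tibble(subject_id = character(), panss_total = numeric(),
                          panss_positive = numeric(),
                          panss_negative = numeric(), property = numeric()))
  }
  prop <- unname(vapply(pats, function(r) unname(r$band_amplitudes[["Theta"]]),
                        numeric(1)))
  with_seed(seed, {
    total <- 50 + slope * prop + stats::rnorm(length(prop), 0, noise_sd)
    tibble::tibble(
      subject_id = vapply(pats, `[[`, "", "subject_id"),
      panss_total = total,
      panss_positive = 0.28 * total + stats::rnorm(length(prop), 0, noise_sd),
      panss_negative = 0.23 * total + stats::rnorm(length(prop), 0, noise_sd),
      property = prop)
  })
}
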