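#' TDA configuration for the EEG-to-image pipeline
#'
#' @param embed_dim delay-embedding dimension (default 3).
#' @param delay embedding delay in samples (default 4); set
#'   `delay = "ami"` to select it per window by the first minimum of the
#'   average mutual information.
#' @param max_points cloud subsample cap before the Rips filtration
#'   (default 200).
#' @param max_hom_dim largest homology dimension computed (default 2).
#' @param hom_dims homology dimensions accumulated into the image
#'   (default `c(1, 2)`: the high-order image).
#' @param resolution image side `R` (default 100).
#' @param sigma persistence-image kernel sd; `NULL` for 0.05 x
#'   persistence-axis range.
#' @return a `tda_config` list.
#' @export
tda_config <- function(embed_dim = 3L, delay = 4L, max_points = 200L,
                       max_hom_dim = 2L, hom_dims = c(1L, 2L),
                       resolution = 100L, sigma = NULL) {
  stopifnot(embed_dim >= 2, max_points >= 2, max_hom_dim %in% 0:2,
            resolution >= 2, all(hom_dims <= max_hom_dim))
  structure(list(embed_dim = as.integer(embed_dim), delay = delay,
                 max_points = as.integer(max_points),
                 max_hom_dim = as.integer(max_hom_dim),
                 hom_dims = as.integer(hom_dims),
                 resolution = as.integer(resolution), sigma = sigma),
            class = "tda_config")
}

#' Extract per-subject persistence-image sequences from a cohort
#'
#' The full preparation pipeline: for every recording and requested band,
#' band-pass filter, collapse channels, cut consecutive non-overlapping
#' windows, delay-embed each window, subsample the cloud, compute the
#' Vietoris-Rips diagram, and vectorize it as a persistence image. Image
#' axis ranges are pooled per band across the whole input so images are
#' comparable across windows and subjects; the pooled ranges are attached
#' to the result.
#'
#' @param cohort an `eeg_cohort` (or bare list of `eeg_recording`s).
#' @param bands character vector of band names (default `"Alpha"`).
#' @param window_s window length in seconds.
#' @param tda a [tda_config()].
#' @param channel `NULL` (channel mean) or a channel index.
#' @param prefilter apply the broadband prefilter + notch first?
#' @param seed integer seed for the cloud subsampling.
#' @return a `pi_sequences` list; each element has `subject_id`, `label`,
#'   `band` and `pis` (array `[n_windows, R, R]`). Attributes: `ranges`
#'   (per-band axis ranges), `tda`.
#' @export
extract_pi_sequences <- function(cohort, bands = "Alpha", window_s = 4,
                                 tda = tda_config(), channel = NULL,
                                 prefilter = FALSE, seed = 1L) {
  recs <- if (inherits(cohort, "eeg_cohort")) cohort$recordings else cohort
  stopifnot(length(recs) > 0, all(bands %in% names(eeg_bands())))
  band_defs <- eeg_bands()[bands]

  diagrams <- list()
  meta <- list()
  for (rec in recs) {
    if (prefilter) rec <- broadband_prefilter(rec)
    bw <- band_windows(rec, band_defs, window_s = window_s,
                       channel = channel)
    for (b in bands) {
      wins <- bw[[b]]
      dgs <- lapply(seq_len(nrow(wins)), function(w) {
        x <- wins[w, ]
        delay <- if (identical(tda$delay, "ami")) select_delay_ami(x) else
          tda$delay
        cloud <- delay_embed(x, tda$embed_dim, delay)
        cloud <- subsample_cloud(cloud, tda$max_points,
                                 seed = substream_seed(
                                   seed, paste(rec$subject_id, b, w)))
        rips_persistence(cloud, max_hom_dim = tda$max_hom_dim)
      })
      key <- paste(rec$subject_id, b, sep = "|")
      diagrams[[key]] <- dgs
      meta[[key]] <- list(subject_id = rec$subject_id, label = rec$label,
                          band = b)
    }
  }

  ranges <- lapply(bands, function(b) {
    keys <- names(meta)[vapply(meta, function(m) m$band == b, logical(1))]
    pi_axis_ranges(unlist(diagrams[keys], recursive = FALSE),
                   hom_dims = tda$hom_dims)
  })
  names(ranges) <- bands

  out <- lapply(names(meta), function(key) {
    m <- meta[[key]]
    rg <- ranges[[m$band]]
    imgs <- lapply(diagrams[[key]], diagram_to_pi,
                   resolution = tda$resolution, sigma = tda$sigma,
                   hom_dims = tda$hom_dims,
                   birth_range = rg$birth_range, pers_range = rg$pers_range)
    pis <- array(0, c(length(imgs), tda$resolution, tda$resolution))
    for (w in seq_along(imgs)) pis[w, , ] <- imgs[[w]]
    list(subject_id = m$subject_id, label = m$label, band = m$band,
         pis = pis)
  })
  structure(out, ranges = ranges, tda = tda, class = "pi_sequences")
}

#' Simulate persistence-image sequences with planted structure
#'
#' A lightweight stand-in for the EEG pipeline when only the forecasting
#' model is under study: each subject's sequence is a Gaussian bump on the
#' image grid whose centre drifts along a circle by `drift_step` radians
#' per window (planted temporal structure), observed with i.i.d. pixel
#' noise and optional occlusions - pixels zeroed at random - so the
#' planted spatial smoothness is informative (neighbouring pixels let a
#' model fill the holes). Values are clipped to `[0, 1]`.
#'
#' @param n_subjects number of subjects.
#' @param n_windows windows per subject.
#' @param resolution image side `R`.
#' @param drift_step angular drift per window (radians).
#' @param bump_sd bump width as a fraction of the image side.
#' @param noise_sd pixel noise standard deviation.
#' @param occlusion_frac fraction of pixels zeroed per window.
#' @param labels optional character vector of per-subject labels.
#' @param seed integer seed.
#' @return a `pi_sequences` list.
#' @export
simulate_pi_sequences <- function(n_subjects, n_windows, resolution = 20L,
                                  drift_step = 0.5, bump_sd = 0.12,
                                  noise_sd = 0.05, occlusion_frac = 0,
                                  labels = NULL, seed = 1L) {
  R <- as.integer(resolution)
  gx <- (seq_len(R) - 0.5) / R
  labels <- labels %||% rep("unknown", n_subjects)
  stopifnot(length(labels) == n_subjects)
  with_seed(substream_seed(seed, "simpi"), {
    out <- lapply(seq_len(n_subjects), function(s) {
      theta <- stats::runif(1, 0, 2 * pi)
      pis <- array(0, c(n_windows, R, R))
      for (w in seq_len(n_windows)) {
        cx <- 0.5 + 0.25 * cos(theta)
        cy <- 0.5 + 0.25 * sin(theta)
        img <- stats::dnorm(gx, cx, bump_sd) %o% stats::dnorm(gx, cy, bump_sd)
        img <- img / max(img)
        img <- img + matrix(stats::rnorm(R * R, 0, noise_sd), R, R)
        if (occlusion_frac > 0) {
          img[matrix(stats::runif(R * R) < occlusion_frac, R, R)] <- 0
        }
        pis[w, , ] <- pmin(pmax(img, 0), 1)
        theta <- theta + drift_step
      }
      list(subject_id = sprintf("S%02d", s), label = labels[s],
           band = "synthetic", pis = pis)
    })
    structure(out, class = "pi_sequences")
  })
}
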