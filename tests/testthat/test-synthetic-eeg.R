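test_that("cohort generation honours shape, labels and determinism", {
  cfg <- cohort_config(n_subjects_per_class = 2, duration_s = 160, fs = 250,
                       n_channels = 3, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co$recordings, 4)
  for (rec in co$recordings) {
    expect_equal(dim(rec$data), c(3L, 40000L))
    expect_true(all(is.finite(rec$data)))
  }
  labs <- vapply(co$recordings, `[[`, "", "label")
  expect_equal(sort(as.vector(table(labs))), c(2L, 2L))

  co2 <- generate_cohort(cfg)
  expect_identical(co$recordings, co2$recordings)
  expect_identical(co$clinical, co2$clinical)

  co3 <- generate_cohort(cohort_config(n_subjects_per_class = 2,
                                       duration_s = 160, seed = 6))
  expect_false(identical(co$recordings[[1]]$data, co3$recordings[[1]]$data))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(fs = 0), "invalid config")
  expect_error(cohort_config(duration_s = -4), "invalid config")
  expect_error(cohort_config(duration_s = 10, window_s = 4),
               "divisible")
  expect_error(cohort_config(band_amplitude = c(Delta = 1)),
               "invalid config")
})

test_that("zero effect sizes give exchangeable classes (Monte-Carlo null)", {
  reps <- 40
  pvals <- vapply(seq_len(reps), function(i) {
    cfg <- cohort_config(n_subjects_per_class = 4L, duration_s = 8,
                         fs = 100, n_channels = 2L, noise_sd = 0,
                         seed = 1000 + i)
    co <- generate_cohort(cfg)
    labs <- vapply(co$recordings, `[[`, "", "label")
    pw <- vapply(co$recordings, function(r) {
      mean(apply(r$data, 1, topoforecast:::band_power, fs = r$fs,
                 band = c(8, 12)))
    }, numeric(1))
    wilcox.test(pw[labs == "patient"], pw[labs == "control"],
                exact = TRUE)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("generated spectra concentrate power inside configured bands", {
  cfg <- cohort_config(n_subjects_per_class = 1, duration_s = 16, fs = 250,
                       n_channels = 1, noise_sd = 1, seed = 21)
  rec <- generate_cohort(cfg)$recordings[[1]]
  x <- rec$data[1, ]
  ref_density <- topoforecast:::band_power(x, rec$fs, c(55, 80)) / 25
  for (b in names(eeg_bands())) {
    band <- eeg_bands()[[b]]
    dens <- topoforecast:::band_power(x, rec$fs, band) / diff(band)
    expect_gt(dens, 2 * ref_density)
  }
})

test_that("larger band effects widen the between-class power gap", {
  gap <- function(effect) {
    diffs <- vapply(1:20, function(i) {
      cfg <- tiny_cohort_config(
        class_effect = c(Delta = 0, Theta = 0, Alpha = effect,
                         Beta = 0, Gamma = 0),
        seed = 3000 + i)
      co <- generate_cohort(cfg)
      labs <- vapply(co$recordings, `[[`, "", "label")
      pw <- vapply(co$recordings, function(r) {
        topoforecast:::band_power(r$data[1, ], r$fs, c(8, 12))
      }, numeric(1))
      mean(pw[labs == "patient"]) - mean(pw[labs == "control"])
    }, numeric(1))
    mean(diffs)
  }
  g0 <- gap(0); g5 <- gap(5); g15 <- gap(15)
  expect_lt(g0, g5)
  expect_lt(g5, g15)
})

test_that("planted clinical relation behaves across slope and noise", {
  recs <- stub_cohort(30, seed = 9)

  # exact linear map when noiseless
  cl <- plant_clinical_relation(recs, slope = 1, noise_sd = 0, seed = 2)
  expect_equal(nrow(cl), 30)
  expect_equal(cor(cl$panss_total, cl$property), 1)
  expect_equal(cl$panss_total, 50 + cl$property)

  # slope 0: score independent of the property
  nulls <- vapply(1:60, function(i) {
    cl0 <- plant_clinical_relation(stub_cohort(30, seed = i), slope = 0,
                                   noise_sd = 1, seed = i)
    abs(cor(cl0$panss_total, cl0$property))
  }, numeric(1))
  expect_gte(mean(nulls < 0.5), 0.95)

  # power: small noise, slope 1
  hits <- vapply(1:100, function(i) {
    cl1 <- plant_clinical_relation(stub_cohort(30, seed = 100 + i),
                                   slope = 1, noise_sd = 0.5,
                                   seed = 100 + i)
    cor.test(cl1$panss_total, cl1$property)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # scores exist only for patient-class subjects
  mixed <- stub_cohort(3, n_controls = 4, seed = 4)
  clm <- plant_clinical_relation(mixed, 1, 0.1, seed = 1)
  expect_equal(nrow(clm), 3)
  expect_true(all(startsWith(clm$subject_id, "P")))
})
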