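test_that("pair construction counts and grouping are correct", {
  seqs <- simulate_pi_sequences(2, 40, resolution = 4, seed = 1,
                                labels = c("patient", "patient"))
  pairs <- make_pairs(seqs)
  expect_equal(pairs$n_pairs, 2 * 39)
  expect_equal(as.vector(table(pairs$subject_id)), c(39L, 39L))

  # inputs at t+1 equal targets at t within a subject, never across
  i1 <- which(pairs$subject_id == "S01")
  expect_equal(pairs$input[, i1[2]], pairs$target[, i1[1]])

  two <- simulate_pi_sequences(1, 2, resolution = 4, seed = 2)
  expect_equal(make_pairs(two)$n_pairs, 1L)

  mixed <- c(simulate_pi_sequences(1, 3, resolution = 4, seed = 3),
             simulate_pi_sequences(1, 1, resolution = 4, seed = 4))
  class(mixed) <- "pi_sequences"
  mixed[[2]]$subject_id <- "S99"
  expect_warning(p <- make_pairs(mixed), "fewer than 2")
  expect_equal(p$n_pairs, 2L)
})

test_that("subject splits are disjoint, complete and reproducible", {
  ids <- sprintf("S%02d", 1:20)
  sp <- split_subjects(ids, train_frac = 0.8, val_frac = 0.1, seed = 5)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_equal(length(sp$test), 4)
  expect_identical(sp, split_subjects(ids, 0.8, 0.1, seed = 5))
  expect_false(identical(sp, split_subjects(ids, 0.8, 0.1, seed = 6)))
})

test_that("pretraining learns a constant target and is seed-deterministic", {
  # every target identical: the generator can push its bias to the target
  R <- 6
  target <- matrix(0.2, R, R); target[2:4, 3:5] <- 0.8
  seqs <- list(list(subject_id = "S01", label = "patient", band = "toy",
                    pis = array(rep(target, 12), c(12, R, R))))
  class(seqs) <- "pi_sequences"
  pairs <- make_pairs(seqs)
  cfg <- training_config(seed = 2, batch_size = 8, gat_dropout = 0.2)
  gen <- generator_state(R, seed = 1, dropout = 0.2)
  out <- pretrain_generator(gen, pairs, cfg, epochs = 15)
  expect_lt(out$losses[15], out$losses[1])

  out2 <- pretrain_generator(gen, pairs, cfg, epochs = 15)
  expect_identical(out$losses, out2$losses)
  expect_identical(out$gen$params, out2$gen$params)
})

test_that("adversarial training is deterministic and tracks both losses", {
  seqs <- simulate_pi_sequences(3, 6, resolution = 6, seed = 9)
  pairs <- make_pairs(seqs)
  cfg <- training_config(seed = 4, batch_size = 8)
  gen <- generator_state(6, seed = 2)
  disc <- discriminator_state(6, seed = 3)
  adv <- adversarial_train(gen, disc, pairs, cfg, epochs = 4)
  expect_length(adv$gen_losses, 4)
  expect_length(adv$disc_losses, 4)
  expect_true(all(is.finite(c(adv$gen_losses, adv$disc_losses))))
  adv2 <- adversarial_train(gen, disc, pairs, cfg, epochs = 4)
  expect_identical(adv$gen_losses, adv2$gen_losses)
  expect_identical(adv$disc_losses, adv2$disc_losses)
})

test_that("the discriminator learns to separate real from frozen-fake", {
  seqs <- simulate_pi_sequences(4, 8, resolution = 6, seed = 31)
  pairs <- make_pairs(seqs)
  gen <- generator_state(6, seed = 11)   # untrained, frozen
  tf <- asNamespace("topoforecast")
  P <- tf$generator_forward_batch(gen, pairs$input)$P
  Y <- t(pairs$target)
  disc <- discriminator_state(6, seed = 12)
  opt <- tf$rmsprop_state(disc$params)
  acc <- NA
  for (ep in 1:20) {
    fr <- tf$discriminator_forward_batch(disc, Y, keep_cache = TRUE)
    ff <- tf$discriminator_forward_batch(disc, P, keep_cache = TRUE)
    br <- tf$discriminator_backward(disc, fr$cache,
                                    (fr$y - 1) * 0.5 / length(fr$y))
    bf <- tf$discriminator_backward(disc, ff$cache,
                                    ff$y * 0.5 / length(ff$y))
    grads <- tf$map_leaves(br$grads, bf$grads, `+`)
    st <- tf$rmsprop_step(disc$params, grads, opt, 0.01)
    disc$params <- st$params; opt <- st$state
    acc <- mean(c(fr$y > 0.5, ff$y < 0.5))
  }
  expect_gt(acc, 0.9)
})

test_that("evaluation reports finite pixelwise metrics on a trained model", {
  seqs <- simulate_pi_sequences(4, 6, resolution = 6, seed = 21)
  pairs <- make_pairs(seqs)
  cfg <- training_config(seed = 7, batch_size = 16)
  gen <- generator_state(6, seed = 5)
  out <- pretrain_generator(gen, pairs, cfg, epochs = 10)
  rep <- evaluate_prediction(out$gen, pairs, cfg)
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$map >= 0 && rep$map <= 1)
  expect_gte(rep$mae, 0)
  expect_equal(nrow(rep$per_image), pairs$n_pairs)
})

test_that("trained forecaster beats the identity predictor on drifting data", {
  seqs <- simulate_pi_sequences(6, 10, resolution = 8, drift_step = 0.9,
                                noise_sd = 0.02, seed = 13)
  pairs <- make_pairs(seqs)
  cfg <- training_config(seed = 3, batch_size = 32, gat_dropout = 0.2)
  gen <- generator_state(8, seed = 6, dropout = 0.2)
  out <- pretrain_generator(gen, pairs, cfg, epochs = 40)
  P <- topoforecast:::generator_forward_batch(out$gen, pairs$input)$P
  model_mae <- mae(P, t(pairs$target))
  identity_mae <- mae(t(pairs$input), t(pairs$target))
  expect_lt(model_mae, identity_mae)
})

test_that("subject classification is seed-deterministic and needs two classes", {
  seqs <- simulate_pi_sequences(8, 5, resolution = 6, seed = 17,
                                labels = rep(c("patient", "control"), 4))
  cfg <- training_config(seed = 9, batch_size = 16, epochs_pretrain = 2)
  r1 <- classify_subjects(seqs, cfg)
  r2 <- classify_subjects(seqs, cfg)
  expect_identical(r1$score, r2$score)
  expect_true(is.numeric(attr(r1, "auc")))

  mono <- simulate_pi_sequences(4, 5, resolution = 6, seed = 18,
                                labels = rep("patient", 4))
  expect_error(classify_subjects(mono, cfg), "both classes")
})
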