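#' Training configuration
#'
#' Collects the optimization hyperparameters: RMSprop with learning rate
#' 0.01 during generator pretraining and 0.001 during joint
#' generator-discriminator training, batch size 32, binary cross-entropy
#' loss, pixel classification threshold 0.4, GAT dropout 0.6, and a
#' subject-level 80/20 train/test split with 10% of the training set held
#' out for validation.
#'
#' @param lr_pretrain,lr_joint RMSprop learning rates.
#' @param batch_size minibatch size.
#' @param classification_threshold pixel binarization threshold for the
#'   pixelwise AUC/MAP protocol.
#' @param gat_dropout dropout rate of the first GAT layer.
#' @param epochs_pretrain,epochs_joint epoch counts.
#' @param train_frac fraction of subjects in the training set.
#' @param val_frac fraction of the training set held out for validation.
#' @param recon_weight weight of the pixelwise reconstruction term in the
#'   generator's joint loss (adversarial BCE + recon_weight * pixel BCE).
#' @param disc_loss_floor balance gate for joint training: discriminator
#'   updates are skipped while its batch loss is below this floor, keeping
#'   the two players' gradients in balance (set to 0 to disable).
#' @param seed integer seed driving splits, initialization and dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(lr_pretrain = 0.01, lr_joint = 0.001,
                            batch_size = 32L, classification_threshold = 0.4,
                            gat_dropout = 0.6, epochs_pretrain = 100L,
                            epochs_joint = 800L, train_frac = 0.8,
                            val_frac = 0.1, recon_weight = 1,
                            disc_loss_floor = 0.35, seed = 1L) {
  stopifnot(lr_pretrain > 0, lr_joint > 0, batch_size >= 1,
            train_frac > 0, train_frac < 1, val_frac >= 0, val_frac < 1)
  structure(list(optimizer = "rmsprop", loss = "bce",
                 lr_pretrain = lr_pretrain, lr_joint = lr_joint,
                 batch_size = as.integer(batch_size),
                 classification_threshold = classification_threshold,
                 gat_dropout = gat_dropout,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_joint = as.integer(epochs_joint),
                 train_frac = train_frac, val_frac = val_frac,
                 recon_weight = recon_weight,
                 disc_loss_floor = disc_loss_floor, seed = as.integer(seed)),
            class = "training_config")
}

#' Build (input, target) image pairs from per-subject PI sequences
#'
#' One pair per consecutive window couple of every subject/band sequence
#' (40 windows give 39 pairs); pairs never cross subjects or bands.
#' Sequences with fewer than two windows are skipped with a warning.
#'
#' @param pi_seqs a `pi_sequences` list (see [extract_pi_sequences()] or
#'   [simulate_pi_sequences()]).
#' @return a `pi_pairs` object: flattened input/target matrices
#'   (`N x n_pairs`, row-major pixel order) plus per-pair metadata vectors
#'   `subject_id`, `label`, `band`, `t`.
#' @export
make_pairs <- function(pi_seqs) {
  stopifnot(length(pi_seqs) > 0)
  xs <- list(); ys <- list()
  sid <- lab <- band <- character(0); tt <- integer(0)
  res <- NULL
  for (entry in pi_seqs) {
    n_win <- dim(entry$pis)[1]
    if (is.null(res)) res <- dim(entry$pis)[2]
    if (n_win < 2L) {
      warning("sequence ", entry$subject_id, "/", entry$band,
              " has fewer than 2 windows; skipped")
      next
    }
    for (t in seq_len(n_win - 1L)) {
      xs[[length(xs) + 1L]] <- flatten_pi(entry$pis[t, , ])
      ys[[length(ys) + 1L]] <- flatten_pi(entry$pis[t + 1L, , ])
      sid <- c(sid, entry$subject_id)
      lab <- c(lab, entry$label %||% "unknown")
      band <- c(band, entry$band %||% "unknown")
      tt <- c(tt, t)
    }
  }
  if (!length(xs)) stop("no usable pairs: all sequences were singletons")
  structure(list(input = do.call(cbind, xs), target = do.call(cbind, ys),
                 subject_id = sid, label = lab, band = band, t = tt,
                 resolution = res, n_pairs = length(sid)),
            class = "pi_pairs")
}

#' @export
print.pi_pairs <- function(x, ...) {
  cat(sprintf("<pi_pairs> %d pairs, R = %d, %d subjects\n",
              x$n_pairs, x$resolution, length(unique(x$subject_id))))
  invisible(x)
}

#' Seed-reproducible subject-level split
#'
#' Splits subjects (not pairs) into train / validation / test sets so no
#' subject's windows straddle train and test.
#'
#' @param subject_ids character vector of subject ids (unique or not).
#' @param train_frac,val_frac split fractions (`val_frac` is taken from the
#'   training set).
#' @param seed integer seed.
#' @return list of character vectors `train`, `val`, `test`.
#' @export
split_subjects <- function(subject_ids, train_frac = 0.8, val_frac = 0.1,
                           seed = 1L) {
  ids <- unique(subject_ids)
  with_seed(substream_seed(seed, "split"), {
    ids <- sample(ids)
    n_train <- max(1L, round(train_frac * length(ids)))
    train <- ids[seq_len(n_train)]
    test <- setdiff(ids, train)
    n_val <- floor(val_frac * length(train))
    val <- if (n_val > 0) train[seq_len(n_val)] else character(0)
    list(train = setdiff(train, val), val = val, test = test)
  })
}

minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Pretrain the generator on pixelwise reconstruction
#'
#' Minimizes the mean pixel binary cross-entropy between the predicted and
#' true next-window images with RMSprop at `lr_pretrain`. Aborts with a
#' diagnostic if the loss diverges to a non-finite value.
#'
#' @param gen a `generator_state`.
#' @param pairs a `pi_pairs` training set.
#' @param config a `training_config`.
#' @param epochs overrides `config$epochs_pretrain` when given.
#' @return list with the trained `gen` and `losses` (per-epoch mean
#'   training loss).
#' @export
pretrain_generator <- function(gen, pairs, config = training_config(),
                               epochs = NULL) {
  stopifnot(inherits(gen, "generator_state"), inherits(pairs, "pi_pairs"),
            pairs$n_pairs > 0, nrow(pairs$input) == gen$n_pixels)
  epochs <- epochs %||% config$epochs_pretrain
  gen$dropout <- config$gat_dropout
  opt <- rmsprop_state(gen$params)
  losses <- numeric(epochs)
  with_seed(substream_seed(config$seed, "pretrain"), {
    for (ep in seq_len(epochs)) {
      batch_losses <- c()
      for (idx in minibatches(pairs$n_pairs, config$batch_size)) {
        X <- pairs$input[, idx, drop = FALSE]
        Y <- t(pairs$target[, idx, drop = FALSE])
        fw <- generator_forward_batch(gen, X, training = TRUE,
                                      keep_cache = TRUE)
        loss <- check_finite_loss(bce_loss(fw$P, Y), "generator pretraining")
        dlogit <- (clamp01(fw$P) - Y) / length(Y)
        grads <- generator_backward(gen, fw$cache, dlogit)
        step <- rmsprop_step(gen$params, grads, opt, config$lr_pretrain)
        gen$params <- step$params
        opt <- step$state
        batch_losses <- c(batch_losses, loss)
      }
      losses[ep] <- mean(batch_losses)
    }
  })
  list(gen = gen, losses = losses)
}

#' Adversarial generator-discriminator training
#'
#' Alternating updates at `lr_joint`: the discriminator minimizes BCE on
#' real next-window images (label 1) versus generated images (label 0); the
#' generator minimizes adversarial BCE toward label 1 plus
#' `recon_weight` times the pixelwise reconstruction BCE.
#'
#' @param gen a (preferably pretrained) `generator_state`.
#' @param disc a `discriminator_state`.
#' @param pairs a `pi_pairs` training set.
#' @param config a `training_config`.
#' @param epochs overrides `config$epochs_joint` when given.
#' @return list with trained `gen`, `disc`, and per-epoch `gen_losses` /
#'   `disc_losses`.
#' @export
adversarial_train <- function(gen, disc, pairs, config = training_config(),
                              epochs = NULL) {
  stopifnot(inherits(gen, "generator_state"),
            inherits(disc, "discriminator_state"),
            inherits(pairs, "pi_pairs"),
            disc$n_pixels == gen$n_pixels)
  epochs <- epochs %||% config$epochs_joint
  gen$dropout <- config$gat_dropout
  opt_g <- rmsprop_state(gen$params)
  opt_d <- rmsprop_state(disc$params)
  gen_losses <- disc_losses <- numeric(epochs)
  lam <- config$recon_weight
  with_seed(substream_seed(config$seed, "adversarial"), {
    for (ep in seq_len(epochs)) {
      gl <- dl <- c()
      for (idx in minibatches(pairs$n_pairs, config$batch_size)) {
        X <- pairs$input[, idx, drop = FALSE]
        Y <- t(pairs$target[, idx, drop = FALSE])
        B <- length(idx)

        fw <- generator_forward_batch(gen, X, training = TRUE,
                                      keep_cache = TRUE)
        P <- fw$P

        # discriminator step: real (label 1) vs generated (label 0)
        fr <- discriminator_forward_batch(disc, Y, keep_cache = TRUE)
        ff <- discriminator_forward_batch(disc, P, keep_cache = TRUE)
        d_loss <- 0.5 * (bce_loss(fr$y, rep(1, B)) +
                           bce_loss(ff$y, rep(0, B)))
        check_finite_loss(d_loss, "discriminator training")
        if (d_loss >= (config$disc_loss_floor %||% 0)) {
          # balance gate: only train the discriminator while it is not
          # already winning, so neither player's gradients swamp the other
          br <- discriminator_backward(disc, fr$cache,
                                       (clamp01(fr$y) - 1) * 0.5 / B)
          bf <- discriminator_backward(disc, ff$cache,
                                       clamp01(ff$y) * 0.5 / B)
          d_grads <- map_leaves(br$grads, bf$grads, `+`)
          step_d <- rmsprop_step(disc$params, d_grads, opt_d,
                                 config$lr_joint)
          disc$params <- step_d$params
          opt_d <- step_d$state
        }

        # generator step: fool the (updated) discriminator + reconstruct
        fg <- discriminator_forward_batch(disc, P, keep_cache = TRUE)
        g_loss <- bce_loss(fg$y, rep(1, B)) + lam * bce_loss(P, Y)
        check_finite_loss(g_loss, "adversarial generator training")
        bg <- discriminator_backward(disc, fg$cache, (clamp01(fg$y) - 1) / B)
        dlogit <- bg$dV * P * (1 - P) + lam * (clamp01(P) - Y) / length(Y)
        g_grads <- generator_backward(gen, fw$cache, dlogit)
        step_g <- rmsprop_step(gen$params, g_grads, opt_g, config$lr_joint)
        gen$params <- step_g$params
        opt_g <- step_g$state

        gl <- c(gl, g_loss); dl <- c(dl, d_loss)
      }
      gen_losses[ep] <- mean(gl)
      disc_losses[ep] <- mean(dl)
    }
  })
  list(gen = gen, disc = disc, gen_losses = gen_losses,
       disc_losses = disc_losses)
}

#' Evaluate next-window prediction with the pixelwise protocol
#'
#' For every test pair the target image is binarized at
#' `classification_threshold` to give pixel labels and the predicted pixel
#' intensities serve as scores; AUC and average precision are computed per
#' image (images whose binarized target is all-zero or all-one are excluded
#' from AUC/AP), MAP is the mean AP over images, and MAE is the pixelwise
#' mean absolute error over all pairs.
#'
#' @param gen a trained `generator_state`.
#' @param pairs a `pi_pairs` test set.
#' @param config a `training_config` (supplies the threshold).
#' @return an `evaluation_report`: list with `auc`, `map`, `mae`,
#'   `n_pairs`, `n_scored`, and a per-image tibble `per_image`.
#' @export
evaluate_prediction <- function(gen, pairs, config = training_config()) {
  stopifnot(inherits(pairs, "pi_pairs"), pairs$n_pairs > 0)
  P <- generator_forward_batch(gen, pairs$input, training = FALSE)$P
  sc <- score_predictions(P, t(pairs$target),
                          config$classification_threshold)
  structure(list(
    band = unique(pairs$band), n_pairs = pairs$n_pairs,
    n_scored = sc$n_scored, auc = sc$auc, map = sc$map, mae = sc$mae,
    per_image = tibble::tibble(subject_id = pairs$subject_id,
                               t = pairs$t, auc = sc$aucs, ap = sc$aps)
  ), class = "evaluation_report")
}

# Pixelwise scoring core: P and Y are n_images x n_pixels matrices;
# targets are binarized at `threshold`, predictions act as scores.
score_predictions <- function(P, Y, threshold) {
  stopifnot(all(dim(P) == dim(Y)))
  n <- nrow(P)
  aucs <- aps <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lab <- Y[i, ] > threshold
    if (any(lab) && !all(lab)) {
      aucs[i] <- auc_metric(P[i, ], lab)
      aps[i] <- average_precision(P[i, ], lab)
    }
  }
  scored <- is.finite(aucs)
  list(n_scored = sum(scored),
       auc = if (any(scored)) mean(aucs[scored]) else NA_real_,
       map = if (any(scored)) mean(aps[scored]) else NA_real_,
       mae = mae(P, Y), aucs = aucs, aps = aps)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> band %s: AUC %.3f, MAP %.3f, MAE %.4f (%d/%d pairs scored)\n",
              paste(x$band, collapse = "/"), x$auc, x$map, x$mae,
              x$n_scored, x$n_pairs))
  invisible(x)
}

#' Subject-level classification readout
#'
#' The generator is trained on the training-split patient subjects only;
#' every held-out subject (patient or control) is then scored by the
#' generator's forecasting skill on that subject: the mean pixelwise
#' reconstruction BCE of the forecast divided by the BCE of the identity
#' baseline that predicts the current image for the next window
#' (`mode = "reconstruction"`). Normalizing by the subject's own
#' window-to-window variability cancels how intrinsically hard each
#' subject's sequence is, leaving how well the trained dynamics transfer -
#' subjects from the trained (patient) class get lower ratios, so the
#' score is the negated ratio and AUC is reported patient-positive over
#' held-out subjects. With `mode = "discriminator"` the score is the mean
#' discriminator output on the subject's forecasts after adversarial
#' training.
#'
#' @param pi_seqs `pi_sequences` for a two-class cohort (single band).
#' @param config a `training_config`.
#' @param mode scoring mode.
#' @param epochs training epochs (defaults to `config$epochs_pretrain`).
#' @return tibble with `subject_id`, `label`, `score`, `predicted`;
#'   attribute `auc` holds the subject-level AUC.
#' @export
classify_subjects <- function(pi_seqs, config = training_config(),
                              mode = c("reconstruction", "discriminator"),
                              epochs = NULL) {
  mode <- match.arg(mode)
  labels <- vapply(pi_seqs, function(e) e$label, character(1))
  if (length(unique(labels[labels != "unknown"])) < 2) {
    stop("subject classification needs both classes in the cohort")
  }
  ids <- vapply(pi_seqs, function(e) e$subject_id, character(1))
  pat_ids <- unique(ids[labels == "patient"])
  sp <- split_subjects(pat_ids, config$train_frac, 0, config$seed)
  train_seqs <- pi_seqs[ids %in% sp$train]
  test_seqs <- pi_seqs[!(ids %in% c(sp$train, sp$val))]

  res <- dim(pi_seqs[[1]]$pis)[2]
  gen <- generator_state(res, dropout = config$gat_dropout,
                         seed = substream_seed(config$seed, "gen"))
  train_pairs <- make_pairs(train_seqs)
  pre <- pretrain_generator(gen, train_pairs, config, epochs = epochs)
  gen <- pre$gen
  disc <- NULL
  if (mode == "discriminator") {
    disc <- discriminator_state(res, seed = substream_seed(config$seed, "d"))
    adv <- adversarial_train(gen, disc, train_pairs, config,
                             epochs = epochs %||% config$epochs_joint)
    gen <- adv$gen; disc <- adv$disc
  }

  raw_stat <- function(entry) {
    pr <- make_pairs(list(entry))
    P <- generator_forward_batch(gen, pr$input, training = FALSE)$P
    if (mode == "reconstruction") {
      -bce_loss(P, t(pr$target)) / bce_loss(t(pr$input), t(pr$target))
    } else {
      mean(discriminator_forward_batch(disc, P)$y)
    }
  }
  scores <- vapply(test_seqs, raw_stat, numeric(1))
  test_ids <- vapply(test_seqs, function(e) e$subject_id, character(1))
  test_lab <- vapply(test_seqs, function(e) e$label, character(1))
  auc <- auc_metric(scores, test_lab == "patient")
  out <- tibble::tibble(subject_id = test_ids, label = test_lab,
                        score = scores,
                        predicted = ifelse(scores >= stats::median(scores),
                                           "patient", "control"))
  attr(out, "auc") <- auc
  out
}

#' The three generator variants of the ablation study
#'
#' Builds structurally matched generators: the full GAT+LSTM model, a
#' GAT-only variant (attention stack followed by a shared per-node affine
#' and sigmoid; the LSTM tail is bypassed) and an LSTM-only variant (the
#' flattened input image feeds the LSTM directly; the attention stack is
#' bypassed). Both ablations have fewer learnable parameters than the full
#' model.
#'
#' @param resolution image side `R`.
#' @param seed shared initialization seed.
#' @param ... forwarded to [generator_state()].
#' @return named list of `generator_state`s: `full`, `gat_only`,
#'   `lstm_only`.
#' @export
ablation_variants <- function(resolution, seed = 1L, ...) {
  list(full = generator_state(resolution, variant = "full", seed = seed, ...),
       gat_only = generator_state(resolution, variant = "gat_only",
                                  seed = seed, ...),
       lstm_only = generator_state(resolution, variant = "lstm_only",
                                   seed = seed, ...))
}

#' Run the ablation comparison on one train/test split
#'
#' Trains each variant with the same pretraining harness and reports the
#' test MAE per variant.
#'
#' @param train_pairs,test_pairs `pi_pairs` sets.
#' @param config a `training_config`.
#' @param epochs training epochs per variant.
#' @return tibble with `variant`, `test_mae`, `n_params`.
#' @export
ablation_experiment <- function(train_pairs, test_pairs,
                                config = training_config(), epochs = NULL) {
  variants <- ablation_variants(train_pairs$resolution,
                                seed = substream_seed(config$seed, "abl"),
                                dropout = config$gat_dropout)
  rows <- lapply(names(variants), function(nm) {
    tr <- pretrain_generator(variants[[nm]], train_pairs, config,
                             epochs = epochs)
    P <- generator_forward_batch(tr$gen, test_pairs$input,
                                 training = FALSE)$P
    tibble::tibble(variant = nm, test_mae = mae(P, t(test_pairs$target)),
                   n_params = count_params(tr$gen))
  })
  do.call(rbind, rows)
}
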