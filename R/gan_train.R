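# Adversarial training loop: alternating discriminator / generator updates
# with one Adam optimizer per network, same-length batches, optional
# coordinate-noise annealing (hinge mode) and critic iterations
# (Wasserstein mode).

#' Training configuration
#'
#' Defaults follow the reference training recipe: clash weight
#' `w_C = 0.3`, clash threshold 0.59 nm, Adam with `beta1 = 0`,
#' `beta2 = 0.9`, learning rates 0.00025 (generator) and 0.0004
#' (discriminators), batch 192, 50 epochs, top-k decay `gamma = 0.99` with
#' initial fraction `nu = 0.5`, gradient-penalty `lambda = 10` with five
#' critic iterations, and coordinate noise `sigma0 = 0.025` nm annealed
#' linearly to zero over the first quarter of the epochs (hinge mode
#' only). The `tiny` preset shrinks network widths, batch and epochs for
#' desk-scale runs; it never changes a loss definition.
#'
#' @param objective `"nonsaturated"`, `"hinge_topk"` or `"wasserstein_gp"`.
#' @param preset `"paper"` or `"tiny"`.
#' @param w_C Clash-penalty weight.
#' @param x_t Clash threshold, nm (or `NULL` to estimate from the data
#'   with [estimate_clash_threshold()]).
#' @param batch Batch size.
#' @param epochs Training epochs.
#' @param lr_G,lr_D Learning rates.
#' @param beta1,beta2 Adam moment decays.
#' @param topk_gamma,topk_nu Top-k decay factor per epoch and initial
#'   kept fraction.
#' @param gp_lambda,critic_iters Gradient-penalty weight and critic steps
#'   per generator step (Wasserstein mode).
#' @param noise_sigma0 Initial coordinate-noise standard deviation, nm
#'   (applied in hinge mode).
#' @param noise_anneal_frac Fraction of epochs over which the noise decays
#'   linearly to zero.
#' @param inst_noise_sigma0 Initial instance-noise standard deviation in
#'   standardized feature units, added to the distance features of both
#'   real and generated discriminator inputs and annealed like the
#'   coordinate noise. Zero disables it. A standard stabilizer for
#'   adversarial training when the two feature distributions barely
#'   overlap early on.
#' @param ema_decay Per-step decay of the exponential moving average kept
#'   over generator weights; sampling uses the averaged weights (a
#'   standard variance-reduction for adversarial generators). Zero
#'   disables averaging.
#' @param plan A [crop_plan()] or `NULL` (derive crop lengths from the
#'   data, quota = number of sequences, `n_frames` = 500).
#' @param seed Integer seed.
#' @param arch_G,arch_D Architecture overrides; defaults depend on the
#'   preset.
#' @return Object of class `training_configuration`.
#' @export
training_configuration <- function(objective = c("nonsaturated", "hinge_topk",
                                                 "wasserstein_gp"),
                                   preset = c("tiny", "paper"),
                                   w_C = 0.3, x_t = 0.59,
                                   batch = NULL, epochs = NULL,
                                   lr_G = 0.00025, lr_D = 0.0004,
                                   beta1 = 0.0, beta2 = 0.9,
                                   topk_gamma = 0.99, topk_nu = 0.5,
                                   gp_lambda = 10, critic_iters = 5L,
                                   noise_sigma0 = 0.025,
                                   noise_anneal_frac = 0.25,
                                   inst_noise_sigma0 = 0,
                                   ema_decay = 0.999,
                                   plan = NULL, seed = 1L,
                                   arch_G = NULL, arch_D = NULL) {
  objective <- match.arg(objective)
  preset <- match.arg(preset)
  if (w_C < 0) stop("w_C must be non-negative")
  if (is.null(batch)) batch <- if (preset == "paper") 192L else 64L
  if (is.null(epochs)) epochs <- if (preset == "paper") 50L else 30L
  stopifnot(lr_G > 0, lr_D > 0, batch >= 1, epochs >= 1)
  out_mode <- if (objective == "nonsaturated") "probability" else "score"
  if (is.null(arch_G))
    arch_G <- if (preset == "paper")
      generator_architecture()
    else
      generator_architecture(n_z = 8L, n_blocks = 2L, d_model = 32L,
                             n_heads = 4L)
  if (is.null(arch_D))
    arch_D <- if (preset == "paper")
      discriminator_architecture(output = out_mode)
    else
      discriminator_architecture(hidden = c(64L, 64L), output = out_mode)
  structure(list(objective = objective, preset = preset, w_C = w_C,
                 x_t = x_t, batch = as.integer(batch),
                 epochs = as.integer(epochs), lr_G = lr_G, lr_D = lr_D,
                 beta1 = beta1, beta2 = beta2, topk_gamma = topk_gamma,
                 topk_nu = topk_nu, gp_lambda = gp_lambda,
                 critic_iters = as.integer(critic_iters),
                 noise_sigma0 = noise_sigma0,
                 noise_anneal_frac = noise_anneal_frac,
                 inst_noise_sigma0 = inst_noise_sigma0,
                 ema_decay = ema_decay,
                 plan = plan, seed = as.integer(seed),
                 arch_G = arch_G, arch_D = arch_D),
            class = "training_configuration")
}

#' Initialize an untrained GAN model
#'
#' @param lengths Crop lengths needing a discriminator.
#' @param std A fitted [fit_standardizer()].
#' @param cfg A [training_configuration()].
#' @return Model object: generator weights `G`, per-length discriminators
#'   `D`, architectures, standardizer and spectral-norm state.
#' @export
init_gan_model <- function(lengths, std, cfg) {
  rng <- local_rng(cfg$seed)
  D <- list()
  sn_env <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    D[[as.character(L)]] <- init_discriminator(L, cfg$arch_D, rng)
    sn_env[[as.character(L)]] <- new.env(parent = emptyenv())
  }
  list(arch_G = cfg$arch_G, arch_D = cfg$arch_D,
       G = init_generator(cfg$arch_G, rng), D = D, sn_env = sn_env,
       std = std, cfg = cfg)
}

# distances -> coordinates gradient for one sample:
# d_p = |r_i - r_j|; dL/dr accumulated from dL/dd
dist_to_coord_grad <- function(coords, dists, ddist, idx) {
  u <- (coords[idx[, "i"], , drop = FALSE] -
        coords[idx[, "j"], , drop = FALSE]) / pmax(dists, 1e-9)
  contrib <- u * ddist
  gi <- rowsum(contrib, idx[, "i"], reorder = FALSE)
  gj <- rowsum(contrib, idx[, "j"], reorder = FALSE)
  g <- matrix(0, nrow(coords), 3L)
  g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
  g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] - gj
  g
}

#' Train the conditional GAN
#'
#' Alternates discriminator and generator Adam updates on same-length
#' batches (five critic iterations per generator step in Wasserstein
#' mode, 1:1 otherwise). Batches mix sequences; the epoch schedule follows
#' the crop plan. Deterministic for a fixed configuration seed.
#'
#' @param data List of [conformational_ensemble()] objects (one per
#'   training sequence).
#' @param cfg A [training_configuration()].
#' @param std Optional pre-fitted standardizer (defaults to fitting on
#'   `data`).
#' @param verbose Print one line per epoch.
#' @return The trained model, with element `log` (a `data.frame` of
#'   per-epoch discriminator/generator losses and clash statistics) and
#'   element `x_t` (the clash threshold used).
#' @export
train_gan <- function(data, cfg = training_configuration(), std = NULL,
                      verbose = FALSE) {
  stopifnot(length(data) >= 1L)
  seqs <- lapply(data, function(e) e$sequence)
  lens <- vapply(seqs, length, integer(1L))
  plan <- cfg$plan
  if (is.null(plan))
    plan <- crop_plan(L_train = unique(lens), c_max = length(data),
                      n_frames = 500L)
  if (is.null(std)) std <- fit_standardizer(data)
  x_t <- if (is.null(cfg$x_t)) estimate_clash_threshold(data) else cfg$x_t
  model <- init_gan_model(plan$L_train, std, cfg)
  optG <- adam_new(model$G, cfg$lr_G, cfg$beta1, cfg$beta2)
  optD <- lapply(model$D, function(w) adam_new(w, cfg$lr_D, cfg$beta1,
                                               cfg$beta2))
  rng <- local_rng(cfg$seed + 1L)
  nu <- cfg$topk_nu
  n_z <- cfg$arch_G$n_z
  log_rows <- vector("list", cfg$epochs)
  # flat per-ensemble coordinate views (frame-major rows) to avoid 3D
  # array slicing in the hot loop
  flat_xyz <- lapply(data, function(e)
    matrix(e$xyz, dim(e$xyz)[1L], dim(e$xyz)[2L] * 3L))
  flat_onehot <- lapply(data, function(e) as.numeric(t(e$sequence$onehot)))
  inst0 <- if (is.null(cfg$inst_noise_sigma0)) 0 else cfg$inst_noise_sigma0
  ema_d <- if (is.null(cfg$ema_decay)) 0 else cfg$ema_decay
  G_ema_flat <- unlist(model$G, use.names = FALSE)
  for (epoch in seq_len(cfg$epochs)) {
    anneal_end <- max(1, cfg$noise_anneal_frac * cfg$epochs)
    anneal <- max(0, 1 - (epoch - 1) / anneal_end)
    sigma <- 0
    if (cfg$objective == "hinge_topk" && cfg$noise_sigma0 > 0)
      sigma <- cfg$noise_sigma0 * anneal
    inst_sigma <- inst0 * anneal
    assignment <- assign_crops(seqs, plan, seed = cfg$seed + 1000L + epoch)
    # build the epoch's sample table: one row per (sequence, frame)
    tabs <- list()
    for (r in seq_len(nrow(assignment))) {
      si <- assignment$seq[r]
      nf <- min(plan$n_frames, n_frames(data[[si]]))
      fr <- rng$sample_int(n_frames(data[[si]]), nf,
                           replace = plan$n_frames > n_frames(data[[si]]))
      tabs[[r]] <- cbind(seq = si, frame = fr, crop = assignment$crop[r])
    }
    tab <- do.call(rbind, tabs)
    tab <- tab[rng$sample_int(nrow(tab)), , drop = FALSE]
    ep_stats <- c(lossD = 0, lossG = 0, clash = 0, nb = 0)
    for (Lt in plan$L_train) {
      sub <- tab[tab[, "crop"] == Lt, , drop = FALSE]
      n_batches <- floor(nrow(sub) / cfg$batch)
      if (n_batches == 0L) next
      key <- as.character(Lt)
      env <- model$sn_env[[key]]
      idxP <- pair_index(Lt)
      critic_count <- 0L
      # one latent draw per crop-length group (per-call RNG stream
      # switching is measurable at this batch size)
      Zall <- rng$norm(n_batches * cfg$batch * Lt * n_z)
      z_per_batch <- cfg$batch * Lt * n_z
      for (bi in seq_len(n_batches)) {
        rows <- sub[((bi - 1L) * cfg$batch + 1L):(bi * cfg$batch), ,
                    drop = FALSE]
        B <- nrow(rows)
        # ---- real batch (cropped, optionally noised) ----
        real_stack <- matrix(NA_real_, B * Lt, 3L)
        seq_batch <- vector("list", B)
        oh_rows <- vector("list", B)
        for (b in seq_len(B)) {
          si <- rows[b, "seq"]
          ens <- data[[si]]
          Lfull <- dim(ens$xyz)[2L]
          s0 <- crop_start(Lfull, Lt, rng)
          cols <- rep(s0:(s0 + Lt - 1L), 3L) + rep(0:2 * Lfull, each = Lt)
          cc <- matrix(flat_xyz[[si]][rows[b, "frame"], cols], Lt, 3L)
          if (sigma > 0) cc <- cc + matrix(rng$norm(Lt * 3L, sd = sigma),
                                           Lt, 3L)
          real_stack[((b - 1L) * Lt + 1L):(b * Lt), ] <- cc
          if (Lfull == Lt) {
            seq_batch[[b]] <- ens$sequence
            oh_rows[[b]] <- flat_onehot[[si]]
          } else {
            seq_batch[[b]] <- residue_sequence(
              ens$sequence$letters[s0:(s0 + Lt - 1L)], id = ens$sequence$id)
            oh_rows[[b]] <- as.numeric(t(seq_batch[[b]]$onehot))
          }
        }
        Aoh_flat <- matrix(unlist(oh_rows), B, 20L * Lt, byrow = TRUE)
        Xr <- cbind(standardize_features(std,
                                         batch_distance_features(real_stack,
                                                                 Lt, B),
                                         Lt),
                    Aoh_flat)
        # ---- fake batch ----
        Z <- matrix(Zall[(bi - 1L) * z_per_batch + seq_len(B * Lt * n_z)],
                    B * Lt, n_z)
        Aoh <- do.call(rbind, lapply(seq_batch, function(s) s$onehot))
        gf <- gen_fwd(model$G, cfg$arch_G, Z, Aoh, Lt, B, train = TRUE)
        fake_dists <- batch_distance_features(gf$coords, Lt, B)
        sepv <- idxP[, "sep"]
        Xf <- cbind(standardize_features(std, fake_dists, Lt),
                    Xr[, (ncol(Xr) - 20L * Lt + 1L):ncol(Xr), drop = FALSE])
        if (inst_sigma > 0) {
          P0 <- nrow(idxP)
          Xr[, seq_len(P0)] <- Xr[, seq_len(P0)] +
            matrix(rng$norm(B * P0, sd = inst_sigma), B, P0)
          Xf[, seq_len(P0)] <- Xf[, seq_len(P0)] +
            matrix(rng$norm(B * P0, sd = inst_sigma), B, P0)
        }
        # ---- discriminator update ----
        fr_ <- disc_fwd(model$D[[key]], cfg$arch_D, Xr, env, update = TRUE)
        ff_ <- disc_fwd(model$D[[key]], cfg$arch_D, Xf, env, update = FALSE)
        gp <- NULL
        if (cfg$objective == "nonsaturated") {
          pr <- sigmoid(fr_$score); pf <- sigmoid(ff_$score)
          lossD <- loss_discriminator(pr, pf, "nonsaturated")
          dsr <- -(1 - pr) / B
          dsf <- pf / B
        } else if (cfg$objective == "hinge_topk") {
          lossD <- loss_discriminator(fr_$score, ff_$score, "hinge_topk")
          dsr <- -as.numeric(1 - fr_$score > 0) / B
          dsf <- as.numeric(1 + ff_$score > 0) / B
        } else {
          gp <- gradient_penalty(model$D[[key]], cfg$arch_D, Xr, Xf, env,
                                 cfg$gp_lambda, rng)
          lossD <- loss_discriminator(fr_$score, ff_$score,
                                      "wasserstein_gp", gp = gp$value)
          dsr <- rep(-1 / B, B)
          dsf <- rep(1 / B, B)
        }
        if (!is.finite(lossD))
          stop(sprintf("non-finite discriminator loss at epoch %d, batch %d",
                       epoch, bi))
        gr <- disc_bwd(model$D[[key]], cfg$arch_D, fr_$cache, dsr)$grad
        gfk <- disc_bwd(model$D[[key]], cfg$arch_D, ff_$cache, dsf)$grad
        gD <- tree_add(gr, gfk)
        if (!is.null(gp)) gD <- tree_add(gD, gp$grad)
        model$D[[key]] <- adam_step(optD[[key]], model$D[[key]], gD)
        # ---- generator update (after critic_iters critic steps in WGAN) ----
        if (cfg$objective == "wasserstein_gp") {
          critic_count <- critic_count + 1L
          if (critic_count < cfg$critic_iters && bi < n_batches) next
          critic_count <- 0L
        }
        fg <- disc_fwd(model$D[[key]], cfg$arch_D, Xf, env, update = FALSE)
        cl <- clash_penalty_batch(fake_dists, Lt, x_t)
        if (cfg$objective == "nonsaturated") {
          pf <- sigmoid(fg$score)
          lossG <- as.numeric(loss_generator(pf, cl$value, "nonsaturated",
                                             w_C = cfg$w_C))
          dsf_g <- -(1 - pf) / B
          keep <- seq_len(B)
        } else if (cfg$objective == "hinge_topk") {
          lg <- loss_generator(fg$score, cl$value, "hinge_topk",
                               w_C = cfg$w_C, nu = nu)
          lossG <- as.numeric(lg)
          keep <- attr(lg, "topk_idx")
          dsf_g <- numeric(B)
          dsf_g[keep] <- -1 / length(keep)
        } else {
          lossG <- as.numeric(loss_generator(fg$score, cl$value,
                                             "wasserstein_gp", w_C = cfg$w_C))
          dsf_g <- rep(-1 / B, B)
          keep <- seq_len(B)
        }
        if (!is.finite(lossG))
          stop(sprintf("non-finite generator loss at epoch %d, batch %d",
                       epoch, bi))
        dXf <- disc_bwd(model$D[[key]], cfg$arch_D, fg$cache, dsf_g)$dX
        # feature gradient -> distance gradient (undo standardization) and
        # add the clash term; then distances -> coordinates
        P <- nrow(idxP)
        ddist <- sweep(dXf[, seq_len(P), drop = FALSE], 2L,
                       std$s[sepv], "/") + (cfg$w_C / B) * cl$grad
        dCoords <- batch_dist_to_coord_grad(gf$coords, fake_dists, ddist,
                                            Lt, B)
        gG <- gen_bwd(model$G, cfg$arch_G, gf$cache, dCoords)
        model$G <- adam_step(optG, model$G, gG)
        if (ema_d > 0)
          G_ema_flat <- ema_d * G_ema_flat +
            (1 - ema_d) * unlist(model$G, use.names = FALSE)
        ep_stats <- ep_stats + c(lossD, lossG, mean(cl$value),
                                 mean(fake_dists[, sepv >= 3L] < x_t))
      }
    }
    n_upd <- max(1, floor(nrow(tab) / cfg$batch))
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, lossD = ep_stats[1L] / n_upd,
      lossG = ep_stats[2L] / n_upd, mean_EC = ep_stats[3L] / n_upd,
      clash_frac = ep_stats[4L] / n_upd, nu = nu, sigma = sigma,
      seed = cfg$seed)
    if (verbose)
      message(sprintf("epoch %3d | D %.4f | G %.4f | E_C %.4f | clash %.4f",
                      epoch, log_rows[[epoch]]$lossD, log_rows[[epoch]]$lossG,
                      log_rows[[epoch]]$mean_EC,
                      log_rows[[epoch]]$clash_frac))
    nu <- max(nu * cfg$topk_gamma, 1 / cfg$batch)
  }
  model$log <- do.call(rbind, log_rows)
  model$x_t <- x_t
  if (ema_d > 0) {
    cursor <- new.env(parent = emptyenv())
    cursor$at <- 1L
    model$G_ema <- tree_refill(model$G, G_ema_flat, cursor)
  }
  model
}

#' Sample a generated ensemble
#'
#' Draws `n` independent conformations for one sequence with fresh latent
#' sequences; reproducible for a fixed seed.
#'
#' @param model A trained GAN model ([train_gan()]).
#' @param seq [residue_sequence()].
#' @param n Number of conformations.
#' @param seed Integer seed.
#' @param batch_cap Largest generator mini-batch.
#' @param use_ema Sample from the exponential-moving-average generator
#'   weights when the model carries them.
#' @return A [conformational_ensemble()] with provenance `"generated"`.
#' @export
sample_ensemble <- function(model, seq, n, seed = 1L, batch_cap = 256L,
                            use_ema = TRUE) {
  stopifnot(n >= 1L)
  L <- length(seq)
  n_z <- model$arch_G$n_z
  G <- if (use_ema && !is.null(model$G_ema)) model$G_ema else model$G
  rng <- local_rng(seed)
  xyz <- array(NA_real_, dim = c(n, L, 3L))
  done <- 0L
  Aoh1 <- seq$onehot
  while (done < n) {
    B <- min(batch_cap, n - done)
    Z <- matrix(rng$norm(B * L * n_z), B * L, n_z)
    Aoh <- Aoh1[rep(seq_len(L), B), , drop = FALSE]
    coords <- gen_fwd(G, model$arch_G, Z, Aoh, L, B)$coords
    for (b in seq_len(B))
      xyz[done + b, , ] <- coords[((b - 1L) * L + 1L):(b * L), ]
    done <- done + B
  }
  conformational_ensemble(seq, xyz, provenance = "generated")
}

#' Select the best of several trained models by validation divergence
#'
#' Ranks models by the average per-pair distance divergence ([akld_d()])
#' of a generated sample against a validation ensemble, averaged over the
#' supplied validation set.
#'
#' @param models List of trained GAN models.
#' @param val_ensembles List of validation [conformational_ensemble()]s.
#' @param n Generated sample size per sequence.
#' @param seed Integer seed.
#' @return The winning model, with attribute `scores` (per-model mean
#'   validation aKLD_d).
#' @export
select_by_validation <- function(models, val_ensembles, n = 500L, seed = 1L) {
  scores <- vapply(seq_along(models), function(mi) {
    mean(vapply(val_ensembles, function(ve) {
      gen <- sample_ensemble(models[[mi]], ve$sequence, n, seed = seed)
      akld_d(ve, gen)
    }, numeric(1L)))
  }, numeric(1L))
  best <- models[[which.min(scores)]]
  attr(best, "scores") <- scores
  best
}
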