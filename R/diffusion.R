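#' One ancestral reverse-diffusion step
#'
#' Standard variance-preserving ancestral update from step `n` to `n - 1`:
#' the posterior mean is computed from the predicted noise, and posterior
#' ("small") variance Gaussian noise is added — none on the final `1 -> 0`
#' step, and none for deterministic (stub/control) denoisers. The coordinate
#' channel is re-projected onto the CoM-free subspace after every step.
#'
#' @param state a `diffusion_state` with `n >= 1`.
#' @param denoiser a denoiser object.
#' @param schedule the `noise_schedule`.
#' @param seed integer seed or NULL (use current RNG stream).
#' @return a `diffusion_state` at step `n - 1`.
#' @export
reverse_step <- function(state, denoiser, schedule, seed = NULL) {
  n <- state$n
  stopifnot(n >= 1)
  a_n <- sched_alpha(schedule, n)
  a_p <- sched_alpha(schedule, n - 1)
  s_n <- sched_sigma(schedule, n)
  s_p <- sched_sigma(schedule, n - 1)
  gam <- a_n / a_p
  s2c <- s_n^2 - gam^2 * s_p^2          # conditional variance of z_n | z_{n-1}
  eps <- predict_noise(denoiser, state, schedule)
  zx <- state$zx / gam - (s2c / (gam * s_n)) * eps$x
  zh <- state$zh / gam - (s2c / (gam * s_n)) * eps$h
  if (n > 1 && !isTRUE(denoiser$deterministic)) {
    sd_post <- s_p * sqrt(s2c) / s_n
    noise <- with_seed(seed, {
      list(x = project_com(matrix(stats::rnorm(length(zx)), nrow(zx), 3)),
           h = matrix(stats::rnorm(length(zh)), nrow(zh), ncol(zh)))
    })
    zx <- zx + sd_post * noise$x
    zh <- zh + sd_post * noise$h
  }
  diffusion_state(project_com(zx), zh, n - 1, state$meta)
}

#' Run full reverse diffusion from pure noise
#'
#' Starts at `z_N ~ Normal(0, 1)` (coordinates CoM-projected) and iterates
#' [reverse_step()] down to `n = 0`, recording the decoded structure at every
#' step. Deterministic given `seed`.
#'
#' @param denoiser a denoiser object.
#' @param n_atoms number of atoms to generate (caller-supplied; no learned
#'   size distribution).
#' @param schedule a `noise_schedule`.
#' @param seed integer seed.
#' @param alphabet species table (channel order).
#' @param h_scale one-hot scale used at decoding time.
#' @param record `"full"` keeps every state and decoded frame (a
#'   `diff_trajectory`); `"final"` returns only the final decoded system.
#' @param alpha_floor decoding guard, see [decode_state()].
#' @return a `diff_trajectory` (see [as_trajectory()]) or, with
#'   `record = "final"`, an [atomic_system()].
#' @export
sample_trajectory <- function(denoiser, n_atoms, schedule, seed = 0,
                              alphabet = default_alphabet(), h_scale = 0.25,
                              record = c("full", "final"), alpha_floor = 0.05) {
  record <- match.arg(record)
  with_seed(seed, {
    meta <- list(alphabet = alphabet, h_scale = h_scale, id = "sample")
    zx <- project_com(matrix(stats::rnorm(n_atoms * 3), n_atoms, 3))
    zh <- matrix(stats::rnorm(n_atoms * nrow(alphabet)), n_atoms,
                 nrow(alphabet))
    state <- diffusion_state(zx, zh, schedule$N, meta)
    states <- if (record == "full") vector("list", schedule$N + 1) else NULL
    if (record == "full") states[[1]] <- state
    for (n in schedule$N:1) {
      state <- reverse_step(state, denoiser, schedule)
      if (record == "full") states[[schedule$N - n + 2]] <- state
    }
    if (record == "final") {
      return(decode_state(state, schedule, alpha_floor))
    }
    as_trajectory(states, schedule, alpha_floor)
  })
}

#' Assemble a diffusion trajectory from recorded states
#'
#' Decodes every state and computes per-step decoded coordinate displacements
#' `deltas[[i]] = decoded[[i+1]] - decoded[[i]]`.
#'
#' @param states list of `diffusion_state`s in inference order (decreasing n).
#' @param schedule the `noise_schedule`.
#' @param alpha_floor decoding guard.
#' @return a `diff_trajectory`: list with `states`, `decoded`, `deltas`,
#'   `steps` (the n value of each frame).
#' @export
as_trajectory <- function(states, schedule, alpha_floor = 0.05) {
  decoded <- lapply(states, decode_state, schedule = schedule,
                    alpha_floor = alpha_floor)
  deltas <- if (length(decoded) > 1) {
    lapply(seq_len(length(decoded) - 1), function(i) {
      decoded[[i + 1]]$coords - decoded[[i]]$coords
    })
  } else list()
  structure(list(states = states,
                 decoded = decoded,
                 deltas = deltas,
                 steps = vapply(states, function(s) s$n, 0L)),
            class = "diff_trajectory")
}

#' @export
print.diff_trajectory <- function(x, ...) {
  cat(sprintf("<diff_trajectory: %d frames, steps %d..%d, %d atoms>\n",
              length(x$decoded), x$steps[1], x$steps[length(x$steps)],
              length(x$decoded[[1]]$species)))
  invisible(x)
}

#' Export a trajectory as a multi-frame XYZ file
#'
#' @param traj a `diff_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  write_xyz(traj$decoded, path)
}

#' Denoising training loss
#'
#' For each clean latent a step `n` is drawn uniformly from `{1..N}`, forward
#' noise is applied, and the loss is the squared error between drawn and
#' predicted noise summed over all latent dimensions (CoM-free coordinates
#' plus channels, weight 1:1), averaged over the batch. A denoiser that
#' predicts exactly the drawn noise scores 0; a zero denoiser scores the
#' dimensionality of the latent in expectation.
#'
#' @param denoiser a denoiser object.
#' @param latents list of `clean_latent`s ([encode_system()]).
#' @param schedule a `noise_schedule`.
#' @param seed integer seed or NULL.
#' @return scalar loss.
#' @export
diffusion_loss <- function(denoiser, latents, schedule, seed = NULL) {
  stopifnot(length(latents) > 0)
  with_seed(seed, {
    tot <- 0
    for (lat in latents) {
      n <- sample.int(schedule$N, 1)
      st <- forward_noise(lat, n, schedule)
      eps <- attr(st, "eps")
      pred <- predict_noise(denoiser, st, schedule)
      tot <- tot + sum((eps$x - pred$x)^2) + sum((eps$h - pred$h)^2)
    }
    tot / length(latents)
  })
}

#' Train the learned denoiser
#'
#' Minibatch Adam on the denoising objective with truncated-SNR weighting:
#' the per-item squared error between drawn and predicted noise is weighted
#' by `w(n) = (sigma_n / max(sigma_n, sigma_ref))^2`. Above the reference
#' noise level the objective is the plain noise-space MSE; below it the
#' weight decays as `sigma_n^2`, which bounds the optimisation stiffness
#' introduced by the network's `1/sigma_n` output parameterization while
#' still exerting full pressure on the small displacement targets of the
#' low-noise (relaxation-regime) steps. The unweighted noise-space loss
#' remains available as [diffusion_loss()]. Training steps are drawn from a mixture of a
#' uniform and a log-uniform distribution over `{1..N}` (`low_step_frac`
#' controls the log-uniform share): uniform sampling alone visits the
#' low-noise steps that drive structure relaxation too rarely for a small
#' model to learn them, while the log-uniform component covers every noise
#' decade evenly. Per epoch the training systems are shuffled, a fresh
#' (seeded) noise draw is made per item, and the (weighted) validation loss
#' is evaluated on the held-out split; the returned model is the checkpoint
#' with the best validation loss. The validation draws are fixed once per
#' training run (several per held-out system), so the per-epoch validation
#' losses are paired and checkpoint selection does not chase draw noise.
#' Fully seeded and reproducible.
#'
#' @param denoiser an [egnn_denoiser()].
#' @param dataset a `ground_state_dataset` with non-empty train and validation
#'   splits.
#' @param schedule a `noise_schedule`.
#' @param epochs number of epochs (0 returns the initial model and an empty
#'   history).
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate (decayed smoothly to ~lr/3 by the
#'   final epoch).
#' @param low_step_frac share of training draws taken log-uniformly over
#'   steps (default 0.5); 0 recovers purely uniform step sampling.
#' @param sigma_ref reference noise level of the truncated-SNR loss weight.
#' @param snapshot_epochs integer vector of epochs at which to capture
#'   parameter snapshots (for snapshot ensembling); default none.
#' @param seed integer seed.
#' @return list with `denoiser` (best-validation checkpoint), `history`
#'   (data.frame epoch/train_loss/val_loss), `best_epoch`, and `snapshots`
#'   (named list of denoisers at the requested epochs).
#' @export
train_denoiser <- function(denoiser, dataset, schedule, epochs = 100,
                           batch_size = 8, lr = 3e-3, low_step_frac = 0.5,
                           sigma_ref = 0.1, snapshot_epochs = integer(0),
                           seed = 0) {
  stopifnot(inherits(denoiser, "egnn_denoiser"))
  if (length(dataset$splits$train) == 0) stop("empty training split")
  if (length(dataset$splits$val) == 0) stop("empty validation split")
  cfg <- denoiser$config
  enc <- lapply(dataset$systems, encode_system, alphabet = cfg$alphabet,
                h_scale = cfg$h_scale)
  train_set <- enc[dataset$splits$train]
  val_set <- enc[dataset$splits$val]
  params <- denoiser$params
  if (epochs == 0) {
    return(list(denoiser = denoiser,
                history = data.frame(epoch = integer(0),
                                     train_loss = numeric(0),
                                     val_loss = numeric(0)),
                best_epoch = NA_integer_, snapshots = list()))
  }
  snapshots <- list()
  adam <- adam_init(params)
  ## fixed validation draws, packed once: per-epoch losses are paired and a
  ## single batched forward scores the whole held-out set
  val_items <- with_seed(derive_seed(seed, "val-fixed"), {
    unlist(lapply(val_set, function(lat) {
      lapply(seq_len(8), function(r) {
        n <- draw_train_step(schedule$N, low_step_frac)
        st <- forward_noise(lat, n, schedule)
        eps <- attr(st, "eps")
        list(zx = st$zx, zh = st$zh, n = n,
             w = snr_weight(schedule, n, sigma_ref),
             eps_x = eps$x, eps_h = eps$h)
      })
    }), recursive = FALSE)
  })
  val_pk <- egnn_batch_pack(val_items, cfg, schedule)
  val_tx <- do.call(rbind, lapply(val_items, `[[`, "eps_x"))
  val_th <- do.call(rbind, lapply(val_items, `[[`, "eps_h"))
  best <- list(val = Inf, params = params, epoch = NA_integer_)
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr / (1 + 2 * (ep - 1) / epochs)
    ep_seed <- derive_seed(seed, paste0("epoch", ep))
    ep_loss <- with_seed(ep_seed, {
      idx <- sample(seq_along(train_set))
      batches <- split(idx, ceiling(seq_along(idx) / batch_size))
      total <- 0
      for (b in batches) {
        items <- lapply(b, function(k) {
          lat <- train_set[[k]]
          n <- draw_train_step(schedule$N, low_step_frac)
          st <- forward_noise(lat, n, schedule)
          eps <- attr(st, "eps")
          list(zx = st$zx, zh = st$zh, n = n,
               w = snr_weight(schedule, n, sigma_ref),
               eps_x = eps$x, eps_h = eps$h)
        })
        pk <- egnn_batch_pack(items, cfg, schedule)
        fw <- egnn_forward_multi(params, cfg, pk)
        tx <- do.call(rbind, lapply(items, `[[`, "eps_x"))
        th <- do.call(rbind, lapply(items, `[[`, "eps_h"))
        wn <- pk$w[pk$node_block]
        gb <- egnn_backward_multi(params, cfg, pk, fw$cache,
                                  2 * wn * (fw$eps_x - tx),
                                  2 * wn * (fw$eps_h - th))
        total <- total + sum(wn * rowSums((fw$eps_x - tx)^2)) +
          sum(wn * rowSums((fw$eps_h - th)^2))
        gb <- scale_grads(gb, 1 / length(b))
        upd <- adam_step(adam, params, gb, lr_ep)
        adam <- upd$adam
        params <- upd$params
      }
      total / length(train_set)
    })
    fw_val <- egnn_forward_multi(params, cfg, val_pk, keep = FALSE)
    wv <- val_pk$w[val_pk$node_block]
    vl <- (sum(wv * rowSums((fw_val$eps_x - val_tx)^2)) +
             sum(wv * rowSums((fw_val$eps_h - val_th)^2))) / length(val_items)
    hist$train_loss[ep] <- ep_loss
    hist$val_loss[ep] <- vl
    if (vl < best$val) best <- list(val = vl, params = params, epoch = ep)
    if (ep %in% snapshot_epochs) {
      snap <- denoiser; snap$params <- params
      snapshots[[paste0("epoch", ep)]] <- snap
    }
  }
  out <- denoiser
  out$params <- best$params
  list(denoiser = out, history = hist, best_epoch = best$epoch,
       snapshots = snapshots)
}

## truncated-SNR loss weight: 1 above sigma_ref, sigma^2-scaled below
snr_weight <- function(schedule, n, sigma_ref) {
  s <- sched_sigma(schedule, n)
  (s / max(s, sigma_ref))^2
}

## uniform/log-uniform mixture over diffusion steps
draw_train_step <- function(N, low_step_frac) {
  if (stats::runif(1) < low_step_frac) {
    max(1L, min(N, as.integer(ceiling(N^stats::runif(1)))))
  } else {
    sample.int(N, 1)
  }
}

## validation loss under the training objective (same step mixture and
## truncated-SNR weight); several draws per held-out system keep the
## best-checkpoint selection from chasing single-draw noise
weighted_val_loss <- function(denoiser, latents, schedule, seed = NULL,
                              low_step_frac = 0.5, sigma_ref = 0.1,
                              draws = 4) {
  with_seed(seed, {
    tot <- 0
    for (lat in latents) {
      for (r in seq_len(draws)) {
        n <- draw_train_step(schedule$N, low_step_frac)
        st <- forward_noise(lat, n, schedule)
        eps <- attr(st, "eps")
        pred <- predict_noise(denoiser, st, schedule)
        w <- snr_weight(schedule, n, sigma_ref)
        tot <- tot + w * (sum((eps$x - pred$x)^2) + sum((eps$h - pred$h)^2))
      }
    }
    tot / (length(latents) * draws)
  })
}

add_grads <- function(a, b) {
  mapply(function(la, lb) mapply(`+`, la, lb, SIMPLIFY = FALSE),
         a, b, SIMPLIFY = FALSE)
}

scale_grads <- function(g, s) {
  lapply(g, function(l) lapply(l, function(m) m * s))
}

adam_init <- function(params) {
  zeros <- lapply(params, function(l) lapply(l, function(m) m * 0))
  list(m = zeros, v = zeros, t = 0)
}

adam_step <- function(adam, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  adam$t <- adam$t + 1
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      g <- grads[[l]][[nm]]
      adam$m[[l]][[nm]] <- beta1 * adam$m[[l]][[nm]] + (1 - beta1) * g
      adam$v[[l]][[nm]] <- beta2 * adam$v[[l]][[nm]] + (1 - beta2) * g^2
      mhat <- adam$m[[l]][[nm]] / (1 - beta1^adam$t)
      vhat <- adam$v[[l]][[nm]] / (1 - beta2^adam$t)
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(adam = adam, params = params)
}

#' Save a denoiser checkpoint (weights + schedule + config)
#'
#' Single-file JSON archive with a versioned header.
#'
#' @param denoiser an [egnn_denoiser()].
#' @param schedule the `noise_schedule` it was trained with.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(denoiser, schedule, path) {
  enc <- list(
    format = "diffpes-checkpoint", version = 1L,
    config = denoiser$config[c("hidden", "msg_dim", "n_layers", "h_scale",
                               "init_sd", "rbf_centers", "rbf_width")],
    alphabet = denoiser$config$alphabet,
    schedule = list(N = schedule$N, kind = schedule$kind,
                    alpha = signif(schedule$alpha, 15)),
    params = lapply(denoiser$params, function(l) lapply(l, signif, digits = 15))
  )
  writeLines(jsonlite::toJSON(enc, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a denoiser checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint path.
#' @return list with `denoiser` and `schedule`.
#' @export
load_checkpoint <- function(path) {
  enc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(enc$format, "diffpes-checkpoint")) {
    stop("not a diffpes checkpoint: ", path)
  }
  cfg <- lapply(enc$config, function(v) {
    if (length(v) > 1) as.numeric(unlist(v)) else v[[1]] %||% v
  })
  cfg$alphabet <- do.call(rbind, lapply(enc$alphabet, function(row) {
    data.frame(species = row$species, max_degree = as.integer(row$max_degree),
               radius = as.numeric(row$radius), stringsAsFactors = FALSE)
  }))
  den <- egnn_denoiser(cfg, seed = 0)
  den$params <- rebuild_params(enc$params, den$params)
  alpha <- as.numeric(unlist(enc$schedule$alpha))
  sched <- structure(list(N = as.integer(enc$schedule$N),
                          alpha = alpha,
                          sigma = sqrt(pmax(0, 1 - alpha^2)),
                          kind = enc$schedule$kind),
                     class = "noise_schedule")
  list(denoiser = den, schedule = sched)
}

## JSON stores matrices as nested row-major arrays; rebuild against the
## freshly initialised parameter template's shapes
rebuild_params <- function(raw, shapes) {
  lapply(seq_along(shapes), function(l) {
    lapply(stats::setNames(names(shapes[[l]]), names(shapes[[l]])), function(nm) {
      v <- raw[[l]][[nm]]
      tmpl <- shapes[[l]][[nm]]
      if (is.matrix(tmpl)) {
        matrix(as.numeric(unlist(v)), nrow(tmpl), ncol(tmpl), byrow = TRUE)
      } else as.numeric(unlist(v))
    })
  })
}
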