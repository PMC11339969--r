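#' Predict the added noise for a diffusion state
#'
#' Generic denoiser contract: maps a `diffusion_state` to the predicted noise
#' `eps_hat` with a coordinate part (n x 3, CoM-free) and a channel part
#' (n x C). The coordinate part of every denoiser in the package is
#' rotation-equivariant and permutation-equivariant; channel outputs are
#' rotation-invariant.
#'
#' @param denoiser a denoiser object ([egnn_denoiser()], [oracle_denoiser()],
#'   [stub_denoiser()]).
#' @param state a `diffusion_state`.
#' @param schedule the `noise_schedule`.
#' @return list with elements `x` (n x 3) and `h` (n x C).
#' @export
predict_noise <- function(denoiser, state, schedule) {
  UseMethod("predict_noise")
}

# ---------------------------------------------------------------------------
# E(n)-equivariant learned denoiser
# ---------------------------------------------------------------------------

#' Construct a small E(n)-equivariant denoiser
#'
#' Message-passing network over the complete atom graph, in the style of
#' equivariant coordinate-update architectures. Per layer and per pair, an
#' MLP consumes only invariants (a radial-basis featurization of the current
#' pair distance, channel vectors of both endpoints, a step embedding) and
#' emits a scalar gate plus a message vector. The coordinates are updated by
#' the gated sum of relative position vectors (exactly rotation- and
#' permutation-equivariant) and the hidden channel state by a node MLP over
#' aggregated messages (invariant), so later layers see geometry moved by
#' earlier layers — the composition is strictly more expressive than a single
#' central pair field. The accumulated coordinate displacement `R(z)` and the
#' final channel state `H(z)` are converted to noise predictions
#' analytically — `eps_x = R(z) / sigma_n` and
#' `eps_h = (zh - alpha_n H(z)) / sigma_n` — so the network only ever learns
#' smooth O(1) functions while the noise target's `1/sigma_n` stiffness at
#' low noise is supplied by the parameterization.
#'
#' @param config list: `hidden` (MLP width, default 32), `msg_dim` (message
#'   width, default 8), `n_layers` (default 3), `alphabet`
#'   ([default_alphabet()]), `h_scale` (default 0.25), `init_sd` (weight
#'   initialisation SD, default 0.1), `rbf_centers`/`rbf_width` (radial basis
#'   over pair distances, angstrom).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `c("egnn_denoiser", "denoiser")`.
#' @export
egnn_denoiser <- function(config = list(), seed = 0) {
  cfg <- utils::modifyList(
    list(hidden = 32L, msg_dim = 8L, n_layers = 3L,
         alphabet = default_alphabet(), h_scale = 0.25, init_sd = 0.1,
         rbf_centers = seq(0.6, 3.4, by = 0.2), rbf_width = 0.2),
    config)
  C <- nrow(cfg$alphabet)
  K <- length(cfg$rbf_centers)
  f1 <- 2 + K + 2 * C + 2            # distance, bounded d2, radial basis, h_i, h_j, step embedding
  f2 <- C + cfg$msg_dim + 2          # h_i, aggregated messages, step embedding
  params <- with_seed(derive_seed(seed, "egnn-init"), {
    lapply(seq_len(cfg$n_layers), function(l) {
      list(
        W1 = matrix(stats::rnorm(f1 * cfg$hidden, 0, cfg$init_sd), f1, cfg$hidden),
        b1 = numeric(cfg$hidden),
        W2 = matrix(stats::rnorm(cfg$hidden * (1 + cfg$msg_dim), 0, cfg$init_sd),
                    cfg$hidden, 1 + cfg$msg_dim),
        b2 = numeric(1 + cfg$msg_dim),
        W3 = matrix(stats::rnorm(f2 * cfg$hidden, 0, cfg$init_sd), f2, cfg$hidden),
        b3 = numeric(cfg$hidden),
        W4 = matrix(stats::rnorm(cfg$hidden * C, 0, cfg$init_sd), cfg$hidden, C),
        b4 = numeric(C)
      )
    })
  })
  structure(list(config = cfg, params = params, deterministic = FALSE),
            class = c("egnn_denoiser", "denoiser"))
}

#' @export
print.egnn_denoiser <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE), length, 0L))
  cat(sprintf("<egnn_denoiser: %d layer(s), hidden %d, %d parameters>\n",
              x$config$n_layers, x$config$hidden, np))
  invisible(x)
}

#' @export
predict_noise.egnn_denoiser <- function(denoiser, state, schedule) {
  fw <- egnn_forward(denoiser$params, denoiser$config, state$zx, state$zh,
                     state$n, schedule, keep = FALSE)
  list(x = fw$eps_x, h = fw$eps_h)
}

## Invariant radial featurization of pair distances: a standardized distance,
## a bounded squared distance, and a Gaussian radial basis over the
## chemically relevant range. All features are O(1) so the tanh layers stay
## in their active region.
pair_dist_features <- function(d2, cfg) {
  d <- sqrt(d2)
  rbf <- exp(-(outer(d, cfg$rbf_centers, `-`))^2 / (2 * cfg$rbf_width^2))
  cbind((d - 2) / 1.5, d2 / (1 + d2), rbf)
}

## channel vectors are h_scale-sized; rescale to O(1) for the MLP inputs
H_FEAT_GAIN <- 4

egnn_forward <- function(params, cfg, zx, zh, n, schedule, keep = TRUE) {
  natom <- nrow(zx)
  C <- ncol(zh)
  s1 <- n / schedule$N
  s2 <- sched_alpha(schedule, n)
  if (natom < 2) {
    ## a single atom has no pairs and no CoM-free coordinate freedom
    return(list(eps_x = matrix(0, natom, 3), eps_h = zh * 0,
                cache = NULL)[if (keep) 1:3 else 1:2])
  }
  ii <- rep(seq_len(natom), each = natom)
  jj <- rep(seq_len(natom), times = natom)
  keep_p <- ii != jj
  ii <- ii[keep_p]; jj <- jj[keep_p]
  P <- length(ii)
  x_cur <- zx
  h_cur <- zh
  cache <- list(ii = ii, jj = jj, natom = natom,
                layers = vector("list", length(params)))
  for (l in seq_along(params)) {
    p <- params[[l]]
    rel <- x_cur[ii, , drop = FALSE] - x_cur[jj, , drop = FALSE]
    d2 <- rowSums(rel^2)
    dfeat <- pair_dist_features(d2, cfg)
    U <- cbind(dfeat, H_FEAT_GAIN * h_cur[ii, , drop = FALSE],
               H_FEAT_GAIN * h_cur[jj, , drop = FALSE],
               rep(s1, P), rep(s2, P))
    A <- tanh(sweep(U %*% p$W1, 2, p$b1, `+`))
    G <- sweep(A %*% p$W2, 2, p$b2, `+`)
    g <- G[, 1]
    m <- G[, -1, drop = FALSE]
    agg <- rowsum(m, ii) / (natom - 1)
    V <- cbind(H_FEAT_GAIN * h_cur, agg, rep(s1, natom), rep(s2, natom))
    B <- tanh(sweep(V %*% p$W3, 2, p$b3, `+`))
    upd <- sweep(B %*% p$W4, 2, p$b4, `+`)
    if (keep) cache$layers[[l]] <- list(rel = rel, d2 = d2, U = U, A = A,
                                        g = g, V = V, B = B)
    x_cur <- x_cur + rowsum(rel * g, ii) / (natom - 1)
    h_cur <- h_cur + upd
  }
  sig <- max(sched_sigma(schedule, n), 1e-4)
  out <- list(eps_x = project_com(x_cur - zx) / sig,
              eps_h = (zh - s2 * h_cur) / sig)
  if (keep) { cache$sig <- sig; cache$alpha_n <- s2; out$cache <- cache }
  out
}

## Analytic gradients of a scalar loss wrt the EGNN parameters, given the
## loss gradients wrt the two outputs. CoM projection is symmetric and
## idempotent, so it is applied to the incoming coordinate gradient.
egnn_backward <- function(params, cfg, cache, d_eps_x, d_eps_h) {
  natom <- cache$natom
  C <- ncol(d_eps_h)
  M <- cfg$msg_dim
  ii <- cache$ii; jj <- cache$jj
  ## undo the output parameterization: eps_x = (x_L - zx)/sig (projected),
  ## eps_h = (zh - a*H)/sig
  dx <- project_com(d_eps_x) / cache$sig
  dh <- -(cache$alpha_n / cache$sig) * d_eps_h
  grads <- vector("list", length(params))
  off <- 2 + length(cfg$rbf_centers)
  for (l in rev(seq_along(params))) {
    p <- params[[l]]
    cl <- cache$layers[[l]]
    rel <- cl$rel
    ## node update path: h_out = h_in + tanh(V W3 + b3) W4 + b4
    d_upd <- dh
    dW4 <- crossprod(cl$B, d_upd)
    db4 <- colSums(d_upd)
    dB <- d_upd %*% t(p$W4)
    dpreB <- dB * (1 - cl$B^2)
    dW3 <- crossprod(cl$V, dpreB)
    db3 <- colSums(dpreB)
    dV <- dpreB %*% t(p$W3)
    dh_node <- H_FEAT_GAIN * dV[, seq_len(C), drop = FALSE]
    dagg <- dV[, C + seq_len(M), drop = FALSE]
    ## coordinate update path: x_out_i = x_in_i + sum_j rel_ij g_ij/(n-1)
    dDelta <- dx
    dg <- rowSums(rel * dDelta[ii, , drop = FALSE]) / (natom - 1)
    drel_delta <- (cl$g / (natom - 1)) * dDelta[ii, , drop = FALSE]
    ## pair MLP
    dm <- dagg[ii, , drop = FALSE] / (natom - 1)
    dG <- cbind(dg, dm)
    dW2 <- crossprod(cl$A, dG)
    db2 <- colSums(dG)
    dA <- dG %*% t(p$W2)
    dpreA <- dA * (1 - cl$A^2)
    dW1 <- crossprod(cl$U, dpreA)
    db1 <- colSums(dpreA)
    dU <- dpreA %*% t(p$W1)
    dh_pair <- H_FEAT_GAIN * (rowsum(dU[, off + seq_len(C), drop = FALSE], ii) +
      rowsum(dU[, off + C + seq_len(C), drop = FALSE], jj))
    ## distance features back to geometry: U cols 1..off are [d, d2/(1+d2), rbf]
    d <- sqrt(cl$d2)
    dd2 <- dU[, 1] / (1.5 * 2 * d) + dU[, 2] / (1 + cl$d2)^2
    for (k in seq_along(cfg$rbf_centers)) {
      rbf_k <- exp(-(d - cfg$rbf_centers[k])^2 / (2 * cfg$rbf_width^2))
      dd2 <- dd2 + dU[, 2 + k] * rbf_k *
        (-(d - cfg$rbf_centers[k]) / cfg$rbf_width^2) / (2 * d)
    }
    drel <- drel_delta + 2 * dd2 * rel
    ## scatter pair gradients back to the layer's input coordinates
    dx <- dx + rowsum(drel, ii) - rowsum(drel, jj)
    grads[[l]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
    dh <- dh + dh_node + dh_pair   # skip connection + feature reuse
  }
  grads
}

# ---------------------------------------------------------------------------
# Closed-form oracle denoiser
# ---------------------------------------------------------------------------

#' Bayes-optimal denoiser for a Gaussian data distribution
#'
#' For data `x ~ Normal(m, tau2 * I)` in the CoM-free coordinate subspace and
#' latent `z = alpha_n x + sigma_n eps`, the posterior mean of the noise is
#' available in closed form:
#' `E[x | z] = m + (alpha tau2 / (alpha^2 tau2 + sigma^2)) (z - alpha m)` and
#' `eps_hat = (z - alpha E[x|z]) / sigma`. With `tau2 = 0` this reduces to the
#' point-mass case `eps_hat = (z - alpha m) / sigma`. Species channels are
#' treated as point mass at the data mean. Used as the analytic test oracle:
#' full reverse sampling with it must reproduce the data distribution without
#' any training.
#'
#' @param data_mean a `clean_latent` ([encode_system()]) at the distribution
#'   mean.
#' @param data_var scalar `tau2 >= 0` (coordinate part).
#' @return an object of class `c("oracle_denoiser", "denoiser")`.
#' @export
oracle_denoiser <- function(data_mean, data_var = 0) {
  stopifnot(inherits(data_mean, "clean_latent"), data_var >= 0)
  structure(list(mean = data_mean, tau2 = data_var, deterministic = FALSE),
            class = c("oracle_denoiser", "denoiser"))
}

#' @export
predict_noise.oracle_denoiser <- function(denoiser, state, schedule) {
  a <- sched_alpha(schedule, state$n)
  s <- sched_sigma(schedule, state$n)
  m <- denoiser$mean
  tau2 <- denoiser$tau2
  shrink <- a * tau2 / (a^2 * tau2 + s^2)
  ex <- m$x + shrink * (state$zx - a * m$x)
  list(x = project_com((state$zx - a * ex) / s),
       h = (state$zh - a * m$h) / s)
}

# ---------------------------------------------------------------------------
# Constructed control denoisers
# ---------------------------------------------------------------------------

#' Construct a stub (control) denoiser
#'
#' Wraps a user function `fun(state, schedule) -> list(x, h)` as a denoiser.
#' Stubs are deterministic: [reverse_step()] injects no posterior noise for
#' them, so e.g. the identity stub (`eps_hat = 0`) makes a reverse step an
#' exact no-op on decoded coordinates — the benchmark's control closure.
#'
#' @param fun prediction function, or NULL for the identity (zero) stub.
#' @param label short description.
#' @return an object of class `c("stub_denoiser", "denoiser")`.
#' @export
stub_denoiser <- function(fun = NULL, label = "identity") {
  if (is.null(fun)) {
    fun <- function(state, schedule) {
      list(x = state$zx * 0, h = state$zh * 0)
    }
  }
  structure(list(fun = fun, label = label, deterministic = TRUE),
            class = c("stub_denoiser", "denoiser"))
}

#' @export
predict_noise.stub_denoiser <- function(denoiser, state, schedule) {
  denoiser$fun(state, schedule)
}

#' Force-follower control denoiser
#'
#' Predicts noise so that each decoded step moves along the PES forces
#' (steepest descent): the constructed positive control for the alignment
#' diagnostics, where `cos(Delta, f)` must be ~1.
#'
#' @param pes a `toy_pes` providing forces.
#' @param gain step magnitude per unit force norm (decoded scale).
#' @return a stub denoiser.
#' @export
force_follower_denoiser <- function(pes, gain = 0.05) {
  stub_denoiser(function(state, schedule) {
    a <- sched_alpha(schedule, state$n)
    coords <- state$zx / max(a, 0.05)
    f <- pes_forces(pes, coords)
    nf <- sqrt(sum(f^2))
    dir <- if (nf < 1e-12) f else f / nf
    ## decoded delta is proportional to -eps_hat (see reverse_step)
    list(x = project_com(-dir * gain), h = state$zh * 0)
  }, label = "force-follower")
}

#' Straight-liner control denoiser
#'
#' Predicts noise so that each decoded step points straight at the ground
#' state: the constructed positive control where `cos(Delta, gs)` must be ~1
#' and `cos(Delta, f)` falls back to the force/ground-state alignment.
#'
#' @param gs_coords ground-state coordinates (n x 3).
#' @param gain step magnitude per unit direction norm (decoded scale).
#' @return a stub denoiser.
#' @export
straight_liner_denoiser <- function(gs_coords, gain = 0.05) {
  gs <- project_com(as.matrix(gs_coords))
  stub_denoiser(function(state, schedule) {
    a <- sched_alpha(schedule, state$n)
    coords <- state$zx / max(a, 0.05)
    d <- gs - project_com(coords)
    nd <- sqrt(sum(d^2))
    dir <- if (nd < 1e-12) d else d / nd
    list(x = project_com(-dir * gain), h = state$zh * 0)
  }, label = "straight-liner")
}

# ---------------------------------------------------------------------------
# Batched training path: one forward/backward over a whole minibatch, with
# per-system blocks stacked into single matrices. Numerically identical to
# the per-item path (verified in the test suite); used by train_denoiser.
# ---------------------------------------------------------------------------

## items: list of list(zx, zh, n, w, eps_x, eps_h)
egnn_batch_pack <- function(items, cfg, schedule) {
  nat <- vapply(items, function(it) nrow(it$zx), 0L)
  off <- cumsum(c(0L, nat[-length(nat)]))
  node_block <- rep(seq_along(items), nat)
  zx <- do.call(rbind, lapply(items, `[[`, "zx"))
  zh <- do.call(rbind, lapply(items, `[[`, "zh"))
  ii <- integer(0); jj <- integer(0); pair_block <- integer(0)
  for (b in seq_along(items)) {
    n_b <- nat[b]
    i0 <- rep(seq_len(n_b), each = n_b)
    j0 <- rep(seq_len(n_b), times = n_b)
    keep <- i0 != j0
    ii <- c(ii, i0[keep] + off[b])
    jj <- c(jj, j0[keep] + off[b])
    pair_block <- c(pair_block, rep(b, sum(keep)))
  }
  n_step <- vapply(items, `[[`, 0, "n")
  list(zx = zx, zh = zh, ii = ii, jj = jj,
       node_block = node_block, pair_block = pair_block, nat = nat,
       s1 = n_step / schedule$N,
       s2 = vapply(n_step, function(n) sched_alpha(schedule, n), 0),
       sig = vapply(n_step, function(n) max(sched_sigma(schedule, n), 1e-4), 0),
       w = vapply(items, `[[`, 0, "w"))
}

## per-block CoM projection of a stacked n x 3 matrix
project_com_blocks <- function(x, block, nat) {
  means <- rowsum(x, block) / nat
  x - means[block, , drop = FALSE]
}

egnn_forward_multi <- function(params, cfg, pk, keep = TRUE) {
  ii <- pk$ii; jj <- pk$jj
  deg <- (pk$nat - 1)[pk$pair_block]        # per-pair 1/(n_atoms - 1)
  s1p <- pk$s1[pk$pair_block]; s2p <- pk$s2[pk$pair_block]
  s1n <- pk$s1[pk$node_block]; s2n <- pk$s2[pk$node_block]
  x_cur <- pk$zx
  h_cur <- pk$zh
  cache <- list(layers = vector("list", length(params)))
  for (l in seq_along(params)) {
    p <- params[[l]]
    rel <- x_cur[ii, , drop = FALSE] - x_cur[jj, , drop = FALSE]
    d2 <- rowSums(rel^2)
    U <- cbind(pair_dist_features(d2, cfg),
               H_FEAT_GAIN * h_cur[ii, , drop = FALSE],
               H_FEAT_GAIN * h_cur[jj, , drop = FALSE], s1p, s2p)
    A <- tanh(sweep(U %*% p$W1, 2, p$b1, `+`))
    G <- sweep(A %*% p$W2, 2, p$b2, `+`)
    g <- G[, 1]
    m <- G[, -1, drop = FALSE]
    agg <- rowsum(m, ii) / (pk$nat[pk$node_block] - 1)
    V <- cbind(H_FEAT_GAIN * h_cur, agg, s1n, s2n)
    B <- tanh(sweep(V %*% p$W3, 2, p$b3, `+`))
    upd <- sweep(B %*% p$W4, 2, p$b4, `+`)
    if (keep) cache$layers[[l]] <- list(rel = rel, d2 = d2, U = U, A = A,
                                        g = g, V = V, B = B)
    x_cur <- x_cur + rowsum(rel * g, ii) / (pk$nat[pk$node_block] - 1)
    h_cur <- h_cur + upd
  }
  sign_ <- pk$sig[pk$node_block]
  eps_x <- project_com_blocks(x_cur - pk$zx, pk$node_block, pk$nat) / sign_
  eps_h <- (pk$zh - s2n * h_cur) / sign_
  out <- list(eps_x = eps_x, eps_h = eps_h)
  if (keep) out$cache <- cache
  out
}

egnn_backward_multi <- function(params, cfg, pk, cache, d_eps_x, d_eps_h) {
  ii <- pk$ii; jj <- pk$jj
  C <- ncol(d_eps_h)
  M <- cfg$msg_dim
  sign_ <- pk$sig[pk$node_block]
  s2n <- pk$s2[pk$node_block]
  dx <- project_com_blocks(d_eps_x / sign_, pk$node_block, pk$nat)
  dh <- -(s2n / sign_) * d_eps_h
  inv_deg_node <- 1 / (pk$nat[pk$node_block] - 1)
  grads <- vector("list", length(params))
  off <- 2 + length(cfg$rbf_centers)
  for (l in rev(seq_along(params))) {
    p <- params[[l]]
    cl <- cache$layers[[l]]
    rel <- cl$rel
    d_upd <- dh
    dW4 <- crossprod(cl$B, d_upd)
    db4 <- colSums(d_upd)
    dB <- d_upd %*% t(p$W4)
    dpreB <- dB * (1 - cl$B^2)
    dW3 <- crossprod(cl$V, dpreB)
    db3 <- colSums(dpreB)
    dV <- dpreB %*% t(p$W3)
    dh_node <- H_FEAT_GAIN * dV[, seq_len(C), drop = FALSE]
    dagg <- dV[, C + seq_len(M), drop = FALSE]
    dDelta <- dx * inv_deg_node
    dg <- rowSums(rel * dDelta[ii, , drop = FALSE])
    drel_delta <- cl$g * dDelta[ii, , drop = FALSE]
    dm <- (dagg * inv_deg_node)[ii, , drop = FALSE]
    dG <- cbind(dg, dm)
    dW2 <- crossprod(cl$A, dG)
    db2 <- colSums(dG)
    dA <- dG %*% t(p$W2)
    dpreA <- dA * (1 - cl$A^2)
    dW1 <- crossprod(cl$U, dpreA)
    db1 <- colSums(dpreA)
    dU <- dpreA %*% t(p$W1)
    dh_pair <- H_FEAT_GAIN * (rowsum(dU[, off + seq_len(C), drop = FALSE], ii) +
      rowsum(dU[, off + C + seq_len(C), drop = FALSE], jj))
    d <- sqrt(cl$d2)
    dd2 <- dU[, 1] / (1.5 * 2 * d) + dU[, 2] / (1 + cl$d2)^2
    for (k in seq_along(cfg$rbf_centers)) {
      rbf_k <- exp(-(d - cfg$rbf_centers[k])^2 / (2 * cfg$rbf_width^2))
      dd2 <- dd2 + dU[, 2 + k] * rbf_k *
        (-(d - cfg$rbf_centers[k]) / cfg$rbf_width^2) / (2 * d)
    }
    drel <- drel_delta + 2 * dd2 * rel
    dx <- dx + rowsum(drel, ii) - rowsum(drel, jj)
    grads[[l]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
    dh <- dh + dh_node + dh_pair
  }
  grads
}

# ---------------------------------------------------------------------------
# Ensembles
# ---------------------------------------------------------------------------

#' Average the predictions of several denoisers
#'
#' Deep-ensemble style: the noise predictions (coordinate and channel parts)
#' of independently trained members are averaged. Averaging preserves
#' equivariance and the CoM-free property, and cancels the seed-specific
#' component of each member's error field — on the relaxation studies a small
#' ensemble is markedly more accurate than any single member trained for the
#' combined budget.
#'
#' @param members list of denoiser objects (same alphabet and h_scale).
#' @return an object of class `c("ensemble_denoiser", "denoiser")`.
#' @export
ensemble_denoiser <- function(members) {
  stopifnot(length(members) >= 1)
  structure(list(members = members, deterministic = FALSE,
                 config = members[[1]]$config),
            class = c("ensemble_denoiser", "denoiser"))
}

#' @export
predict_noise.ensemble_denoiser <- function(denoiser, state, schedule) {
  ps <- lapply(denoiser$members, predict_noise, state = state,
               schedule = schedule)
  list(x = Reduce(`+`, lapply(ps, `[[`, "x")) / length(ps),
       h = Reduce(`+`, lapply(ps, `[[`, "h")) / length(ps))
}

#' @export
print.ensemble_denoiser <- function(x, ...) {
  cat(sprintf("<ensemble_denoiser: %d members>\n", length(x$members)))
  invisible(x)
}

#' Train an ensemble of denoisers
#'
#' Runs [train_denoiser()] `n_runs` times from independent initialisations,
#' each consisting of a main denoising phase followed by an optional short
#' low-noise fine-tuning phase (log-uniform step draws only, reduced learning
#' rate) that specialises the model to the relaxation-regime steps, and
#' returns the prediction-averaging [ensemble_denoiser()].
#'
#' @param dataset a `ground_state_dataset`.
#' @param schedule a `noise_schedule`.
#' @param n_runs number of independent training runs (default 3).
#' @param epochs main-phase epochs per run.
#' @param ft_epochs fine-tuning epochs per run (0 to skip).
#' @param ft_lr fine-tuning learning rate.
#' @param config `egnn_denoiser()` configuration for every member.
#' @param seed integer seed.
#' @param ... further arguments passed to the main-phase [train_denoiser()].
#' @return list with `denoiser` (the ensemble) and `histories`.
#' @export
train_denoiser_ensemble <- function(dataset, schedule, n_runs = 3,
                                    epochs = 2500, ft_epochs = 1200,
                                    ft_lr = 1e-3, config = list(), seed = 0,
                                    ...) {
  members <- vector("list", n_runs)
  histories <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    den <- egnn_denoiser(config, seed = derive_seed(seed, paste0("init", k)))
    tr <- train_denoiser(den, dataset, schedule, epochs = epochs,
                         seed = derive_seed(seed, paste0("run", k)), ...)
    hist <- tr$history
    if (ft_epochs > 0) {
      tr <- train_denoiser(tr$denoiser, dataset, schedule,
                           epochs = ft_epochs, lr = ft_lr,
                           low_step_frac = 1.0,
                           seed = derive_seed(seed, paste0("ft", k)))
      hist <- rbind(hist, tr$history)
    }
    members[[k]] <- tr$denoiser
    histories[[k]] <- hist
  }
  list(denoiser = ensemble_denoiser(members), histories = histories)
}
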