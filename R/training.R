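# ---------------------------------------------------------------------------
# Unsupervised training: the loss backward pass through warp, pyramid and
# transform composition into every stage head, an Adam optimizer over the
# nested parameter lists, seeded data splitting and model selection.
#
# Gradient routing: the final transform is the matrix product of the
# centre-of-mass initialization and all stage matrices, so every stage
# receives gradient through the product rule. The *feature* inputs of later
# stages (the progressively warped moving image) are treated as detached
# constants — a standard stabilization for cascaded registration networks;
# see the methods vignette.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4; batch size is fixed at 1).
#' @param epochs maximum epochs (default 300; the tiny preset experiments
#'   use far fewer).
#' @param max_iterations optional hard cap on total optimizer steps.
#' @param lambda regularization weight (default 0.01).
#' @param ncc_window local NCC window (default 7).
#' @param levels loss pyramid depth (default 3).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 30).
#' @param val_fraction fraction held out for validation when no explicit
#'   validation pairs are supplied.
#' @param seed master seed covering weight init, shuffling and sampling.
#' @param com_init fold centre-of-mass pre-alignment into the cascade.
#' @param head_calibration data-dependent initialization of the stage heads
#'   on a handful of training pairs before the first step (centres and
#'   rescales the first head layer; see the methods vignette).
#' @param checkpoint_dir optional directory receiving a checkpoint per
#'   epoch plus a `best.rds` copy of the selected model.
#' @export
train_config <- function(lr = 1e-4, epochs = 300L, max_iterations = NULL,
                         lambda = 0.01, ncc_window = 7L, levels = 3L,
                         patience = 30L, val_fraction = 0.2, seed = 1L,
                         com_init = TRUE, head_calibration = TRUE,
                         checkpoint_dir = NULL) {
  stopifnot(lr > 0, epochs >= 0)
  list(lr = lr, epochs = as.integer(epochs), max_iterations = max_iterations,
       lambda = lambda, ncc_window = as.integer(ncc_window),
       levels = as.integer(levels), patience = as.integer(patience),
       val_fraction = val_fraction, seed = as.integer(seed),
       com_init = com_init, head_calibration = head_calibration,
       checkpoint_dir = checkpoint_dir)
}

#' Seeded train/validation/test split with repeated resampling
#'
#' Outer 80/20 train-pool/test split; within the pool, `repeats` seeded
#' 80/20 train/validation resamples (disjoint within each resample, their
#' union always the full pool). Deterministic per seed.
#'
#' @param ids subject identifiers (>= 5).
#' @param seed integer seed.
#' @param repeats number of inner resamples (default 5).
#' @return list with `test`, `pool` and `resamples` (each `train` / `val`).
#' @export
split_dataset <- function(ids, seed = 1L, repeats = 5L) {
  n <- length(ids)
  if (n < 5) stop("need at least 5 subjects to split")
  set.seed(seed)
  n_pool <- round(0.8 * n)
  pool_idx <- sample.int(n, n_pool)
  pool <- ids[sort(pool_idx)]
  test <- ids[setdiff(seq_len(n), pool_idx)]
  resamples <- vector("list", repeats)
  n_tr <- round(0.8 * length(pool))
  for (r in seq_len(repeats)) {
    tr <- sample.int(length(pool), n_tr)
    resamples[[r]] <- list(train = pool[sort(tr)],
                           val = pool[setdiff(seq_along(pool), tr)])
  }
  list(test = test, pool = pool, resamples = resamples)
}

# --- calibrated head initialization ----------------------------------------

# Data-dependent initialization of each stage head (LSUV-style centring +
# whitening): the pooled head inputs vary across pairs by orders of
# magnitude less than their mean and the variation is concentrated in a few
# correlated directions, so the first head layer is centred on the observed
# mean and rotated/rescaled so its tanh pre-activations are decorrelated
# with O(1) spread across training pairs. This conditions the head
# regression for the short batch-1 schedules used here; purely an
# initialization — all parameters remain trainable afterwards.
calibrate_heads <- function(model, pairs, cfg, n_cal = 40L,
                            target_sd = 0.3, max_gain = 50) {
  n_cal <- min(n_cal, length(pairs))
  if (n_cal < 8) return(model)
  nlev <- model$config$n_stages
  feats <- vector("list", nlev)
  for (k in seq_len(n_cal)) {
    fw <- network_forward(model, pairs[[k]]$fixed, pairs[[k]]$moving,
                          com_init = cfg$com_init, training = TRUE)
    for (i in seq_len(nlev))
      feats[[i]] <- rbind(feats[[i]], fw$caches[[i]]$hd$m)
  }
  for (i in seq_len(nlev)) {
    M <- feats[[i]]
    mbar <- colMeans(M)
    W1 <- model$stages[[i]]$head$W1
    pre <- sweep(M, 2, mbar) %*% W1
    S <- stats::cov(pre)
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    gain <- pmin(target_sd / sqrt(vals + 1e-12), max_gain)
    Tw <- eg$vectors %*% (gain * t(eg$vectors))
    W1 <- W1 %*% Tw
    model$stages[[i]]$head$W1 <- W1
    model$stages[[i]]$head$b1 <- as.vector(-mbar %*% W1)
  }
  model
}

# --- loss + gradient for one training pair ---------------------------------

# evaluates the total loss and its gradient with respect to every trainable
# parameter; also returns the BatchNorm running-stat updates
train_step_grad <- function(model, fixed, moving, cfg) {
  fw <- network_forward(model, fixed, moving, com_init = cfg$com_init,
                        training = TRUE)
  warped <- warp_volume(moving, fw$transform)
  f_pyr <- if (!is.null(attr(fixed, "pyramid"))) attr(fixed, "pyramid")
  else build_pyramid(fixed, cfg$levels)
  w_pyr <- build_pyramid(warped, cfg$levels)
  sim <- 0
  gW <- array(0, dim(warped))
  for (i in seq_len(cfg$levels)) {
    wt <- 1 / 2^(cfg$levels - i)
    vg <- local_ncc_value_grad(f_pyr[[i]], w_pyr[[i]], cfg$ncc_window)
    sim <- sim - wt * vg$value
    gW <- gW + if (all(dim(w_pyr[[i]]) == dim(warped))) -wt * vg$grad
    else resize_adjoint(-wt * vg$grad, dim(warped))
  }
  reg <- sum(vapply(fw$stages, function(s) regularization(s$params), 0))
  total <- sim + cfg$lambda * reg

  G4 <- rbind(warp_affine_grad(moving, fw$transform, gW), 0)
  nlev <- model$config$n_stages
  mats <- lapply(fw$stages, function(s) s$transform$mat)
  stage_grads <- vector("list", nlev)
  bn_updates <- vector("list", nlev)
  for (i in seq_len(nlev)) {
    p_left <- fw$init$mat
    if (i > 1) for (j in seq_len(i - 1)) p_left <- p_left %*% mats[[j]]
    p_right <- diag(4)
    if (i < nlev) for (j in (i + 1):nlev) p_right <- p_right %*% mats[[j]]
    dA <- t(p_left) %*% G4 %*% t(p_right)
    jac <- compose_affine_jacobian(fw$stages[[i]]$params, fw$pivot)
    dtheta <- vapply(jac, function(J) sum(dA * J), 0)
    dtheta <- dtheta + cfg$lambda * regularization_grad(fw$stages[[i]]$params)
    draw <- dtheta * constrain_params_grad(fw$stages[[i]]$raw)
    stage_grads[[i]] <- stage_backward(draw, fw$caches[[i]],
                                       model$stages[[i]], model$config)$dp
    bn_updates[[i]] <- list(bn1 = fw$caches[[i]]$cv$bn1$stats,
                            bn2 = fw$caches[[i]]$cv$bn2$stats)
  }
  list(sim = sim, reg = reg, total = total,
       grads = list(stages = stage_grads), bn = bn_updates,
       transform = fw$transform, stages = fw$stages)
}

# --- Adam over nested parameter lists --------------------------------------

adam_new <- function() list(m = NULL, v = NULL, t = 0L)

# walk the gradient structure (which contains trainable leaves only) and
# update matching parameter leaves
adam_apply <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.numeric(g)) {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    return(list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v))
  }
  if (is.null(m)) { m <- vector("list", length(g)); v <- vector("list", length(g)) }
  keys <- if (!is.null(names(g))) names(g) else seq_along(g)
  for (k in keys) {
    if (is.null(g[[k]])) next
    r <- adam_apply(p[[k]], g[[k]],
                    if (length(m) >= 1) m[[k]] else NULL,
                    if (length(v) >= 1) v[[k]] else NULL,
                    lr, t, b1, b2, eps)
    p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
  }
  list(p = p, m = m, v = v)
}

apply_bn_updates <- function(model, bn) {
  for (i in seq_along(bn)) {
    model$stages[[i]]$conv$bn1$rm <- bn[[i]]$bn1$rm
    model$stages[[i]]$conv$bn1$rv <- bn[[i]]$bn1$rv
    model$stages[[i]]$conv$bn2$rm <- bn[[i]]$bn2$rm
    model$stages[[i]]$conv$bn2$rv <- bn[[i]]$bn2$rv
  }
  model
}

# mean validation similarity loss (label-free model selection criterion)
validation_loss <- function(model, pairs, cfg) {
  if (length(pairs) == 0) return(NA_real_)
  vals <- vapply(pairs, function(pr) {
    fw <- network_forward(model, pr$fixed, pr$moving, com_init = cfg$com_init)
    warped <- warp_volume(pr$moving, fw$transform)
    similarity_loss(build_pyramid(pr$fixed, cfg$levels),
                    build_pyramid(warped, cfg$levels), cfg$ncc_window)
  }, 0)
  mean(vals)
}

#' Train the registration network on (fixed, moving) pairs
#'
#' Adam steps (batch size 1) on the total loss; after each epoch the mean
#' validation similarity loss is computed and the best model (minimum, ties
#' to the earliest epoch) is retained. Training aborts if the loss is
#' non-finite for 10 consecutive steps.
#'
#' @param pairs list of `list(fixed =, moving =)` volume pairs.
#' @param net_config `stage_config` for the network.
#' @param cfg `train_config`.
#' @param val_pairs explicit validation pairs; if `NULL`, `val_fraction` of
#'   `pairs` is held out (seeded).
#' @param log_path optional CSV path receiving per-iteration loss terms.
#' @param verbose print progress lines.
#' @return list with `model` (best), `last` (final weights), `log`
#'   (per-iteration data frame), `val_log`, `best_epoch`.
#' @export
train_network <- function(pairs, net_config = stage_config("tiny"),
                          cfg = train_config(), val_pairs = NULL,
                          log_path = NULL, verbose = FALSE) {
  set.seed(cfg$seed)
  model <- init_network(net_config, seed = cfg$seed)
  if (is.null(val_pairs)) {
    if (length(pairs) >= 5 && cfg$val_fraction > 0) {
      nv <- max(1L, round(cfg$val_fraction * length(pairs)))
      vi <- sample.int(length(pairs), nv)
      val_pairs <- pairs[vi]
      pairs <- pairs[-vi]
    } else val_pairs <- list()
  }
  if (isTRUE(cfg$head_calibration))
    model <- calibrate_heads(model, pairs, cfg)
  # fixed-image pyramids are constant across iterations; precompute
  for (k in seq_along(pairs))
    attr(pairs[[k]]$fixed, "pyramid") <- build_pyramid(pairs[[k]]$fixed,
                                                       cfg$levels)
  st <- adam_new()
  it <- 0L
  bad <- 0L
  log <- list()
  val_log <- data.frame(epoch = integer(), val_sim = numeric())
  best <- list(model = model, val = Inf, epoch = 0L)
  done <- FALSE
  no_improve <- 0L
  if (cfg$epochs == 0) {
    return(list(model = model, last = model,
                log = data.frame(iteration = integer(), sim = numeric(),
                                 reg = numeric(), total = numeric()),
                val_log = val_log, best_epoch = 0L))
  }
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(pairs))
    for (k in ord) {
      it <- it + 1L
      sg <- train_step_grad(model, pairs[[k]]$fixed, pairs[[k]]$moving, cfg)
      if (!is.finite(sg$total)) {
        bad <- bad + 1L
        if (bad >= 10L) stop("training diverged: loss non-finite for 10 steps")
        next
      }
      bad <- 0L
      st$t <- st$t + 1L
      r <- adam_apply(model$stages, sg$grads$stages, st$m, st$v,
                      cfg$lr, st$t)
      model$stages <- r$p; st$m <- r$m; st$v <- r$v
      model <- apply_bn_updates(model, sg$bn)
      log[[it]] <- c(iteration = it, sim = sg$sim, reg = sg$reg,
                     total = sg$total)
      if (!is.null(cfg$max_iterations) && it >= cfg$max_iterations) {
        done <- TRUE; break
      }
    }
    vl <- validation_loss(model, val_pairs, cfg)
    val_log <- rbind(val_log, data.frame(epoch = ep, val_sim = vl))
    if (!is.null(cfg$checkpoint_dir)) {
      dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_model(model, file.path(cfg$checkpoint_dir,
                                  sprintf("epoch%03d.rds", ep)))
    }
    if (verbose)
      message(sprintf("epoch %d  it %d  train %.4f  val %.4f",
                      ep, it, log[[it]]["total"], vl))
    if (is.finite(vl) && vl < best$val - 1e-12) {
      best <- list(model = model, val = vl, epoch = ep)
      no_improve <- 0L
    } else no_improve <- no_improve + 1L
    if (done || no_improve >= cfg$patience) break
  }
  log_df <- as.data.frame(do.call(rbind, log))
  if (!is.null(log_path)) utils::write.csv(log_df, log_path, row.names = FALSE)
  final_model <- if (is.finite(best$val)) best$model else model
  if (!is.null(cfg$checkpoint_dir))
    save_model(final_model, file.path(cfg$checkpoint_dir, "best.rds"))
  list(model = final_model, last = model, log = log_df, val_log = val_log,
       best_epoch = best$epoch)
}

# --- checkpointing ---------------------------------------------------------

#' Save / load a trained model
#'
#' Weights go to a single serialized file; the full stage configuration is
#' echoed to a JSON sidecar so the architecture can be reconstructed from
#' the sidecar alone.
#'
#' @param model model list; `path` checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfgj <- model$config
  class(cfgj) <- NULL
  jsonlite::write_json(cfgj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
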