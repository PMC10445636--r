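# Trainer: exponentially decaying learning rate, composite
# energy/force/virial losses with learning-rate-interpolated prefactors,
# Adam optimization with exact force-loss gradients (forward-over-reverse on
# the tape), multi-task training with a shared descriptor, ensemble model
# deviation and concurrent-learning candidate selection.

#' Learning-rate schedule
#'
#' `gamma(tau) = gamma0 * r^floor(tau / s)` with
#' `r = (gamma_stop / gamma0)^(s / tau_stop)`: piecewise-constant
#' exponential decay that reaches `gamma_stop` at the stopping step when
#' `s` divides `tau_stop`.
#'
#' @param start_lr learning rate at step 0.
#' @param stop_lr learning rate at the stopping step.
#' @param decay_steps window length `s` between decays.
#' @param stop_steps stopping step `tau_stop`.
#' @return a `dp_lr_schedule`.
#' @export
lr_schedule <- function(start_lr = 1e-3, stop_lr = 1e-5, decay_steps = 500L,
                        stop_steps = 10000L) {
  stopifnot(start_lr > 0, stop_lr > 0, stop_lr < start_lr,
            decay_steps >= 1L, decay_steps <= stop_steps)
  structure(list(start_lr = start_lr, stop_lr = stop_lr,
                 decay_steps = as.integer(decay_steps),
                 stop_steps = as.integer(stop_steps)),
            class = "dp_lr_schedule")
}

#' Learning rate at a step
#' @param tau training step (0-based).
#' @param sch a [lr_schedule()].
#' @return learning rate.
#' @export
lr_at <- function(tau, sch) {
  r <- (sch$stop_lr / sch$start_lr)^(sch$decay_steps / sch$stop_steps)
  sch$start_lr * r^floor(tau / sch$decay_steps)
}

#' Loss prefactor at a step
#'
#' Interpolates between the starting and limiting prefactor with weight
#' `gamma(tau) / gamma0`.
#'
#' @param tau training step.
#' @param p_start,p_limit prefactor at step 0 and in the infinite-step
#'   limit.
#' @param sch a [lr_schedule()].
#' @return prefactor value.
#' @export
loss_prefactor <- function(tau, p_start, p_limit, sch) {
  w <- lr_at(tau, sch) / sch$start_lr
  p_limit * (1 - w) + p_start * w
}

#' Loss specification
#'
#' Per-property prefactor pairs; a property with both prefactors zero (or
#' absent labels) is inactive.  Optional relative-force mode divides each
#' atom's force residual by `|F*_k| + nu`, and `atom_pref` weights atoms in
#' the force loss.
#'
#' @param start_pref_e,limit_pref_e energy prefactors.
#' @param start_pref_f,limit_pref_f force prefactors.
#' @param start_pref_v,limit_pref_v virial prefactors.
#' @param start_pref_de,limit_pref_de energy-difference prefactors.
#' @param relative_f `NULL` or the protection constant `nu` (eV/Angstrom)
#'   enabling the relative force loss.
#' @param atom_pref optional per-atom weights `q_k` for the force loss.
#' @param batch_size frames per mini-batch.
#' @param delta_reference pairing rule for the energy-difference loss: a
#'   `dp_frame` paired with every labeled frame, or a function mapping a
#'   frame entry to its reference frame.  The predicted difference is
#'   `E(frame) - E(reference)` and is compared with the `delta_energy`
#'   label.
#' @return a `dp_loss_spec`.
#' @export
loss_spec <- function(start_pref_e = 0.02, limit_pref_e = 1,
                      start_pref_f = 1000, limit_pref_f = 1,
                      start_pref_v = 0, limit_pref_v = 0,
                      start_pref_de = 0, limit_pref_de = 0,
                      relative_f = NULL, atom_pref = NULL,
                      batch_size = 1L, delta_reference = NULL) {
  if (!is.null(relative_f) && relative_f <= 0)
    stop("the protection constant nu must be positive", call. = FALSE)
  if ((start_pref_de > 0 || limit_pref_de > 0) && is.null(delta_reference))
    stop("the energy-difference loss needs a delta_reference pairing rule",
         call. = FALSE)
  structure(list(start_pref_e = start_pref_e, limit_pref_e = limit_pref_e,
                 start_pref_f = start_pref_f, limit_pref_f = limit_pref_f,
                 start_pref_v = start_pref_v, limit_pref_v = limit_pref_v,
                 start_pref_de = start_pref_de,
                 limit_pref_de = limit_pref_de,
                 relative_f = relative_f, atom_pref = atom_pref,
                 batch_size = as.integer(batch_size),
                 delta_reference = delta_reference),
            class = "dp_loss_spec")
}

delta_ref_frame <- function(spec, fr) {
  if (is.function(spec$delta_reference)) spec$delta_reference(fr)
  else spec$delta_reference
}

active_props <- function(spec) {
  c(e = spec$start_pref_e > 0 || spec$limit_pref_e > 0,
    f = spec$start_pref_f > 0 || spec$limit_pref_f > 0,
    v = spec$start_pref_v > 0 || spec$limit_pref_v > 0,
    de = spec$start_pref_de > 0 || spec$limit_pref_de > 0)
}

# per-frame property losses given predictions and labels (Eqs. of the
# composite MSE: energy and virial normalized by N, forces by 3N)
frame_losses <- function(pred, lab, n, spec) {
  out <- list()
  if (!is.null(lab$energy))
    out$e <- (pred$energy - lab$energy)^2 / n
  if (!is.null(lab$force) && !is.null(pred$forces)) {
    d <- pred$forces - lab$force
    if (!is.null(spec$relative_f)) {
      den <- sqrt(.rowSums(lab$force^2, n, 3L)) + spec$relative_f
      d <- d / den
    }
    if (!is.null(spec$atom_pref)) d <- d * sqrt(spec$atom_pref)
    out$f <- sum(d^2) / (3 * n)
  }
  if (!is.null(lab$virial) && !is.null(pred$virial))
    out$v <- sum((pred$virial - lab$virial)^2) / (9 * n)
  out
}

#' Composite loss of a batch of frames
#'
#' Evaluation-only: the batch-averaged weighted sum of per-frame property
#' losses at the prefactors of step `tau`.
#'
#' @param model a `dp_energy_model`.
#' @param frames list of `list(frame, labels)` entries (or a `dp_system`).
#' @param spec a [loss_spec()].
#' @param sch a [lr_schedule()].
#' @param tau training step determining the prefactors.
#' @return list with `total` and the per-property breakdown.
#' @export
compute_loss <- function(model, frames, spec = loss_spec(),
                         sch = lr_schedule(), tau = 0L) {
  if (inherits(frames, "dp_system")) frames <- frames$frames
  act <- active_props(spec)
  pe <- loss_prefactor(tau, spec$start_pref_e, spec$limit_pref_e, sch)
  pf <- loss_prefactor(tau, spec$start_pref_f, spec$limit_pref_f, sch)
  pv <- loss_prefactor(tau, spec$start_pref_v, spec$limit_pref_v, sch)
  pd <- loss_prefactor(tau, spec$start_pref_de, spec$limit_pref_de, sch)
  tot <- 0; br <- c(e = 0, f = 0, v = 0, de = 0)
  for (fr in frames) {
    n <- fr$frame$n_atoms
    if ((act["e"] && is.null(fr$labels$energy)) ||
        (act["f"] && is.null(fr$labels$force)) ||
        (act["v"] && is.null(fr$labels$virial)) ||
        (act["de"] && is.null(fr$labels$delta_energy)))
      stop("active loss property lacks labels", call. = FALSE)
    pred <- predict_frame(model, fr$frame,
                          what = c("energy",
                                   if (act["f"]) "forces",
                                   if (act["v"]) "virial"))
    l <- frame_losses(pred, fr$labels, n, spec)
    if (act["de"]) {
      de <- pred$energy - total_energy(model, delta_ref_frame(spec, fr))
      l$de <- (de - fr$labels$delta_energy)^2 / n
    }
    br["e"] <- br["e"] + (l$e %||% 0)
    br["f"] <- br["f"] + (l$f %||% 0)
    br["v"] <- br["v"] + (l$v %||% 0)
    br["de"] <- br["de"] + (l$de %||% 0)
    tot <- tot + pe * (l$e %||% 0) + pf * (l$f %||% 0) +
      pv * (l$v %||% 0) + pd * (l$de %||% 0)
  }
  nb <- length(frames)
  list(total = tot / nb, breakdown = br / nb,
       prefactors = c(e = pe, f = pf, v = pv, de = pd))
}

# Mini-batch loss gradient w.r.t. all parameters, on one shared tape.
# Energy part: chain rule through dE_f/dtheta with per-frame coefficients.
# Force/virial parts: both are linear images of g_f = dE_f/d(pair vectors),
# so their parameter gradient is d/dtheta of sum_f <v_f, g_f> for constant
# cotangents v_f; the JVP of the summed energy with tangents v_f is built
# on the tape and back-propagated together with the weighted energy sum in
# a single reverse sweep.
batch_grad <- function(model, entries, nls_list, pe, pf, pv, spec, pd = 0) {
  nf <- length(entries)
  fw <- model_forward_multi(model, entries, nls_list)
  tape <- fw$tape
  Evals <- as.vector(ad_value(tape, fw$Efr))
  param_ids <- fw$reg$ids

  rvec_ids <- unlist(lapply(fw$leaves, function(ctxs)
    vapply(ctxs, function(l) l$rvec, 0L)))
  total <- ad_sumall(tape, fw$Efr)
  gs <- ad_backward(tape, total, as.list(rvec_ids), mask_off = param_ids)

  losses <- list(e = 0, f = 0, v = 0, de = 0)
  coefs <- numeric(nf)
  seeds <- list()
  per_frame <- vector("list", nf)
  pos <- 0L
  nleaf <- length(fw$leaves[[1L]])
  for (f in seq_len(nf)) {
    fr <- entries[[f]]
    n <- fr$frame$n_atoms
    lab <- fr$labels
    if (pe > 0 && !is.null(lab$energy)) {
      losses$e <- losses$e + (Evals[f] - lab$energy)^2 / n
      coefs[f] <- coefs[f] + pe * 2 * (Evals[f] - lab$energy) / n
    }
    forces <- matrix(0, n, 3L)
    virial <- matrix(0, 3L, 3L)
    for (k in seq_len(nleaf)) {
      nl <- fw$leaves[[f]][[k]]$nl
      g <- gs[[pos + k]]
      if (length(nl$i) == 0L) next
      forces <- forces + rowsum_pad(g, nl$i, n) - rowsum_pad(g, nl$j, n)
      virial <- virial - crossprod(g, nl$rvec)
    }
    u <- NULL
    if (pf > 0 && !is.null(lab$force)) {
      d <- forces - lab$force
      scale <- rep(1, n)
      if (!is.null(spec$relative_f))
        scale <- 1 / (sqrt(.rowSums(lab$force^2, n, 3L)) +
                        spec$relative_f)^2
      if (!is.null(spec$atom_pref)) scale <- scale * spec$atom_pref
      losses$f <- losses$f + sum(d^2 * scale) / (3 * n)
      u <- pf * (2 / (3 * n)) * d * scale
    }
    W <- NULL
    if (pv > 0 && !is.null(lab$virial) && fr$frame$pbc) {
      dv <- virial - lab$virial
      losses$v <- losses$v + sum(dv^2) / (9 * n)
      W <- pv * (2 / (9 * n)) * dv
    }
    if (!is.null(u) || !is.null(W)) {
      for (k in seq_len(nleaf)) {
        nl <- fw$leaves[[f]][[k]]$nl
        if (length(nl$i) == 0L) next
        v <- matrix(0, length(nl$i), 3L)
        if (!is.null(u)) v <- v + u[nl$i, , drop = FALSE] -
            u[nl$j, , drop = FALSE]
        if (!is.null(W)) v <- v - nl$rvec %*% t(W)
        seeds[[as.character(rvec_ids[pos + k])]] <- v
      }
    }
    per_frame[[f]] <- list(energy = Evals[f], forces = forces,
                           virial = virial)
    pos <- pos + nleaf
  }

  # energy-difference terms need one extra forward/backward per labeled
  # frame (the reference frame is its own graph)
  grad_ref <- NULL
  if (pd > 0) {
    for (f in seq_len(nf)) {
      lab <- entries[[f]]$labels
      if (is.null(lab$delta_energy)) next
      n <- entries[[f]]$frame$n_atoms
      ref <- delta_ref_frame(spec, entries[[f]])
      fwr <- model_forward(model, ref)
      de <- Evals[f] - ad_value(fwr$tape, fwr$E)[1L]
      losses$de <- losses$de + (de - lab$delta_energy)^2 / n
      cde <- pd * 2 * (de - lab$delta_energy) / n
      coefs[f] <- coefs[f] + cde
      gref <- ad_backward(fwr$tape, fwr$E, fwr$reg$ids)
      gref <- lapply(gref, function(g) -cde * g)
      grad_ref <- if (is.null(grad_ref)) gref else
        mapply(`+`, grad_ref, gref, SIMPLIFY = FALSE)
    }
  }

  # combined scalar: weighted energy sum plus the force/virial JVP
  C <- NULL
  if (any(coefs != 0))
    C <- ad_sumall(tape, ad_mul(tape, fw$Efr,
                                ad_const(tape, matrix(coefs, nf, 1L))))
  if (length(seeds)) {
    J <- ad_jvp(tape, total, seeds)
    if (J != 0L) C <- if (is.null(C)) J else ad_add(tape, C, J)
  }
  grad <- if (!is.null(C)) ad_backward(tape, C, param_ids)
  else lapply(ad_backward(tape, total, param_ids), function(g) g * 0)
  if (!is.null(grad_ref))
    for (nm in names(grad)) grad[[nm]] <- grad[[nm]] + grad_ref[[nm]]
  list(grad = grad, losses = losses, per_frame = per_frame)
}

# single-frame adapter kept for multi-task training and diagnostics
frame_grad <- function(model, fr, nls, pe, pf, pv, spec, pd = 0) {
  bg <- batch_grad(model, list(fr), list(nls), pe, pf, pv, spec, pd)
  drop_zero <- function(x) if (is.numeric(x) && length(x) == 1 && x == 0)
    NULL else x
  list(grad = bg$grad,
       losses = Filter(Negate(is.null), lapply(bg$losses, drop_zero)),
       energy = bg$per_frame[[1L]]$energy,
       forces = bg$per_frame[[1L]]$forces,
       virial = bg$per_frame[[1L]]$virial)
}

# least-squares energy bias per species added to the fitting-net output
# bias, so initial predictions start near the label scale
init_energy_bias <- function(model, data) {
  ys <- vapply(data$frames, function(f) f$labels$energy %||% NA_real_, 0)
  if (anyNA(ys)) return(model)
  counts <- matrix(0, length(data$frames), model$nt)
  for (k in seq_along(data$frames))
    counts[k, ] <- tabulate(data$frames[[k]]$frame$species + 1L, model$nt)
  coefs <- tryCatch(qr.solve(counts, ys), error = function(e) NULL)
  if (is.null(coefs)) coefs <- rep(mean(ys / rowSums(counts)), model$nt)
  if (model$share_fitting) {
    net <- model$params$fit[[1L]]
    last <- length(net$layers)
    net$layers[[last]]$b <- net$layers[[last]]$b +
      mean(ys / rowSums(counts))
    model$params$fit[[1L]] <- net
  } else {
    for (a in seq_len(model$nt)) {
      net <- model$params$fit[[a]]
      last <- length(net$layers)
      net$layers[[last]]$b <- net$layers[[last]]$b + coefs[a]
      model$params$fit[[a]] <- net
    }
  }
  model$bias_done <- TRUE
  model
}

precompute_nls <- function(model, frames) {
  cfgs <- leaf_configs(model$descriptor)
  lapply(frames, function(fr)
    lapply(cfgs, function(cfg)
      build_neighbor_list(fr$frame, cfg$rcut, desc_sel(cfg, model$nt))))
}

rmse_report <- function(model, frames, nls = NULL) {
  se_e <- 0; se_f <- 0; n_f <- 0; se_v <- 0; n_v <- 0; nfr <- 0
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    n <- fr$frame$n_atoms
    pred <- predict_frame(model, fr$frame)
    if (!is.null(fr$labels$energy)) {
      se_e <- se_e + ((pred$energy - fr$labels$energy) / n)^2
      nfr <- nfr + 1
    }
    if (!is.null(fr$labels$force)) {
      se_f <- se_f + sum((pred$forces - fr$labels$force)^2)
      n_f <- n_f + 3 * n
    }
    if (!is.null(fr$labels$virial) && !is.null(pred$virial)) {
      se_v <- se_v + sum((pred$virial - fr$labels$virial)^2 / n^2)
      n_v <- n_v + 9
    }
  }
  c(energy_per_atom = if (nfr) sqrt(se_e / nfr) else NA_real_,
    force = if (n_f) sqrt(se_f / n_f) else NA_real_,
    virial_per_atom = if (n_v) sqrt(se_v / n_v) else NA_real_)
}

adam_step <- function(flat, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grad)) {
    u <- .adam_update(flat[[nm]], grad[[nm]], state$m[[nm]], state$v[[nm]],
                      lr, beta1, beta2, eps, bc1, bc2)
    flat[[nm]] <- u$p
    state$m[[nm]] <- u$m
    state$v[[nm]] <- u$v
  }
  list(flat = flat, state = state)
}

adam_init <- function(flat) {
  z <- lapply(flat, function(x) x * 0)
  list(t = 0L, m = z, v = z)
}

#' Train an energy model
#'
#' Adam optimization of the composite loss for `tau_stop` steps at the
#' scheduled learning rate.  Mini-batches are drawn with replacement from
#' the training frames; the parameter gradient of the force and virial
#' terms is exact (forward-over-reverse differentiation on the tape).
#' Deterministic given the seed.
#'
#' @param model a `dp_energy_model`.
#' @param data training `dp_system`.
#' @param sch a [lr_schedule()]; its `stop_steps` is the number of steps
#'   unless `tau_stop` overrides it.
#' @param spec a [loss_spec()].
#' @param tau_stop number of Adam steps.
#' @param seed integer seed for batching.
#' @param validation optional held-out `dp_system`; validation RMSEs are
#'   recorded every `val_freq` steps.
#' @param disp_freq history recording interval.
#' @param val_freq validation interval.
#' @return list with the trained `model` and a `history` data frame.
#' @export
train_model <- function(model, data, sch = lr_schedule(),
                        spec = loss_spec(), tau_stop = sch$stop_steps,
                        seed = 1L, validation = NULL, disp_freq = 100L,
                        val_freq = 1000L) {
  frames <- data$frames
  if (length(frames) == 0L) stop("no training frames", call. = FALSE)
  if (is.null(model$bias_done)) model <- init_energy_bias(model, data)
  nls <- precompute_nls(model, frames)
  flat <- flatten_params(model$params)
  state <- adam_init(flat)
  hist <- list()
  with_seed(seed, {
    for (tau in seq_len(tau_stop) - 1L) {
      lr <- lr_at(tau, sch)
      pe <- loss_prefactor(tau, spec$start_pref_e, spec$limit_pref_e, sch)
      pf <- loss_prefactor(tau, spec$start_pref_f, spec$limit_pref_f, sch)
      pv <- loss_prefactor(tau, spec$start_pref_v, spec$limit_pref_v, sch)
      pd <- loss_prefactor(tau, spec$start_pref_de, spec$limit_pref_de, sch)
      batch <- sample.int(length(frames), spec$batch_size, replace = TRUE)
      bg <- batch_grad(model, frames[batch], nls[batch], pe, pf, pv, spec,
                       pd = pd)
      if (!all(vapply(bg$grad, function(g) all(is.finite(g)), TRUE)))
        stop("training diverged at step ", tau, ": non-finite gradient",
             call. = FALSE)
      grad <- lapply(bg$grad, function(g) g / length(batch))
      le <- bg$losses$e; lf <- bg$losses$f; lv <- bg$losses$v
      if (lr > 0) {
        upd <- adam_step(flat, grad, state, lr)
        flat <- upd$flat
        state <- upd$state
        model$params <- assign_params(model$params, flat)
      }
      if (tau %% disp_freq == 0L || tau == tau_stop - 1L) {
        rec <- list(step = tau, lr = lr,
                    loss = (pe * le + pf * lf + pv * lv) /
                      length(batch),
                    rmse_e = sqrt(le / length(batch)),
                    rmse_f = sqrt(lf / length(batch)),
                    rmse_v = sqrt(lv / length(batch)))
        if (!is.null(validation) &&
            (tau %% val_freq == 0L || tau == tau_stop - 1L)) {
          vr <- rmse_report(model, validation$frames)
          rec$val_rmse_e <- vr[["energy_per_atom"]]
          rec$val_rmse_f <- vr[["force"]]
        }
        hist[[length(hist) + 1L]] <- rec
      }
    }
  })
  hdf <- do.call(rbind, lapply(hist, function(r)
    as.data.frame(r[c("step", "lr", "loss", "rmse_e", "rmse_f", "rmse_v")])))
  vals <- Filter(function(r) !is.null(r$val_rmse_f), hist)
  list(model = model, history = hdf,
       validation = if (length(vals)) do.call(rbind, lapply(vals,
         function(r) data.frame(step = r$step, rmse_e = r$val_rmse_e,
                                rmse_f = r$val_rmse_f))))
}

#' Multi-task training with a shared descriptor
#'
#' All tasks share the descriptor (and type-embedding) parameters; each
#' task owns its fitting network and dataset.  At every step one task is
#' picked at random and one Adam step is taken on its loss, updating the
#' shared descriptor and that task's fitting parameters only.
#'
#' @param models list of `dp_energy_model` built with identical descriptor
#'   configs (task fitting nets may differ).
#' @param datasets list of `dp_system`, one per task.
#' @param sch,spec,tau_stop,seed as in [train_model()].
#' @param probs task-pick probabilities (default uniform).
#' @return list with `models` (sharing the final descriptor parameters) and
#'   the per-step `history` of picked tasks and losses.
#' @export
train_multitask <- function(models, datasets, sch = lr_schedule(),
                            spec = loss_spec(), tau_stop = sch$stop_steps,
                            seed = 1L, probs = NULL) {
  nt_task <- length(models)
  if (nt_task < 2L) stop("multi-task training needs >= 2 tasks",
                         call. = FALSE)
  if (is.null(probs)) probs <- rep(1 / nt_task, nt_task)
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  for (t in seq_len(nt_task))
    if (is.null(models[[t]]$bias_done))
      models[[t]] <- init_energy_bias(models[[t]], datasets[[t]])
  # shared parameters live under p/desc and p/te
  is_shared <- function(nm) startsWith(nm, "p/desc") | startsWith(nm, "p/te")
  flats <- lapply(models, function(m) flatten_params(m$params))
  shared <- flats[[1L]][is_shared(names(flats[[1L]]))]
  states <- lapply(flats, adam_init)
  nlss <- lapply(seq_len(nt_task), function(t)
    precompute_nls(models[[t]], datasets[[t]]$frames))
  hist <- list()
  with_seed(seed, {
    for (tau in seq_len(tau_stop) - 1L) {
      t <- sample.int(nt_task, 1L, prob = probs)
      lr <- lr_at(tau, sch)
      pe <- loss_prefactor(tau, spec$start_pref_e, spec$limit_pref_e, sch)
      pf <- loss_prefactor(tau, spec$start_pref_f, spec$limit_pref_f, sch)
      pv <- loss_prefactor(tau, spec$start_pref_v, spec$limit_pref_v, sch)
      flats[[t]][names(shared)] <- shared
      models[[t]]$params <- assign_params(models[[t]]$params, flats[[t]])
      b <- sample.int(length(datasets[[t]]$frames), 1L)
      fg <- frame_grad(models[[t]], datasets[[t]]$frames[[b]],
                       nlss[[t]][[b]], pe, pf, pv, spec)
      upd <- adam_step(flats[[t]], fg$grad, states[[t]], lr)
      flats[[t]] <- upd$flat
      states[[t]] <- upd$state
      shared <- flats[[t]][names(shared)]
      models[[t]]$params <- assign_params(models[[t]]$params, flats[[t]])
      hist[[length(hist) + 1L]] <-
        data.frame(step = tau, task = t,
                   loss_e = fg$losses$e %||% NA_real_,
                   loss_f = fg$losses$f %||% NA_real_)
    }
  })
  for (t in seq_len(nt_task)) {
    flats[[t]][names(shared)] <- shared
    models[[t]]$params <- assign_params(models[[t]]$params, flats[[t]])
  }
  list(models = models, history = do.call(rbind, hist))
}

# ---- ensemble model deviation -------------------------------------------

# ensemble standard deviation of per-atom forces: for each atom the root
# mean (over models) squared norm of the deviation from the ensemble mean.
# The mean is computed in centered form so identical ensembles give a
# deviation of exactly zero.
force_deviation <- function(Fs) {
  n <- nrow(Fs[[1L]])
  Fbar <- Fs[[1L]] + Reduce(`+`, lapply(Fs, function(f) f - Fs[[1L]])) /
    length(Fs)
  sqrt(Reduce(`+`, lapply(Fs, function(f)
    .rowSums((f - Fbar)^2, n, 3L))) / length(Fs))
}

# per-component virial deviation with its 1/N normalization
virial_deviation <- function(Vs, n_atoms) {
  Vbar <- Vs[[1L]] + Reduce(`+`, lapply(Vs, function(v) v - Vs[[1L]])) /
    length(Vs)
  sqrt(Reduce(`+`, lapply(Vs, function(v) (v - Vbar)^2)) / length(Vs)) /
    n_atoms
}

#' Ensemble model deviation of forces and virials
#'
#' For an ensemble of models trained on the same data from independent
#' initializations, the per-atom force deviation is the ensemble standard
#' deviation `eps_F,i = sqrt(< ||F_i - <F_i>||^2 >)` and the virial
#' deviation is `eps_Xi = (1/N) sqrt(< (Xi - <Xi>)^2 >)` per component.
#' Relative variants divide by the magnitude of the ensemble mean plus the
#' protection constant `nu`.
#'
#' @param models list of >= 2 `dp_energy_model` with identical type maps.
#' @param frames a `dp_system` or list of `list(frame, ...)`.
#' @param nu protection constant for the relative deviations (eV/Angstrom).
#' @return list of per-frame results: `eps_f` (per atom), `eps_v`
#'   (`3 x 3`), `rel_eps_f`, `rel_eps_v`, and summaries `max/mean/min` of
#'   both, plus a per-frame summary data frame `table` with the columns of
#'   the deviation output file.
#' @export
model_deviation <- function(models, frames, nu = 0.01) {
  if (length(models) < 2L)
    stop("model deviation needs an ensemble of >= 2 models", call. = FALSE)
  tm <- models[[1L]]$type_map
  for (m in models) if (!identical(m$type_map, tm))
    stop("ensemble models disagree on the type map", call. = FALSE)
  if (inherits(frames, "dp_system")) frames <- frames$frames
  per_frame <- vector("list", length(frames))
  tab <- NULL
  for (k in seq_along(frames)) {
    fr <- frames[[k]]$frame %||% frames[[k]]
    n <- fr$n_atoms
    Fs <- vector("list", length(models))
    Vs <- vector("list", length(models))
    for (j in seq_along(models)) {
      p <- predict_frame(models[[j]], fr)
      Fs[[j]] <- p$forces
      Vs[[j]] <- p$virial %||% matrix(0, 3L, 3L)
    }
    Fbar <- Reduce(`+`, Fs) / length(Fs)
    Vbar <- Reduce(`+`, Vs) / length(Vs)
    eps_f <- force_deviation(Fs)
    eps_v <- virial_deviation(Vs, n)
    rel_f <- eps_f / (sqrt(.rowSums(Fbar^2, n, 3L)) + nu)
    rel_v <- eps_v / (sqrt(sum(Vbar^2)) + nu)
    per_frame[[k]] <- list(eps_f = eps_f, eps_v = eps_v,
                           rel_eps_f = rel_f, rel_eps_v = rel_v,
                           max_f = max(eps_f), mean_f = mean(eps_f),
                           min_f = min(eps_f),
                           max_v = max(eps_v), mean_v = mean(eps_v),
                           min_v = min(eps_v))
    tab <- rbind(tab, data.frame(
      frame = k - 1L,
      max_devi_f = max(eps_f), min_devi_f = min(eps_f),
      avg_devi_f = mean(eps_f),
      max_devi_v = max(eps_v), min_devi_v = min(eps_v),
      avg_devi_v = mean(eps_v)))
  }
  list(frames = per_frame, table = tab)
}

#' Select candidate configurations by force deviation
#'
#' Candidates are the frames whose maximum per-atom force deviation falls
#' in `[theta_low, theta_high)`; frames below `theta_low` count as
#' accurate.  An optional atom subsample reduces the cost of the deviation
#' statistic.
#'
#' @param devi_max_f per-frame maximum force deviations (eV/Angstrom).
#' @param theta_low,theta_high selection thresholds,
#'   `theta_low < theta_high` (the upper one defaults to 0.15 eV/Angstrom
#'   above the lower).
#' @return list with `candidates` (1-based frame indices) and
#'   `accurate_ratio` (`NULL` for empty input).
#' @export
select_candidates <- function(devi_max_f, theta_low,
                              theta_high = theta_low + 0.15) {
  if (!(theta_low < theta_high))
    stop("selection thresholds must satisfy theta_low < theta_high",
         call. = FALSE)
  if (length(devi_max_f) == 0L)
    return(list(candidates = integer(0), accurate_ratio = NULL))
  list(candidates = which(devi_max_f >= theta_low &
                            devi_max_f < theta_high),
       accurate_ratio = mean(devi_max_f < theta_low))
}
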