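# Energy and tensor models: descriptor + fitting head, analytic forces and
# virial via the tape, QM/MM range correction, reciprocal-space long-range
# electrostatics and pairwise-potential interpolation.

# ---- parameter plumbing --------------------------------------------------
# Trainable parameters are the numeric matrices found anywhere in the nested
# parameter list; flatten/assign walk them by slash-separated path.

flatten_params <- function(x, prefix = "p") {
  if (is.matrix(x) && is.numeric(x)) {
    out <- list(x); names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    nm <- names(x)
    out <- list()
    for (k in seq_along(x)) {
      key <- if (!is.null(nm) && nzchar(nm[k])) nm[k] else as.character(k)
      out <- c(out, flatten_params(x[[k]], paste0(prefix, "/", key)))
    }
    return(out)
  }
  list()
}

assign_params <- function(x, flat, prefix = "p") {
  if (is.matrix(x) && is.numeric(x)) {
    v <- flat[[prefix]]
    return(if (is.null(v)) x else v)
  }
  if (is.list(x)) {
    nm <- names(x)
    for (k in seq_along(x)) {
      key <- if (!is.null(nm) && nzchar(nm[k])) nm[k] else as.character(k)
      x[k] <- list(assign_params(x[[k]], flat, paste0(prefix, "/", key)))
    }
  }
  x
}

# mirror of the parameter list with matrices replaced by tape leaf ids;
# records name -> id in reg$ids
tape_params <- function(tape, x, reg, prefix = "p") {
  if (is.matrix(x) && is.numeric(x)) {
    id <- ad_input(tape, x)
    reg$ids[[prefix]] <- id
    return(id)
  }
  if (is.list(x)) {
    nm <- names(x)
    out <- vector("list", length(x))
    names(out) <- nm
    for (k in seq_along(x)) {
      key <- if (!is.null(nm) && nzchar(nm[k])) nm[k] else as.character(k)
      out[k] <- list(tape_params(tape, x[[k]], reg,
                                 paste0(prefix, "/", key)))
    }
    return(out)
  }
  x
}

# ---- model constructors --------------------------------------------------

#' Fitting-network configuration
#'
#' @param neuron hidden-layer widths of the fitting network.
#' @param activation activation name.
#' @param resnet_dt trainable timesteps.
#' @param numb_aparam,numb_fparam widths of per-atom / per-frame parameter
#'   inputs appended to the descriptor.
#' @return a `dp_fitting_config`.
#' @export
fitting_config <- function(neuron = c(240L, 240L, 240L), activation = "tanh",
                           resnet_dt = FALSE, numb_aparam = 0L,
                           numb_fparam = 0L) {
  structure(list(neuron = as.integer(neuron), activation = activation,
                 resnet_dt = resnet_dt, numb_aparam = as.integer(numb_aparam),
                 numb_fparam = as.integer(numb_fparam)),
            class = "dp_fitting_config")
}

needs_type_embedding <- function(dcfg) {
  if (dcfg$kind == "hybrid")
    return(any(vapply(dcfg$children, needs_type_embedding, TRUE)))
  dcfg$kind == "se_atten" || dcfg$routing == "type_embed"
}

#' Construct an energy model
#'
#' A Deep Potential energy model: descriptor plus scalar fitting head.  The
#' atomic energy is the fitting-network image of the atomic descriptor (and
#' optional atomic/frame parameters and type embedding); the frame energy is
#' the atomic sum, and forces/virial are its analytic derivatives.
#'
#' @param type_map species names; defines `Nt` and the index meaning.
#' @param descriptor a [descriptor_config()].
#' @param fitting a [fitting_config()].
#' @param type_embed_neuron layer widths of the type-embedding network, used
#'   when the descriptor routing requires it (or when sharing the fitting
#'   net across species is requested via `share_fitting`).
#' @param share_fitting use one fitting network for all species, with the
#'   type embedding appended to its input.
#' @param dprc optional per-atom region labels (`"QM"`/`"MM"`): switches off
#'   MM-MM interactions and removes the energy bias of MM atoms.
#' @param seed integer seed for parameter initialization.
#' @return a `dp_energy_model`.
#' @export
energy_model <- function(type_map, descriptor = descriptor_config(),
                         fitting = fitting_config(),
                         type_embed_neuron = c(8L), share_fitting = FALSE,
                         dprc = NULL, seed = 1L) {
  nt <- length(type_map)
  use_te <- needs_type_embedding(descriptor) || share_fitting
  with_seed(seed, {
    te <- if (use_te) new_type_embedding(nt, type_embed_neuron)
    te_dim <- if (use_te) te$dim else 0L
    dpar <- init_desc_params(descriptor, nt, te_dim)
    ddim <- desc_dim(descriptor, nt)
    fin <- ddim + fitting$numb_aparam + fitting$numb_fparam +
      if (share_fitting) te_dim else 0L
    fit <- if (share_fitting)
      list(new_network(fin, fitting$neuron, n_out = 1L,
                       activation = fitting$activation,
                       resnet_dt = fitting$resnet_dt))
    else lapply(seq_len(nt), function(a)
      new_network(fin, fitting$neuron, n_out = 1L,
                  activation = fitting$activation,
                  resnet_dt = fitting$resnet_dt))
    params <- list(desc = dpar, fit = fit)
    if (use_te) params$te <- te$net
    structure(list(type_map = type_map, nt = nt, descriptor = descriptor,
                   fitting = fitting, share_fitting = share_fitting,
                   use_te = use_te, te_meta = if (use_te) te[c("n_types",
                                                               "dim")],
                   dprc = dprc, params = params, compressed = FALSE),
              class = "dp_energy_model")
  })
}

#' @export
print.dp_energy_model <- function(x, ...) {
  cat("Deep Potential energy model:", x$descriptor$kind, "descriptor,",
      x$nt, "species (", paste(x$type_map, collapse = ", "), ")",
      if (x$compressed) ", compressed", "\n")
  cat("Parameters:",
      sum(vapply(flatten_params(x$params), length, 1L)), "\n")
  invisible(x)
}

leaf_configs <- function(dcfg) {
  if (dcfg$kind == "hybrid") dcfg$children else list(dcfg)
}

leaf_params <- function(model) {
  if (model$descriptor$kind == "hybrid") model$params$desc$children
  else list(model$params$desc)
}

# ---- forward -------------------------------------------------------------

# Build the full tape for one frame.  Returns list(tape, E, Ei, leaves
# (per-leaf ctx with rvec input ids), reg (param name -> node id), D, atoms).
model_forward <- function(model, frame, nls = NULL, aparam = NULL,
                          fparam = NULL, pair_interp = NULL) {
  tape <- ad_tape()
  reg <- new.env(parent = emptyenv())
  reg$ids <- list()
  pids <- tape_params(tape, model$params, reg)
  nt <- model$nt
  regions <- model$dprc
  if (!is.null(regions) && length(regions) != frame$n_atoms)
    stop("dprc region labels must match the atom count", call. = FALSE)

  te_id <- NULL
  if (model$use_te) {
    onehot <- ad_const(tape, diag(nt))
    te_id <- net_forward_tape(tape, model$params$te, onehot, pids$te)
  }

  cfgs <- leaf_configs(model$descriptor)
  dpars <- leaf_params(model)
  dpids <- if (model$descriptor$kind == "hybrid") pids$desc$children
  else list(pids$desc)
  leaves <- vector("list", length(cfgs))
  Ds <- vector("list", length(cfgs))
  atoms <- NULL
  for (k in seq_along(cfgs)) {
    ctx <- pair_ctx(tape, frame, cfgs[[k]], nt, regions = regions,
                    nl = if (!is.null(nls)) nls[[k]])
    out <- desc_forward(tape, cfgs[[k]], dpars[[k]], dpids[[k]], ctx, frame,
                        nt, te_id)
    leaves[[k]] <- ctx
    Ds[[k]] <- out$D
    if (is.null(atoms)) atoms <- out$atoms
  }
  D <- if (length(Ds) > 1L) ad_concat_cols(tape, unlist(Ds)) else Ds[[1L]]

  # fitting input: descriptor (+ atomic/frame parameters + type embedding)
  fin <- list(D)
  if (model$fitting$numb_aparam > 0L) {
    if (is.null(aparam)) stop("model expects aparam input", call. = FALSE)
    fin <- c(fin, ad_const(tape, as_mat(aparam)))
  }
  if (model$fitting$numb_fparam > 0L) {
    if (is.null(fparam)) stop("model expects fparam input", call. = FALSE)
    fin <- c(fin, ad_const(tape, matrix(fparam, frame$n_atoms,
                                        length(fparam), byrow = TRUE)))
  }
  if (model$share_fitting)
    fin <- c(fin, ad_slice_rows(tape, te_id, frame$species + 1L))
  X <- if (length(fin) > 1L) ad_concat_cols(tape, unlist(fin)) else
    fin[[1L]]

  n <- frame$n_atoms
  Ei <- fit_head(tape, model, pids, X, frame$species, n, regions, te_id)

  # pairwise-potential interpolation (blended atomic energies)
  if (!is.null(pair_interp))
    Ei <- blend_pair_interp(tape, Ei, leaves[[1L]], pair_interp, n)

  E <- ad_sumall(tape, Ei)
  list(tape = tape, E = E, Ei = Ei, leaves = leaves, reg = reg, D = D,
       atoms = atoms, frame = frame)
}

# Fitting head over stacked per-atom input rows, with the range-correction
# bias removal.  When regions are present, one zero-environment row per
# species is appended to the fitting input before the network runs, so the
# subtraction F0(D) - F0(0) cancels bit-exactly for an MM atom whose own
# input row is zero (same network call, same row values).
fit_head <- function(tape, model, pids, X, species_vec, n, regions_vec,
                     te_id) {
  nt <- model$nt
  dprc_on <- !is.null(regions_vec) && any(regions_vec == "MM")
  if (dprc_on) {
    fdim <- ncol(ad_value(tape, X))
    zero_rows <- if (model$share_fitting)
      ad_concat_cols(tape, c(
        ad_const(tape, matrix(0, nt, fdim - model$te_meta$dim)), te_id))
    else ad_const(tape, matrix(0, nt, fdim))
    X <- ad_concat_rows(tape, c(X, zero_rows))
    species_vec <- c(species_vec, 0:(nt - 1L))
  }
  n_aug <- n + if (dprc_on) nt else 0L
  if (model$share_fitting) {
    Ei <- net_forward_tape(tape, model$params$fit[[1L]], X, pids$fit[[1L]])
  } else {
    Ei <- NULL
    for (a in seq_len(nt)) {
      idx <- which(species_vec == a - 1L)
      if (length(idx) == 0L) next
      e <- net_forward_tape(tape, model$params$fit[[a]],
                            ad_slice_rows(tape, X, idx), pids$fit[[a]])
      sc <- ad_scatter_rows(tape, e, idx, n_aug)
      Ei <- if (is.null(Ei)) sc else ad_add(tape, Ei, sc)
    }
  }
  if (dprc_on) {
    E0 <- ad_slice_rows(tape, Ei, n + seq_len(nt))
    Ei <- ad_slice_rows(tape, Ei, seq_len(n))
    mask <- matrix(as.numeric(regions_vec == "MM"), n, 1L)
    bias <- ad_scale_rows(tape,
                          ad_slice_rows(tape, E0, species_vec[seq_len(n)] +
                                          1L),
                          ad_const(tape, mask))
    Ei <- ad_sub(tape, Ei, bias)
  }
  Ei
}

# Batched forward for training: all frames of one mini-batch share a tape,
# so parameters are registered once and the fitting network runs on the
# concatenated descriptor rows of the whole batch.  entries: list of
# list(frame, labels); labels supply aparam/fparam when the model wants
# them.  Returns per-frame energy nodes and per-frame/per-leaf pair
# contexts.
model_forward_multi <- function(model, entries, nls_list = NULL) {
  tape <- ad_tape()
  reg <- new.env(parent = emptyenv())
  reg$ids <- list()
  pids <- tape_params(tape, model$params, reg)
  nt <- model$nt
  regions <- model$dprc
  nf <- length(entries)

  te_id <- NULL
  if (model$use_te) {
    onehot <- ad_const(tape, diag(nt))
    te_id <- net_forward_tape(tape, model$params$te, onehot, pids$te)
  }

  cfgs <- leaf_configs(model$descriptor)
  dpars <- leaf_params(model)
  dpids <- if (model$descriptor$kind == "hybrid") pids$desc$children
  else list(pids$desc)

  leaves <- vector("list", nf)
  Dfr <- vector("list", nf)
  for (f in seq_len(nf)) {
    frame <- entries[[f]]$frame
    ctxs <- vector("list", length(cfgs))
    Ds <- vector("list", length(cfgs))
    for (k in seq_along(cfgs)) {
      ctx <- pair_ctx(tape, frame, cfgs[[k]], nt, regions = regions,
                      nl = if (!is.null(nls_list)) nls_list[[f]][[k]])
      Ds[[k]] <- desc_forward(tape, cfgs[[k]], dpars[[k]], dpids[[k]], ctx,
                              frame, nt, te_id)$D
      ctxs[[k]] <- ctx
    }
    leaves[[f]] <- ctxs
    Dfr[[f]] <- if (length(Ds) > 1L) ad_concat_cols(tape, unlist(Ds)) else
      Ds[[1L]]
  }
  D <- if (nf > 1L) ad_concat_rows(tape, unlist(Dfr)) else Dfr[[1L]]

  natoms <- vapply(entries, function(e) e$frame$n_atoms, 1L)
  species_all <- unlist(lapply(entries, function(e) e$frame$species))
  n_tot <- sum(natoms)
  frame_idx <- rep(seq_len(nf), natoms)

  fin <- list(D)
  if (model$fitting$numb_aparam > 0L) {
    ap <- do.call(rbind, lapply(entries, function(e) {
      if (is.null(e$labels$aparam)) stop("model expects aparam input",
                                         call. = FALSE)
      as_mat(e$labels$aparam)
    }))
    fin <- c(fin, ad_const(tape, ap))
  }
  if (model$fitting$numb_fparam > 0L) {
    fp <- do.call(rbind, lapply(seq_len(nf), function(f) {
      if (is.null(entries[[f]]$labels$fparam))
        stop("model expects fparam input", call. = FALSE)
      matrix(entries[[f]]$labels$fparam, natoms[f],
             length(entries[[f]]$labels$fparam), byrow = TRUE)
    }))
    fin <- c(fin, ad_const(tape, fp))
  }
  if (model$share_fitting)
    fin <- c(fin, ad_slice_rows(tape, te_id, species_all + 1L))
  X <- if (length(fin) > 1L) ad_concat_cols(tape, unlist(fin)) else
    fin[[1L]]

  Ei <- fit_head(tape, model, pids, X, species_all, n_tot,
                 if (!is.null(regions)) rep(regions, nf), te_id)

  Efr <- ad_rowsum_groups(tape, Ei, frame_idx, nf)
  list(tape = tape, Efr = Efr, Ei = Ei, leaves = leaves, reg = reg,
       frame_idx = frame_idx, natoms = natoms, entries = entries)
}

#' Predict energy, forces and virial of a frame
#'
#' The energy is the sum of atomic contributions; forces are
#' `-dE/dr` and the virial is `-sum_p (dE/dr_p) (x) r_p` over ordered
#' neighbor pairs (equal to the cell derivative at fixed fractional
#' coordinates), both obtained by reverse-mode differentiation of the tape.
#'
#' @param model a `dp_energy_model`.
#' @param frame a `dp_frame`.
#' @param what any of `"energy"`, `"forces"`, `"virial"`.
#' @param aparam,fparam optional per-atom / per-frame extra inputs.
#' @param pair_interp optional [pair_interp_config()] blended into the
#'   atomic energies.
#' @return list with `energy` (eV), `atomic_energies`, `forces`
#'   (`N x 3`, eV/Angstrom), and `virial` (`3 x 3`, eV; periodic frames
#'   only).
#' @export
predict_frame <- function(model, frame,
                          what = c("energy", "forces", "virial"),
                          aparam = NULL, fparam = NULL, pair_interp = NULL) {
  fw <- model_forward(model, frame, aparam = aparam, fparam = fparam,
                      pair_interp = pair_interp)
  out <- list(energy = ad_value(fw$tape, fw$E)[1L],
              atomic_energies = as.vector(ad_value(fw$tape, fw$Ei)))
  if (any(c("forces", "virial") %in% what)) {
    wrt <- lapply(fw$leaves, function(l) l$rvec)
    names(wrt) <- as.character(seq_along(wrt))
    gs <- ad_backward(fw$tape, fw$E, unlist(wrt))
    n <- frame$n_atoms
    forces <- matrix(0, n, 3L)
    virial <- matrix(0, 3L, 3L)
    for (k in seq_along(fw$leaves)) {
      nl <- fw$leaves[[k]]$nl
      g <- gs[[k]]
      if (length(nl$i) == 0L) next
      forces <- forces + rowsum_pad(g, nl$i, n) - rowsum_pad(g, nl$j, n)
      virial <- virial - crossprod(g, nl$rvec)
    }
    if ("forces" %in% what) out$forces <- forces
    if ("virial" %in% what && frame$pbc) out$virial <- virial
  }
  out
}

#' Total potential energy of a frame
#' @inheritParams predict_frame
#' @return scalar energy (eV).
#' @export
total_energy <- function(model, frame, aparam = NULL, fparam = NULL)
  predict_frame(model, frame, what = "energy", aparam = aparam,
                fparam = fparam)$energy

#' Atomic energy contributions of a frame
#' @inheritParams predict_frame
#' @return numeric vector of per-atom energies (eV).
#' @export
atomic_energy <- function(model, frame, aparam = NULL, fparam = NULL)
  predict_frame(model, frame, what = "energy", aparam = aparam,
                fparam = fparam)$atomic_energies

#' Analytic forces and virial of a frame
#' @inheritParams predict_frame
#' @return list with `forces` and (periodic frames) `virial`.
#' @export
forces_and_virial <- function(model, frame, aparam = NULL, fparam = NULL) {
  p <- predict_frame(model, frame, aparam = aparam, fparam = fparam)
  list(forces = p$forces, virial = p$virial)
}

# ---- DPRc helpers --------------------------------------------------------

#' Range-corrected switching function
#'
#' The QM/MM range correction zeroes the switching function — and with it
#' every descriptor contribution and force — between two MM atoms; all other
#' pairs use the ordinary smooth switch.
#'
#' @param r distances.
#' @param region_i,region_j region labels (`"QM"` or `"MM"`) of the two
#'   atoms.
#' @param rs,rc switching radii.
#' @return switching values.
#' @export
dprc_switch <- function(r, region_i, region_j, rs, rc) {
  out <- switch_fn(r, rs, rc)
  out[region_i == "MM" & region_j == "MM"] <- 0
  out
}

#' Range-corrected atomic energy
#'
#' MM atoms have the vacuum image of their fitting network subtracted, so an
#' MM atom with an empty neighborhood contributes exactly zero energy.
#'
#' @param model a `dp_energy_model` with `dprc` region labels set.
#' @param frame a `dp_frame`.
#' @return per-atom energies (eV).
#' @export
dprc_energy <- function(model, frame) {
  if (is.null(model$dprc)) stop("model has no dprc region labels",
                                call. = FALSE)
  atomic_energy(model, frame)
}

# ---- tensor fitting ------------------------------------------------------

#' Construct a tensor-fitting model
#'
#' Predicts per-atom first-order (vector) or second-order (matrix) tensors
#' from the two-body embedding intermediates: the embedding matrix is
#' contracted with the directional columns of the environment matrix and
#' weighted by the fitting-network output, which makes the prediction
#' exactly equivariant under rigid rotations.
#'
#' @param type_map species names.
#' @param descriptor a full-information `se_e2_a` (or `se_atten`)
#'   [descriptor_config()].
#' @param order 1 (vector) or 2 (matrix).
#' @param neuron fitting-net hidden widths.
#' @param seed integer seed.
#' @return a `dp_tensor_model`.
#' @export
tensor_model <- function(type_map, descriptor = descriptor_config(),
                         order = 1L, neuron = c(100L, 100L), seed = 1L) {
  if (!descriptor$kind %in% c("se_e2_a", "se_atten"))
    stop("tensor fitting requires a full-information two-body embedding ",
         "descriptor", call. = FALSE)
  nt <- length(type_map)
  M <- descriptor$neuron[length(descriptor$neuron)]
  with_seed(seed, {
    dpar <- init_desc_params(descriptor, nt,
                             te_dim = 0L)
    ddim <- desc_dim(descriptor, nt)
    fit <- lapply(seq_len(nt), function(a)
      new_network(ddim, neuron, n_out = M))
    structure(list(type_map = type_map, nt = nt, descriptor = descriptor,
                   order = as.integer(order), M = M,
                   params = list(desc = dpar, fit = fit)),
              class = "dp_tensor_model")
  })
}

# tape forward for the tensor model; returns per-atom tensor node list
tensor_forward <- function(model, frame) {
  tape <- ad_tape()
  reg <- new.env(parent = emptyenv())
  reg$ids <- list()
  pids <- tape_params(tape, model$params, reg)
  nt <- model$nt
  cfg <- model$descriptor
  ctx <- pair_ctx(tape, frame, cfg, nt)
  out <- desc_forward(tape, cfg, model$params$desc, pids$desc, ctx, frame,
                      nt, want_atoms = TRUE)
  n <- frame$n_atoms
  Mv <- model$M
  nc <- ctx$nc
  Ti <- vector("list", n)
  for (a in seq_len(n)) {
    sp <- frame$species[a] + 1L
    drow <- ad_slice_rows(tape, out$D, a)
    f <- net_forward_tape(tape, model$params$fit[[sp]], drow,
                          pids$fit[[sp]])                     # 1 x M
    at <- out$atoms[[a]]
    if (is.null(at)) {
      Ti[[a]] <- NULL   # isolated atom: zero tensor
      next
    }
    B <- ad_slice_cols(tape, at$GR, 2:4)                      # M x 3
    if (model$order == 1L) {
      Ti[[a]] <- ad_smul(tape, ad_matmul(tape, f, B), 1 / nc) # 1 x 3
    } else {
      C <- ad_scale_rows(tape, B, ad_transpose(tape, f))
      Ti[[a]] <- ad_smul(tape, ad_matmul(tape, ad_transpose(tape, B), C),
                         1 / nc^2)                            # 3 x 3
    }
  }
  list(tape = tape, Ti = Ti, reg = reg, ctx = ctx)
}

#' Predict per-atom tensors
#'
#' @param model a `dp_tensor_model`.
#' @param frame a `dp_frame`.
#' @return list with `atomic` (per-atom `N x 3` matrix for order 1, list of
#'   `3 x 3` matrices for order 2) and `total` (their sum).
#' @export
atomic_tensor <- function(model, frame) {
  fw <- tensor_forward(model, frame)
  n <- frame$n_atoms
  if (model$order == 1L) {
    at <- matrix(0, n, 3L)
    for (a in seq_len(n))
      if (!is.null(fw$Ti[[a]])) at[a, ] <- ad_value(fw$tape, fw$Ti[[a]])
    list(atomic = at, total = colSums(at))
  } else {
    at <- lapply(seq_len(n), function(a)
      if (is.null(fw$Ti[[a]])) matrix(0, 3L, 3L) else
        ad_value(fw$tape, fw$Ti[[a]]))
    list(atomic = at, total = Reduce(`+`, at))
  }
}

# ---- long-range electrostatics ------------------------------------------

#' Long-range electrostatics configuration
#'
#' @param beta Gaussian spread parameter (1/Angstrom).
#' @param L Fourier-space cutoff: integer triples `m` with `||m|| <= L` in
#'   the reciprocal-lattice basis enter the sum.
#' @param ion_charges per-atom point charges (e).
#' @param wc_charges charges of the Wannier centroids (e), may be empty.
#' @param coulomb_constant energy scale of `q^2 / r`
#'   (default 14.399645 eV Angstrom / e^2).
#' @return a `dp_dplr_config`.
#' @export
dplr_config <- function(beta = 0.4, L = 6L, ion_charges, wc_charges =
                          numeric(0), coulomb_constant = 14.399645) {
  if (L < 1L) stop("Fourier cutoff L must be >= 1", call. = FALSE)
  structure(list(beta = beta, L = as.integer(L),
                 ion_charges = as.numeric(ion_charges),
                 wc_charges = as.numeric(wc_charges),
                 coulomb_constant = coulomb_constant),
            class = "dp_dplr_config")
}

#' Reciprocal-space electrostatic energy of Gaussian charges
#'
#' The structure factor sums ionic point charges and Wannier-centroid
#' charges; the energy is `1/(2 pi V) sum_{m != 0, ||m|| <= L}
#' exp(-pi^2 m^2 / beta^2) / m^2 |S(m)|^2`, multiplied by the Coulomb
#' constant to give eV.  `S^2` is read as the complex modulus squared so the
#' energy is real.
#'
#' @param frame periodic `dp_frame` whose atoms carry `ion_charges`.
#' @param cfg a [dplr_config()].
#' @param wc_positions `n x 3` Wannier-centroid coordinates (from a dipole
#'   tensor model), or `NULL` when `wc_charges` is empty.
#' @return scalar electrostatic energy (eV).
#' @export
dplr_energy <- function(frame, cfg, wc_positions = NULL) {
  if (!frame$pbc)
    stop("long-range electrostatics requires a periodic frame",
         call. = FALSE)
  if (length(cfg$wc_charges) > 0L && is.null(wc_positions))
    stop("wc_positions required when wc_charges are present", call. = FALSE)
  h <- frame$cell
  V <- det(h)
  L <- cfg$L
  grid <- as.matrix(expand.grid(-L:L, -L:L, -L:L))
  grid <- grid[rowSums(grid^2) > 0 & sqrt(rowSums(grid^2)) <= L, ,
               drop = FALSE]
  m_cart <- grid %*% t(solve(h))
  m2 <- rowSums(m_cart^2)
  pos <- frame$coords
  q <- cfg$ion_charges
  if (length(cfg$wc_charges) > 0L) {
    pos <- rbind(pos, as.matrix(wc_positions))
    q <- c(q, cfg$wc_charges)
  }
  phase <- pos %*% t(m_cart)                        # ncharge x nm
  S <- colSums(q * exp(-2i * pi * phase))
  cfg$coulomb_constant / (2 * pi * V) *
    sum(exp(-pi^2 * m2 / cfg$beta^2) / m2 * Mod(S)^2)
}

# ---- pairwise-potential interpolation ------------------------------------

#' Read a tabulated pairwise potential
#'
#' Two-column text (`# r u` header optional): evenly spaced radii
#' (Angstrom) and energies (eV).  Evaluation uses a natural cubic spline,
#' which is twice continuously differentiable, so blending preserves smooth
#' forces; radii outside the tabulated range raise an error.
#'
#' @param path file path, or a two-column matrix.
#' @return a `dp_pair_table` with evaluator `f(x, deriv = 0)`.
#' @export
read_pair_table <- function(path) {
  m <- if (is.matrix(path)) path else
    as.matrix(utils::read.table(path, comment.char = "#"))
  if (ncol(m) != 2L || nrow(m) < 2L)
    stop("pair table must have two columns and at least two rows",
         call. = FALSE)
  r <- m[, 1L]; u <- m[, 2L]
  dr <- diff(r)
  if (any(abs(dr - dr[1L]) > 1e-8 * dr[1L]))
    stop("pair table grid must be evenly spaced", call. = FALSE)
  sf <- stats::splinefun(r, u, method = "natural")
  rng <- range(r)
  f <- function(x, deriv = 0L) {
    if (any(x < rng[1L] - 1e-12) || any(x > rng[2L] + 1e-12))
      stop("pair-table evaluation outside tabulated range [",
           rng[1L], ", ", rng[2L], "]", call. = FALSE)
    sf(x, deriv = deriv)
  }
  structure(list(r = r, u = u, f = f, range = rng),
            class = "dp_pair_table")
}

#' Pairwise-interpolation configuration
#'
#' @param ra,rb interpolation bounds (Angstrom): pure pairwise below `ra`,
#'   pure model beyond `rb`, quintic blend between.
#' @param alpha_s softmin scale (Angstrom).
#' @param table a [read_pair_table()].
#' @return a `dp_pair_interp_config`.
#' @export
pair_interp_config <- function(ra, rb, alpha_s, table) {
  if (!(ra < rb)) stop("pair interpolation needs ra < rb", call. = FALSE)
  structure(list(ra = ra, rb = rb, alpha_s = alpha_s, table = table),
            class = "dp_pair_interp_config")
}

#' Softmin of neighbor distances
#'
#' `sigma_i = sum_j r_ij exp(-r_ij / alpha_s) / sum_j exp(-r_ij / alpha_s)`;
#' equal distances return the distance exactly.
#'
#' @param dists numeric vector of one atom's neighbor distances.
#' @param alpha_s softmin scale (Angstrom).
#' @return scalar.
#' @export
softmin_dist <- function(dists, alpha_s) {
  m0 <- min(dists)
  e <- exp(-(dists - m0) / alpha_s)
  # centered form: exact for equal distances, overflow-safe otherwise
  m0 + sum((dists - m0) * e) / sum(e)
}

#' Pairwise interpolation weight
#'
#' `w = 1` for `sigma < ra`, the quintic bracket of
#' `u = (sigma - ra)/(rb - ra)` in between, `0` for `sigma >= rb`; twice
#' continuously differentiable in `sigma`.
#'
#' @param sigma softmin distances.
#' @param ra,rb interpolation bounds.
#' @param deriv 0, 1 or 2 (derivatives in `sigma`).
#' @return numeric like `sigma`.
#' @export
interp_weight <- function(sigma, ra, rb, deriv = 0L) {
  u <- (sigma - ra) / (rb - ra)
  poly_switch(u, deriv = deriv) / (rb - ra)^deriv
}

# blend per-atom model energies with the tabulated pair potential on tape
blend_pair_interp <- function(tape, Ei, ctx, cfg, n) {
  nl <- ctx$nl
  if (length(nl$i) == 0L) return(Ei)
  upair <- ad_pairtab(tape, ctx$r, cfg$table)
  Epair <- ad_rowsum_groups(tape, upair, nl$i, n)
  es <- ad_exp(tape, ad_smul(tape, ctx$r, -1 / cfg$alpha_s))
  num <- ad_rowsum_groups(tape, ad_mul(tape, ctx$r, es), nl$i, n)
  den <- ad_rowsum_groups(tape, es, nl$i, n)
  # isolated atoms: den = 0; force sigma far beyond rb so w = 0 exactly
  denv <- ad_value(tape, den)
  iso <- which(denv[, 1L] == 0)
  if (length(iso)) {
    fix <- matrix(0, n, 1L)
    fix[iso, 1L] <- 1
    den <- ad_add(tape, den, ad_const(tape, fix))
    big <- matrix(0, n, 1L)
    big[iso, 1L] <- 10 * cfg$rb
    num <- ad_add(tape, num, ad_const(tape, big))
  }
  sigma <- ad_mul(tape, num, ad_recip(tape, den))
  u <- ad_smul(tape,
               ad_sub(tape, sigma, ad_const(tape, matrix(cfg$ra, n, 1L))),
               1 / (cfg$rb - cfg$ra))
  w <- ad_polyswitch(tape, u)
  one <- ad_const(tape, matrix(1, n, 1L))
  ad_add(tape,
         ad_mul(tape, ad_sub(tape, one, w), Ei),
         ad_mul(tape, w, Epair))
}

#' Blended energy of model and pairwise potential
#'
#' Atomic energies interpolate between the model and the tabulated pairwise
#' potential according to the softmin of each atom's neighbor distances.
#'
#' @param model a `dp_energy_model`.
#' @param frame a `dp_frame`.
#' @param cfg a [pair_interp_config()].
#' @return list as in [predict_frame()].
#' @export
pair_interp_energy <- function(model, frame, cfg)
  predict_frame(model, frame, pair_interp = cfg)
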