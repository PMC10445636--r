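# Atomic-environment descriptors.  Every smooth descriptor is assembled on
# the autodiff tape from the per-pair relative-vector input, so energies,
# forces, virials and training gradients all flow through one code path.
# Multi-species parameter routing supports per-pair networks (Nt^2),
# per-neighbor-species networks (Nt) and the shared type-embedding network.

#' Descriptor configuration
#'
#' @param kind one of `"loc_frame"`, `"se_e2_a"` (two-body embedding, full
#'   information), `"se_e2_r"` (radial-only), `"se_e3"` (three-body
#'   embedding), `"se_atten"` (attention-based), `"hybrid"`.
#' @param rcut cutoff radius (Angstrom).
#' @param rcut_smth inner switching radius (Angstrom).
#' @param sel expected maximum neighbors per species (padding sizes); scalar
#'   or vector of length `Nt`.
#' @param neuron embedding-network layer widths; the last entry is the
#'   embedding width `M`.
#' @param axis_neuron number of leading embedding columns `M<` kept on the
#'   axis side of the contraction.
#' @param activation embedding activation.
#' @param resnet_dt trainable timesteps in embedding nets.
#' @param routing species routing of embedding parameters: `"pair"`
#'   (`Nt^2` nets), `"neighbor"` (`Nt` nets), `"type_embed"` (one shared
#'   net fed the type embeddings).
#' @param mode `"full"` or `"radial"`, for `loc_frame` only.
#' @param attn_layer,attn_dk,attn_dotr attention depth `La`, key width
#'   `d_k`, and whether attention weights are gated by the normalized
#'   direction overlap.
#' @param children list of child configs, for `hybrid` only.
#' @return a `dp_descriptor_config`.
#' @export
descriptor_config <- function(kind = "se_e2_a", rcut = 5.5, rcut_smth = 2.0,
                              sel = 20L, neuron = c(25L, 50L, 100L),
                              axis_neuron = 16L, activation = "tanh",
                              resnet_dt = FALSE,
                              routing = c("pair", "neighbor", "type_embed"),
                              mode = c("full", "radial"),
                              attn_layer = 2L, attn_dk = 64L,
                              attn_dotr = TRUE, children = NULL) {
  kind <- match.arg(kind, c("loc_frame", "se_e2_a", "se_e2_r", "se_e3",
                            "se_atten", "hybrid"))
  routing <- match.arg(routing)
  mode <- match.arg(mode)
  if (kind == "hybrid") {
    if (length(children) == 0L)
      stop("hybrid descriptor needs a non-empty child list", call. = FALSE)
    return(structure(list(kind = kind, children = children),
                     class = "dp_descriptor_config"))
  }
  M <- neuron[length(neuron)]
  if (kind %in% c("se_e2_a", "se_atten") && axis_neuron > M)
    stop("axis_neuron (M<) must not exceed the embedding width M",
         call. = FALSE)
  if (kind == "se_atten") {
    routing <- "type_embed"      # type-embedding input is the default here
    if (attn_layer < 1L) stop("se_atten needs attn_layer >= 1",
                              call. = FALSE)
  }
  structure(list(kind = kind, rcut = rcut, rcut_smth = rcut_smth,
                 sel = as.integer(sel), neuron = as.integer(neuron),
                 axis_neuron = as.integer(axis_neuron),
                 activation = activation, resnet_dt = resnet_dt,
                 routing = routing, mode = mode,
                 attn_layer = as.integer(attn_layer),
                 attn_dk = as.integer(attn_dk), attn_dotr = attn_dotr),
            class = "dp_descriptor_config")
}

desc_sel <- function(cfg, nt) {
  s <- cfg$sel
  if (length(s) == 1L) rep(s, nt) else {
    stopifnot(length(s) == nt)
    s
  }
}

#' Descriptor output dimension per atom
#' @param cfg a descriptor config.
#' @param nt number of species.
#' @export
desc_dim <- function(cfg, nt) {
  switch(cfg$kind,
    loc_frame = sum(desc_sel(cfg, nt)) * if (cfg$mode == "full") 4L else 1L,
    se_e2_a = cfg$neuron[length(cfg$neuron)] * cfg$axis_neuron,
    se_e2_r = cfg$neuron[length(cfg$neuron)],
    se_e3 = cfg$neuron[length(cfg$neuron)],
    se_atten = cfg$neuron[length(cfg$neuron)] * cfg$axis_neuron,
    hybrid = sum(vapply(cfg$children, desc_dim, 1L, nt = nt)))
}

max_cutoff <- function(cfg) {
  if (cfg$kind == "hybrid") max(vapply(cfg$children, max_cutoff, 0))
  else cfg$rcut
}

#' Resolve the embedding network used for a species combination
#'
#' Maps a (center, neighbor) species pair — or a neighbor pair for the
#' three-body descriptor — to the embedding-network parameter set under the
#' configured routing: `Nt^2` per-pair nets, `Nt` per-neighbor nets, or the
#' single shared net when type embeddings carry the species information.
#'
#' @param params descriptor parameter list of an energy model.
#' @param cfg descriptor config.
#' @param alpha_i,alpha_j 0-based species of the two atoms of the pair.
#' @return the network object routed to.
#' @export
route_species <- function(params, cfg, alpha_i, alpha_j) {
  switch(cfg$routing,
    pair = params$emb[[alpha_i + 1L]][[alpha_j + 1L]],
    neighbor = params$emb[[alpha_j + 1L]],
    type_embed = params$emb)
}

emb_input_dim <- function(cfg, te_dim) {
  if (cfg$routing == "type_embed") 1L + 2L * te_dim else 1L
}

init_desc_params <- function(cfg, nt, te_dim = 0L) {
  if (cfg$kind == "hybrid")
    return(list(children = lapply(cfg$children, init_desc_params, nt = nt,
                                  te_dim = te_dim)))
  if (cfg$kind == "loc_frame") return(list())
  if (!act_is_smooth(cfg$activation) && cfg$kind != "loc_frame")
    warning("non-smooth activation '", cfg$activation,
            "' breaks force smoothness", call. = FALSE)
  n_in <- emb_input_dim(cfg, te_dim)
  mknet <- function() new_network(n_in, cfg$neuron, n_out = NULL,
                                  activation = cfg$activation,
                                  resnet_dt = cfg$resnet_dt)
  p <- list()
  p$emb <- switch(cfg$routing,
    pair = lapply(seq_len(nt), function(a) lapply(seq_len(nt),
                                                  function(b) mknet())),
    neighbor = lapply(seq_len(nt), function(b) mknet()),
    type_embed = mknet())
  if (cfg$kind == "se_atten") {
    M <- cfg$neuron[length(cfg$neuron)]
    dk <- cfg$attn_dk
    p$attn <- lapply(seq_len(cfg$attn_layer), function(l) list(
      wq = matrix(stats::rnorm(M * dk, sd = 1 / sqrt(M + dk)), M, dk),
      bq = matrix(0, 1L, dk),
      wk = matrix(stats::rnorm(M * dk, sd = 1 / sqrt(M + dk)), M, dk),
      bk = matrix(0, 1L, dk),
      wv = matrix(stats::rnorm(M * M, sd = 1 / sqrt(2 * M)), M, M),
      bv = matrix(0, 1L, M),
      ln_g = matrix(1, 1L, M), ln_b = matrix(0, 1L, M)))
  }
  p
}

# Pair context: neighbor list + per-pair tape nodes shared by one leaf
# descriptor.  regions: optional per-atom QM/MM factor masking the switch.
pair_ctx <- function(tape, frame, cfg, nt, regions = NULL, nl = NULL) {
  if (is.null(nl)) nl <- build_neighbor_list(frame, cfg$rcut,
                                             desc_sel(cfg, nt))
  np <- length(nl$i)
  ctx <- list(nl = nl, np = np, nc = sum(desc_sel(cfg, nt)))
  ctx$rvec <- ad_input(tape, nl$rvec)
  if (np > 0L) {
    ctx$r <- ad_sqrt(tape, ad_rowsums(tape, ad_square(tape, ctx$rvec)))
    s <- ad_switch(tape, ctx$r, cfg$rcut_smth, cfg$rcut)
    if (!is.null(regions)) {
      mm <- regions[nl$i] == "MM" & regions[nl$j] == "MM"
      if (any(mm))
        s <- ad_scale_rows(tape, s, ad_const(tape, matrix(!mm + 0,
                                                          ncol = 1L)))
    }
    ctx$s <- s
    ctx$rinv <- ad_recip(tape, ctx$r)
    ctx$rhat <- ad_scale_rows(tape, ctx$rvec, ctx$rinv)
    ctx$R4 <- ad_concat_cols(tape, c(ctx$s,
                                     ad_scale_rows(tape, ctx$rhat, ctx$s)))
  }
  ctx
}

# Routed embedding evaluation over an input column x_id (n x 1), returning
# the n x M embedding matrix.  group_i/group_j: 0-based species per row.
# When the descriptor has been compressed (params$tab present), the routed
# network is replaced by its tabulated quintic.
routed_embedding <- function(tape, cfg, params, pids, x_id, group_i, group_j,
                             te_id, n) {
  if (cfg$routing == "type_embed") {
    inp <- ad_concat_cols(tape, c(
      x_id,
      ad_slice_rows(tape, te_id, group_i + 1L),
      ad_slice_rows(tape, te_id, group_j + 1L)))
    return(net_forward_tape(tape, params$emb, inp, pids$emb))
  }
  tabbed <- !is.null(params$tab)
  eval_group <- function(a, b, idx) {
    x <- ad_slice_rows(tape, x_id, idx)
    if (tabbed) {
      tab <- if (cfg$routing == "pair") params$tab[[a]][[b]] else
        params$tab[[b]]
      ad_tab(tape, x, tab)
    } else if (cfg$routing == "pair")
      net_forward_tape(tape, params$emb[[a]][[b]], x, pids$emb[[a]][[b]])
    else net_forward_tape(tape, params$emb[[b]], x, pids$emb[[b]])
  }
  acc <- NULL
  if (cfg$routing == "pair") {
    key <- paste(group_i, group_j)
    for (lev in unique(key)) {
      idx <- which(key == lev)
      g <- eval_group(group_i[idx[1L]] + 1L, group_j[idx[1L]] + 1L, idx)
      sc <- ad_scatter_rows(tape, g, idx, n)
      acc <- if (is.null(acc)) sc else ad_add(tape, acc, sc)
    }
  } else {
    for (b in sort(unique(group_j))) {
      idx <- which(group_j == b)
      g <- eval_group(NA_integer_, b + 1L, idx)
      sc <- ad_scatter_rows(tape, g, idx, n)
      acc <- if (is.null(acc)) sc else ad_add(tape, acc, sc)
    }
  }
  acc
}

# embedding of the zero input for every (center, neighbor) species pair,
# as an Nt^2 x M node (row index = a * nt + b + 1, 0-based a, b)
zero_embedding_pairs <- function(tape, cfg, params, pids, te_id, nt) {
  ga <- rep(0:(nt - 1L), each = nt)
  gb <- rep(0:(nt - 1L), times = nt)
  x0 <- ad_const(tape, matrix(0, nt * nt, 1L))
  routed_embedding(tape, cfg, params, pids, x0, ga, gb, te_id, nt * nt)
}

layer_norm_rows <- function(tape, a, gain, bias, eps = 1e-6) {
  v <- ad_value(tape, a)
  m <- ncol(v)
  mu <- ad_smul(tape, ad_rowsums(tape, a), 1 / m)
  cen <- ad_sub(tape, a, ad_scale_rows(tape,
    ad_const(tape, matrix(1, nrow(v), m)), mu))
  varr <- ad_smul(tape, ad_rowsums(tape, ad_square(tape, cen)), 1 / m)
  inv <- ad_recip(tape, ad_sqrt(tape,
    ad_add(tape, varr, ad_const(tape, matrix(eps, nrow(v), 1L)))))
  ad_addbias(tape, ad_scale_cols(tape, ad_scale_rows(tape, cen, inv), gain),
             bias)
}

# Forward evaluation of one leaf descriptor.  Returns list(D = node
# (n_atoms x dim), atoms = per-atom list(rows, G, R) for tensor heads).
desc_forward <- function(tape, cfg, params, pids, ctx, frame, nt,
                         te_id = NULL, want_atoms = FALSE) {
  switch(cfg$kind,
    se_e2_a = , se_atten = desc_se2_full(tape, cfg, params, pids, ctx,
                                         frame, nt, te_id, want_atoms),
    se_e2_r = desc_se2_radial(tape, cfg, params, pids, ctx, frame, nt,
                              te_id),
    se_e3 = desc_se3(tape, cfg, params, pids, ctx, frame, te_id),
    loc_frame = desc_locframe(tape, cfg, ctx, frame),
    stop("unsupported descriptor kind ", cfg$kind, call. = FALSE))
}

desc_se2_full <- function(tape, cfg, params, pids, ctx, frame, nt, te_id,
                          want_atoms = FALSE) {
  n <- frame$n_atoms
  nl <- ctx$nl
  M <- cfg$neuron[length(cfg$neuron)]
  Mlt <- cfg$axis_neuron
  dim_out <- M * Mlt
  atten <- cfg$kind == "se_atten"
  G <- if (ctx$np > 0L)
    routed_embedding(tape, cfg, params, pids, ctx$s,
                     frame$species[nl$i], nl$alpha_j, te_id, ctx$np)
  if (!atten && !want_atoms) {
    # fused path: one bilinear-contraction node for all atoms
    if (ctx$np == 0L)
      return(list(D = ad_const(tape, matrix(0, n, dim_out)), atoms = NULL))
    rows <- lapply(seq_len(n), function(a) nl_rows(nl, a))
    Glt <- ad_slice_cols(tape, G, seq_len(Mlt))
    D <- ad_quadcontract(tape, G, ctx$R4, ctx$R4, Glt, rows, n,
                         1 / ctx$nc^2)
    return(list(D = D, atoms = NULL))
  }
  rows_out <- vector("list", n)
  atoms <- vector("list", n)
  zero_row <- NULL
  for (a in seq_len(n)) {
    rows <- nl_rows(nl, a)
    if (length(rows) == 0L) {
      if (is.null(zero_row)) zero_row <- ad_const(tape,
                                                  matrix(0, 1L, dim_out))
      rows_out[[a]] <- zero_row
      next
    }
    Ri <- ad_slice_rows(tape, ctx$R4, rows)
    Gi <- ad_slice_rows(tape, G, rows)
    if (atten) {
      Rh <- ad_slice_rows(tape, ctx$rhat, rows)
      RR <- if (cfg$attn_dotr) ad_matmul(tape, Rh, ad_transpose(tape, Rh))
      for (l in seq_len(cfg$attn_layer)) {
        pa <- params$attn[[l]]; pl <- pids$attn[[l]]
        Q <- ad_addbias(tape, ad_matmul(tape, Gi, pl$wq), pl$bq)
        K <- ad_addbias(tape, ad_matmul(tape, Gi, pl$wk), pl$bk)
        V <- ad_addbias(tape, ad_matmul(tape, Gi, pl$wv), pl$bv)
        W <- ad_softmax_rows(tape, ad_smul(tape,
          ad_matmul(tape, Q, ad_transpose(tape, K)),
          1 / sqrt(cfg$attn_dk)))
        if (cfg$attn_dotr) W <- ad_mul(tape, W, RR)
        A <- ad_matmul(tape, W, V)
        Gi <- ad_add(tape, Gi, layer_norm_rows(tape, A, pl$ln_g, pl$ln_b))
      }
    }
    T1 <- ad_matmul(tape, ad_transpose(tape, Gi), Ri)             # M x 4
    T2 <- ad_matmul(tape,
                    ad_transpose(tape, ad_slice_cols(tape, Gi,
                                                     seq_len(Mlt))), Ri)
    Di <- ad_smul(tape, ad_matmul(tape, T1, ad_transpose(tape, T2)),
                  1 / ctx$nc^2)                                   # M x M<
    rows_out[[a]] <- ad_reshape(tape, Di, 1L, dim_out)
    atoms[[a]] <- list(rows = rows, G = Gi, R = Ri, GR = T1)
  }
  list(D = ad_concat_rows(tape, rows_out), atoms = atoms)
}

desc_se2_radial <- function(tape, cfg, params, pids, ctx, frame, nt, te_id) {
  n <- frame$n_atoms
  nl <- ctx$nl
  M <- cfg$neuron[length(cfg$neuron)]
  sel <- desc_sel(cfg, nt)
  ntt <- nt
  G <- if (ctx$np > 0L)
    routed_embedding(tape, cfg, params, pids, ctx$s,
                     frame$species[nl$i], nl$alpha_j, te_id, ctx$np)
  G0 <- zero_embedding_pairs(tape, cfg, params, pids, te_id, ntt)
  rows_out <- vector("list", n)
  for (a in seq_len(n)) {
    rows <- nl_rows(nl, a)
    ai <- frame$species[a]
    # padded slots contribute the zero-input embedding of their species
    # block, so a departing neighbor fades continuously into the padding
    counts <- tabulate(nl$alpha_j[rows] + 1L, nbins = ntt)
    pad <- NULL
    for (b in seq_len(ntt)) {
      npad <- sel[b] - counts[b]
      if (npad <= 0L) next
      g0 <- ad_smul(tape, ad_slice_rows(tape, G0, (ai * ntt + b - 1L) + 1L),
                    npad)
      pad <- if (is.null(pad)) g0 else ad_add(tape, pad, g0)
    }
    tot <- if (length(rows))
      ad_colsums(tape, ad_slice_rows(tape, G, rows)) else NULL
    tot <- if (is.null(tot)) pad else if (is.null(pad)) tot else
      ad_add(tape, tot, pad)
    rows_out[[a]] <- ad_smul(tape, tot, 1 / ctx$nc)
  }
  list(D = ad_concat_rows(tape, rows_out), atoms = NULL)
}

desc_se3 <- function(tape, cfg, params, pids, ctx, frame, te_id) {
  n <- frame$n_atoms
  nl <- ctx$nl
  M <- cfg$neuron[length(cfg$neuron)]
  rows_out <- vector("list", n)
  zero_row <- NULL
  for (a in seq_len(n)) {
    rows <- nl_rows(nl, a)
    k <- length(rows)
    if (k == 0L) {
      if (is.null(zero_row)) zero_row <- ad_const(tape, matrix(0, 1L, M))
      rows_out[[a]] <- zero_row
      next
    }
    Ri <- ad_slice_rows(tape, ctx$R4, rows)
    Th <- ad_matmul(tape, Ri, ad_transpose(tape, Ri))     # k x k angles
    th <- ad_reshape(tape, Th, k * k, 1L)
    gj <- rep(nl$alpha_j[rows], times = k)
    gk <- rep(nl$alpha_j[rows], each = k)
    G <- routed_embedding(tape, cfg, params, pids, th, gj, gk, te_id, k * k)
    rows_out[[a]] <- ad_smul(tape,
      ad_colsums(tape, ad_scale_rows(tape, G, th)), 1 / ctx$nc^2)
  }
  list(D = ad_concat_rows(tape, rows_out), atoms = NULL)
}

cross_tape <- function(tape, a, b) {
  comp <- function(x, k) ad_slice_cols(tape, x, k)
  term <- function(i, j) ad_mul(tape, comp(a, i), comp(b, j))
  ad_concat_cols(tape, c(
    ad_sub(tape, term(2L, 3L), term(3L, 2L)),
    ad_sub(tape, term(3L, 1L), term(1L, 3L)),
    ad_sub(tape, term(1L, 2L), term(2L, 1L))))
}

desc_locframe <- function(tape, cfg, ctx, frame) {
  n <- frame$n_atoms
  nl <- ctx$nl
  w <- if (cfg$mode == "full") 4L else 1L
  nc <- ctx$nc
  rows_out <- vector("list", n)
  for (a in seq_len(n)) {
    rows <- nl_rows(nl, a)
    if (length(rows) < 2L)
      stop("local-frame descriptor requires >= 2 neighbors (atom ", a, ")",
           call. = FALSE)
    ord <- order(nl$dist[rows], nl$j[rows])   # pure distance order
    rows <- rows[ord]
    rr <- ad_slice_rows(tape, ctx$r, rows)
    rinv <- ad_recip(tape, rr)
    if (cfg$mode == "radial") {
      body <- rinv
    } else {
      # local frame from the two nearest neighbors, r_ij = r_i - r_j
      rij <- ad_neg(tape, ad_slice_rows(tape, ctx$rvec, rows))
      ra <- ad_slice_rows(tape, rij, 1L)
      rb <- ad_slice_rows(tape, rij, 2L)
      e1 <- ad_scale_rows(tape, ra, ad_recip(tape, ad_sqrt(tape,
        ad_rowsums(tape, ad_square(tape, ra)))))
      proj <- ad_rowsums(tape, ad_mul(tape, rb, e1))
      v <- ad_sub(tape, rb, ad_scale_rows(tape, e1, proj))
      nv <- ad_sqrt(tape, ad_rowsums(tape, ad_square(tape, v)))
      if (ad_value(tape, nv)[1L] < 1e-10)
        stop("degenerate local frame: collinear axis atoms (atom ", a, ")",
             call. = FALSE)
      e2 <- ad_scale_rows(tape, v, ad_recip(tape, nv))
      e3 <- cross_tape(tape, e1, e2)
      E <- ad_concat_rows(tape, c(e1, e2, e3))
      loc <- ad_matmul(tape, rij, ad_transpose(tape, E))
      body <- ad_concat_cols(tape, c(rinv,
        ad_scale_rows(tape, loc, ad_square(tape, rinv))))
    }
    k <- length(rows)
    padded <- if (k < nc)
      ad_concat_rows(tape, c(body, ad_const(tape, matrix(0, nc - k, w))))
    else body
    rows_out[[a]] <- ad_reshape(tape, ad_transpose(tape, padded), 1L, nc * w)
  }
  list(D = ad_concat_rows(tape, rows_out), atoms = NULL)
}
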