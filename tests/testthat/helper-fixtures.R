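# Shared fixtures: random rotations, small frames and compact models used
# across the suite.  Everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a small periodic LJ frame (single species unless told otherwise)
tiny_frame <- function(n = 12L, seed = 1L, nt = 1L) {
  spec <- lj_spec(n_atoms = n, type_map = LETTERS[seq_len(nt)],
                  species = rep(seq_len(nt) - 1L, length.out = n))
  gen_lj_dataset(spec, 1L, seed = seed)$frames[[1L]]$frame
}

tiny_system <- function(n_frames = 4L, n = 12L, seed = 1L, nt = 1L) {
  spec <- lj_spec(n_atoms = n, type_map = LETTERS[seq_len(nt)],
                  species = rep(seq_len(nt) - 1L, length.out = n))
  gen_lj_dataset(spec, n_frames, seed = seed)
}

# compact descriptor configs keyed by kind, shared rc/rs
small_desc <- function(kind, nt = 1L, routing = "pair", rcut = 5.5,
                       rcut_smth = 2.0) {
  if (kind == "hybrid")
    return(descriptor_config("hybrid", children = list(
      small_desc("se_e2_a", nt, routing, rcut, rcut_smth),
      small_desc("se_e2_r", nt, routing, 4.5, 1.5))))
  descriptor_config(kind, rcut = rcut, rcut_smth = rcut_smth,
                    sel = rep(16L, nt), neuron = c(6L, 12L),
                    axis_neuron = 3L, routing = routing)
}

small_model <- function(kind = "se_e2_a", nt = 1L, routing = "pair",
                        seed = 4L, dprc = NULL) {
  energy_model(LETTERS[seq_len(nt)], small_desc(kind, nt, routing),
               fitting_config(neuron = c(16L, 16L)), dprc = dprc,
               seed = seed)
}

# rotate a periodic frame rigidly (coordinates and cell)
rotate_frame <- function(frame, u) {
  frame$coords <- frame$coords %*% u
  if (frame$pbc) frame$cell <- frame$cell %*% u
  frame
}

translate_frame <- function(frame, v) {
  frame$coords <- frame$coords + matrix(v, frame$n_atoms, 3L, byrow = TRUE)
  frame
}

# central finite difference of total_energy along one coordinate
energy_fd_force <- function(model, frame, atom, comp, h = 1e-4, ...) {
  f1 <- frame; f1$coords[atom, comp] <- f1$coords[atom, comp] + h
  f2 <- frame; f2$coords[atom, comp] <- f2$coords[atom, comp] - h
  -(total_energy(model, f1, ...) - total_energy(model, f2, ...)) / (2 * h)
}
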