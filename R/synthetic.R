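# Synthetic labeled data.  A Lennard-Jones labeler stands in for the ab
# initio labelers that produce real training data: random configurations are
# drawn uniformly in the cell with a minimum-distance rejection, optionally
# jittered, and labeled with the exact truncated-and-shifted LJ energy,
# analytic forces and analytic virial under the minimum-image convention.
# A second generator produces exactly rotation-equivariant per-atom vector
# labels for exercising the tensor fitting head.

#' Specification of the Lennard-Jones generator
#'
#' Defaults describe the package's reference study system: 16 argon-like
#' atoms in a 12 Angstrom periodic cube, epsilon = 0.0104 eV,
#' sigma = 3.4 Angstrom, pair cutoff 5.5 Angstrom, rejection radius 3.0
#' Angstrom and a 0.15 Angstrom Gaussian displacement scale that plays the
#' role of thermal disorder.
#'
#' @param n_atoms number of atoms per frame.
#' @param species 0-based species index per atom (single species by default).
#' @param type_map species names.
#' @param epsilon,sigma LJ parameters, scalars or `Nt x Nt` matrices
#'   (eV, Angstrom).
#' @param cutoff pair interaction cutoff (Angstrom); the potential is
#'   shifted to zero there.
#' @param cell cube edge (Angstrom) or full `3 x 3` cell, `NULL` for open
#'   boundary.
#' @param min_distance rejection radius during placement (Angstrom).
#' @param displacement Gaussian jitter scale applied after placement
#'   (Angstrom); a temperature-like knob.
#' @return an `lj_spec` list.
#' @export
lj_spec <- function(n_atoms = 16L, species = NULL, type_map = "Ar",
                    epsilon = 0.0104, sigma = 3.4, cutoff = 5.5,
                    cell = 12.0, min_distance = 3.0, displacement = 0.15) {
  nt <- length(type_map)
  if (is.null(species)) species <- rep(0L, n_atoms)
  stopifnot(length(species) == n_atoms)
  eps <- if (is.matrix(epsilon)) epsilon else matrix(epsilon, nt, nt)
  sig <- if (is.matrix(sigma)) sigma else matrix(sigma, nt, nt)
  if (any(eps <= 0) || any(sig <= 0))
    stop("epsilon and sigma must be positive", call. = FALSE)
  cellm <- if (is.null(cell)) NULL else if (is.matrix(cell)) cell else
    diag(3) * cell
  structure(list(n_atoms = as.integer(n_atoms), species = as.integer(species),
                 type_map = type_map, epsilon = eps, sigma = sig,
                 cutoff = cutoff, cell = cellm, min_distance = min_distance,
                 displacement = displacement),
            class = "lj_spec")
}

# minimum-image ordered pair table (i < j) without a cutoff restriction
all_pairs_minimg <- function(coords, cell) {
  n <- nrow(coords)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  d <- coords[jj, , drop = FALSE] - coords[ii, , drop = FALSE]
  if (!is.null(cell)) {
    s <- d %*% solve(cell)
    d <- (s - round(s)) %*% cell
  }
  list(i = ii, j = jj, rvec = d,
       dist = sqrt(.rowSums(d * d, length(ii), 3L)))
}

#' Exact Lennard-Jones labels for a frame
#'
#' Truncated-and-shifted LJ: `u(r) = 4 eps ((sig/r)^12 - (sig/r)^6) -
#' u_c` for `r <` cutoff, zero beyond.  Energy sums unordered minimum-image
#' pairs; forces are the analytic gradient; the virial is
#' `-sum_pairs u'(r) rhat (x) r_vec` (positive diagonal for repulsion).
#'
#' @param frame a `dp_frame`.
#' @param spec an [lj_spec()].
#' @return a `dp_labels` with energy, force and (for periodic frames)
#'   virial.
#' @export
lj_labels <- function(frame, spec) {
  p <- all_pairs_minimg(frame$coords, frame$cell)
  keep <- p$dist < spec$cutoff
  n <- frame$n_atoms
  forces <- matrix(0, n, 3L)
  energy <- 0
  virial <- matrix(0, 3L, 3L)
  if (any(keep)) {
    i <- p$i[keep]; j <- p$j[keep]
    r <- p$dist[keep]; rv <- p$rvec[keep, , drop = FALSE]
    a <- cbind(frame$species[i] + 1L, frame$species[j] + 1L)
    eps <- spec$epsilon[a]; sig <- spec$sigma[a]
    sr6 <- (sig / r)^6
    shift <- 4 * eps * ((sig / spec$cutoff)^12 - (sig / spec$cutoff)^6)
    energy <- sum(4 * eps * (sr6^2 - sr6) - shift)
    # u'(r) = -24 eps (2 sr12 - sr6) / r
    du <- -24 * eps * (2 * sr6^2 - sr6) / r
    g <- rv * (du / r)          # dU/d(rvec) for the pair vector r_j - r_i
    forces <- rowsum_pad(g, i, n) - rowsum_pad(g, j, n)
    virial <- -crossprod(g, rv)
  }
  dp_labels(energy = energy, force = forces,
            virial = if (frame$pbc) virial else NULL)
}

rowsum_pad <- function(x, group, n) {
  z <- matrix(0, n, ncol(x))
  rs <- rowsum(x, group)
  z[as.integer(rownames(rs)), ] <- rs
  z
}

#' Generate a Lennard-Jones-labeled dataset
#'
#' Deterministic given the seed.  Positions are uniform in the cell with a
#' minimum-image rejection radius, then jittered by the displacement scale;
#' generation aborts if rejection stalls (packing infeasible).
#'
#' @param spec an [lj_spec()].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a labeled `dp_system`.
#' @export
gen_lj_dataset <- function(spec, n_frames, seed = 1L) {
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      fr <- dp_frame(spec$species, sample_positions(spec), spec$cell)
      frames[[k]] <- list(frame = fr, labels = lj_labels(fr, spec))
    }
    dp_system(spec$type_map, frames,
              provenance = sprintf("synthetic LJ, seed %d", seed))
  })
}

sample_positions <- function(spec) {
  n <- spec$n_atoms
  cell <- spec$cell
  extent <- if (is.null(cell)) max(1, n^(1 / 3)) * spec$min_distance * 1.5
  coords <- matrix(NA_real_, n, 3L)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n)
      stop("packing infeasible: minimum-distance rejection stalled",
           call. = FALSE)
    cand <- if (is.null(cell)) stats::runif(3L, 0, extent)
    else stats::runif(3L) %*% cell
    ok <- TRUE
    if (placed > 0L) {
      d <- coords[seq_len(placed), , drop = FALSE] -
        matrix(cand, placed, 3L, byrow = TRUE)
      if (!is.null(cell)) {
        s <- d %*% solve(cell)
        d <- (s - round(s)) %*% cell
      }
      ok <- min(sqrt(.rowSums(d * d, placed, 3L))) >= spec$min_distance
    }
    if (ok) {
      placed <- placed + 1L
      coords[placed, ] <- cand
    }
  }
  coords + matrix(stats::rnorm(3L * n, sd = spec$displacement), n, 3L)
}

#' Generate a dataset with rotation-equivariant vector labels
#'
#' Per-atom vector labels built from switched neighbor unit vectors,
#' `T_i = sum_j c(alpha_j) s(r_ij) rhat_ij`, which rotate exactly with the
#' frame and vanish for isolated atoms; used to exercise the first-order
#' tensor fitting head.
#'
#' @param spec an [lj_spec()] with at least two species.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param rs,rc switching radii of the label rule (Angstrom).
#' @param coeff per-species weight vector (length `Nt`).
#' @return a `dp_system` with `atomic_tensor` labels.
#' @export
gen_dipole_dataset <- function(spec, n_frames, seed = 1L, rs = 2.0,
                               rc = spec$cutoff,
                               coeff = seq_len(length(spec$type_map))) {
  if (length(spec$type_map) < 2L)
    stop("gen_dipole_dataset needs at least two species", call. = FALSE)
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      fr <- dp_frame(spec$species, sample_positions(spec), spec$cell)
      frames[[k]] <- list(frame = fr,
                          labels = dipole_labels(fr, rs, rc, coeff))
    }
    dp_system(spec$type_map, frames,
              provenance = sprintf("synthetic dipole, seed %d", seed))
  })
}

dipole_labels <- function(frame, rs, rc, coeff) {
  p <- all_pairs_minimg(frame$coords, frame$cell)
  keep <- p$dist < rc
  lab <- matrix(0, frame$n_atoms, 3L)
  if (any(keep)) {
    i <- p$i[keep]; j <- p$j[keep]
    r <- p$dist[keep]; rv <- p$rvec[keep, , drop = FALSE]
    s <- switch_fn(r, rs, rc)
    rhat <- rv / r
    # contribution of j to i uses rhat_ij = +rhat; of i to j uses -rhat
    lab <- rowsum_pad(rhat * (s * coeff[frame$species[j] + 1L]), i,
                      frame$n_atoms) -
      rowsum_pad(rhat * (s * coeff[frame$species[i] + 1L]), j, frame$n_atoms)
  }
  dp_labels(atomic_tensor = lab)
}
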