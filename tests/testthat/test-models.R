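# Energy and tensor heads: forces and virial against finite differences,
# invariance and extensivity of the energy, QM/MM range correction,
# reciprocal-space electrostatics against a naive oracle, and the
# pairwise-potential blend.

test_that("analytic forces match energy finite differences for every descriptor", {
  set.seed(61)
  kinds <- list(c("se_e2_a", "pair"), c("se_e2_r", "pair"),
                c("se_e3", "pair"), c("se_atten", "type_embed"),
                c("hybrid", "pair"), c("loc_frame", "pair"))
  for (kk in kinds) {
    m <- small_model(kk[1], nt = 1L, routing = kk[2])
    fr <- if (kk[1] == "loc_frame") {
      # compact open cluster so every atom has >= 2 neighbors in range
      set.seed(7)
      dp_frame(rep(0L, 8L), matrix(runif(24, 0, 4.2), 8, 3))
    } else tiny_frame(10L, seed = 200L + match(kk[1], sapply(kinds, `[`, 1)))
    p <- predict_frame(m, fr)
    fscale <- max(abs(p$forces))
    for (probe in 1:4) {
      a <- sample(fr$n_atoms, 1); k <- sample(3L, 1)
      fd <- energy_fd_force(m, fr, a, k)
      expect_lt(abs(fd - p$forces[a, k]) / max(fscale, 1e-10), 1e-5)
    }
    # net force vanishes under periodic boundary conditions
    expect_lt(max(abs(colSums(p$forces))), 1e-10 * max(1, fscale))
  }
})

test_that("virial matches cell-strain finite differences", {
  m <- small_model("se_e2_a")
  fr <- tiny_frame(12L, seed = 71L)
  V <- predict_frame(m, fr)$virial
  h <- 1e-5
  for (al in 1:3) for (be in al:3) {
    eps <- matrix(0, 3, 3); eps[al, be] <- 1
    strained <- function(s) {
      Fm <- diag(3) + s * h * eps
      f2 <- fr
      f2$cell <- fr$cell %*% t(Fm)
      f2$coords <- fr$coords %*% t(Fm)
      total_energy(m, f2)
    }
    fd <- -(strained(1) - strained(-1)) / (2 * h)
    expect_equal(V[al, be], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("energy is invariant under rigid motion and extensive over clusters", {
  m <- small_model("se_e2_a")
  fr <- tiny_frame(10L, seed = 81L)
  e0 <- total_energy(m, fr)
  expect_equal(total_energy(m, translate_frame(fr, c(2.3, -1.1, 0.7))), e0,
               tolerance = 1e-12)
  expect_equal(total_energy(m, rotate_frame(fr, rand_rotation())), e0,
               tolerance = 1e-12)
  # two far-separated identical clusters in an open box
  cl <- matrix(runif(15, 0, 4), 5, 3)
  one <- dp_frame(rep(0L, 5), cl)
  two <- dp_frame(rep(0L, 10), rbind(cl, cl + 100))
  expect_equal(total_energy(m, two), 2 * total_energy(m, one),
               tolerance = 1e-10)
})

test_that("atomic and frame parameters enter the fitting input", {
  m <- energy_model("A", small_desc("se_e2_a"),
                    fitting_config(neuron = c(8L, 8L), numb_aparam = 1L,
                                   numb_fparam = 2L), seed = 5L)
  fr <- tiny_frame(6L, seed = 91L)
  ap <- matrix(rnorm(6), 6, 1)
  e1 <- atomic_energy(m, fr, aparam = ap, fparam = c(0.5, -0.2))
  e2 <- atomic_energy(m, fr, aparam = ap, fparam = c(0.9, -0.2))
  expect_true(all(abs(e1 - e2) > 0))       # frame parameter broadcasts
  ap2 <- ap; ap2[3, 1] <- ap2[3, 1] + 1
  e3 <- atomic_energy(m, fr, aparam = ap2, fparam = c(0.5, -0.2))
  expect_equal(e3[-3], e1[-3])             # atomic parameter is local
  expect_false(e3[3] == e1[3])
  expect_error(atomic_energy(m, fr), "aparam")
})

test_that("range correction zeroes MM-MM interactions and MM energy bias", {
  regions <- c(rep("QM", 4L), rep("MM", 4L))
  m <- small_model("se_e2_a", dprc = c(regions, rep("MM", 2L)))
  # frame: QM cluster, MM pair nearby, and two isolated MM atoms
  coords <- rbind(matrix(runif(12, 0, 3.5), 4, 3),
                  matrix(c(1, 5, 1,  2.5, 5, 1,  1, 1, 5,  4, 4, 5), 4, 3,
                         byrow = TRUE),
                  c(60, 60, 60), c(80, 80, 80))
  fr <- dp_frame(rep(0L, 10), coords)
  p <- predict_frame(m, fr)
  expect_equal(p$atomic_energies[9:10], c(0, 0))   # isolated MM atoms
  # forces between two isolated MM atoms are exactly zero
  mm_pair <- dp_frame(rep(0L, 2), rbind(c(0, 0, 0), c(1.8, 0, 0)))
  m2 <- small_model("se_e2_a", dprc = c("MM", "MM"))
  expect_equal(max(abs(predict_frame(m2, mm_pair)$forces)), 0)
  expect_equal(total_energy(m2, mm_pair), 0)
  # dprc_switch truth table
  expect_equal(dprc_switch(1.5, "MM", "MM", 1, 2), 0)
  expect_equal(dprc_switch(1.5, "QM", "MM", 1, 2), switch_fn(1.5, 1, 2))
  # QM atoms keep the plain-model energies when MM atoms are out of range
  mq <- small_model("se_e2_a")
  mq_rc <- mq; mq_rc$dprc <- c(rep("QM", 4L), rep("MM", 6L))
  e_plain <- atomic_energy(mq, fr)
  e_rc <- atomic_energy(mq_rc, fr)
  expect_equal(e_rc[1:4], e_plain[1:4], tolerance = 1e-12)
})

test_that("tensor heads are equivariant; order 2 is symmetric by construction", {
  set.seed(101)
  fr <- tiny_frame(8L, seed = 111L, nt = 2L)
  t1 <- tensor_model(c("A", "B"), small_desc("se_e2_a", nt = 2L),
                     order = 1L, neuron = c(12L, 12L), seed = 6L)
  t2 <- tensor_model(c("A", "B"), small_desc("se_e2_a", nt = 2L),
                     order = 2L, neuron = c(12L, 12L), seed = 6L)
  a1 <- atomic_tensor(t1, fr)
  a2 <- atomic_tensor(t2, fr)
  expect_equal(a1$total, colSums(a1$atomic))
  for (rep in 1:5) {
    u <- rand_rotation()
    fru <- rotate_frame(fr, u)
    b1 <- atomic_tensor(t1, fru)
    expect_lt(max(abs(b1$atomic - a1$atomic %*% u)), 1e-10)
    b2 <- atomic_tensor(t2, fru)
    for (i in seq_len(fr$n_atoms))
      expect_lt(max(abs(b2$atomic[[i]] - t(u) %*% a2$atomic[[i]] %*% u)),
                1e-10)
  }
  for (i in seq_len(fr$n_atoms))
    expect_equal(a2$atomic[[i]], t(a2$atomic[[i]]), tolerance = 1e-14)
  expect_error(tensor_model("A", small_desc("se_e2_r")), "full-information")
})

test_that("reciprocal-space electrostatics matches a naive loop oracle", {
  cell <- diag(3) * 8
  fr <- dp_frame(c(0L, 0L), rbind(c(0.4, 0.2, 0.1), c(2.5, 1.3, 0.5)), cell)
  cfg <- dplr_config(beta = 0.5, L = 4L, ion_charges = c(1, -1))
  # independent naive reciprocal-space loop
  naive <- 0
  for (i in -4:4) for (j in -4:4) for (k in -4:4) {
    n <- c(i, j, k)
    if (sum(n^2) == 0 || sqrt(sum(n^2)) > 4) next
    mc <- n %*% t(solve(cell))
    m2 <- sum(mc^2)
    S <- sum(c(1, -1) * exp(-2i * pi * (fr$coords %*% t(mc))))
    naive <- naive + exp(-pi^2 * m2 / 0.5^2) / m2 * Mod(S)^2
  }
  naive <- 14.399645 / (2 * pi * det(cell)) * naive
  expect_equal(dplr_energy(fr, cfg), naive, tolerance = 1e-10)
  # zero charges and translation invariance
  expect_equal(dplr_energy(fr, dplr_config(0.5, 4L, c(0, 0))), 0)
  frt <- translate_frame(fr, c(1.7, -2.9, 0.8))
  expect_equal(dplr_energy(frt, cfg), dplr_energy(fr, cfg),
               tolerance = 1e-10)
  # Wannier centroids enter the structure factor like ions
  wc <- matrix(c(0.5, 0.5, 0.5), 1, 3)
  cfg2 <- dplr_config(0.5, 4L, c(1, -1), wc_charges = -0.4)
  all3 <- dp_frame(rep(0L, 3), rbind(fr$coords, wc), cell)
  cfg3 <- dplr_config(0.5, 4L, c(1, -1, -0.4))
  expect_equal(dplr_energy(fr, cfg2, wc_positions = wc),
               dplr_energy(all3, cfg3), tolerance = 1e-12)
  expect_error(dplr_energy(dp_frame(0L, matrix(0, 1, 3)), cfg), "periodic")
})

test_that("pairwise interpolation weight and softmin behave as specified", {
  ra <- 3.0; rb <- 4.5
  expect_equal(interp_weight(2.5, ra, rb), 1)   # sigma < ra: pure pairwise
  expect_equal(interp_weight(5.0, ra, rb), 0)   # sigma >= rb: pure model
  expect_equal(interp_weight(ra, ra, rb), 1)
  u <- (3.8 - ra) / (rb - ra)
  expect_equal(interp_weight(3.8, ra, rb),
               u^3 * (-6 * u^2 + 15 * u - 10) + 1)
  expect_equal(softmin_dist(rep(2.2, 7), 0.5), 2.2)  # equal distances
  expect_lt(softmin_dist(c(2, 3, 4), 0.3), mean(c(2, 3, 4)))
  # w is C2 across sigma = ra and rb: one-sided jumps vanish with h
  for (s0 in c(ra, rb)) for (d in 0:2) {
    jump <- function(h) abs(interp_weight(s0 + h, ra, rb, d) -
                              interp_weight(s0 - h, ra, rb, d))
    expect_lt(jump(1e-4), 1e-2)
    expect_lt(jump(1e-6), 1e-4)
    expect_lt(jump(1e-6), jump(1e-4) + 1e-12)
  }
})

test_that("blended energies interpolate the model and the pair table smoothly", {
  m <- small_model("se_e2_a")
  fr <- tiny_frame(10L, seed = 121L)
  grid <- seq(0, 7, by = 0.05)
  pt <- read_pair_table(cbind(grid, 0.2 * exp(-grid / 1.5)))
  # far bounds: blended energy equals the plain model (w = 0 everywhere)
  cfg0 <- pair_interp_config(ra = 0.5, rb = 1.0, alpha_s = 0.5, table = pt)
  expect_equal(pair_interp_energy(m, fr, cfg0)$energy, total_energy(m, fr),
               tolerance = 1e-12)
  # near bounds: pure pairwise sum
  cfgp <- pair_interp_config(ra = 8.0, rb = 9.0, alpha_s = 0.5, table = pt)
  nl <- build_neighbor_list(fr, 5.5, 16L)
  epair <- sum(pt$f(nl$dist))
  expect_equal(pair_interp_energy(m, fr, cfgp)$energy, epair,
               tolerance = 1e-10)
  # blended forces are consistent with the blended energy
  cfg <- pair_interp_config(ra = 3.4, rb = 4.8, alpha_s = 0.6, table = pt)
  p <- pair_interp_energy(m, fr, cfg)
  h <- 1e-4
  for (probe in list(c(2L, 1L), c(7L, 3L))) {
    f1 <- fr; f1$coords[probe[1], probe[2]] <- f1$coords[probe[1], probe[2]] + h
    f2 <- fr; f2$coords[probe[1], probe[2]] <- f2$coords[probe[1], probe[2]] - h
    fd <- -(pair_interp_energy(m, f1, cfg)$energy -
              pair_interp_energy(m, f2, cfg)$energy) / (2 * h)
    expect_equal(fd, p$forces[probe[1], probe[2]],
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
  expect_error(pt$f(9.5), "outside")
  expect_error(pair_interp_config(2, 1, 0.5, pt), "ra < rb")
  expect_error(read_pair_table(cbind(c(0, 1, 3), c(0, 0, 0))), "evenly")
})

test_that("force work along a path integrates to the energy difference", {
  # energy-conservation proxy: trapezoid quadrature of F . dr on a linear
  # path between two configurations
  m <- small_model("se_e2_a")
  fr <- tiny_frame(8L, seed = 131L)
  set.seed(14)
  delta <- matrix(rnorm(24, sd = 0.08), 8, 3)
  nstep <- 100L
  work <- 0
  prev <- NULL
  for (k in 0:nstep) {
    fk <- fr; fk$coords <- fr$coords + (k / nstep) * delta
    Fk <- predict_frame(m, fk)$forces
    fdot <- sum(Fk * delta) / nstep
    if (!is.null(prev)) work <- work + (fdot + prev) / 2
    prev <- fdot
  }
  e0 <- total_energy(m, fr)
  f1 <- fr; f1$coords <- fr$coords + delta
  e1 <- total_energy(m, f1)
  expect_lt(abs(work + (e1 - e0)),
            1e-4 * max(abs(e1 - e0), abs(work), 1e-4))
})
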