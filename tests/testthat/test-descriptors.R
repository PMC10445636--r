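# Descriptor families: symmetry invariances, zero-padding exactness,
# species routing, smoothness at the cutoff and hybrid composition.

desc_of <- function(model, frame) {
  fw <- deeppotr:::model_forward(model, frame)
  deeppotr:::ad_value(fw$tape, fw$D)
}

test_that("smooth descriptors are invariant under translation, rotation and permutation", {
  set.seed(21)
  kinds <- list(c("se_e2_a", "pair"), c("se_e2_a", "type_embed"),
                c("se_e2_r", "pair"), c("se_e3", "pair"),
                c("se_atten", "type_embed"), c("hybrid", "pair"))
  for (kk in kinds) {
    m <- small_model(kk[1], nt = 2L, routing = kk[2])
    for (rep in 1:4) {
      fr <- tiny_frame(12L, seed = 100L + rep, nt = 2L)
      d0 <- desc_of(m, fr)
      expect_lt(max(abs(desc_of(m, translate_frame(fr, rnorm(3))) - d0)),
                1e-12)
      expect_lt(max(abs(desc_of(m, rotate_frame(fr, rand_rotation())) - d0)),
                1e-12)
      # permute atoms within each species
      pp <- seq_len(12L)
      for (sp in 0:1) {
        idx <- which(fr$species == sp)
        pp[idx] <- sample(idx)
      }
      fp <- fr; fp$coords <- fr$coords[pp, ]
      expect_lt(max(abs(desc_of(m, fp)[order(pp), ] - d0)), 1e-12)
    }
  }
})

test_that("empty neighborhoods give exactly zero full-mode descriptors", {
  m <- small_model("se_e2_a")
  # dilute gas: all atoms far apart in an open box
  fr <- dp_frame(rep(0L, 3), rbind(c(0, 0, 0), c(30, 0, 0), c(0, 40, 0)))
  expect_equal(max(abs(desc_of(m, fr))), 0)
  m3 <- small_model("se_e3")
  expect_equal(max(abs(desc_of(m3, fr))), 0)
  # and the atomic energies then equal the single-atom baseline
  e <- atomic_energy(m, fr)
  expect_equal(e[1], e[2])
  expect_equal(e[1], e[3])
})

test_that("descriptors are continuous as a neighbor crosses the cutoff", {
  m <- small_model("se_e2_a")
  mr <- small_model("se_e2_r")
  base <- dp_frame(rep(0L, 3), rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5.5, 0)))
  probe <- function(model, eps) {
    fr <- base
    fr$coords[3, 2] <- 5.5 + eps
    desc_of(model, fr)
  }
  for (model in list(m, mr)) {
    eps <- c(1e-2, 1e-3, 1e-4)
    jump <- vapply(eps, function(e)
      max(abs(probe(model, e) - probe(model, -e))), 0)
    expect_true(all(diff(jump) < 0))
    expect_lt(jump[3], 1e-8)
  }
})

test_that("species routing allocates the documented number of networks", {
  p2 <- deeppotr:::init_desc_params(small_desc("se_e2_a", nt = 2L), 2L)
  expect_length(p2$emb, 2L)                  # Nt x Nt per-pair nets
  expect_length(p2$emb[[1]], 2L)
  pn <- deeppotr:::init_desc_params(
    small_desc("se_e2_a", nt = 2L, routing = "neighbor"), 2L)
  expect_length(pn$emb, 2L)                  # Nt per-neighbor nets
  expect_s3_class(pn$emb[[1]], "dp_network")
  p1 <- deeppotr:::init_desc_params(small_desc("se_e2_a", nt = 1L), 1L)
  expect_length(p1$emb, 1L)
  # type embedding: one shared network however many species
  cfg57 <- descriptor_config("se_e2_a", sel = 4L, neuron = c(4L, 8L),
                             axis_neuron = 2L, routing = "type_embed")
  p57 <- deeppotr:::init_desc_params(cfg57, 57L, te_dim = 4L)
  expect_s3_class(p57$emb, "dp_network")
  expect_equal(p57$emb$n_in, 1L + 2L * 4L)
  # routing accessor agrees
  expect_identical(route_species(p2, small_desc("se_e2_a", nt = 2L), 0L, 1L),
                   p2$emb[[1]][[2]])
  expect_identical(route_species(pn,
    small_desc("se_e2_a", nt = 2L, routing = "neighbor"), 0L, 1L),
    pn$emb[[2]])
})

test_that("three-body angles are symmetric and the descriptor rotation-invariant", {
  fr <- tiny_frame(8L, seed = 31L)
  nl <- build_neighbor_list(fr, 5.5, 16L)
  env <- env_matrix(nl, 2.0, 5.5)
  rows <- which(env$index[1, ] >= 0L)
  R <- env$R[[1]][rows, , drop = FALSE]
  theta <- R %*% t(R)
  expect_equal(theta, t(theta), tolerance = 1e-15)
})

test_that("hybrid concatenates children and reduces to its only child", {
  nt <- 1L
  c1 <- small_desc("se_e2_a", nt)
  c2 <- small_desc("se_e2_r", nt)
  hy <- descriptor_config("hybrid", children = list(c1, c2))
  expect_equal(desc_dim(hy, nt), desc_dim(c1, nt) + desc_dim(c2, nt))
  fr <- tiny_frame(10L, seed = 41L)
  m1 <- energy_model("A", c1, fitting_config(neuron = c(8L, 8L)), seed = 2L)
  mh1 <- energy_model("A", descriptor_config("hybrid", children = list(c1)),
                      fitting_config(neuron = c(8L, 8L)), seed = 2L)
  expect_equal(desc_of(mh1, fr), desc_of(m1, fr), tolerance = 1e-14)
  expect_error(descriptor_config("hybrid", children = list()), "child")
})

test_that("local-frame descriptor rows and documented non-smoothness", {
  # two-atom pair along +x at distance d: first row is (1/d, 1/d, 0, 0)
  d <- 2.5
  fr3 <- dp_frame(rep(0L, 3),
                  rbind(c(0, 0, 0), c(d, 0, 0), c(0.3, 3.9, 0)))
  cfg <- descriptor_config("loc_frame", rcut = 5.5, rcut_smth = 2.0,
                           sel = 4L)
  m <- energy_model("A", cfg, fitting_config(neuron = c(8L, 8L)), seed = 3L)
  fw <- deeppotr:::model_forward(m, fr3)
  D <- deeppotr:::ad_value(fw$tape, fw$D)
  expect_equal(D[1, 1:2], c(1 / d, 1 / d), tolerance = 1e-12)
  expect_equal(D[1, 3:4], c(0, 0), tolerance = 1e-12)
  # exchanging the ranking of the two nearest neighbors jumps the
  # descriptor: the documented non-smoothness of the local frame
  v3 <- c(0.4, 2.0, 0.3) / sqrt(sum(c(0.4, 2.0, 0.3)^2))
  at_eps <- function(eps) {
    fr4 <- dp_frame(rep(0L, 4),
                    rbind(c(0, 0, 0), c(2, 0, 0), (2 + eps) * v3,
                          c(1.5, 1.5, 1.2)))
    desc_of(m, fr4)
  }
  jump <- max(abs(at_eps(1e-8)[1, ] - at_eps(-1e-8)[1, ]))
  expect_gt(jump, 1e-3)
  expect_error(desc_of(m, dp_frame(c(0L, 0L), rbind(c(0, 0, 0), c(2, 0, 0)))),
               "2 neighbors")
})

test_that("attention weights are gated row-stochastically before gating", {
  # with the value map zeroed, attention contributes nothing and the
  # residual keeps the two-body embedding
  m <- small_model("se_atten", nt = 1L, routing = "type_embed")
  fr <- tiny_frame(8L, seed = 51L)
  d0 <- desc_of(m, fr)
  mz <- m
  for (l in seq_along(mz$params$desc$attn)) {
    mz$params$desc$attn[[l]]$wv[] <- 0
    mz$params$desc$attn[[l]]$bv[] <- 0
    mz$params$desc$attn[[l]]$ln_g[] <- 0   # layer norm of 0 stays 0
    mz$params$desc$attn[[l]]$ln_b[] <- 0
  }
  m2 <- small_model("se_e2_a", nt = 1L, routing = "type_embed", seed = 4L)
  # same embedding parameters: copy them over so only attention differs
  m2$params$desc$emb <- mz$params$desc$emb
  m2$params$te <- mz$params$te
  m2$params$fit <- mz$params$fit
  expect_equal(desc_of(mz, fr), desc_of(m2, fr), tolerance = 1e-12)
  expect_error(descriptor_config("se_atten", attn_layer = 0L), "attn_layer")
})
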