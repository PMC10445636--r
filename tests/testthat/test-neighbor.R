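# Neighbor lists against a brute-force pair scan, the 64-bit sort key
# against a lexicographic oracle, the switching function and its
# derivatives, environment matrices and the local frame.

test_that("switching function branches and continuity", {
  expect_equal(switch_fn(2.0, 1.0, 2.0), 0)          # zero at the cutoff
  expect_equal(switch_fn(0.25, 0.5, 1.0), 4.0)        # 1/r branch
  expect_equal(switch_fn(1.5, 1.0, 2.0), 1 / 3)       # hand-evaluated quintic
  expect_error(switch_fn(0, 1, 2), "singular")
  expect_error(switch_fn(1, 2, 1), "rs < rc")
  # value and first two derivatives continuous at rs and rc
  set.seed(2)
  rs <- 1.3; rc <- 2.7
  eps <- 10^seq(-3, -6)
  for (r0 in c(rs, rc)) for (d in 0:2) {
    jump <- abs(switch_fn(r0 + eps, rs, rc, d) - switch_fn(r0 - eps, rs, rc, d))
    expect_lt(jump[length(eps)], 1e-4)
    expect_true(all(diff(jump) <= 1e-8))   # shrinks with eps
  }
  # derivatives match central differences at random radii
  r <- runif(1000, 0.3, 3.2)
  h <- 1e-5
  fd1 <- (switch_fn(r + h, rs, rc) - switch_fn(r - h, rs, rc)) / (2 * h)
  expect_lt(max(abs(fd1 - switch_fn(r, rs, rc, 1L))), 1e-6)
})

test_that("the 64-bit sort key packs fields and orders lexicographically", {
  expect_equal(neighbor_sort_key(2L, 1.5, 7L), 2015000000000007)
  expect_equal(neighbor_sort_key(0L, 0.0, 0L), 0)
  expect_identical(neighbor_sort_key(9000L, 91.9, 99999L, as = "character"),
                   "9000919000000099999")
  expect_error(neighbor_sort_key(9223L, 1, 1), "species")
  expect_error(neighbor_sort_key(1L, 93, 1), "distance")
  expect_error(neighbor_sort_key(1L, 1, 100000L), "atom index")
  set.seed(4)
  n <- 1000L
  alpha <- sample(0:9222, n, replace = TRUE)
  r <- runif(n, 0, 91.99)
  j <- sample(0:99999, n, replace = TRUE)
  oracle <- order(alpha, floor(r * 1e8), j)
  expect_identical(deeppotr:::sort_key_order(alpha, r, j), oracle)
})

test_that("neighbor list equals the brute-force pair scan", {
  set.seed(5)
  for (rep in 1:6) {
    pbc <- rep %% 2 == 0
    n <- sample(8:32, 1)
    cell <- if (pbc) diag(3) * runif(1, 9, 14)
    coords <- if (pbc) matrix(runif(3 * n), n, 3) %*% cell
    else matrix(runif(3 * n, 0, 8), n, 3)
    fr <- dp_frame(rep(0L, n), coords, cell)
    rc <- if (pbc) 0.45 * min(diag(cell)) else 4.0
    nl <- build_neighbor_list(fr, rc)
    # brute force over all ordered pairs (minimum image when periodic)
    got <- split(nl$j, nl$i)
    for (i in seq_len(n)) {
      d <- coords[-i, , drop = FALSE] -
        matrix(coords[i, ], n - 1L, 3, byrow = TRUE)
      if (pbc) {
        s <- d %*% solve(cell)
        d <- (s - round(s)) %*% cell
      }
      expected <- sort(((1:n)[-i])[sqrt(rowSums(d^2)) < rc])
      expect_identical(sort(got[[as.character(i)]] %||% integer(0)),
                       as.integer(expected))
    }
  }
})

test_that("minimum image finds wrapped neighbors and guards its validity", {
  fr <- dp_frame(c(0L, 0L), rbind(c(0, 0, 0), c(9.5, 0, 0)), diag(3) * 10)
  nl <- build_neighbor_list(fr, 1.0)
  expect_equal(nl$dist, c(0.5, 0.5))
  expect_equal(nl$rvec[1, ], c(-0.5, 0, 0))
  expect_error(build_neighbor_list(fr, 5.5), "minimum-image")
  # two open atoms 1 A apart with rc = 2 list each other
  fo <- dp_frame(c(0L, 0L), rbind(c(0, 0, 0), c(1, 0, 0)))
  nlo <- build_neighbor_list(fo, 2.0)
  expect_identical(nlo$j, c(2L, 1L))
})

test_that("species blocks are ordered and truncation keeps the nearest", {
  set.seed(6)
  fr <- tiny_frame(14L, nt = 2L)
  nl <- build_neighbor_list(fr, 5.5, c(16L, 16L))
  for (a in seq_len(fr$n_atoms)) {
    rows <- deeppotr:::nl_rows(nl, a)
    if (length(rows) < 2L) next
    key <- neighbor_sort_key(nl$alpha_j[rows], nl$dist[rows],
                             nl$j[rows] - 1L)
    expect_true(all(diff(key) > 0))
  }
  # block offsets partition each atom's sorted list by species
  for (a in seq_len(fr$n_atoms)) {
    bl <- neighbor_species_blocks(nl, a)
    rows <- deeppotr:::nl_rows(nl, a)
    if (nrow(bl) == 0L) next
    expect_equal(bl$end[nrow(bl)], length(rows))
    for (k in seq_len(nrow(bl)))
      expect_true(all(nl$alpha_j[rows[bl$start[k]:bl$end[k]]] ==
                        bl$species[k]))
    expect_true(all(diff(bl$species) > 0))
  }
  expect_warning(build_neighbor_list(fr, 5.5, c(2L, 2L)), "truncated")
  nt <- suppressWarnings(build_neighbor_list(fr, 5.5, c(2L, 2L)))
  for (a in seq_len(fr$n_atoms))
    expect_lte(length(deeppotr:::nl_rows(nt, a)), 4L)
})

test_that("environment matrix rows follow s * (1, x/r, y/r, z/r) with zero padding", {
  # single neighbor along +x
  fr <- dp_frame(c(0L, 0L), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  nl <- build_neighbor_list(fr, 2.0, 4L)
  env <- env_matrix(nl, 1.0, 2.0)
  sigma <- switch_fn(1.5, 1.0, 2.0)
  expect_equal(env$R[[1]][1, ], c(sigma, sigma, 0, 0))
  expect_equal(env$R[[1]][2:4, ], matrix(0, 3, 4))   # padded slots
  expect_equal(env$index[1, ], c(1L, -1L, -1L, -1L))
  # neighbor exactly at the cutoff gives a zero row
  fc <- dp_frame(c(0L, 0L), rbind(c(0, 0, 0), c(2.0 - 1e-12, 0, 0)))
  nlc <- build_neighbor_list(fc, 2.0, 4L)
  expect_lt(max(abs(env_matrix(nlc, 1.0, 2.0)$R[[1]][1, ])), 1e-11)
  # radial mode keeps only s
  expect_equal(env_matrix(nl, 1.0, 2.0, mode = "radial")$R[[1]][1, 1], sigma)
})

test_that("local frame is orthonormal, puts a(i) on +x, and cancels rotations", {
  set.seed(8)
  fr <- tiny_frame(10L, seed = 3L)
  nl <- build_neighbor_list(fr, 5.5)
  lf <- local_frame(nl, 1L)
  R <- lf$rotation
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # the first axis atom maps onto the local +x axis
  ra <- fr$coords[1, ] - fr$coords[lf$axis_atoms[1], ]
  d <- nl$rvec[deeppotr:::nl_rows(nl, 1L), , drop = FALSE]
  a_row <- which(nl$j[deeppotr:::nl_rows(nl, 1L)] == lf$axis_atoms[1])
  loc <- (-d[a_row, ]) %*% t(R)
  expect_equal(loc[2:3], c(0, 0), tolerance = 1e-12)
  expect_gt(loc[1], 0)
  # rotated coordinates are invariant under a global rotation
  u <- rand_rotation()
  fr2 <- rotate_frame(fr, u)
  nl2 <- build_neighbor_list(fr2, 5.5)
  lf2 <- local_frame(nl2, 1L)
  rows <- deeppotr:::nl_rows(nl, 1L)
  rows2 <- deeppotr:::nl_rows(nl2, 1L)
  expect_identical(nl$j[rows], nl2$j[rows2])
  loc1 <- (-nl$rvec[rows, , drop = FALSE]) %*% t(lf$rotation)
  loc2 <- (-nl2$rvec[rows2, , drop = FALSE]) %*% t(lf2$rotation)
  expect_equal(loc1, loc2, tolerance = 1e-10)
  # errors: fewer than two neighbors, collinear axis atoms
  f1 <- dp_frame(c(0L, 0L), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(local_frame(build_neighbor_list(f1, 2), 1L), "2 neighbors")
  f2 <- dp_frame(rep(0L, 3), rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(local_frame(build_neighbor_list(f2, 3), 1L), "collinear")
})
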