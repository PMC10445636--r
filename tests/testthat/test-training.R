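# Trainer algebra, composite loss, optimization contracts, multi-task
# sharing, ensemble deviation and candidate selection.

test_that("learning-rate schedule follows the floor-decay algebra", {
  sch <- lr_schedule(1e-2, 1e-4, decay_steps = 50L, stop_steps = 1000L)
  expect_equal(lr_at(0L, sch), 1e-2)
  expect_equal(lr_at(1000L, sch), 1e-4, tolerance = 1e-12)  # s | tau_stop
  # piecewise constant within each decay window
  expect_equal(lr_at(0:49, sch), rep(1e-2, 50))
  expect_equal(lr_at(50L, sch), lr_at(99L, sch))
  expect_gt(lr_at(49L, sch), lr_at(50L, sch))
  # gamma non-increasing, log-linear over window starts
  taus <- seq(0L, 1000L, by = 50L)
  g <- lr_at(taus, sch)
  expect_true(all(diff(g) < 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], length(g) - 1L),
               tolerance = 1e-12)
  expect_error(lr_schedule(1e-3, 1e-2), "stop_lr")
})

test_that("prefactors interpolate between start and limit with weight gamma/gamma0", {
  sch <- lr_schedule(1e-2, 1e-6, decay_steps = 10L, stop_steps = 200L)
  expect_equal(loss_prefactor(0L, 0.02, 1, sch), 0.02)
  w <- lr_at(120L, sch) / 1e-2
  expect_equal(loss_prefactor(120L, 0.02, 1, sch), 1 * (1 - w) + 0.02 * w)
  # the gamma -> 0 limit approaches p_limit
  sch2 <- lr_schedule(1e-2, 1e-12, decay_steps = 1L, stop_steps = 100L)
  expect_equal(loss_prefactor(100L, 0.02, 1, sch2), 1, tolerance = 1e-9)
})

test_that("the composite loss reproduces hand-evaluated cases", {
  m <- small_model("se_e2_a", seed = 8L)
  fr <- tiny_frame(2L, seed = 151L)
  pred <- predict_frame(m, fr)
  # single frame, N = 2, energy error forced to 1 eV, only-energy loss
  lab <- dp_labels(energy = pred$energy - 1, force = pred$forces,
                   virial = pred$virial)
  sch <- lr_schedule()
  spec <- loss_spec(start_pref_e = 1, limit_pref_e = 1,
                    start_pref_f = 0, limit_pref_f = 0)
  l <- compute_loss(m, list(list(frame = fr, labels = lab)), spec, sch, 0L)
  expect_equal(l$total, 0.5)               # (1 eV)^2 / N with N = 2
  expect_equal(unname(l$breakdown["e"]), 0.5)
  # perfect predictions give exactly zero loss
  lab0 <- dp_labels(energy = pred$energy, force = pred$forces,
                    virial = pred$virial)
  l0 <- compute_loss(m, list(list(frame = fr, labels = lab0)),
                     loss_spec(start_pref_v = 1, limit_pref_v = 1), sch, 0L)
  expect_equal(l0$total, 0)
  # relative force loss stays finite at F* = 0 (protection constant)
  labz <- dp_labels(energy = pred$energy, force = pred$forces * 0)
  nu <- 0.01
  lr <- compute_loss(m, list(list(frame = fr, labels = labz)),
                     loss_spec(start_pref_e = 0, limit_pref_e = 0,
                               start_pref_f = 1, limit_pref_f = 1,
                               relative_f = nu), sch, 0L)
  expect_equal(unname(lr$breakdown["f"]),
               sum((pred$forces / nu)^2) / (3 * fr$n_atoms))
  # missing labels for an active property is a data error
  expect_error(compute_loss(m, list(list(frame = fr,
                                         labels = dp_labels(energy = 1))),
                            loss_spec(), sch, 0L), "labels")
})

test_that("the energy-difference loss pairs frames through the reference rule", {
  m <- small_model("se_e2_a", seed = 8L)
  fr <- tiny_frame(6L, seed = 181L)
  ref <- tiny_frame(6L, seed = 182L)
  de_pred <- total_energy(m, fr) - total_energy(m, ref)
  lab <- dp_labels(delta_energy = de_pred - 0.6)
  spec <- loss_spec(start_pref_e = 0, limit_pref_e = 0,
                    start_pref_f = 0, limit_pref_f = 0,
                    start_pref_de = 1, limit_pref_de = 1,
                    delta_reference = ref)
  l <- compute_loss(m, list(list(frame = fr, labels = lab)), spec,
                    lr_schedule(), 0L)
  expect_equal(l$total, 0.6^2 / 6)
  expect_error(loss_spec(start_pref_de = 1), "delta_reference")
  # training on the difference label moves parameters
  ds <- dp_system("A", list(list(frame = fr, labels = lab)))
  r <- train_model(m, ds, lr_schedule(1e-3, 1e-4, 2L, 6L), spec,
                   tau_stop = 6L, seed = 1L)
  f0 <- deeppotr:::flatten_params(deeppotr:::init_energy_bias(m, ds)$params)
  f1 <- deeppotr:::flatten_params(r$model$params)
  expect_gt(max(abs(f0[["p/fit/1/layers/1/w"]] -
                      f1[["p/fit/1/layers/1/w"]])), 0)
})

test_that("per-atom loss normalization survives exact frame duplication", {
  m <- small_model("se_e2_a", seed = 8L)
  fr <- tiny_frame(8L, seed = 161L)
  spec <- lj_spec(n_atoms = 8L)
  lab <- lj_labels(fr, spec)
  # duplicate the frame in a doubled non-interacting cell
  big <- dp_frame(rep(0L, 16L), rbind(fr$coords, fr$coords + 50),
                  NULL)
  fr_open <- dp_frame(fr$species, fr$coords, NULL)
  lab1 <- lj_labels(fr_open, spec)
  lab2 <- dp_labels(energy = 2 * lab1$energy,
                    force = rbind(lab1$force, lab1$force))
  sch <- lr_schedule()
  sp <- loss_spec(start_pref_e = 1, limit_pref_e = 1, start_pref_f = 1,
                  limit_pref_f = 1)
  l1 <- compute_loss(m, list(list(frame = fr_open, labels = lab1)), sp,
                     sch, 0L)
  l2 <- compute_loss(m, list(list(frame = big, labels = lab2)), sp, sch, 0L)
  expect_equal(l2$breakdown[["e"]], 2 * l1$breakdown[["e"]],
               tolerance = 1e-8)
  expect_equal(l2$breakdown[["f"]], l1$breakdown[["f"]], tolerance = 1e-8)
})

test_that("zero learning rate is a no-op and fixed seeds reproduce bit-exactly", {
  ds <- tiny_system(4L, n = 8L)
  m <- small_model("se_e2_a", seed = 9L)
  sch <- lr_schedule(1e-30, 1e-31, 2L, 10L)   # effectively zero
  r <- train_model(m, ds, sch, loss_spec(batch_size = 1L), tau_stop = 5L,
                   seed = 3L)
  m_bias <- deeppotr:::init_energy_bias(m, ds)
  f0 <- deeppotr:::flatten_params(m_bias$params)
  f1 <- deeppotr:::flatten_params(r$model$params)
  for (nm in names(f0))
    expect_lt(max(abs(f0[[nm]] - f1[[nm]])), 1e-25)
  # determinism: identical seeds give identical trajectories
  sch2 <- lr_schedule(1e-3, 1e-4, 5L, 20L)
  ra <- train_model(m, ds, sch2, loss_spec(batch_size = 2L), tau_stop = 20L,
                    seed = 11L)
  rb <- train_model(m, ds, sch2, loss_spec(batch_size = 2L), tau_stop = 20L,
                    seed = 11L)
  expect_identical(ra$history$loss, rb$history$loss)
  fa <- deeppotr:::flatten_params(ra$model$params)
  fb <- deeppotr:::flatten_params(rb$model$params)
  for (nm in names(fa)) expect_identical(fa[[nm]], fb[[nm]])
})

test_that("training reduces the loss on a small system", {
  ds <- tiny_system(10L, n = 10L)
  m <- energy_model("A", small_desc("se_e2_a"),
                    fitting_config(neuron = c(12L, 12L)), seed = 12L)
  r <- train_model(m, ds, lr_schedule(5e-3, 1e-4, 30L, 300L),
                   loss_spec(batch_size = 2L), tau_stop = 300L, seed = 5L,
                   disp_freq = 299L)
  expect_lt(r$history$loss[nrow(r$history)], r$history$loss[1L])
})

test_that("multi-task training shares the descriptor and isolates fitting nets", {
  ds1 <- tiny_system(4L, n = 8L, seed = 21L)
  ds2 <- tiny_system(4L, n = 8L, seed = 22L)
  m1 <- small_model("se_e2_a", seed = 30L)
  m2 <- small_model("se_e2_a", seed = 31L)
  m2$params$desc <- m1$params$desc        # start from the shared descriptor
  before_fit2 <- deeppotr:::flatten_params(m2$params$fit)
  r <- train_multitask(list(m1, m2), list(ds1, ds2),
                       lr_schedule(1e-3, 1e-4, 5L, 40L),
                       loss_spec(batch_size = 1L), tau_stop = 40L,
                       seed = 13L)
  # descriptors are identical across tasks after training, and changed
  d1 <- deeppotr:::flatten_params(r$models[[1]]$params$desc)
  d2 <- deeppotr:::flatten_params(r$models[[2]]$params$desc)
  for (nm in names(d1)) expect_identical(d1[[nm]], d2[[nm]])
  d0 <- deeppotr:::flatten_params(m1$params$desc)
  expect_gt(max(abs(d0[[1]] - d1[[1]])), 0)
  # a task's fitting net is untouched by the other task's steps
  expect_true(any(r$history$task == 1L) && any(r$history$task == 2L))
  # gradient isolation: task-1 loss has zero gradient w.r.t. task-2 fit
  fg <- deeppotr:::frame_grad(m1, ds1$frames[[1]],
                              deeppotr:::precompute_nls(m1,
                                ds1$frames[1])[[1]],
                              1, 1, 0, loss_spec())
  expect_false(any(grepl("^p/fit2", names(fg$grad))))
  expect_error(train_multitask(list(m1), list(ds1)), ">= 2 tasks")
})

test_that("ensemble deviation: zero for duplicates, hand case, relative protection", {
  m <- small_model("se_e2_a", seed = 40L)
  fr <- tiny_frame(6L, seed = 171L)
  sys <- list(list(frame = fr))
  dv <- model_deviation(list(m, m, m), sys)
  expect_equal(max(dv$frames[[1]]$eps_f), 0)
  expect_equal(max(dv$frames[[1]]$eps_v), 0)
  # permutation over models is irrelevant
  m2 <- small_model("se_e2_a", seed = 41L)
  a <- model_deviation(list(m, m2), sys)$frames[[1]]$eps_f
  b <- model_deviation(list(m2, m), sys)$frames[[1]]$eps_f
  expect_equal(a, b, tolerance = 1e-14)
  # two-model hand example: forces (1,0,0) vs (3,0,0) -> eps_F = 1
  Fs <- list(matrix(c(1, 0, 0), 1, 3), matrix(c(3, 0, 0), 1, 3))
  Fbar <- (Fs[[1]] + Fs[[2]]) / 2
  eps <- sqrt(mean(sapply(Fs, function(f) sum((f - Fbar)^2))))
  expect_equal(eps, 1)
  # relative deviation with a zero ensemble mean equals eps / nu
  nu <- 0.01
  Fs0 <- list(matrix(c(1, 0, 0), 1, 3), matrix(c(-1, 0, 0), 1, 3))
  Fbar0 <- (Fs0[[1]] + Fs0[[2]]) / 2
  eps0 <- sqrt(mean(sapply(Fs0, function(f) sum((f - Fbar0)^2))))
  expect_equal(eps0 / (sqrt(sum(Fbar0^2)) + nu), eps0 / nu)
  expect_error(model_deviation(list(m), sys), ">= 2")
})

test_that("candidate selection applies the interval rule and accuracy ratio", {
  sel <- select_candidates(c(0.05, 0.12, 0.30), 0.10, 0.25)
  expect_identical(sel$candidates, 2L)
  expect_equal(sel$accurate_ratio, 1 / 3)
  # theta_low = 0: every frame below theta_high is a candidate
  s2 <- select_candidates(c(0.05, 0.12, 0.30), 0, 0.25)
  expect_identical(s2$candidates, c(1L, 2L))
  expect_equal(s2$accurate_ratio, 0)
  s3 <- select_candidates(numeric(0), 0.1, 0.25)
  expect_identical(s3$candidates, integer(0))
  expect_null(s3$accurate_ratio)
  # default upper threshold sits 0.15 above the lower
  s4 <- select_candidates(c(0.2, 0.26), 0.12)
  expect_identical(s4$candidates, c(1L, 2L))
  expect_error(select_candidates(1, 0.3, 0.2), "theta_low")
})
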