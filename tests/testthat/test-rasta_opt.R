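test_that("schedule profiles satisfy their constraints", {
  sc <- anneal_schedule(1000, sigma0 = 3, eta0 = 1e-3, eta1 = 1e-4)
  sig <- vapply(0:999, function(t) sigma_at(sc, t), numeric(1))
  expect_true(all(diff(sig) <= 0))
  expect_equal(sig[sc$t_anneal + 1], 0)
  eta <- vapply(0:999, function(t) eta_at(sc, t), numeric(1))
  expect_true(all(eta > 0))
  expect_equal(eta[1], 1e-3)
  expect_equal(eta[1000], 1e-4, tolerance = 1e-10)
  expect_true(beta_at(sc, 5) >= 0 && beta_at(sc, 5) < 1)
  # power profile still hits 0 and is nonincreasing
  sc2 <- anneal_schedule(100, sigma0 = 2, sigma_power = 2, t_anneal = 80)
  s2 <- vapply(0:99, function(t) sigma_at(sc2, t), numeric(1))
  expect_true(all(diff(s2) <= 0))
  expect_equal(s2[81], 0)
})

test_that("photon thinning: identity, emptying limit, binomial rate", {
  beam <- toy_beam()
  set.seed(1)
  kt <- runif(200, 0.1, 2.5); phi <- runif(200, 0, 2 * pi)
  img <- rasta:::scattering_image(cbind(kt * cos(phi), kt * sin(phi)))
  expect_identical(thin_image(img, 0, beam$k_in), img)
  set.seed(2)
  expect_equal(nrow(thin_image(img, 1e4, beam$k_in)$photons), 0L)

  # kept fraction at fixed |k| within 3 binomial SEs of exp(-sigma^2 k^2)
  q0 <- 1.2; s_ <- 0.8
  kt0 <- sqrt(q0^2 - q0^4 / (4 * beam$k_in^2))
  n <- 1e5
  set.seed(3)
  ang <- runif(n, 0, 2 * pi)
  big <- rasta:::scattering_image(cbind(kt0 * cos(ang), kt0 * sin(ang)))
  p <- exp(-s_^2 * q0^2)
  kept <- nrow(thin_image(big, s_, beam$k_in)$photons)
  expect_lt(abs(kept / n - p), 3 * sqrt(p * (1 - p) / n))

  # order preserved
  set.seed(4)
  th <- thin_image(img, 0.5, beam$k_in)
  idx <- match(asplit(th$photons, 1), asplit(img$photons, 1))
  expect_true(all(diff(idx) > 0))
})

test_that("rasta_step arithmetic matches the momentum update equations", {
  m <- random_model(2, seed = 5, spread = 3)
  beam <- calibrated_beam(m, 20)
  quad <- toy_quad(8); grid <- toy_grid(beam, 12, 12)
  iset <- simulate_imageset(m, beam, 10, seed = 6)
  pp <- prior_params()
  st0 <- optimizer_state(m, velocity = matrix(0.05, 2, 3))
  # sigma = 0: no thinning RNG; gradient is deterministic
  g <- grad_log_likelihood(iset$images, m, quad, grid, beam)$gradient *
    (10 / 10) + grad_log_prior(m, pp)
  eta <- 3e-4; beta <- 0.7
  st1 <- rasta_step(st0, iset$images, 0, eta, beta, quad, grid, beam,
                    prior = pp, n_total = 10)
  v_expect <- beta * st0$velocity + g
  expect_equal(st1$velocity, v_expect, tolerance = 1e-12)
  expect_equal(st1$model$positions, m$positions + eta * v_expect,
               tolerance = 1e-12)
  expect_equal(st1$t, 1L)

  # eta = 0, beta = 0: positions unchanged, velocity = gradient
  st2 <- rasta_step(st0, iset$images, 0, 0, 0, quad, grid, beam,
                    prior = pp, n_total = 10)
  expect_equal(st2$model$positions, m$positions)
  expect_equal(st2$velocity, g, tolerance = 1e-12)

  expect_error(rasta_step(st0, list(), 0, eta, beta, quad, grid, beam),
               "nonempty")
})

test_that("run_rasta: T = 0, reproducibility, metrics, checkpoints", {
  m <- random_model(3, seed = 7, spread = 2)
  beam <- calibrated_beam(m, 20)
  quad <- toy_quad(8); grid <- toy_grid(beam, 12, 12)
  iset <- simulate_imageset(m, beam, 40, seed = 8)

  sc0 <- anneal_schedule(0, batch_size = 10)
  expect_equal(run_rasta(iset, m, sc0, quad, grid)$model, m)

  sc <- anneal_schedule(30, sigma0 = 2, t_anneal = 20, eta0 = 1e-4,
                        eta1 = 1e-5, batch_size = 10, seed = 99)
  f1 <- run_rasta(iset, m, sc, quad, grid, checkpoint_sigmas = c(1, 0.5))
  f2 <- run_rasta(iset, m, sc, quad, grid, checkpoint_sigmas = c(1, 0.5))
  expect_identical(f1$model, f2$model)
  expect_equal(nrow(f1$metrics), 30)
  expect_true(all(is.finite(f1$metrics$loglik)))
  expect_named(f1$checkpoints, c("sigma_1", "sigma_0.5"))
  expect_equal(f1$provenance$n_images, 40)
})

test_that("no information loss: every photon is eventually used at sigma > 0", {
  beam <- toy_beam()
  set.seed(9)
  kt <- runif(300, 0.05, 2.9); phi <- runif(300, 0, 2 * pi)
  img <- rasta:::scattering_image(cbind(kt * cos(phi), kt * sin(phi)))
  seen <- rep(FALSE, 300)
  set.seed(10)
  for (step in 1:200) {
    th <- thin_image(img, 0.5, beam$k_in)
    idx <- match(asplit(th$photons, 1), asplit(img$photons, 1))
    seen[idx] <- TRUE
  }
  expect_true(all(seen))
})

test_that("two-bead separation recovery and posterior improvement", {
  truth <- make_toy_molecule("two-bead", spacing = 6)
  beam <- calibrated_beam(truth, 30)
  quad <- toy_quad(32); grid <- toy_grid(beam)
  iset <- simulate_imageset(truth, beam, 2000, seed = 11)
  init <- random_init_model(2, rg = 2, seed = 12)
  sc <- anneal_schedule(300, sigma0 = 2, t_anneal = 220, eta0 = 5e-4,
                        eta1 = 5e-5, batch_size = 128, clip_norm = 500,
                        seed = 13)
  fit <- run_rasta(iset, init, sc, quad, grid, prior = prior_params())
  sep <- dist(fit$model$positions)[1]
  expect_lt(abs(sep - 6), 0.3)

  # held-out log-posterior increased over the run (trend, not per-step)
  held <- iset$images[1:400]
  ll0 <- log_likelihood_batch(held, init, quad, grid, beam)$total +
    log_prior(init, prior_params())
  ll1 <- log_likelihood_batch(held, fit$model, quad, grid, beam)$total +
    log_prior(fit$model, prior_params())
  expect_gt(ll1, ll0)
})
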