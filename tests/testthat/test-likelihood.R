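test_that("intensity maps match pointwise intensity calls and symmetry", {
  beam <- toy_beam()
  quad <- toy_quad(8); grid <- toy_grid(beam, 12, 10)
  m <- random_model(4, seed = 1, spread = 2)
  maps <- compute_intensity_maps(m, quad, grid)
  expect_equal(dim(maps$values), c(12, 10, 8))
  set.seed(2)
  for (i in 1:20) {
    l <- sample(8, 1); r <- sample(12, 1); s <- sample(10, 1)
    kp <- grid$centers[r + 12 * (s - 1), ] %*% t(quad$rotations[[l]])
    expect_equal(maps$values[r, s, l], intensity(m, kp))
  }
  # spherically symmetric single bead: maps constant across l and s
  b1 <- bead_model(matrix(0, 1, 3), height = 2, width = 1.1)
  mb <- compute_intensity_maps(b1, quad, grid)$values
  expect_equal(mb, array(rep(mb[, 1, 1], 80), dim = c(12, 10, 8)),
               tolerance = 1e-12)
  expect_equal(mb[, 1, 1], 4 * exp(-grid$q_mid^2 / 1.1^2))
})

test_that("lambda estimates: closed form, l-independence, scaling, zero model", {
  beam <- toy_beam()
  quad <- toy_quad(32); grid <- toy_grid(beam, 64, 32)
  b1 <- bead_model(matrix(0, 1, 3), height = 2, width = 1.2)
  lam <- estimate_lambdas(compute_intensity_maps(b1, quad, grid))
  expect_lt(diff(range(lam)), 1e-10)
  closed <- pi * 1.2^2 * 2^2 * (1 - exp(-9 / 1.2^2))  # 2 pi int I(q) q dq
  expect_lt(abs(mean(lam) / closed - 1), 1e-3)

  b2 <- bead_model(matrix(0, 1, 3), height = 4, width = 1.2)
  lam2 <- estimate_lambdas(compute_intensity_maps(b2, quad, grid))
  expect_equal(lam2, 4 * lam)

  zero <- bead_model(matrix(0, 1, 3), height = 0, width = 1)
  expect_equal(estimate_lambdas(compute_intensity_maps(zero, quad, grid)),
               rep(0, 32))
})

test_that("single-image likelihood: empty image, brute-force enumeration, shifts", {
  beam <- toy_beam(2e-6)
  quad <- toy_quad(2); grid <- toy_grid(beam, 2, 2)
  m <- random_model(3, seed = 3, spread = 2)
  maps <- compute_intensity_maps(m, quad, grid)
  lam <- estimate_lambdas(maps)

  empty <- rasta:::scattering_image(matrix(numeric(0), 0, 2))
  expect_equal(log_likelihood_image(empty, maps, beam),
               log(sum(maps$quad$weights * exp(-beam$i0_eff * lam))))

  # brute-force enumeration of the (l, s') mixture for a 2-photon image
  kt <- c(0.4, 1.9); phi <- c(0.3, 3.6)
  img <- rasta:::scattering_image(cbind(kt * cos(phi), kt * sin(phi)))
  b <- bin_photon(img$photons, grid)
  brute <- 0
  for (l in 1:2) for (sp in 0:1) {
    term <- maps$quad$weights[l] * exp(-beam$i0_eff * lam[l]) / 2
    for (i in 1:2) term <- term * maps$values[b$r[i], ((b$s[i] - 1 + sp) %% 2) + 1, l]
    brute <- brute + term
  }
  expect_equal(log_likelihood_image(img, maps, beam), log(brute),
               tolerance = 1e-12)

  # cyclic shift invariance on a finer grid
  grid2 <- toy_grid(beam, 16, 12)
  maps2 <- compute_intensity_maps(m, toy_quad(8), grid2)
  set.seed(4)
  kt <- runif(6, 0.1, 2.5); phi <- runif(6, 0, 2 * pi)
  img2 <- rasta:::scattering_image(cbind(kt * cos(phi), kt * sin(phi)))
  rot <- rasta:::scattering_image(img2$photons %*% t(rot_z(2 * pi / 12)[1:2, 1:2]))
  expect_equal(log_likelihood_image(rot, maps2, beam),
               log_likelihood_image(img2, maps2, beam), tolerance = 1e-12)
})

test_that("batch likelihood: additivity, reorder, translation and rotation symmetry", {
  m <- random_model(4, seed = 5, spread = 2)
  beam <- calibrated_beam(m, 25)
  quad <- toy_quad(32); grid <- toy_grid(beam)
  iset <- simulate_imageset(m, beam, 25, seed = 6)
  res <- log_likelihood_batch(iset, m, quad, grid, beam)
  expect_equal(res$total, sum(res$per_image))
  one <- log_likelihood_batch(iset$images[3], m, quad, grid, beam)
  expect_equal(one$total, res$per_image[3])
  perm <- sample(length(iset$images))
  expect_equal(log_likelihood_batch(iset$images[perm], m, quad, grid, beam)$total,
               res$total)

  mt <- bead_model(sweep(m$positions, 2, c(4, -7, 2), "+"), m$height, m$width)
  expect_equal(log_likelihood_batch(iset, mt, quad, grid, beam)$total, res$total,
               tolerance = 1e-10)
  set.seed(7)
  Rm <- rasta:::random_rotation()
  mr <- bead_model(m$positions %*% t(Rm), m$height, m$width)
  expect_equal(log_likelihood_batch(iset, mr, quad, grid, beam)$total, res$total,
               tolerance = 1e-2 * abs(res$total))
})

test_that("gradient matches central finite differences (mandatory oracle)", {
  for (seed in 1:2) {
    m <- random_model(4, seed = seed, spread = 1.8)
    beam <- calibrated_beam(m, 25)
    quad <- toy_quad(18); grid <- toy_grid(beam, 16, 16)
    iset <- simulate_imageset(m, beam, 20, seed = 100 + seed)
    g <- grad_log_likelihood(iset, m, quad, grid, beam)
    num <- fd_gradient(function(mod)
      log_likelihood_batch(iset$images, mod, quad, grid, beam)$total, m)
    expect_lt(max(abs(g$gradient - num) / pmax(abs(num), 1e-8)), 1e-4)
    # translation invariance => per-bead gradients sum to ~0
    expect_lt(max(abs(colSums(g$gradient))), 1e-8 * max(abs(g$gradient)))
  }
})

test_that("gradient symmetry and equivariance", {
  # spherically symmetric single bead at the origin: zero gradient
  b1 <- bead_model(matrix(0, 1, 3), height = 7, width = 1.18)
  beam <- calibrated_beam(b1, 20)
  quad <- toy_quad(18); grid <- toy_grid(beam, 16, 16)
  iset <- simulate_imageset(b1, beam, 30, seed = 8)
  g <- grad_log_likelihood(iset, b1, quad, grid, beam)
  expect_lt(max(abs(g$gradient)), 1e-8)

  # rotating model and images together about the beam axis rotates the
  # gradient; choosing the angle as a common multiple of the grid bin and the
  # quadrature azimuth spacing makes the equivariance exact (both the node
  # set and the photon binning map onto themselves)
  m <- random_model(4, seed = 9, spread = 1.8)
  beam <- calibrated_beam(m, 25)
  quad <- toy_quad(32)  # azimuth spacing pi/4; grid bin pi/8
  iset <- simulate_imageset(m, beam, 40, seed = 10)
  g0 <- grad_log_likelihood(iset, m, quad, grid, beam)$gradient
  ang <- pi / 2
  Rz <- rot_z(ang)
  mrot <- bead_model(m$positions %*% t(Rz), m$height, m$width)
  irot <- lapply(iset$images, function(im)
    rasta:::scattering_image(im$photons %*% t(Rz[1:2, 1:2])))
  g1 <- grad_log_likelihood(irot, mrot, quad, grid, beam)$gradient
  expect_equal(g1, g0 %*% t(Rz), tolerance = 1e-8)
})

test_that("generating model beats a jittered model on a large set", {
  m <- random_model(5, seed = 11, spread = 2)
  beam <- calibrated_beam(m, 25)
  quad <- toy_quad(32); grid <- toy_grid(beam)
  iset <- simulate_imageset(m, beam, 1000, seed = 12)
  set.seed(13)
  jit <- bead_model(m$positions + matrix(rnorm(15, sd = 2), 5, 3),
                    m$height, m$width)
  ll_true <- log_likelihood_batch(iset, m, quad, grid, beam)$total
  ll_jit <- log_likelihood_batch(iset, jit, quad, grid, beam)$total
  expect_gt(ll_true, ll_jit)
})

test_that("log-domain evaluation survives extreme dynamic range", {
  # 1000-photon image over intensities spanning >30 orders of magnitude
  m <- bead_model(rbind(c(0, 0, 0), c(2, 0, 0)), height = 5, width = 0.35)
  beam <- toy_beam(1e-3)
  quad <- toy_quad(8); grid <- toy_grid(beam, 24, 16)
  maps <- compute_intensity_maps(m, quad, grid)
  expect_gt(log10(max(maps$values) / min(maps$values[maps$values > 0])), 30)
  set.seed(14)
  kt <- runif(1000, 0.05, 2.35); phi <- runif(1000, 0, 2 * pi)
  img <- rasta:::scattering_image(cbind(kt * cos(phi), kt * sin(phi)))
  ll <- log_likelihood_image(img, maps, beam)
  expect_true(is.finite(ll))

  # all-zero maps: honest -Inf with warning; gradient errors out
  zero <- bead_model(matrix(0, 1, 3), height = 0, width = 1)
  mz <- compute_intensity_maps(zero, quad, grid)
  expect_warning(llz <- log_likelihood_image(img, mz, beam), "-Inf")
  expect_identical(llz, -Inf)
  expect_error(grad_log_likelihood(list(img), zero, quad, grid, beam),
               "undefined")
})
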