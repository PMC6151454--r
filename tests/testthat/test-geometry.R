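test_that("superpose recovers exact transforms and is symmetric", {
  set.seed(1)
  P <- matrix(rnorm(15, sd = 5), ncol = 3L)
  # identical sets
  fit0 <- superpose(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)
  # constructed rigid motion: rotate 90 deg about z, translate (1,2,3)
  tr <- rigid_transform(rotation_matrix(c(0, 0, 1), 90), c(1, 2, 3))
  Q <- apply_transform(tr, P)
  fit <- superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(fit$transform$translation, tr$translation, tolerance = 1e-9)
  # rmsd is symmetric in argument order
  Qn <- Q + matrix(rnorm(15, sd = 0.3), ncol = 3L)
  expect_equal(superpose(P, Qn)$rmsd, superpose(Qn, P)$rmsd,
               tolerance = 1e-9)
  # superposition never increases the rmsd
  expect_lte(superpose(P, Qn)$rmsd, sqrt(mean(rowSums((P - Qn)^2))))
})

test_that("superpose rejects degenerate input", {
  P <- matrix(rnorm(15), ncol = 3L)
  expect_error(superpose(P, P[1:4, ]), "pairing")
  expect_error(superpose(P[1:2, ], P[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose matches the rotation-grid oracle on noisy clouds", {
  set.seed(7)
  for (i in 1:5) {
    P <- matrix(rnorm(15, sd = 3), ncol = 3L)
    Q <- apply_transform(
      rigid_transform(rotation_matrix(rnorm(3), runif(1, 0, 180)),
                      rnorm(3)), P) + matrix(rnorm(15, sd = 0.5), ncol = 3L)
    expect_equal(superpose(P, Q)$rmsd, oracle_min_rmsd(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("superpose agrees with an independent library implementation", {
  set.seed(9)
  P <- matrix(rnorm(60, sd = 4), ncol = 3L)
  Q <- P + matrix(rnorm(60, sd = 0.4), ncol = 3L)
  ours <- superpose(P, Q)
  # bio3d fits mobile onto fixed via its own Kabsch path (it emits an
  # informational warning when no fitting indices are given)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                            mobile = as.vector(t(P))))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3L, byrow = TRUE) - Q)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("ensemble RMSD to mean: identical and rigidly-moved models", {
  base <- make_toy_complex(toy_complex_params())
  xyz <- rbind(base$xyz, base$xyz)
  ens <- structure_ensemble(base$atoms, xyz, id = "dup")
  st <- ensemble_rmsd_to_mean(ens, selection_spec("P", atoms = "backbone"))
  expect_equal(st$mean_rmsd, 0, tolerance = 1e-9)
  expect_equal(st$sd_rmsd, 0, tolerance = 1e-9)
  # second model rigidly moved: superposition removes the difference
  tr <- rigid_transform(rotation_matrix(c(1, 1, 0), 40), c(5, -3, 2))
  co2 <- apply_transform(tr, model_coords(base, 1L))
  ens2 <- structure_ensemble(base$atoms,
                             rbind(base$xyz, as.vector(t(co2))), "moved")
  st2 <- ensemble_rmsd_to_mean(ens2, selection_spec("P", atoms = "backbone"))
  expect_equal(st2$mean_rmsd, 0, tolerance = 1e-7)
})

test_that("ensemble RMSD matches the closed form for Gaussian noise", {
  m <- 20L
  sigma <- 0.5
  ens <- make_toy_complex(toy_complex_params(noise_sigma = sigma,
                                             n_models = m, seed = 3L))
  st <- ensemble_rmsd_to_mean(ens, selection_spec("P", atoms = "backbone"))
  expected <- sigma * sqrt(3) * sqrt((m - 1) / m)
  expect_equal(st$mean_rmsd, expected, tolerance = 0.1 * expected)
  expect_equal(st$mean_rmsd, mean(st$per_model_rmsd))
})

test_that("screw decomposition handles identity and 180-degree cases", {
  s0 <- screw_decompose(rigid_transform(diag(3), c(0, 0, 0)))
  expect_equal(s0$angle, 0)
  expect_equal(s0$translation_along_axis, 0)
  # pure translation
  st <- screw_decompose(rigid_transform(diag(3), c(3, 4, 0)))
  expect_equal(st$angle, 0)
  expect_equal(st$translation_along_axis, 5)
  s180 <- screw_decompose(
    rigid_transform(rotation_matrix(c(0, 0, 1), 180), c(0, 0, 0)))
  expect_equal(s180$angle, 180)
  expect_equal(abs(s180$axis), c(0, 0, 1))
})

test_that("screw decompose/recompose round-trips random transforms", {
  set.seed(11)
  for (i in 1:50) {
    t0 <- rigid_transform(rotation_matrix(rnorm(3), runif(1, 0.01, 179.99)),
                          rnorm(3, sd = 10))
    t1 <- screw_recompose(screw_decompose(t0))
    expect_lt(max(abs(t1$rotation - t0$rotation)), 1e-6)
    expect_lt(max(abs(t1$translation - t0$translation)), 1e-6)
  }
})
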