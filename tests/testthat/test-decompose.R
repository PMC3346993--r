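test_that("initialization is deterministic and sensible on rank-1 data", {
  one <- component_spec("only", 2.2, 0.3, rbind(c(260, 25, 1)), "analyte")
  sim <- simulate_cube(simulation_config(
    list(one), n_calibration = 4, n_prediction = 0, n_blank = 0,
    time_axis = seq(0, 5, length.out = 30),
    wavelength_axis = seq(200, 320, length.out = 20),
    calibration_conc = matrix(c(1, 2, 3, 4), 4, 1), noise_sd = 0, seed = 1))

  s1 <- init_loadings(sim$cube, fit_options(1, init = "svd"))
  s2 <- init_loadings(sim$cube, fit_options(1, init = "svd"))
  expect_identical(s1$A, s2$A)
  expect_identical(s1$C, s2$C)

  r1 <- init_loadings(sim$cube, fit_options(1, init = "random", seed = 4))
  r2 <- init_loadings(sim$cube, fit_options(1, init = "random", seed = 4))
  expect_identical(r1$A, r2$A)
  r3 <- init_loadings(sim$cube, fit_options(1, init = "random", seed = 5))
  expect_false(identical(r1$A, r3$A))

  # SVD of a noiseless rank-1 cube recovers the profiles up to sign
  expect_gt(col_cosines(s1$A, sim$truth$A), 0.999)
  expect_gt(col_cosines(s1$B, sim$truth$B), 0.999)

  expect_error(init_loadings(sim$cube, fit_options(10)), "exceeds")
})

test_that("both algorithms fit exactly trilinear data to machine accuracy", {
  sim <- two_comp_cube(seed = 5, noise_sd = 0)
  for (fitter in list(parafac_als, swatld)) {
    fit <- fitter(sim$cube, fit_options(2))
    expect_gt(fit$fit_percent, 99.999)
    al <- align_factors(fit, sim$truth$B)
    cos <- truth_cosines(al, sim$truth)
    expect_true(all(cos$A > 0.999))
    expect_true(all(cos$B > 0.999))
    expect_true(all(cos$C > 0.999))
    # unit-norm convention: scale lives in C only
    expect_equal(colSums(al$A^2), rep(1, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(colSums(al$B^2), rep(1, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("PARAFAC-ALS is monotone and accurate on noisy data", {
  sim <- coarse_paperlike(seed = 21, noise_sd = 0.01)
  fit <- parafac_als(sim$cube, fit_options(3))
  expect_true(fit$converged)
  expect_gt(fit$fit_percent, 99)
  expect_true(all(diff(fit$fit_trace) > -1e-8))
  # default constraints: physical modes nonnegative
  expect_true(all(fit$A >= 0) && all(fit$B >= 0))
})

test_that("SWATLD tolerates one excess factor", {
  # at realistic noise the excess factor spans noise space; on exactly
  # noiseless data it collapses to zero norm and trips the degeneracy guard
  sim <- two_comp_cube(seed = 6, noise_sd = 0.005)
  fit <- swatld(sim$cube, fit_options(3))
  al <- align_factors(fit, sim$truth$B)
  expect_true(all(al$analyte_correlations >= 0.99))
  cosB <- col_cosines(al$B[, 1:2], sim$truth$B)
  expect_true(all(cosB >= 0.99))
})

test_that("SWATLD and PARAFAC-ALS agree on the concentration mode", {
  sim <- paperlike_dataset(seed = 22, noise_sd = 0.005)
  opts <- fit_options(3)
  ap <- align_factors(parafac_als(sim$cube, opts), sim$truth$B[, 1:2])
  as_ <- align_factors(swatld(sim$cube, opts), sim$truth$B[, 1:2])
  for (n in 1:2) {
    rel <- sqrt(sum((ap$C[, n] - as_$C[, n])^2) / sum(ap$C[, n]^2))
    expect_lt(rel, 0.02)
  }
})

test_that("factor alignment resolves permutation and sign", {
  sim <- two_comp_cube(seed = 7, noise_sd = 0)
  fit <- parafac_als(sim$cube, fit_options(2))
  # references given in reversed order are matched back
  al <- align_factors(fit, fit$B[, 2:1])
  expect_equal(al$B[, 1], fit$B[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(al$analyte_correlations), c(1, 1), tolerance = 1e-9)

  # a sign-flipped component is flipped back (concentration column too,
  # leaving the reconstruction unchanged)
  flipped <- fit
  flipped$B[, 1] <- -flipped$B[, 1]
  flipped$C[, 1] <- -flipped$C[, 1]
  al2 <- align_factors(flipped, fit$B)
  expect_equal(al2$B, fit$B, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(reconstruct(al2), reconstruct(fit), tolerance = 1e-12)

  expect_error(align_factors(fit, fit$B[-1, ]), "wavelength grid")
})

test_that("reconstruction is consistent with the stored fit", {
  sim <- two_comp_cube(seed = 8, noise_sd = 0.005)
  fit <- parafac_als(sim$cube, fit_options(2))
  xh <- reconstruct(fit, dim(sim$cube))
  # residual norm is sqrt(IJK) * sigma relative to the signal norm
  relerr <- sqrt(sum((sim$cube$values - xh)^2) / sum(sim$cube$values^2))
  expect_lt(relerr, 0.05)
  expect_equal(explained_fit(fit, sim$cube), fit$fit_percent,
               tolerance = 1e-6)

  z <- fit; z$C[] <- 0
  expect_true(all(reconstruct(z) == 0))
  expect_error(reconstruct(fit, c(3, 3, 3)), "does not match")
})

test_that("exact noiseless fits reconstruct the cube", {
  sim <- two_comp_cube(seed = 9, noise_sd = 0)
  fit <- swatld(sim$cube, fit_options(2))
  xh <- reconstruct(fit)
  relerr <- sqrt(sum((sim$cube$values - xh)^2) / sum(sim$cube$values^2))
  expect_lt(relerr, 1e-6)
})

test_that("row-wise NNLS matches the Lawson-Hanson reference", {
  set.seed(33)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    Z <- matrix(rnorm(25 * N), 25)
    X <- matrix(rnorm(3 * 25), 3)
    G <- crossprod(Z)
    W <- X %*% Z
    mine <- trical:::nnls_rows(G, W)
    for (r in 1:3) {
      ref <- pracma::lsqnonneg(Z, X[r, ])$x
      expect_equal(unname(mine[r, ]), ref, tolerance = 1e-7)
    }
  }
})
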