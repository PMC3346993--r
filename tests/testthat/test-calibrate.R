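make_design <- function(conc, roles = NULL) {
  n <- nrow(conc)
  if (is.null(roles)) roles <- rep("calibration", n)
  calibration_design(sprintf("s%02d", seq_len(n)), roles, conc)
}

test_that("score regression recovers exact proportionality through the origin", {
  y <- c(1, 2, 3, 4, 5)
  design <- make_design(cbind(a = y))
  k <- score_regression(2 * y, design, "a")
  expect_equal(k, 2, tolerance = 1e-12)
  expect_equal((2 * y) / k, y, tolerance = 1e-12)

  # noisy scores: the coefficient stays inside the regression's own
  # standard-error band around the noiseless value
  set.seed(101)
  s <- 2 * y + rnorm(5, sd = 0.05)
  k2 <- score_regression(s, design, "a")
  se <- summary(lm(s ~ 0 + y))$coefficients[1, 2]
  expect_lt(abs(k2 - 2), 4 * se)

  expect_error(score_regression(rep(0, 5), design, "a"), "zero")
  dup <- make_design(cbind(a = rep(3, 4)))
  expect_error(score_regression(1:4, dup, "a"), "distinct")
})

test_that("rmsep reproduces the published worked examples", {
  res <- plasma_study_results()
  expect_equal(round(rmsep(res$added_vancomycin, res$swatld_vancomycin), 2),
               0.81)
  expect_equal(round(rmsep(res$added_cephalexin, res$swatld_cephalexin), 2),
               0.95)
  expect_equal(round(rmsep(res$added_vancomycin, res$parafac_vancomycin), 2),
               0.89)
  expect_equal(round(rmsep(res$added_cephalexin, res$parafac_cephalexin), 2),
               1.02)
})

test_that("rmsep has its defining algebraic properties", {
  expect_equal(rmsep(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
  expect_identical(rmsep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(rmsep(numeric(), numeric()), "empty")
  expect_error(rmsep(1:3, 1:4), "length")
  # order invariance and linear scaling
  a <- c(5, 1, 9, 4); p <- c(4.5, 1.3, 9.8, 3.6)
  o <- sample(4)
  expect_equal(rmsep(a[o], p[o]), rmsep(a, p), tolerance = 1e-12)
  expect_equal(rmsep(3 * a, 3 * p), 3 * rmsep(a, p), tolerance = 1e-12)
})

test_that("recoveries and their summary match the published rounding", {
  res <- plasma_study_results()
  rec <- function(p, a) 100 * p / a
  expect_equal(trical:::round_half_up(
    rec(res$swatld_vancomycin, res$added_vancomycin), 1)[c(1, 2, 6)],
    c(94.1, 101.9, 105.2))
  expect_equal(trical:::round_half_up(
    rec(res$swatld_cephalexin, res$added_cephalexin), 1)[3], 98.1)
  expect_equal(trical:::round_half_up(
    rec(res$parafac_vancomycin, res$added_vancomycin), 1)[1], 92.5)

  pc <- rec(res$parafac_cephalexin, res$added_cephalexin)
  expect_identical(trical:::round_half_up(mean(pc), 0), 96)
  expect_identical(trical:::round_half_up(sd(pc), 0), 3)
})

test_that("prediction reports score recoveries only where defined", {
  # synthetic aligned loadings whose C column is exactly 2x concentration
  conc <- cbind(a = c(1, 2, 3, 4, NA, NA))
  roles <- c(rep("calibration", 4), "prediction", "blank")
  design <- make_design(conc, roles)
  L <- structure(list(
    A = matrix(1, 5, 1), B = matrix(1, 4, 1),
    C = matrix(2 * c(1, 2, 3, 4, 2.5, 0), 6, 1,
               dimnames = list(NULL, "a")),
    n_components = 1L, algorithm = "parafac_als", iterations = 1L,
    fit_percent = 100, fit_trace = 100, converged = TRUE,
    analyte_names = "a", n_analytes = 1L),
    class = "LoadingSet")
  rep <- predict_concentrations(L, design)
  expect_equal(rep$k[["a"]], 2, tolerance = 1e-12)
  tab <- rep$table
  expect_equal(tab$predicted[tab$role == "prediction"], 2.5)
  expect_true(is.na(tab$recovery_percent[tab$role == "prediction"]))
  expect_equal(tab$predicted[tab$role == "blank"], 0)
})

test_that("the recovery table follows the published layout and rounding", {
  conc <- cbind(a = c(1, 2, 3, 10, 10))
  roles <- c(rep("calibration", 3), "prediction", "prediction")
  design <- make_design(conc, roles)
  L <- structure(list(
    A = matrix(1, 5, 1), B = matrix(1, 4, 1),
    C = matrix(3 * c(1, 2, 3, 9.55, 10.45), 5, 1,
               dimnames = list(NULL, "a")),
    n_components = 1L, algorithm = "swatld", iterations = 1L,
    fit_percent = 100, fit_trace = 100, converged = TRUE,
    analyte_names = "a", n_analytes = 1L), class = "LoadingSet")
  rep <- predict_concentrations(L, design)
  rt <- recovery_table(rep)
  expect_equal(rt$samples$a, c(95.5, 104.5))
  expect_equal(rt$summary$mean_recovery, 100)
  expect_equal(rt$summary$rmsep,
               trical:::round_half_up(sqrt(mean(c(0.45, 0.45)^2)), 2))

  # one prediction sample: spread undefined
  design1 <- make_design(cbind(a = c(1, 2, 3, 10)),
                         c(rep("calibration", 3), "prediction"))
  L1 <- L; L1$C <- L$C[1:4, , drop = FALSE]; L1$A <- matrix(1, 4, 1)
  rep1 <- predict_concentrations(L1, design1)
  expect_true(is.na(recovery_table(rep1)$summary$recovery_sd))

  # identical recoveries: spread exactly zero
  L0 <- L; L0$C[4:5, 1] <- 3 * c(10, 10)
  rep0 <- predict_concentrations(L0, design)
  expect_identical(recovery_table(rep0)$summary$recovery_sd, 0)
})

test_that("direct pseudo-inverse prediction has its closed forms", {
  set.seed(55)
  A <- qr.Q(qr(matrix(rnorm(30 * 2), 30)))
  B <- qr.Q(qr(matrix(rnorm(20 * 2), 20)))
  cc <- c(1.5, 0.7)
  X <- A %*% diag(cc) %*% t(B)
  expect_equal(direct_prediction(X, A, B), cc, tolerance = 1e-10)
  expect_equal(direct_prediction(0 * X, A, B), c(0, 0), tolerance = 1e-12)

  # a species missing from A and B biases the estimate beyond noise level
  extra_a <- qr.resid(qr(A), rnorm(30)); extra_a <- extra_a / sqrt(sum(extra_a^2))
  extra_b <- qr.resid(qr(B), rnorm(20)); extra_b <- extra_b / sqrt(sum(extra_b^2))
  Xbad <- X + 0.8 * tcrossprod(A[, 1] + extra_a, B[, 1] + extra_b)
  est <- direct_prediction(Xbad, A, B)
  expect_gt(max(abs(est - cc)), 0.1)

  expect_error(direct_prediction(X, cbind(A[, 1], A[, 1]), B),
               "rank-deficient")
  expect_error(direct_prediction(X[1:10, ], A, B), "shape")
})

test_that("noiseless end-to-end calibration reproduces the spiked levels", {
  sim <- coarse_paperlike(seed = 30, noise_sd = 0)
  res <- second_order_calibration(sim$cube, sim$design,
                                  sim$truth$B[, 1:2],
                                  algorithm = "swatld",
                                  options = fit_options(3, tol = 1e-12,
                                                        max_iter = 1000))
  tab <- res$prediction$table
  pred <- tab[tab$role == "prediction", ]
  expect_lt(max(abs(pred$predicted / pred$added - 1)), 5e-7)

  # alternating least squares reaches a few parts in 1e5 on the same data
  resp <- second_order_calibration(sim$cube, sim$design,
                                   sim$truth$B[, 1:2],
                                   algorithm = "parafac_als",
                                   options = fit_options(3, tol = 1e-12,
                                                         max_iter = 5000))
  tabp <- resp$prediction$table
  predp <- tabp[tabp$role == "prediction", ]
  expect_lt(max(abs(predp$predicted / predp$added - 1)), 1e-4)
})
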